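test_that("the skeleton topology carries the documented node counts", {
  topo <- skeleton_topology()
  expect_equal(topo$n_nodes, 50L)
  expect_length(topo$head_nodes, 9L)
  expect_equal(topo$plane_count, 47L)
  expect_equal(length(unique(c(topo$jhd_index, topo$jhl_index,
                               topo$jhr_index))), 3L)
  # connected: every hop distance finite; hops symmetric with zero diagonal
  expect_true(all(is.finite(topo$hops)))
  expect_equal(topo$hops, t(topo$hops))
  expect_true(all(diag(topo$hops) == 0))
  # hand joints terminate the arm chains: a single neighbour each
  deg <- table(c(topo$edges))
  expect_equal(unname(deg[as.character(topo$jhl_index)]), 1L)
  expect_equal(unname(deg[as.character(topo$jhr_index)]), 1L)
})

test_that("initialization places the head ring at the cloud's highest region", {
  sc <- cached_scene("seated_quiet")
  pc <- scene_person_cloud(sc, 15)            # standing, mid-walk
  model <- init_model(pc)
  # renderer's head centre: centroid of the minimum-depth plateau (the flat
  # top of the noise-free head disc)
  zmin <- min(pc[, 3])
  top_face <- pc[pc[, 3] <= zmin + 5, , drop = FALSE]
  centre <- c(mean(top_face[, 1]), mean(top_face[, 2]), zmin)
  ring <- model$nodes[model$topology$head_nodes, , drop = FALSE]
  d <- sqrt(rowSums(sweep(ring, 2, centre)^2))
  expect_lt(max(d), 150)
  expect_error(init_model(pc[0, , drop = FALSE]), "empty")
  expect_error(init_model(pc[1:20, , drop = FALSE]), "at least 50")
})

test_that("explicit orientations rotate the torso lattice equivariantly", {
  # compact cloud, exactly symmetric under 90-degree rotation, with no
  # forward arm mass: the lattice layout is purely geometric
  set.seed(4)
  n <- 100
  ang <- runif(n, 0, 2 * pi); rad <- sqrt(runif(n)) * 150
  z <- sample(c(rep(1200, 20), rep(1550, n - 20)))
  quarter <- cbind(rad * cos(ang), rad * sin(ang), z)
  pc <- rbind(quarter,
              cbind(-quarter[, 2], quarter[, 1], z),
              cbind(-quarter[, 1], -quarter[, 2], z),
              cbind(quarter[, 2], -quarter[, 1], z))
  class(pc) <- c("point_cloud", class(pc))
  m0 <- init_model(pc, orientation_deg = 0)
  m90 <- init_model(pc, orientation_deg = 90)
  rot <- function(p, jhd) {
    rel <- sweep(p, 2, jhd)
    cbind(-rel[, 2], rel[, 1], rel[, 3])
  }
  torso <- 11:42
  expect_equal(rot(m0$nodes[torso, ], m0$nodes[1, ]),
               cbind(sweep(m90$nodes[torso, ], 2, m90$nodes[1, ])[, 1:2],
                     sweep(m90$nodes[torso, ], 2, m90$nodes[1, ])[, 3]),
               tolerance = 1e-6)
})

test_that("fitting reaches a fixed point on a static cloud", {
  sc <- cached_scene("meal3_quiet")
  pc <- scene_person_cloud(sc, 200)
  params <- tracker_params()
  model <- init_model(pc)
  for (i in 1:25) model <- fit_frame(model, pc, params)
  again <- fit_frame(model, pc, params)
  expect_lt(max(abs(again$nodes - model$nodes)), 1)
})

test_that("fitting is translation-equivariant", {
  sc <- cached_scene("meal3_quiet")
  pc <- scene_person_cloud(sc, 200)
  params <- tracker_params()
  model <- init_model(pc)
  shift <- c(50, 0, 0)
  pc_t <- sweep(unclass(pc), 2, -shift)
  model_t <- model
  model_t$nodes <- sweep(model$nodes, 2, -shift)
  f1 <- fit_frame(model, pc, params)
  f2 <- fit_frame(model_t, pc_t, params)
  expect_equal(sweep(f2$nodes, 2, shift), f1$nodes, tolerance = 1e-8)

  # a converged model follows a 50 mm displacement of the person; discrete
  # winner reassignment can shift the re-converged equilibrium by up to
  # half the arm-chain node spacing, so the displacement is tracked within 40 mm
  for (i in 1:20) model <- fit_frame(model, pc, params)
  moved <- model
  for (i in 1:20) moved <- fit_frame(moved, pc_t, params)
  j0 <- mealscan:::joint_positions(model)
  j1 <- mealscan:::joint_positions(moved)
  for (joint in c("jhd", "jhl", "jhr"))
    expect_lt(max(abs(j1[[joint]] - (j0[[joint]] + shift))), 40)
})

test_that("fit energy never increases within a frame's passes", {
  sc <- cached_scene("meal3")
  params <- tracker_params()
  model <- NULL
  for (f in seq(120, 220, by = 10)) {
    pc <- scene_person_cloud(sc, f)
    if (is.null(model)) model <- init_model(pc)
    before <- mealscan:::cpp_fit_energy(model$nodes, unclass(pc))
    model <- fit_frame(model, pc, params)
    expect_lte(attr(model, "energy"), before + 1e-9)
    trace <- attr(model, "energy_trace")
    expect_equal(trace[1], before, tolerance = 1e-9)
    expect_lte(attr(model, "energy"), min(trace) + 1e-9)
  }
})

test_that("fitted nodes stay inside the inflated cloud bounding box", {
  sc <- cached_scene("meal3")
  model <- NULL
  params <- tracker_params()
  for (f in seq(100, 400, by = 25)) {
    pc <- scene_person_cloud(sc, f)
    if (is.null(model)) model <- init_model(pc)
    model <- fit_frame(model, pc, params)
    lo <- apply(pc, 2, min) - 100
    hi <- apply(pc, 2, max) + 100
    for (d in 1:3) {
      expect_gte(min(model$nodes[, d]), lo[d])
      expect_lte(max(model$nodes[, d]), hi[d])
    }
  }
})

test_that("fusion is declared only after a full consecutive dwell", {
  params <- tracker_params()                    # 150-frame window, 200 mm
  near <- fake_track(dl = rep(100, 150))
  expect_equal(detect_fusion(near, params), "left")
  broken <- fake_track(dl = c(rep(100, 149), 250))
  expect_equal(detect_fusion(broken, params), "none")
  far <- fake_track(dl = rep(400, 200), dr = rep(350, 200))
  expect_equal(detect_fusion(far, params), "none")
  right <- fake_track(dl = rep(400, 150), dr = rep(120, 150))
  expect_equal(detect_fusion(right, params), "right")
  short <- fake_track(dl = rep(100, 80))
  expect_equal(detect_fusion(short, params), "none")
})

test_that("a reset restores separated joints and is deterministic", {
  sc <- cached_scene("meal3_quiet")
  pc <- scene_person_cloud(sc, 250)
  params <- tracker_params()
  model <- init_model(pc)
  # collapse the hands onto the head to fake a fusion
  fused <- model
  fused$nodes[fused$jhl_index, ] <- fused$nodes[fused$jhd_index, ] + 5
  fused$nodes[fused$jhr_index, ] <- fused$nodes[fused$jhd_index, ] - 5
  fresh <- reset_model(fused, pc, params)
  j <- mealscan:::joint_positions(fresh)
  expect_gt(sqrt(sum((j$jhd - j$jhl)^2)), params$fusion_dist_mm)
  expect_gt(sqrt(sum((j$jhd - j$jhr)^2)), params$fusion_dist_mm)
  # repeated reset on the same cloud is idempotent
  expect_equal(reset_model(fused, pc, params)$nodes, fresh$nodes)
  expect_equal(reset_model(fresh, pc, params)$nodes, fresh$nodes)
})

test_that("tracking a calm meal produces no resets and a complete track", {
  sc <- cached_scene("seated_quiet")            # seated, no gestures
  tr <- track_sequence(sc$frames, sc$background, 45, 115)
  expect_equal(nrow(tr), 71L)
  expect_equal(sum(tr$reset), 0L)
  expect_false(any(tr$absent))
  expect_true(all(tr$dist_left > 200, na.rm = TRUE))
  expect_true(all(tr$dist_right > 200, na.rm = TRUE))
  expect_error(track_sequence(sc$frames, sc$background, 50, 40), "ef")
})

test_that("a hand held at the head beyond the fusion window forces a reset", {
  s <- scene_script(n_frames = 420, seed = 6, events = list(
    list(enter = 5, sit = 30, hands = 45,
         actions = list(c(80, 250)),          # > 150-frame fusion window
         stand = 400, leave = 420)))
  sc <- render_sequence(s)
  tr <- track_sequence(sc$frames, sc$background, 50, 400,
                       tracker_params(fusion_frames = 150))
  expect_gte(sum(tr$reset), 1L)
  # immediately after each reset the joints are separated
  post <- which(tr$reset)
  expect_true(all(pmin(tr$dist_left[post], tr$dist_right[post]) >= 200))
})

test_that("tracking is deterministic for identical inputs and seeds", {
  sc <- cached_scene("meal3")
  a <- track_sequence(sc$frames, sc$background, 100, 220,
                      tracker_params(seed = 5))
  b <- track_sequence(sc$frames, sc$background, 100, 220,
                      tracker_params(seed = 5))
  expect_identical(a, b)
})

test_that("the hand joint closes in on the head through a scripted sweep", {
  sc <- cached_scene("meal3_quiet")
  w <- sc$truth$action_windows[[1]]
  tr <- track_sequence(sc$frames, sc$background, sc$truth$sf_true[1],
                       w["end"] + 10, scene_tracker_params(sc$script))
  d <- pmin(tr$dist_left, tr$dist_right)
  before <- d[tr$frame < w["start"] - 5]
  during <- d[tr$frame >= w["start"] + 15 & tr$frame <= w["end"] - 15]
  expect_true(all(before > 250, na.rm = TRUE))
  expect_true(all(during < 200, na.rm = TRUE))
  # the approach is essentially monotone across the sweep-in
  approach <- d[tr$frame >= w["start"] & tr$frame <= w["start"] + 15]
  expect_lt(approach[length(approach)], approach[1])
  expect_true(all(diff(cummin(approach)) <= 0))
})
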