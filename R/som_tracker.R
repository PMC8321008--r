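# Adaptive 50-node SOM skeleton: topology, initialization, per-frame
# competitive-learning fit, joint-fusion detection and reset.

#' Fixed 50-node skeleton topology
#'
#' The model has a designated head-centre joint (Jhd) surrounded by a ring of
#' 9 head nodes, a 4x8 torso lattice, and two 4-node arm chains whose
#' terminal nodes are the hand joints (Jhl, Jhr). The 47 nodes that are not
#' one of the three designated joints are the model's plain surface nodes;
#' `plane_count` reports their number, derived from the node roles.
#'
#' @return A list of class `skeleton_topology`: `n_nodes`, `edges` (two-column
#'   matrix), `head_nodes` (the 9 ring indices), `jhd_index`, `jhl_index`,
#'   `jhr_index`, `plane_count`, and `hops` (50x50 topological hop-distance
#'   matrix).
#' @export
skeleton_topology <- function() {
  torso <- function(r, c) 10L + (r - 1L) * 4L + c   # r in 1..8, c in 1..4
  edges <- list()
  add <- function(a, b) edges[[length(edges) + 1L]] <<- c(a, b)
  ring <- 2:10
  for (i in seq_along(ring)) {
    add(ring[i], ring[if (i == length(ring)) 1L else i + 1L])  # head ring
    add(1L, ring[i])                                           # spokes to Jhd
  }
  for (r in 1:8) for (c in 1:4) {
    if (c < 4) add(torso(r, c), torso(r, c + 1))
    if (r < 8) add(torso(r, c), torso(r + 1, c))
  }
  add(1L, torso(1, 2)); add(1L, torso(1, 3))        # head centre to torso top
  add(torso(1, 1), 43L); add(43L, 44L); add(44L, 45L); add(45L, 46L)
  add(torso(1, 4), 47L); add(47L, 48L); add(48L, 49L); add(49L, 50L)
  em <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(em, directed = FALSE)
  stopifnot(igraph::components(g)$no == 1)
  joints <- c(jhd = 1L, jhl = 46L, jhr = 50L)
  structure(list(
    n_nodes = 50L, edges = em, head_nodes = 2:10,
    jhd_index = joints[["jhd"]], jhl_index = joints[["jhl"]],
    jhr_index = joints[["jhr"]],
    plane_count = 50L - length(joints),
    hops = igraph::distances(g)
  ), class = "skeleton_topology")
}

#' Tracker parameters
#'
#' Fusion defaults follow the stabilization rule of the tracker: a hand
#' joint dwelling within 300 px (about 200 mm at working depth) of the head
#' joint for more than five seconds (150 frames at 30 fps) indicates node
#' fusion and triggers a model reset. The fusion test is applied in metric
#' space (mm) by default because an image-space pixel distance depends on
#' depth; set `fusion_space = "px"` for the image-space variant.
#'
#' @param iterations_per_frame competitive-learning passes over the point
#'   cloud per frame.
#' @param lr learning-rate schedule `c(initial, final)`, linear decay.
#' @param radius neighbourhood-radius schedule in topology hops,
#'   `c(initial, final)`.
#' @param fusion_dist_mm metric fusion threshold (default 200 mm).
#' @param fusion_dist_px image-space fusion threshold (default 300 px).
#' @param fusion_frames dwell frames to declare fusion; default
#'   `round(5 * fps)`, i.e., 150 at 30 fps.
#' @param fps frame rate.
#' @param point_cap seeded subsampling cap on cloud points per frame
#'   (`Inf` reproduces full fitting).
#' @param seed RNG seed for subsampling.
#' @param fusion_space `"mm"` or `"px"`.
#' @return A list of class `tracker_params`.
#' @export
tracker_params <- function(iterations_per_frame = 3L, lr = c(0.5, 0.3),
                           radius = c(1, 0.6), fusion_dist_mm = 200,
                           fusion_dist_px = 300, fps = 30,
                           fusion_frames = round(5 * fps),
                           point_cap = 2000, seed = 1L,
                           fusion_space = c("mm", "px")) {
  if (any(lr <= 0) || lr[2] > lr[1]) stop("lr must be positive, non-increasing")
  if (any(radius <= 0) || radius[2] > radius[1])
    stop("radius must be positive, non-increasing")
  if (iterations_per_frame < 1) stop("iterations_per_frame must be >= 1")
  structure(list(iterations_per_frame = as.integer(iterations_per_frame),
                 lr = lr, radius = radius, fusion_dist_mm = fusion_dist_mm,
                 fusion_dist_px = fusion_dist_px,
                 fusion_frames = as.integer(fusion_frames), fps = fps,
                 point_cap = point_cap, seed = as.integer(seed),
                 fusion_space = match.arg(fusion_space)),
            class = "tracker_params")
}

#' Initialize the skeleton model on a point cloud
#'
#' Places the 9 head-ring nodes around the cloud's highest (minimum-Z)
#' region, spans the torso lattice over the remaining extent rotated to the
#' person's orientation, and extends the two arm chains toward the facing
#' (table) side, hands at the extremities.
#'
#' @param pc a `point_cloud` with at least 50 points.
#' @param orientation_deg facing angle in degrees (0 = +X); when `NULL`,
#'   estimated as the direction from the body centroid to the head centre.
#' @return A list of class `skeleton_model` with `nodes` (50x3 mm),
#'   `topology`, and the joint indices.
#' @export
init_model <- function(pc, orientation_deg = NULL) {
  if (is.null(pc) || nrow(pc) == 0) stop("empty point cloud")
  if (nrow(pc) < 50) stop("under-determined fit: need at least 50 points")
  topo <- skeleton_topology()
  zmin <- min(pc[, 3])
  head_pts <- pc[pc[, 3] < zmin + 150, , drop = FALSE]
  hc <- c(mean(head_pts[, 1]), mean(head_pts[, 2]), zmin)
  if (is.null(orientation_deg)) {
    # facing = direction from the head centre to the farthest body point in
    # the image plane: at a meal the arms reaching over the table are the
    # longest extent of the silhouette
    rest <- pc[pc[, 3] >= zmin + 150, , drop = FALSE]
    if (nrow(rest) >= 10) {
      dx <- rest[, 1] - hc[1]
      dy <- rest[, 2] - hc[2]
      far <- which.max(dx^2 + dy^2)
      dir <- c(dx[far], dy[far])
    } else dir <- c(1, 0)
    if (sum(dir^2) < 1e-9) dir <- c(1, 0)
    theta <- atan2(dir[2], dir[1])
  } else theta <- orientation_deg * pi / 180
  f <- c(cos(theta), sin(theta))
  n <- c(-f[2], f[1])
  rest <- pc[pc[, 3] >= zmin + 150, , drop = FALSE]
  along_all <- (rest[, 1] - hc[1]) * f[1] + (rest[, 2] - hc[2]) * f[2]
  across_all <- (rest[, 1] - hc[1]) * n[1] + (rest[, 2] - hc[2]) * n[2]
  fwd <- along_all > 100            # arm/hand side (toward the table)
  ztor <- if (any(!fwd)) median(rest[!fwd, 3]) else zmin + 350
  nodes <- matrix(0, 50, 3)
  nodes[1, ] <- hc
  ang <- seq(0, 2 * pi, length.out = 10)[1:9] + theta
  nodes[2:10, ] <- cbind(hc[1] + 70 * cos(ang), hc[2] + 70 * sin(ang),
                         zmin + 30)
  # torso lattice spans the extent behind the head
  back_depth <- if (any(!fwd)) max(100, -min(along_all[!fwd])) else 400
  for (r in 1:8) for (c in 1:4) {
    along <- -(60 + (r - 1) * (back_depth - 60) / 7)
    across <- c(-150, -50, 50, 150)[c]
    i <- 10L + (r - 1L) * 4L + c
    nodes[i, ] <- c(hc[1] + along * f[1] + across * n[1],
                    hc[2] + along * f[2] + across * n[2], ztor)
  }
  # arm chains follow the forward point mass of each side when present,
  # hands at the extremities nearest the table side
  for (side in c(-1, 1)) {
    base <- if (side < 0) 43L else 47L
    sel <- fwd & (side * across_all > 0)
    if (sum(sel) >= 10) {
      a_sel <- along_all[sel]
      zarm <- median(rest[sel, 3])
      across_m <- median(across_all[sel])
      lo <- stats::quantile(a_sel, 0.15)
      hi <- max(a_sel)
      for (k in 0:3) {
        along <- lo + (hi - lo) * k / 3
        nodes[base + k, ] <- c(hc[1] + along * f[1] + across_m * n[1],
                               hc[2] + along * f[2] + across_m * n[2],
                               zarm)
      }
    } else {
      for (k in 0:3) {
        along <- 60 + k * 90
        nodes[base + k, ] <- c(hc[1] + along * f[1] + side * 180 * n[1],
                               hc[2] + along * f[2] + side * 180 * n[2], ztor)
      }
    }
  }
  structure(list(nodes = nodes, topology = topo,
                 jhd_index = topo$jhd_index, jhl_index = topo$jhl_index,
                 jhr_index = topo$jhr_index, orientation_deg = theta * 180 / pi),
            class = "skeleton_model")
}

#' @export
print.skeleton_model <- function(x, ...) {
  j <- joint_positions(x)
  cat("skeleton model: 50 nodes\n")
  cat(sprintf("  Jhd (%.0f, %.0f, %.0f) mm\n", j$jhd[1], j$jhd[2], j$jhd[3]))
  cat(sprintf("  Jhl (%.0f, %.0f, %.0f)  Jhr (%.0f, %.0f, %.0f)\n",
              j$jhl[1], j$jhl[2], j$jhl[3], j$jhr[1], j$jhr[2], j$jhr[3]))
  invisible(x)
}

#' @export
plot.skeleton_model <- function(x, pc = NULL, ...) {
  nodes <- x$nodes
  if (!is.null(pc))
    plot(pc[, 1], pc[, 2], pch = ".", col = "grey70", asp = 1,
         xlab = "X (mm)", ylab = "Y (mm)", ...)
  else
    plot(nodes[, 1], nodes[, 2], type = "n", asp = 1,
         xlab = "X (mm)", ylab = "Y (mm)", ...)
  e <- x$topology$edges
  segments(nodes[e[, 1], 1], nodes[e[, 1], 2],
           nodes[e[, 2], 1], nodes[e[, 2], 2], col = "steelblue")
  points(nodes[, 1], nodes[, 2], pch = 19, cex = 0.5)
  j <- c(x$jhd_index, x$jhl_index, x$jhr_index)
  points(nodes[j, 1], nodes[j, 2], pch = 19, col = "red")
  invisible(x)
}

joint_positions <- function(model) {
  list(jhd = model$nodes[model$jhd_index, ],
       jhl = model$nodes[model$jhl_index, ],
       jhr = model$nodes[model$jhr_index, ])
}

#' Fit the skeleton model to one frame's point cloud
#'
#' One call runs `iterations_per_frame` passes of online competitive
#' learning (winner by Euclidean distance, ties to the lowest node index,
#' Gaussian topological neighbourhood, linear schedule decay), warm-started
#' from the supplied model. The returned model is the pass snapshot with the
#' lowest fit energy (mean node-to-nearest-point distance), so the energy
#' never exceeds the warm start's. Nodes are kept inside the cloud's
#' axis-aligned bounding box inflated by 100 mm.
#'
#' @param model a `skeleton_model`.
#' @param pc a non-empty `point_cloud`.
#' @param params a [tracker_params()].
#' @return The fitted `skeleton_model`, with attributes `energy` and
#'   `energy_trace` (energy before fitting and after each pass).
#' @export
fit_frame <- function(model, pc, params = tracker_params()) {
  if (is.null(pc) || nrow(pc) == 0) stop("empty point cloud")
  lo <- apply(pc, 2, min) - 100
  hi <- apply(pc, 2, max) + 100
  nodes <- model$nodes
  for (d in 1:3) nodes[, d] <- pmin(pmax(nodes[, d], lo[d]), hi[d])
  fit <- cpp_som_fit(nodes, unclass(pc)[, 1:3, drop = FALSE],
                     model$topology$hops,
                     params$iterations_per_frame,
                     params$lr[1], params$lr[2],
                     params$radius[1], params$radius[2])
  model$nodes <- fit$nodes
  attr(model, "energy") <- fit$energy
  attr(model, "energy_trace") <- fit$trace
  model
}

#' Detect head-hand joint fusion
#'
#' Reports the hand whose head-joint distance stayed below the fusion
#' threshold for the last `fusion_frames` consecutive records (left checked
#' first); `"none"` otherwise.
#'
#' @param track a `joint_track` (see [track_sequence()]).
#' @param params a [tracker_params()].
#' @return `"left"`, `"right"` or `"none"`.
#' @export
detect_fusion <- function(track, params = tracker_params()) {
  n <- nrow(track)
  if (n < params$fusion_frames) return("none")
  idx <- (n - params$fusion_frames + 1):n
  if (params$fusion_space == "px") {
    dl <- track$dist_left_px[idx]; dr <- track$dist_right_px[idx]
    thr <- params$fusion_dist_px
  } else {
    dl <- track$dist_left[idx]; dr <- track$dist_right[idx]
    thr <- params$fusion_dist_mm
  }
  if (all(!is.na(dl)) && all(dl < thr)) return("left")
  if (all(!is.na(dr)) && all(dr < thr)) return("right")
  "none"
}

#' Reset the skeleton model after a joint fusion
#'
#' Re-runs [init_model()] on the current cloud; if an initial hand placement
#' still lies within the fusion distance of the head joint, that hand is
#' pushed outward along its arm direction until the separation clears the
#' threshold. Deterministic and idempotent for an unchanged cloud.
#'
#' @param model the fused `skeleton_model` (its stored orientation is
#'   reused).
#' @param pc the current `point_cloud`.
#' @param params a [tracker_params()].
#' @return A fresh `skeleton_model` with both head-hand separations above
#'   `fusion_dist_mm`.
#' @export
reset_model <- function(model, pc, params = tracker_params()) {
  m <- init_model(pc, orientation_deg = model$orientation_deg)
  jhd <- m$nodes[m$jhd_index, ]
  for (hand in c(m$jhl_index, m$jhr_index)) {
    v <- m$nodes[hand, ] - jhd
    sep <- sqrt(sum(v^2))
    if (sep <= params$fusion_dist_mm) {
      if (sep < 1e-6) v <- c(1, 0, 0) else v <- v / sep
      m$nodes[hand, ] <- jhd + v * (params$fusion_dist_mm + 50)
    }
  }
  m
}

#' Track the head and hand joints over a frame range
#'
#' Preprocesses each frame (hole filling, median denoising, background
#' subtraction), fits the SOM skeleton to the largest foreground blob's
#' point cloud, monitors head-hand distances for joint fusion and resets the
#' model when fusion is detected. The model orientation is estimated from
#' the first tracked frame's cloud and then held. Frames without a person
#' are recorded as absent and freeze the model.
#'
#' @param frames list of depth frames.
#' @param background background-only depth frame.
#' @param sf,ef 1-based first/last frame to process (`sf <= ef`).
#' @param params a [tracker_params()].
#' @param cam a [camera_model()] matching the frame size.
#' @param min_diff_mm,min_area_px foreground extraction thresholds.
#' @param median_window median-filter window (odd px).
#' @return A `data.frame` of class `joint_track`, one row per processed
#'   frame: joint positions (mm), head-to-hand distances in mm and px,
#'   `reset` and `absent` flags.
#' @export
track_sequence <- function(frames, background, sf = 1L,
                           ef = length(frames), params = tracker_params(),
                           cam = camera_model(ncol(as_depth_matrix(frames[[1]])),
                                              nrow(as_depth_matrix(frames[[1]]))),
                           min_diff_mm = 100, min_area_px = 300,
                           median_window = 5L) {
  if (ef < sf) stop("ef must be >= sf")
  if (sf < 1 || ef > length(frames)) stop("frame range outside sequence")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(params$seed)
  bg <- fill_holes(background)
  n <- ef - sf + 1L
  absent <- logical(n); reset <- logical(n)
  jm <- matrix(NA_real_, n, 9)  # jhd, jhl, jhr xyz
  dl_v <- rep(NA_real_, n); dr_v <- rep(NA_real_, n)
  dlp_v <- rep(NA_real_, n); drp_v <- rep(NA_real_, n)
  model <- NULL
  run_l <- 0L; run_r <- 0L
  for (i in seq_len(n)) {
    fr <- frames[[sf + i - 1L]]
    pre <- median_denoise(fill_holes(fr), median_window)
    blobs <- subtract_background(pre, bg, min_diff_mm, min_area_px)
    if (!length(blobs) || blobs[[1]]$area_px < 50) {
      absent[i] <- TRUE
      run_l <- 0L; run_r <- 0L
      next
    }
    pc <- to_point_cloud(blobs[[1]], cam)
    if (is.finite(params$point_cap) && nrow(pc) > params$point_cap)
      pc <- pc[sample.int(nrow(pc), params$point_cap), , drop = FALSE]
    if (is.null(model)) {
      if (nrow(pc) < 50) { absent[i] <- TRUE; next }
      model <- init_model(pc)
    }
    model <- fit_frame(model, pc, params)
    j <- joint_positions(model)
    dl <- sqrt(sum((j$jhd - j$jhl)^2))
    dr <- sqrt(sum((j$jhd - j$jhr)^2))
    pxy <- project_points(rbind(j$jhd, j$jhl, j$jhr), cam)
    jm[i, ] <- c(j$jhd, j$jhl, j$jhr)
    dl_v[i] <- dl; dr_v[i] <- dr
    dlp_v[i] <- sqrt(sum((pxy[1, ] - pxy[2, ])^2))
    drp_v[i] <- sqrt(sum((pxy[1, ] - pxy[3, ])^2))
    if (params$fusion_space == "px") {
      run_l <- if (dlp_v[i] < params$fusion_dist_px) run_l + 1L else 0L
      run_r <- if (drp_v[i] < params$fusion_dist_px) run_r + 1L else 0L
    } else {
      run_l <- if (dl < params$fusion_dist_mm) run_l + 1L else 0L
      run_r <- if (dr < params$fusion_dist_mm) run_r + 1L else 0L
    }
    if (run_l >= params$fusion_frames || run_r >= params$fusion_frames) {
      model <- reset_model(model, pc, params)
      reset[i] <- TRUE
      run_l <- 0L; run_r <- 0L
      # the reset frame records the restored model, whose joints are
      # separated again by construction
      j <- joint_positions(model)
      pxy <- project_points(rbind(j$jhd, j$jhl, j$jhr), cam)
      jm[i, ] <- c(j$jhd, j$jhl, j$jhr)
      dl_v[i] <- sqrt(sum((j$jhd - j$jhl)^2))
      dr_v[i] <- sqrt(sum((j$jhd - j$jhr)^2))
      dlp_v[i] <- sqrt(sum((pxy[1, ] - pxy[2, ])^2))
      drp_v[i] <- sqrt(sum((pxy[1, ] - pxy[3, ])^2))
    }
  }
  out <- data.frame(frame = sf:ef, absent = absent,
                    jhd_x = jm[, 1], jhd_y = jm[, 2], jhd_z = jm[, 3],
                    jhl_x = jm[, 4], jhl_y = jm[, 5], jhl_z = jm[, 6],
                    jhr_x = jm[, 7], jhr_y = jm[, 8], jhr_z = jm[, 9],
                    dist_left = dl_v, dist_right = dr_v,
                    dist_left_px = dlp_v, dist_right_px = drp_v,
                    reset = reset)
  class(out) <- c("joint_track", "data.frame")
  attr(out, "params") <- params
  out
}

#' @export
plot.joint_track <- function(x, ...) {
  plot(x$frame, x$dist_left, type = "l", col = "steelblue",
       xlab = "frame", ylab = "head-hand distance (mm)",
       ylim = range(c(x$dist_left, x$dist_right), na.rm = TRUE), ...)
  lines(x$frame, x$dist_right, col = "tomato")
  if (any(x$reset)) points(x$frame[x$reset], rep(0, sum(x$reset)), pch = 4)
  legend("topright", c("left", "right"), lty = 1,
         col = c("steelblue", "tomato"), bty = "n")
  invisible(x)
}
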