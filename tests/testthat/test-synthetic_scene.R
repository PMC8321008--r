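test_that("the background frame holds the floor and table distances", {
  script <- scene_script(noise_sigma_mm = 0, hole_rate = 0)
  bg <- render_background(script)
  r <- script$table_rect
  inside <- bg[(r["y0"] + 2), (r["x0"] + 2)]
  outside <- bg[2, 2]
  expect_equal(inside, 2100L)
  expect_equal(outside, 3000L)
  expect_equal(sort(unique(as.vector(bg))), c(2100L, 3000L))

  bad <- scene_script()
  bad$table_rect <- c(x0 = 150, y0 = 10, x1 = 400, y1 = 50)
  expect_error(render_background(bad), "outside frame")
})

test_that("rendering is deterministic given the script seed", {
  s <- meal_scene_script(500, 3, seed = 9)
  a <- render_sequence(s)
  b <- render_sequence(s)
  for (f in c(1, 100, 300, 500))
    expect_identical(a$frames[[f]][, ], b$frames[[f]][, ])
})

test_that("scene truth follows the script's closed-form geometry", {
  s <- meal_scene_script(550, 3, seed = 1, person_height_mm = 1800,
                         sensor_height_mm = 3000, sit_drop = 0.35,
                         noise_sigma_mm = 0, hole_rate = 0)
  truth <- scene_truth(s)
  expect_equal(truth$standing_distance_mm, 1200)
  expect_equal(truth$sitting_distance_mm, 1620)
  expect_length(truth$action_windows, 3)

  # the rendered head reaches exactly those distances
  sc <- render_sequence(s)
  standing_frame <- sc$frames[[20]]     # mid-walk
  seated_frame <- sc$frames[[sc$truth$sf_true[1] + 5]]
  expect_equal(min(standing_frame), 1200L)
  expect_equal(min(seated_frame), 1620L)
})

test_that("scenes without events reproduce the background everywhere", {
  s <- scene_script(n_frames = 5, noise_sigma_mm = 0, hole_rate = 0)
  sc <- render_sequence(s)
  bg <- render_background(s)
  for (f in 1:5) expect_identical(sc$frames[[f]][, ], bg[, ])
  expect_length(sc$truth$action_windows, 0)
})

test_that("noise-free background subtraction recovers the exact silhouette", {
  sc <- cached_scene("meal3_quiet")
  bg <- mealscan:::as_depth_matrix(sc$background)
  for (f in c(30, 200, 400)) {
    fr <- mealscan:::as_depth_matrix(sc$frames[[f]])
    sil <- sum(fr != bg)
    blobs <- subtract_background(fr, bg, min_diff_mm = 100, min_area_px = 30)
    expect_equal(sum(vapply(blobs, function(b) b$area_px, 0L)), sil)
  }
})

test_that("noise and holes concentrate where the script says they should", {
  s <- meal_scene_script(480, 3, seed = 5)   # default sigma 15, holes 0.05
  expect_error(meal_scene_script(480, 3, seed = 5, hole_rate = 1.2),
               "hole_rate")
  sc <- render_sequence(s)
  quiet <- render_sequence(meal_scene_script(480, 3, seed = 5,
                                             noise_sigma_mm = 0,
                                             hole_rate = 0))
  f <- 200
  m <- mealscan:::as_depth_matrix(sc$frames[[f]])
  clean <- mealscan:::as_depth_matrix(quiet$frames[[f]])
  holes <- which(m == 0)
  expect_gt(length(holes), 0)
  # every hole lies within 2 px (chessboard) of a depth discontinuity
  for (idx in holes) {
    i <- (idx - 1) %% nrow(m) + 1
    j <- (idx - 1) %/% nrow(m) + 1
    ii <- max(1, i - 2):min(nrow(m), i + 2)
    jj <- max(1, j - 2):min(ncol(m), j + 2)
    expect_gt(diff(range(clean[ii, jj])), 250)
  }
  # noise is zero-mean and mm-scaled away from holes
  d <- (m - clean)[m > 0]
  expect_lt(abs(mean(d)), 3)
  expect_gt(sd(d), 5)
  expect_lt(sd(d), 30)
})

test_that("event scripts are validated", {
  expect_error(scene_script(events = list(list(enter = 10, sit = 5,
                                               hands = 20, actions = list(),
                                               stand = 30, leave = 40))),
               "enter < sit")
  expect_error(scene_script(n_frames = 100,
                            events = list(list(enter = 10, sit = 20,
                                               hands = 30, actions = list(),
                                               stand = 90, leave = 150))),
               "past n_frames")
  expect_error(scene_script(n_frames = 300,
                            events = list(list(enter = 10, sit = 20, hands = 30,
                                               actions = list(c(10, 20)),
                                               stand = 200, leave = 220))),
               "between hands and stand")
})

test_that("a seated scene trips the sitting Ratio test exactly when it should", {
  # sit_drop 0.5: seated = 1.5 x standing; the ratio-0.3 rule needs
  # seated >= standing / 0.7, i.e. sit_drop above 0.3/(1-0.3) = 0.4286
  cfg <- session_config(table_rect = c(x0 = 5, y0 = 5, x1 = 10, y1 = 10))
  expect_true(is_sitting(1200, 1200 * 1.5, cfg))
  expect_false(is_sitting(1200, 1200 * 1.35, cfg))
})
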