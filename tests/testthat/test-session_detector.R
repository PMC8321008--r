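table_cfg <- function(...) {
  session_config(table_rect = c(x0 = 40, y0 = 30, x1 = 80, y1 = 70),
                 table_top_mm = 2100, ...)
}

test_that("the table box test is inclusive at exactly Dist pixels", {
  cfg <- table_cfg()                       # dist_px = 45
  expect_true(near_table(fake_blob(50, 50), cfg))          # inside the rect
  expect_true(near_table(fake_blob(80 + 45, 50), cfg))     # exactly 45 out
  expect_false(near_table(fake_blob(80 + 46, 50), cfg))    # 46 px out
  expect_false(near_table(fake_blob(50, 30 - 46), cfg))
})

test_that("the sitting Ratio rule matches the worked 1700/1190 mm example", {
  cfg <- table_cfg()                       # ratio = 0.3, threshold form
  # threshold = 30% below the 1700 mm sitting distance = 1190 mm
  expect_equal(1700 * (1 - cfg$ratio), 1190)
  expect_true(is_sitting(1190, 1700, cfg))         # boundary inclusive
  expect_false(is_sitting(1190, 1600, cfg))        # 1600*0.7 = 1120 < 1190
  expect_false(is_sitting(1400, 1400, cfg))        # no rise at all
  pending <- is_sitting(NA, 1700, cfg)
  expect_false(as.logical(pending))
  expect_equal(attr(pending, "status"), "baseline-pending")
})

test_that("the prose dialect reads the ratio off the standing distance", {
  fig10 <- table_cfg()
  prose <- table_cfg(sitting_rule = "prose")
  # 1600 vs baseline 1190: only the prose reading classifies sitting
  expect_false(is_sitting(1190, 1600, fig10))
  expect_true(is_sitting(1190, 1600, prose))       # 1190*1.3 = 1547 <= 1600
  expect_true(is_sitting(1190, 1700, prose))
})

test_that("hand blobs are selected by the height band over the table", {
  cfg <- table_cfg(hand_area_px = 300)
  bg <- matrix(3000L, 100, 120)
  bg[30:70, 40:80] <- 2100L                # the table
  frame <- bg
  frame[45:64, 50:69] <- 2100L - 120L      # 400-px hand 120 mm above the top
  expect_length(hands_on_table(frame, bg, cfg), 1)

  # a trunk protruding 450 mm above the table fails the 200 mm hand gap
  trunk <- bg
  trunk[40:65, 45:75] <- 2100L - 450L
  expect_length(hands_on_table(trunk, bg, cfg), 0)

  # two hands
  two <- bg
  two[36:49, 45:69] <- 1980L               # 350 px
  two[55:68, 45:69] <- 1980L               # 350 px
  expect_length(hands_on_table(two, bg, cfg), 2)
})

test_that("a default meal scene yields its scripted start and end frames", {
  sc <- cached_scene("meal3_quiet")
  cfg <- scene_session_config(sc$script)
  st <- detect_sessions(sc$frames, sc$background, cfg, test_number = 7L)
  expect_equal(nrow(st), 1L)
  expect_equal(st$test_number, 7L)
  expect_lte(abs(st$sf - sc$truth$sf_true), 5)     # noise-free tolerance
  expect_lte(abs(st$ef - sc$truth$ef_true), 5)
})

test_that("the checklist short-circuits in order", {
  sc <- cached_scene("meal3_quiet")
  cfg <- scene_session_config(sc$script)
  st <- detect_sessions(sc$frames, sc$background, cfg)
  log <- attr(st, "state_log")
  expect_true(all(is.na(log$near[!log$present])))
  expect_true(all(is.na(log$sitting[log$present & !log$near])))
  expect_true(all(is.na(log$hands[which(log$sitting == FALSE)])))
  # the walking-in phase contributes the standing baseline
  expect_equal(min(log$baseline, na.rm = TRUE),
               min(log$head_mm[!is.na(log$near) & !log$near], na.rm = TRUE))
})

test_that("too small a seated head-distance rise never opens a session", {
  s <- meal_scene_script(550, 3, seed = 2, sit_drop = 0.35,
                         noise_sigma_mm = 0, hole_rate = 0)
  sc <- render_sequence(s)
  st <- detect_sessions(sc$frames, sc$background, scene_session_config(s))
  expect_equal(nrow(st), 0L)
})

test_that("an empty room yields an empty SetParam table", {
  s <- scene_script(n_frames = 40)
  sc <- render_sequence(s)
  st <- detect_sessions(sc$frames, sc$background, scene_session_config(s))
  expect_equal(nrow(st), 0L)
  expect_error(detect_sessions(list(), sc$background,
                               scene_session_config(s)), "empty sequence")
})

test_that("lowering the ratio never delays the detected start frame", {
  sc <- cached_scene("meal3")
  base <- scene_session_config(sc$script)
  sf_at <- function(r) {
    cfg <- base; cfg$ratio <- r
    st <- detect_sessions(sc$frames, sc$background, cfg)
    if (nrow(st)) st$sf[1] else Inf
  }
  sf3 <- sf_at(0.30)
  sf25 <- sf_at(0.25)
  sf2 <- sf_at(0.20)
  expect_lte(sf25, sf3)
  expect_lte(sf2, sf25)
})

test_that("a leave-and-return meal produces two ordered segments", {
  s <- scene_script(n_frames = 1000, seed = 4, events = list(
    list(enter = 10, sit = 50, hands = 65, actions = list(c(100, 80)),
         stand = 300, leave = 330),
    list(enter = 500, sit = 540, hands = 555, actions = list(c(600, 80)),
         stand = 830, leave = 860)))
  sc <- render_sequence(s)
  st <- detect_sessions(sc$frames, sc$background, scene_session_config(s), 11L)
  expect_equal(nrow(st), 2L)
  expect_gt(st$sf[2], st$ef[1])
  expect_lte(abs(st$sf[1] - sc$truth$sf_true[1]), 15)
  expect_lte(abs(st$sf[2] - sc$truth$sf_true[2]), 15)
  expect_true(all(st$sf >= 1 & st$sf <= st$ef & st$ef <= s$n_frames))
})

test_that("rollover splits sequences into acquisition files", {
  frames <- as.list(1:27000)
  expect_length(rollover(frames), 1)
  expect_length(rollover(as.list(1:27001)), 2)
  chunks <- rollover(as.list(1:27001))
  expect_length(chunks[[1]], 27000)
  expect_length(chunks[[2]], 1)
  expect_length(rollover(list()), 0)
  small <- rollover(as.list(1:10), rollover_frames = 4)
  expect_equal(lengths(small), c(4L, 4L, 2L))
})

test_that("session config validates its thresholds", {
  expect_error(session_config(ratio = 0), "ratio")
  expect_error(session_config(ratio = 1.2), "ratio")
  expect_error(session_config(dist_px = -1), "dist_px")
})
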