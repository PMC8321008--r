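# Shared synthetic scenes, rendered on first use and cached for the session.

.scene_cache <- new.env(parent = emptyenv())

cached_scene <- function(name) {
  if (!exists(name, envir = .scene_cache)) {
    script <- switch(name,
      meal3 = meal_scene_script(550, 3, seed = 2),
      meal3_quiet = meal_scene_script(550, 3, seed = 2,
                                      noise_sigma_mm = 0, hole_rate = 0),
      seated_quiet = scene_script(
        n_frames = 120, seed = 3, noise_sigma_mm = 0, hole_rate = 0,
        events = list(list(enter = 5, sit = 25, hands = 40, actions = list(),
                           stand = 115, leave = 120))),
      stop("unknown cached scene: ", name))
    assign(name, c(render_sequence(script), list(script = script)),
           envir = .scene_cache)
  }
  get(name, envir = .scene_cache)
}

# largest foreground blob of a rendered frame, preprocessed like the pipeline
scene_person_blob <- function(scene, frame) {
  cfg <- scene_session_config(scene$script)
  pre <- median_denoise(fill_holes(scene$frames[[frame]]), 5L)
  blobs <- subtract_background(pre, fill_holes(scene$background),
                               cfg$min_diff_mm, cfg$min_area_px)
  expect_gt(length(blobs), 0)
  blobs[[1]]
}

scene_person_cloud <- function(scene, frame) {
  blob <- scene_person_blob(scene, frame)
  cam <- camera_model(scene$script$width, scene$script$height)
  to_point_cloud(blob, cam)
}

# brute-force chessboard nearest-valid fill: each hole takes the minimum
# depth among valid pixels at minimal chessboard distance
oracle_fill <- function(m) {
  valid <- which(m > 0, arr.ind = TRUE)
  out <- m
  for (idx in which(m == 0)) {
    i <- (idx - 1) %% nrow(m) + 1
    j <- (idx - 1) %/% nrow(m) + 1
    d <- pmax(abs(valid[, 1] - i), abs(valid[, 2] - j))
    nearest <- valid[d == min(d), , drop = FALSE]
    out[i, j] <- min(m[nearest])
  }
  out
}

# brute-force edge-replicated median filter
oracle_median <- function(m, w) {
  r <- (w - 1) / 2
  out <- m
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    ii <- pmin(pmax((i - r):(i + r), 1), nrow(m))
    jj <- pmin(pmax((j - r):(j + r), 1), ncol(m))
    out[i, j] <- median(m[ii, jj])
  }
  out
}

# independent run-length action counter over two distance series; mirrors the
# counting contract with explicit loops
oracle_count <- function(dl, dr, thr, dwell, refractory) {
  runs_of_series <- function(d) {
    below <- !is.na(d) & d < thr
    runs <- list()
    start <- NA
    for (i in seq_along(below)) {
      if (below[i] && is.na(start)) start <- i
      if (!below[i] && !is.na(start)) {
        runs[[length(runs) + 1]] <- c(start, i - 1)
        start <- NA
      }
    }
    if (!is.na(start)) runs[[length(runs) + 1]] <- c(start, length(below))
    # merge close runs
    merged <- list()
    for (r in runs) {
      n <- length(merged)
      if (n > 0 && r[1] - merged[[n]][2] - 1 < refractory)
        merged[[n]][2] <- r[2]
      else merged[[n + 1]] <- r
    }
    Filter(function(r) r[2] - r[1] + 1 >= dwell, merged)
  }
  ev <- c(runs_of_series(dl), runs_of_series(dr))
  if (!length(ev)) return(0L)
  ev <- ev[order(vapply(ev, `[`, 0, 1))]
  count <- 1L
  cur_end <- ev[[1]][2]
  for (r in ev[-1]) {
    if (r[1] > cur_end) count <- count + 1L
    cur_end <- max(cur_end, r[2])
  }
  count
}

# minimal blob stand-in for geometric checks
fake_blob <- function(x, y, mm = 1500) {
  structure(list(mask = NULL, depth_mm = mm,
                 centroid_px = c(x = x, y = y), area_px = 1L,
                 max_height_point = c(x = x, y = y, mm = mm)),
            class = "foreground_blob")
}

# joint-track stand-in from distance series
fake_track <- function(dl, dr = rep(1000, length(dl))) {
  n <- length(dl)
  structure(data.frame(frame = seq_len(n), absent = FALSE,
                       dist_left = dl, dist_right = dr,
                       dist_left_px = dl * 1.5, dist_right_px = dr * 1.5,
                       reset = FALSE),
            class = c("joint_track", "data.frame"))
}
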