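# Seeded synthetic top-view depth scenes with known ground truth.
#
# The person is modelled as a 2.5-D stack of discs/ellipses/capsules (head
# above torso above arms) painted over a flat floor + raised table
# background; the pipeline only ever consumes the depth silhouette, so no
# mesh is needed. Gaussian mm-noise is added over the frame and hole dropout
# is concentrated within 2 px of depth discontinuities, where real sensors
# lose measurements.

#' Scene script for the synthetic depth renderer
#'
#' Defaults mirror the experimental geometry the pipeline targets: sensor
#' 3000 mm above the floor, table top 2100 mm from the sensor, 30 fps.
#' `sit_drop` is the fractional head-distance increase on sitting
#' (seated = standing * (1 + sit_drop)); the default 0.5 corresponds to a
#' standing head-to-sensor distance of 1200 mm rising to 1800 mm when seated,
#' in line with top-view observations of adults (standing around 1100-1200 mm,
#' seated around 1700-1800 mm under a 3 m ceiling sensor).
#'
#' `events` is a list of meal segments; each segment is a list with frame
#' numbers `enter < sit < hands <= stand <= leave` and `actions`, a list of
#' `c(start, duration)` hand-to-mouth windows lying between `hands` and
#' `stand`. Segments must be disjoint and ordered; the person is absent
#' between `leave` and the next `enter`.
#'
#' @param width,height frame size in pixels.
#' @param n_frames number of frames to render.
#' @param fps frame rate.
#' @param sensor_height_mm sensor height above the floor, mm.
#' @param table_top_mm sensor-to-table-top distance, mm.
#' @param table_rect table rectangle `c(x0, y0, x1, y1)` in 1-based pixel
#'   coordinates (inclusive); default: a right-of-centre rectangle scaled to
#'   the frame.
#' @param person_height_mm standing body height, mm.
#' @param sit_drop fractional head-distance increase when seated.
#' @param noise_sigma_mm std. dev. of zero-mean Gaussian depth noise.
#' @param hole_rate probability that a pixel within 2 px of a depth
#'   discontinuity drops to 0 (invalid).
#' @param seed RNG seed for noise and holes.
#' @param events list of meal segments (see Details).
#' @return A list of class `scene_script`.
#' @export
scene_script <- function(width = 160, height = 120, n_frames = 300,
                         fps = 30, sensor_height_mm = 3000,
                         table_top_mm = 2100, table_rect = NULL,
                         person_height_mm = 1800, sit_drop = 0.5,
                         noise_sigma_mm = 15, hole_rate = 0.05,
                         seed = 1L, events = list()) {
  if (is.null(table_rect))
    table_rect <- c(x0 = round(0.55 * width), y0 = round(0.27 * height),
                    x1 = round(0.94 * width), y1 = round(0.73 * height))
  names(table_rect) <- c("x0", "y0", "x1", "y1")
  if (person_height_mm >= sensor_height_mm)
    stop("person_height_mm must be below sensor_height_mm")
  if (hole_rate < 0 || hole_rate >= 1) stop("hole_rate must be in [0, 1)")
  if (table_top_mm >= sensor_height_mm)
    stop("table top must be above the floor")
  s <- structure(list(width = width, height = height, n_frames = n_frames,
                      fps = fps, sensor_height_mm = sensor_height_mm,
                      table_top_mm = table_top_mm, table_rect = table_rect,
                      person_height_mm = person_height_mm,
                      sit_drop = sit_drop, noise_sigma_mm = noise_sigma_mm,
                      hole_rate = hole_rate, seed = as.integer(seed),
                      events = events),
                 class = "scene_script")
  validate_events(s)
  s
}

validate_events <- function(script) {
  last_end <- 0
  for (seg in script$events) {
    t <- c(seg$enter, seg$sit, seg$hands, seg$stand, seg$leave)
    if (any(is.na(t)) || length(t) != 5)
      stop("each segment needs enter, sit, hands, stand, leave frames")
    if (is.unsorted(c(seg$enter, seg$sit, seg$hands), strictly = TRUE) ||
        seg$hands > seg$stand || seg$stand > seg$leave)
      stop("segment frames must satisfy enter < sit < hands <= stand <= leave")
    if (seg$enter <= last_end) stop("segments must be disjoint and ordered")
    if (seg$leave > script$n_frames) stop("segment extends past n_frames")
    for (a in seg$actions) {
      if (a[1] < seg$hands || a[1] + a[2] - 1 > seg$stand)
        stop("action windows must lie between hands and stand")
    }
    if (length(seg$actions) > 1) {
      st <- vapply(seg$actions, `[`, 0, 1)
      en <- st + vapply(seg$actions, `[`, 0, 2) - 1
      if (any(st[-1] <= en[-length(en)])) stop("action windows must not overlap")
    }
    last_end <- seg$leave
  }
  invisible(script)
}

#' Ground truth of a scene script
#'
#' @param script a [scene_script()].
#' @return A list of class `scene_truth` with 1-based `sf_true`/`ef_true`
#'   per segment (sitting with hands on table / rising), `action_windows`
#'   (list of `c(start, end)`), and the standing and sitting head-to-sensor
#'   distances in mm.
#' @export
scene_truth <- function(script) {
  standing <- script$sensor_height_mm - script$person_height_mm
  structure(list(
    sf_true = vapply(script$events, function(s) as.integer(s$hands), 0L),
    ef_true = vapply(script$events, function(s) as.integer(s$stand), 0L),
    action_windows = do.call(c, c(list(list()), lapply(script$events, function(s)
      lapply(s$actions, function(a) c(start = a[1], end = a[1] + a[2] - 1))))),
    standing_distance_mm = standing,
    sitting_distance_mm = standing * (1 + script$sit_drop)
  ), class = "scene_truth")
}

#' Render the background-only reference frame
#'
#' Floor at `sensor_height_mm` everywhere except the table rectangle at
#' `table_top_mm`. The reference frame is the idealized (noise-free) scene:
#' it plays the role of a background average captured while nobody is
#' present.
#'
#' @param script a [scene_script()].
#' @return A `depth_frame`.
#' @export
render_background <- function(script) {
  r <- script$table_rect
  if (r["x0"] < 1 || r["y0"] < 1 || r["x1"] > script$width ||
      r["y1"] > script$height || r["x0"] > r["x1"] || r["y0"] > r["y1"])
    stop("table_rect outside frame")
  m <- matrix(script$sensor_height_mm, script$height, script$width)
  m[r["y0"]:r["y1"], r["x0"]:r["x1"]] <- script$table_top_mm
  depth_frame(m)
}

# ---- painting primitives (x = col, y = row, 1-based px) --------------------

paint_disc <- function(m, cx, cy, r, depth) {
  paint_ellipse(m, cx, cy, r, r, 0, depth)
}

paint_ellipse <- function(m, cx, cy, a, b, theta, depth) {
  xs <- max(1, floor(cx - a - b)):min(ncol(m), ceiling(cx + a + b))
  ys <- max(1, floor(cy - a - b)):min(nrow(m), ceiling(cy + a + b))
  if (!length(xs) || !length(ys)) return(m)
  dx <- outer(rep(1, length(ys)), xs - cx)
  dy <- outer(ys - cy, rep(1, length(xs)))
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  mask <- (u / a)^2 + (v / b)^2 <= 1
  sub <- m[ys, xs, drop = FALSE]
  sub[mask] <- pmin(sub[mask], depth)
  m[ys, xs] <- sub
  m
}

paint_capsule <- function(m, x1, y1, x2, y2, r, depth) {
  xs <- max(1, floor(min(x1, x2) - r)):min(ncol(m), ceiling(max(x1, x2) + r))
  ys <- max(1, floor(min(y1, y2) - r)):min(nrow(m), ceiling(max(y1, y2) + r))
  if (!length(xs) || !length(ys)) return(m)
  px <- outer(rep(1, length(ys)), xs)
  py <- outer(ys, rep(1, length(xs)))
  vx <- x2 - x1; vy <- y2 - y1
  L2 <- vx^2 + vy^2
  t <- if (L2 > 0) pmin(pmax(((px - x1) * vx + (py - y1) * vy) / L2, 0), 1) else 0
  d2 <- (px - (x1 + t * vx))^2 + (py - (y1 + t * vy))^2
  mask <- d2 <= r^2
  sub <- m[ys, xs, drop = FALSE]
  sub[mask] <- pmin(sub[mask], depth)
  m[ys, xs] <- sub
  m
}

# Per-frame kinematic state of the person. Returns NULL when absent.
person_state <- function(script, f, cam) {
  seg <- NULL
  for (s in script$events)
    if (f >= s$enter && f <= s$leave) { seg <- s; break }
  if (is.null(seg)) return(NULL)
  standing_z <- script$sensor_height_mm - script$person_height_mm
  seated_z <- standing_z * (1 + script$sit_drop)
  r <- script$table_rect
  sc <- script$width / 160
  entry <- c(x = 6 * sc, y = script$height / 2)
  seat <- c(x = r["x0"] - 6 * sc, y = (r["y0"] + r["y1"]) / 2)
  names(seat) <- c("x", "y")
  trans <- 10  # frames for the sit-down / stand-up transition
  if (f < seg$sit - trans) {          # walking in
    a <- (f - seg$enter) / max(1, seg$sit - trans - seg$enter)
    pos <- entry + a * (seat - entry)
    z <- standing_z
  } else if (f < seg$sit) {           # sitting down
    a <- (f - (seg$sit - trans)) / trans
    pos <- seat
    z <- standing_z + a * (seated_z - standing_z)
  } else if (f <= seg$stand) {        # seated
    pos <- seat
    z <- seated_z
  } else if (f <= seg$stand + trans) { # rising
    a <- (f - seg$stand) / trans
    pos <- seat
    z <- seated_z + a * (standing_z - seated_z)
  } else {                            # walking out
    a <- (f - seg$stand - trans) / max(1, seg$leave - seg$stand - trans)
    pos <- seat + a * (entry - seat)
    z <- standing_z
  }
  # facing: toward the table while at the seat, along the walk otherwise
  facing <- atan2(0, 1)
  if (f < seg$sit - trans) {
    d <- seat - pos
    if (sum(d^2) > 1e-9) facing <- atan2(d["y"], d["x"])
  } else if (f > seg$stand + trans) {
    d <- entry - seat
    facing <- atan2(d["y"], d["x"])
  }
  hands <- list(left = NULL, right = NULL)
  if (f >= seg$hands && f <= seg$stand) {
    px_hand <- cam$fx / (script$table_top_mm - 120)
    fx_ <- cos(facing); fy_ <- sin(facing)
    nx <- -fy_; ny <- fx_
    for (side in c("left", "right")) {
      sgn <- if (side == "left") -1 else 1
      rest <- c(x = pos[["x"]] + 420 * px_hand * fx_ + sgn * 150 * px_hand * nx,
                y = pos[["y"]] + 420 * px_hand * fy_ + sgn * 150 * px_hand * ny,
                z = script$table_top_mm - 120)
      hands[[side]] <- rest
    }
    # one hand per action window sweeps to the head and back
    k <- 0
    for (a in seg$actions) {
      k <- k + 1
      a_start <- a[1]; a_end <- a[1] + a[2] - 1
      if (f >= a_start && f <= a_end) {
        side <- if (k %% 2 == 1) "right" else "left"
        sgn <- if (side == "left") -1 else 1
        px_head <- cam$fx / z
        target <- c(x = pos[["x"]] + sgn * 105 * px_head * nx,
                    y = pos[["y"]] + sgn * 105 * px_head * ny,
                    z = z + 45)
        mv <- min(12, floor(a[2] / 3))
        w <- if (f < a_start + mv) (f - a_start) / mv
             else if (f > a_end - mv) (a_end - f) / mv
             else 1
        hands[[side]] <- hands[[side]] + w * (target - hands[[side]])
      }
    }
  }
  list(pos = pos, z = z, facing = facing, hands = hands)
}

#' Render a synthetic depth sequence
#'
#' Renders the scripted scene frame by frame and returns the frames together
#' with the scene's ground truth. Deterministic given the script (including
#' its seed); the caller's RNG state is left untouched.
#'
#' @param script a [scene_script()].
#' @return A list with `frames` (list of `depth_frame`), `truth`
#'   ([scene_truth()]), and `background` (the clean reference frame).
#' @export
render_sequence <- function(script) {
  validate_events(script)
  bg <- as_depth_matrix(render_background(script))
  cam <- camera_model(script$width, script$height,
                      sensor_height_mm = script$sensor_height_mm)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(script$seed)
  frames <- vector("list", script$n_frames)
  for (f in seq_len(script$n_frames)) {
    m <- bg
    st <- person_state(script, f, cam)
    if (!is.null(st)) {
      z <- st$z
      px <- cam$fx / z           # px per mm at head depth
      torso_z <- z + 400
      px_t <- cam$fx / torso_z
      fx_ <- cos(st$facing); fy_ <- sin(st$facing)
      tc <- c(st$pos[["x"]] - 120 * px_t * fx_, st$pos[["y"]] - 120 * px_t * fy_)
      m <- paint_ellipse(m, tc[1], tc[2], 280 * px_t, 200 * px_t,
                         st$facing + pi / 2, torso_z)
      for (side in c("left", "right")) {
        h <- st$hands[[side]]
        if (!is.null(h)) {
          sgn <- if (side == "left") -1 else 1
          sh <- c(st$pos[["x"]] - sgn * 220 * px_t * fy_,
                  st$pos[["y"]] + sgn * 220 * px_t * fx_)
          m <- paint_capsule(m, sh[1], sh[2], h[["x"]], h[["y"]],
                             45 * cam$fx / h[["z"]], round(h[["z"]]))
          m <- paint_disc(m, h[["x"]], h[["y"]], 60 * cam$fx / h[["z"]],
                          round(h[["z"]]))
        }
      }
      m <- paint_disc(m, st$pos[["x"]], st$pos[["y"]], 125 * px, round(z))
    }
    storage.mode(m) <- "integer"
    if (script$noise_sigma_mm > 0 || script$hole_rate > 0)
      m <- cpp_scene_noise(m, script$noise_sigma_mm, script$hole_rate,
                           250, 2L)
    frames[[f]] <- depth_frame(m, frame_index = f - 1L)
  }
  list(frames = frames, truth = scene_truth(script),
       background = render_background(script))
}

#' Script a complete synthetic meal
#'
#' Convenience constructor of a [scene_script()] containing one meal segment
#' with `n_actions` hand-to-mouth windows: the person enters, walks to the
#' table, sits, puts the hands on the table, performs the actions, rises near
#' the end of the file and leaves. Action windows last `dwell_frames + 35`
#' frames and are separated by at least 45 frames plus seeded jitter, so
#' every scripted action satisfies a dwell criterion of `dwell_frames` and
#' no two actions merge.
#'
#' @param n_frames sequence length (>= 450).
#' @param n_actions number of scripted intake actions.
#' @param seed RNG seed (scene noise and window placement).
#' @param dwell_frames dwell window the actions are scripted against
#'   (default 45 frames, i.e., 1.5 s at 30 fps).
#' @param ... further arguments passed to [scene_script()].
#' @return A `scene_script` with an `action_dwell_frames` field.
#' @export
meal_scene_script <- function(n_frames, n_actions, seed = 1L,
                              dwell_frames = 45L, ...) {
  if (n_frames < 450) stop("n_frames must be at least 450")
  enter <- 10
  sit <- 50
  hands <- 65
  stand <- n_frames - 55
  leave <- min(n_frames, stand + 30)
  dur <- dwell_frames + 35
  gap <- 45
  first <- hands + 15
  last <- stand - 15
  span <- last - first + 1
  need <- n_actions * dur + max(0, n_actions - 1) * gap
  if (need > span)
    stop(sprintf("cannot fit %d actions of %d frames into %d frames",
                 n_actions, dur, span))
  slack <- span - need
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed + 7L)
  jitter <- if (n_actions > 0) {
    g <- runif(n_actions + 1)
    floor(g / sum(g) * slack)
  } else numeric(0)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  actions <- list()
  at <- first
  for (i in seq_len(n_actions)) {
    at <- at + jitter[i] + if (i > 1) gap else 0
    actions[[i]] <- c(at, dur)
    at <- at + dur
  }
  s <- scene_script(n_frames = n_frames, seed = seed,
                    events = list(list(enter = enter, sit = sit,
                                       hands = hands, actions = actions,
                                       stand = stand, leave = leave)), ...)
  s$action_dwell_frames <- as.integer(dwell_frames)
  s
}

#' Tracker and action-counting parameters matched to a scene script
#'
#' The action dwell follows the script's `action_dwell_frames`; the fusion
#' window is set to the scripted gesture length (`dwell + 35` frames) plus a
#' 20-frame margin, so a legitimate gesture never triggers a mid-action
#' reset while a hand joint left stuck on the head is released soon after
#' the gesture ends.
#'
#' @param script a script from [meal_scene_script()].
#' @return `scene_tracker_params`: a [tracker_params()];
#'   `scene_action_params`: an [action_params()].
#' @export
scene_tracker_params <- function(script) {
  dw <- script$action_dwell_frames
  if (is.null(dw)) return(tracker_params())
  tracker_params(fusion_frames = dw + 55L)
}

#' @rdname scene_tracker_params
#' @export
scene_action_params <- function(script) {
  dw <- script$action_dwell_frames
  if (is.null(dw)) return(action_params())
  action_params(dwell_min_frames = dw)
}

#' Session-detector configuration matched to a scene script
#'
#' Rescales the pixel-denominated detector thresholds (tuned for a 640x480
#' grid) to the script's frame size and points the detector at the script's
#' table geometry.
#'
#' @param script a [scene_script()].
#' @return A [session_config()].
#' @export
scene_session_config <- function(script) {
  sc <- script$width / 640
  session_config(table_rect = script$table_rect,
                 table_top_mm = script$table_top_mm,
                 dist_px = max(3, round(45 * sc)),
                 hand_area_px = max(10, round(300 * sc^2)),
                 min_area_px = max(30, round(300 * sc^2)))
}
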