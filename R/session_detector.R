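# Automatic start-frame / end-frame detection: per-frame checklist
# (person present -> near table -> sitting -> hands on table), head-height
# history with a running standing baseline, multi-segment meals, SetParam
# construction and file rollover.

#' Session-detector configuration
#'
#' Pixel thresholds (`dist_px`, `hand_area_px`, `min_area_px`) are tuned for
#' a 640x480 grid; rescale them for other frame sizes (see
#' [scene_session_config()]).
#'
#' The sitting test compares the current head-to-sensor distance with the
#' running standing baseline. Two dialects are provided:
#' `"fig10"` (default) classifies sitting when
#' `current * (1 - ratio) >= baseline` (the threshold is `ratio` below the
#' sitting distance: at ratio 0.3 a 1700 mm sitting distance gives a 1190 mm
#' standing threshold); `"prose"` classifies sitting when
#' `current >= baseline * (1 + ratio)`. The two readings are reciprocal, not
#' identical.
#'
#' @param dist_px box margin around the table within which the head midpoint
#'   counts as "near the table" (default 45 px; the boundary is inclusive).
#' @param ratio fractional head-distance increase separating sitting from
#'   standing (default 0.3).
#' @param hand_gap_mm height band above the table top within which pixels
#'   qualify as hands (default 200 mm).
#' @param hand_area_px minimum hand-blob area; a blob strictly greater than
#'   this is taken as a hand on the table (default 300 px).
#' @param table_rect table rectangle `c(x0, y0, x1, y1)`, 1-based inclusive
#'   pixel coordinates.
#' @param table_top_mm sensor-to-table distance; when `NULL`, measured as
#'   the median background depth inside `table_rect`.
#' @param absence_frames consecutive non-sitting frames that confirm a
#'   departure and close the segment (default 90, i.e., 3 s at 30 fps).
#' @param rollover_frames file rollover length (default 27000 frames,
#'   15 min at 30 fps).
#' @param min_diff_mm,min_area_px foreground extraction thresholds.
#' @param min_segment_frames segments shorter than this are discarded as
#'   flicker (default 30).
#' @param median_window median-filter window.
#' @param sitting_rule `"fig10"` or `"prose"` (see Details).
#' @return A list of class `session_config`.
#' @export
session_config <- function(dist_px = 45, ratio = 0.3, hand_gap_mm = 200,
                           hand_area_px = 300, table_rect = NULL,
                           table_top_mm = NULL, absence_frames = 90,
                           rollover_frames = 27000, min_diff_mm = 100,
                           min_area_px = 300, min_segment_frames = 30,
                           median_window = 5L,
                           sitting_rule = c("fig10", "prose")) {
  if (ratio <= 0 || ratio >= 1) stop("ratio must be in (0, 1)")
  if (dist_px <= 0 || hand_gap_mm <= 0 || hand_area_px <= 0)
    stop("dist_px, hand_gap_mm and hand_area_px must be > 0")
  structure(list(dist_px = dist_px, ratio = ratio,
                 hand_gap_mm = hand_gap_mm, hand_area_px = hand_area_px,
                 table_rect = table_rect, table_top_mm = table_top_mm,
                 absence_frames = absence_frames,
                 rollover_frames = rollover_frames,
                 min_diff_mm = min_diff_mm, min_area_px = min_area_px,
                 min_segment_frames = min_segment_frames,
                 median_window = as.integer(median_window),
                 sitting_rule = match.arg(sitting_rule)),
            class = "session_config")
}

#' Is the person near the table?
#'
#' True when the head-blob midpoint (the blob's highest point) lies within
#' the table rectangle expanded by `dist_px` on all sides; the boundary is
#' inclusive: a head exactly `dist_px` outside the rectangle edge still
#' counts as near.
#'
#' @param blob a `foreground_blob`.
#' @param cfg a [session_config()] with `table_rect` set.
#' @return Logical.
#' @export
near_table <- function(blob, cfg) {
  if (is.null(cfg$table_rect)) stop("cfg$table_rect is required")
  r <- cfg$table_rect
  x <- blob$max_height_point[["x"]]
  y <- blob$max_height_point[["y"]]
  x >= r[["x0"]] - cfg$dist_px && x <= r[["x1"]] + cfg$dist_px &&
    y >= r[["y0"]] - cfg$dist_px && y <= r[["y1"]] + cfg$dist_px
}

#' Is the person sitting?
#'
#' Compares the current head-to-sensor distance against the running standing
#' baseline under the configured dialect (see [session_config()]). With no
#' baseline yet the answer is `FALSE` with attribute
#' `status = "baseline-pending"`.
#'
#' @param baseline_mm running standing baseline (minimum head distance
#'   observed while not classified sitting), or `NA`.
#' @param current_mm current head-to-sensor distance.
#' @param cfg a [session_config()].
#' @return Logical, with a `status` attribute when the baseline is pending.
#' @export
is_sitting <- function(baseline_mm, current_mm, cfg) {
  if (is.na(baseline_mm))
    return(structure(FALSE, status = "baseline-pending"))
  if (cfg$sitting_rule == "prose")
    current_mm >= baseline_mm * (1 + cfg$ratio)
  else
    current_mm * (1 - cfg$ratio) >= baseline_mm
}

#' Extract hand blobs on the table
#'
#' Intersects the foreground with the table area and keeps pixels lying
#' within the `hand_gap_mm` height band above the table top (a protruding
#' trunk, typically 400+ mm above the table, fails the band). Connected
#' components (8-connectivity) with area strictly greater than
#' `hand_area_px` are returned: 0, 1 or 2 hands.
#'
#' @param frame hole-filled, denoised depth frame.
#' @param background hole-filled background frame.
#' @param cfg a [session_config()] with `table_rect` set.
#' @return List of `foreground_blob` objects, largest first.
#' @export
hands_on_table <- function(frame, background, cfg) {
  if (is.null(cfg$table_rect)) stop("cfg$table_rect is required")
  m <- as_depth_matrix(frame)
  b <- as_depth_matrix(background)
  r <- cfg$table_rect
  top <- if (is.null(cfg$table_top_mm))
    median(b[r[["y0"]]:r[["y1"]], r[["x0"]]:r[["x1"]]]) else cfg$table_top_mm
  in_rect <- matrix(FALSE, nrow(m), ncol(m))
  in_rect[r[["y0"]]:r[["y1"]], r[["x0"]]:r[["x1"]]] <- TRUE
  height_above <- top - m
  mask <- in_rect & ((b - m) > cfg$min_diff_mm) &
    height_above > 0 & height_above < cfg$hand_gap_mm
  if (!any(mask)) return(list())
  lab <- cpp_label8(mask)
  sizes <- tabulate(lab)
  keep <- which(sizes > cfg$hand_area_px)
  if (!length(keep)) return(list())
  keep <- keep[order(sizes[keep], decreasing = TRUE)]
  lapply(keep, function(k) new_blob(lab == k, m))
}

#' Detect meal segments (start/end frames)
#'
#' Runs the ordered per-frame checklist - person blob present, head near the
#' table, sitting by the Ratio test, at least one hand blob on the table -
#' with short-circuit evaluation (a later check is never evaluated when an
#' earlier one fails). The start frame (SF) is the first frame passing all
#' four checks; the head-height history accumulates the standing baseline
#' from every present, not-sitting frame. The sitting condition ending and
#' the head leaving the table box for at least `absence_frames` confirms a
#' departure and closes the segment at the last sitting frame (EF); a
#' sequence ending mid-meal closes at the last frame. Re-seating after a
#' confirmed departure opens a new segment in the same table. A person
#' already seated at frame 1 (no baseline can exist) is admitted when the
#' hands check passes.
#'
#' @param frames list of depth frames.
#' @param background background-only depth frame.
#' @param cfg a [session_config()] with `table_rect` set.
#' @param test_number test label for the SetParam column(s).
#' @return A [session_table()]; attribute `state_log` holds the per-frame
#'   audit log (frame, present, head_mm, baseline, near, sitting, hands;
#'   `NA` where a check was short-circuited).
#' @export
detect_sessions <- function(frames, background, cfg, test_number = 1L) {
  if (!length(frames)) stop("empty sequence")
  bg <- fill_holes(background)
  n <- length(frames)
  l_present <- logical(n)
  l_head <- rep(NA_real_, n); l_base <- rep(NA_real_, n)
  l_near <- rep(NA, n); l_sit <- rep(NA, n); l_hands <- rep(NA, n)
  baseline <- NA_real_
  in_session <- FALSE
  sf <- integer(); ef <- integer()
  cur_sf <- NA_integer_; last_sit <- NA_integer_; departure <- 0L
  for (f in seq_len(n)) {
    pre <- median_denoise(fill_holes(frames[[f]]), cfg$median_window)
    blobs <- subtract_background(pre, bg, cfg$min_diff_mm, cfg$min_area_px)
    present <- length(blobs) > 0
    l_present[f] <- present
    sitting_now <- FALSE
    if (present) {
      person <- blobs[[1]]
      head_mm <- head_distance_mm(person)
      l_head[f] <- head_mm
      near <- near_table(person, cfg)
      l_near[f] <- near
      if (near) {
        sit <- is_sitting(baseline, head_mm, cfg)
        pending <- identical(attr(sit, "status"), "baseline-pending")
        l_sit[f] <- as.logical(sit)
        hands_ok <- NA
        if (isTRUE(as.logical(sit)) || pending) {
          hands_ok <- length(hands_on_table(pre, bg, cfg)) >= 1
          l_hands[f] <- hands_ok
        }
        sitting_now <- isTRUE(as.logical(sit)) || (pending && isTRUE(hands_ok))
        if (!in_session && sitting_now && isTRUE(hands_ok)) {
          in_session <- TRUE
          cur_sf <- f
        }
      }
      if (!sitting_now) baseline <- min(baseline, head_mm, na.rm = TRUE)
      l_base[f] <- baseline
    }
    if (in_session) {
      if (sitting_now) {
        last_sit <- f
        departure <- 0L
      } else {
        departure <- departure + 1L
        if (departure >= cfg$absence_frames) {
          sf <- c(sf, cur_sf); ef <- c(ef, last_sit)
          in_session <- FALSE
          departure <- 0L
        }
      }
    }
  }
  if (in_session) {
    sf <- c(sf, cur_sf)
    ef <- c(ef, if (departure == 0L) n else last_sit)
  }
  keep <- which(ef - sf + 1L >= cfg$min_segment_frames)
  st <- session_table(test_number = rep(as.integer(test_number), length(keep)),
                      sf = sf[keep], ef = ef[keep])
  attr(st, "state_log") <- data.frame(frame = seq_len(n), present = l_present,
                                      head_mm = l_head, baseline = l_base,
                                      near = l_near, sitting = l_sit,
                                      hands = l_hands)
  st
}

#' Split a sequence at the file-rollover length
#'
#' The acquisition system re-initializes after every 15-minute sequence
#' (27000 frames at 30 fps) and continues in a new file; this splits a frame
#' list into such chunks (the last may be short).
#'
#' @param frames list of depth frames.
#' @param rollover_frames chunk length (default 27000).
#' @return List of frame lists; zero frames yield an empty list.
#' @export
rollover <- function(frames, rollover_frames = 27000) {
  n <- length(frames)
  if (n == 0) return(list())
  starts <- seq(1L, n, by = rollover_frames)
  lapply(starts, function(s) frames[s:min(n, s + rollover_frames - 1L)])
}
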