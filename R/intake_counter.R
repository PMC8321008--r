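# Dwell-based counting of food-intake actions from a joint track.

#' Action-counting parameters
#'
#' An intake action is a maximal interval during which a hand joint stays
#' within `action_dist_mm` of the head joint for at least
#' `dwell_min_frames` (default 150 frames = 5 s at 30 fps, so that brief
#' hand-to-mouth gestures are not counted). Runs of the same hand separated
#' by fewer than `refractory_frames` frames are merged, which keeps a
#' tracker reset inside one long gesture from splitting it in two.
#'
#' @param action_dist_mm metric head-hand threshold (default 200 mm).
#' @param dwell_min_frames minimum below-threshold dwell (default 150).
#' @param refractory_frames merge gap between runs (default 15).
#' @param space `"mm"` (3-D metric, default) or `"px"` (image space).
#' @param action_dist_px image-space threshold used when `space = "px"`.
#' @return A list of class `action_params`.
#' @export
action_params <- function(action_dist_mm = 200, dwell_min_frames = 150,
                          refractory_frames = 15,
                          space = c("mm", "px"), action_dist_px = 300) {
  if (dwell_min_frames < 1) stop("dwell_min_frames must be >= 1")
  if (refractory_frames < 0) stop("refractory_frames must be >= 0")
  structure(list(action_dist_mm = action_dist_mm,
                 dwell_min_frames = as.integer(dwell_min_frames),
                 refractory_frames = as.integer(refractory_frames),
                 space = match.arg(space),
                 action_dist_px = action_dist_px),
            class = "action_params")
}

# maximal runs of TRUE, as a 2-column matrix of (start, end) indices
runs_of <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

merge_close_runs <- function(runs, gap) {
  if (nrow(runs) < 2 || gap <= 0) return(runs)
  out <- runs[1, , drop = FALSE]
  for (i in 2:nrow(runs)) {
    if (runs[i, "start"] - out[nrow(out), "end"] - 1L < gap)
      out[nrow(out), "end"] <- runs[i, "end"]
    else out <- rbind(out, runs[i, , drop = FALSE])
  }
  out
}

#' Count food-intake actions
#'
#' Scans the per-hand head-hand distance series of a joint track. For each
#' hand, maximal runs of consecutive below-threshold frames are found,
#' near-contiguous runs are merged (refractory gap), and runs at least
#' `dwell_min_frames` long each yield one action. Overlapping left/right
#' events merge into a single event whose hand is `"both"` when the overlap
#' covers at least half of the shorter run, otherwise the hand of the
#' longer run.
#'
#' @param track a `joint_track` from [track_sequence()].
#' @param params an [action_params()].
#' @return A `data.frame` of class `action_events`: `start_frame`,
#'   `end_frame`, `hand`, `min_distance_mm`.
#' @export
count_actions <- function(track, params = action_params()) {
  if (!nrow(track)) stop("empty track")
  series <- if (params$space == "px")
    list(left = track$dist_left_px, right = track$dist_right_px)
  else list(left = track$dist_left, right = track$dist_right)
  thr <- if (params$space == "px") params$action_dist_px
         else params$action_dist_mm
  per_hand <- lapply(series, function(d) {
    below <- !is.na(d) & d < thr & !track$absent
    r <- runs_of(below)
    r <- merge_close_runs(r, params$refractory_frames)
    r[r[, "end"] - r[, "start"] + 1L >= params$dwell_min_frames, ,
      drop = FALSE]
  })
  ev <- rbind(
    if (nrow(per_hand$left))
      data.frame(start = per_hand$left[, "start"], end = per_hand$left[, "end"],
                 hand = "left"),
    if (nrow(per_hand$right))
      data.frame(start = per_hand$right[, "start"],
                 end = per_hand$right[, "end"], hand = "right"))
  if (is.null(ev) || !nrow(ev)) {
    out <- data.frame(start_frame = integer(), end_frame = integer(),
                      hand = character(), min_distance_mm = numeric())
    class(out) <- c("action_events", "data.frame")
    return(out)
  }
  ev <- ev[order(ev$start, ev$end), , drop = FALSE]
  merged <- ev[1, , drop = FALSE]
  for (i in seq_len(nrow(ev))[-1]) {
    last <- nrow(merged)
    if (ev$start[i] <= merged$end[last]) {   # overlapping left/right runs
      ov <- min(merged$end[last], ev$end[i]) - ev$start[i] + 1L
      shorter <- min(merged$end[last] - merged$start[last],
                     ev$end[i] - ev$start[i]) + 1L
      longer_hand <- if (ev$end[i] - ev$start[i] >
                         merged$end[last] - merged$start[last])
        ev$hand[i] else merged$hand[last]
      merged$hand[last] <- if (ov >= shorter / 2) "both" else longer_hand
      merged$end[last] <- max(merged$end[last], ev$end[i])
    } else merged <- rbind(merged, ev[i, , drop = FALSE])
  }
  dmin <- vapply(seq_len(nrow(merged)), function(i) {
    idx <- merged$start[i]:merged$end[i]
    min(c(series$left[idx], series$right[idx]), na.rm = TRUE)
  }, 0)
  out <- data.frame(start_frame = track$frame[merged$start],
                    end_frame = track$frame[merged$end],
                    hand = merged$hand, min_distance_mm = dmin)
  class(out) <- c("action_events", "data.frame")
  out
}

#' Run the full meal-evaluation pipeline on one sequence
#'
#' Composes [detect_sessions()], [track_sequence()] per detected segment and
#' [count_actions()], returning the SetParam table with the action count of
#' each segment.
#'
#' @param frames list of depth frames.
#' @param background background-only depth frame.
#' @param cfg a [session_config()].
#' @param tparams a [tracker_params()].
#' @param aparams an [action_params()].
#' @param cam a [camera_model()] matching the frames.
#' @param test_number test label.
#' @return A list of class `intake_eval`: `sessions` ([session_table()]),
#'   `counts` (actions per segment), `events` (list of `action_events`).
#' @export
evaluate_session <- function(frames, background, cfg,
                             tparams = tracker_params(),
                             aparams = action_params(),
                             cam = camera_model(ncol(as_depth_matrix(frames[[1]])),
                                                nrow(as_depth_matrix(frames[[1]]))),
                             test_number = 1L) {
  sessions <- detect_sessions(frames, background, cfg, test_number)
  events <- vector("list", nrow(sessions))
  counts <- integer(nrow(sessions))
  for (i in seq_len(nrow(sessions))) {
    tr <- track_sequence(frames, background, sessions$sf[i], sessions$ef[i],
                         tparams, cam, cfg$min_diff_mm, cfg$min_area_px,
                         cfg$median_window)
    events[[i]] <- count_actions(tr, aparams)
    counts[i] <- nrow(events[[i]])
  }
  structure(list(sessions = sessions, counts = counts, events = events),
            class = "intake_eval")
}

#' @export
print.intake_eval <- function(x, ...) {
  cat(sprintf("meal evaluation: %d segment(s)\n", nrow(x$sessions)))
  if (nrow(x$sessions)) {
    d <- as.data.frame(x$sessions)
    d$actions <- x$counts
    print(d, row.names = FALSE)
  }
  invisible(x)
}
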