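# Depth-frame preprocessing: hole filling, median denoising, background
# subtraction with blob extraction, and Sobel edge detection.

#' Fill invalid ("hole") pixels in a depth frame
#'
#' Zero-valued pixels are invalid sensor readings. Each hole receives the
#' minimum depth among the valid pixels at minimal chessboard
#' (8-neighbourhood) distance; the fill is computed level-synchronously so it
#' is deterministic and independent of traversal order. Non-hole pixels are
#' unchanged and the operation is idempotent.
#'
#' @param frame depth frame (integer matrix, mm; 0 = hole).
#' @return Depth frame with no zero pixels.
#' @export
fill_holes <- function(frame) {
  m <- as_depth_matrix(frame)
  if (all(m > 0)) return(frame)
  out <- cpp_fill_holes(m)
  keep_frame_attrs(out, frame)
}

keep_frame_attrs <- function(m, template) {
  attr(m, "frame_index") <- attr(template, "frame_index")
  if (inherits(template, "depth_frame")) class(m) <- class(template)
  m
}

#' Median-denoise a depth frame
#'
#' Sliding-window median with edge-replicated borders; the default 5x5 window
#' suppresses the impulsive sensor noise that concentrates at depth
#' discontinuities (table edges, silhouette borders).
#'
#' @param frame hole-filled depth frame.
#' @param window odd window side length in pixels, >= 3 (default 5).
#' @return Denoised depth frame (integer mm).
#' @export
median_denoise <- function(frame, window = 5L) {
  if (window %% 2 != 1 || window < 3) stop("window must be odd and >= 3")
  m <- as_depth_matrix(frame)
  out <- cpp_median_filter(m, as.integer(window))
  keep_frame_attrs(out, frame)
}

#' Subtract a background frame and extract foreground blobs
#'
#' With a ceiling sensor a person is closer to the sensor than the background
#' surfaces, so foreground pixels satisfy `background - frame > min_diff_mm`.
#' Connected components (8-connectivity) of the foreground mask with at least
#' `min_area_px` pixels are returned sorted by area, largest first.
#'
#' @param frame,background hole-filled depth frames of equal size.
#' @param min_diff_mm minimum depth difference for foreground (default 100).
#' @param min_area_px minimum component area in pixels (default 300).
#' @return List of `foreground_blob` objects (possibly empty). Each blob has
#'   `mask` (logical matrix), `depth_mm` (frame values under the mask),
#'   `centroid_px` (x, y), `area_px`, and `max_height_point` (x, y, mm): the
#'   masked pixel closest to the sensor.
#' @export
subtract_background <- function(frame, background, min_diff_mm = 100,
                                min_area_px = 300) {
  m <- as_depth_matrix(frame)
  b <- as_depth_matrix(background)
  if (!identical(dim(m), dim(b)))
    stop("frame and background dimensions differ")
  fg <- (b - m) > min_diff_mm
  if (!any(fg)) return(list())
  lab <- cpp_label8(fg)
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_area_px)
  if (!length(keep)) return(list())
  keep <- keep[order(sizes[keep], decreasing = TRUE)]
  lapply(keep, function(k) new_blob(lab == k, m))
}

new_blob <- function(mask, depth) {
  idx <- which(mask, arr.ind = TRUE)
  vals <- depth[mask]
  zmin <- min(vals)
  # the "maximum midpoint": centroid of the pixels within 50 mm of the
  # closest surface (stable under flat-top ties and sensor noise)
  top <- vals <= zmin + 50
  structure(list(
    mask = mask,
    depth_mm = vals,
    centroid_px = c(x = mean(idx[, 2]), y = mean(idx[, 1])),
    area_px = nrow(idx),
    max_height_point = c(x = mean(idx[top, 2]), y = mean(idx[top, 1]),
                         mm = zmin)
  ), class = "foreground_blob")
}

#' @export
print.foreground_blob <- function(x, ...) {
  cat(sprintf(
    "foreground blob: %d px, centroid (%.1f, %.1f), top point (%d, %d) @ %d mm\n",
    x$area_px, x$centroid_px["x"], x$centroid_px["y"],
    x$max_height_point["x"], x$max_height_point["y"],
    x$max_height_point["mm"]))
  invisible(x)
}

shift_mat <- function(m, dr, dc) {
  # shift with edge replication
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) - dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) - dc, 1L), nc)
  m[ri, ci, drop = FALSE]
}

#' Sobel edge detection on a depth frame
#'
#' Marks pixels whose Sobel gradient magnitude (mm per pixel) is at least
#' `threshold`; used to find object borders, e.g., separating the person from
#' the table. Borders are edge-replicated.
#'
#' @param frame hole-filled depth frame.
#' @param threshold gradient-magnitude threshold in mm/px (default 200).
#' @return Logical matrix, `TRUE` at edges.
#' @export
sobel_edges <- function(frame, threshold = 200) {
  m <- as_depth_matrix(frame)
  storage.mode(m) <- "double"
  # x = columns, y = rows
  gx <- (shift_mat(m, -1, -1) + 2 * shift_mat(m, 0, -1) + shift_mat(m, 1, -1)) -
        (shift_mat(m, -1,  1) + 2 * shift_mat(m, 0,  1) + shift_mat(m, 1,  1))
  gy <- (shift_mat(m, -1, -1) + 2 * shift_mat(m, -1, 0) + shift_mat(m, -1, 1)) -
        (shift_mat(m,  1, -1) + 2 * shift_mat(m,  1, 0) + shift_mat(m,  1, 1))
  sqrt(gx^2 + gy^2) >= threshold
}
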