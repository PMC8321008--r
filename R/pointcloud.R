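# Back-projection of foreground blobs into sensor-centred 3-D point clouds.
#
# Coordinate convention (stated because nothing else fixes it): right-handed,
# origin at the sensor's optical centre, Z along the optical axis pointing
# down toward the floor, X along image columns, Y along image rows. All
# coordinates in mm. Pixel coordinates are 0-based (u = column - 1,
# v = row - 1) so the Kinect-v1-style principal point (319.5, 239.5) sits at
# the centre of a 640x480 grid.

#' Pinhole camera model
#'
#' Defaults are Kinect-v1-like intrinsics for 640x480 (fx = fy = 585,
#' principal point at the image centre), rescaled proportionally when another
#' grid size is given.
#'
#' @param width,height image size in pixels.
#' @param fx,fy focal lengths in pixels.
#' @param cx,cy principal point (0-based pixel coordinates).
#' @param sensor_height_mm sensor height above the floor.
#' @return A list of class `camera_model`.
#' @export
camera_model <- function(width = 640, height = 480,
                         fx = 585 * width / 640, fy = fx,
                         cx = (width - 1) / 2, cy = (height - 1) / 2,
                         sensor_height_mm = 3000) {
  if (fx <= 0 || fy <= 0) stop("focal lengths must be > 0")
  if (cx < 0 || cx >= width || cy < 0 || cy >= height)
    stop("principal point must lie inside the image")
  structure(list(width = width, height = height, fx = fx, fy = fy,
                 cx = cx, cy = cy, sensor_height_mm = sensor_height_mm),
            class = "camera_model")
}

#' Convert a foreground blob to a 3-D point cloud
#'
#' For a pixel at 0-based coordinates (u, v) with depth Z:
#' `X = (u - cx) * Z / fx`, `Y = (v - cy) * Z / fy`. One point per blob pixel.
#'
#' @param blob a `foreground_blob` (hole-free depths).
#' @param cam a [camera_model()].
#' @return An n-by-3 numeric matrix (columns X, Y, Z, mm) of class
#'   `point_cloud`.
#' @export
to_point_cloud <- function(blob, cam = camera_model(ncol(blob$mask),
                                                    nrow(blob$mask))) {
  idx <- which(blob$mask, arr.ind = TRUE)
  z <- as.numeric(blob$depth_mm)
  if (any(z <= 0)) stop("blob contains zero depth: holes must be filled first")
  u <- idx[, 2] - 1
  v <- idx[, 1] - 1
  pc <- cbind(X = (u - cam$cx) * z / cam$fx,
              Y = (v - cam$cy) * z / cam$fy,
              Z = z)
  class(pc) <- c("point_cloud", class(pc))
  pc
}

#' Project 3-D points back to pixel coordinates
#'
#' Inverse of [to_point_cloud()]; used for image-space (pixel) distance
#' checks and round-trip validation.
#'
#' @param pts n-by-3 matrix (X, Y, Z mm).
#' @param cam a [camera_model()].
#' @return n-by-2 matrix of 0-based pixel coordinates (u, v).
#' @export
project_points <- function(pts, cam) {
  cbind(u = pts[, 1] * cam$fx / pts[, 3] + cam$cx,
        v = pts[, 2] * cam$fy / pts[, 3] + cam$cy)
}

#' Head distance from the sensor
#'
#' The closest surface of a top-view person blob is the top of the head, so
#' the head-to-sensor distance is the minimum depth under the blob mask.
#'
#' @param blob a non-empty `foreground_blob`.
#' @return Distance in mm.
#' @export
head_distance_mm <- function(blob) {
  if (is.null(blob) || !length(blob$depth_mm)) stop("empty blob")
  min(blob$depth_mm)
}

#' Export a point cloud as XYZ text
#'
#' @param pc a `point_cloud`.
#' @param path output file (three space-separated columns, mm).
#' @return `path`, invisibly.
#' @export
write_xyz <- function(pc, path) {
  write.table(unclass(pc), path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
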