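# Reading and writing depth sequences, SetParam tables and annotations.
#
# Conventions: a depth frame is an integer matrix with nrow = image height
# (rows = y) and ncol = image width (cols = x); values are sensor-to-surface
# distances in mm, 0 marks an invalid ("hole") pixel. Frames are 0-indexed
# internally (frame_index attribute); SetParam tables and annotations use
# 1-based frame numbers, converted only here at the I/O boundary (internal
# code already works 1-based on R sequences, so the stored numbers are used
# as-is).

#' Construct a depth frame
#'
#' @param values integer matrix of mm distances (rows = y, cols = x);
#'   0 encodes an invalid pixel.
#' @param frame_index 0-based position of the frame in its sequence.
#' @return An integer matrix of class `depth_frame`.
#' @export
depth_frame <- function(values, frame_index = 0L) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (any(values < 0)) stop("depth values must be >= 0")
  m <- values
  storage.mode(m) <- "integer"
  attr(m, "frame_index") <- as.integer(frame_index)
  class(m) <- c("depth_frame", class(m))
  m
}

as_depth_matrix <- function(frame) {
  if (!is.matrix(frame)) stop("a depth frame must be a matrix")
  m <- unclass(frame)
  attr(m, "frame_index") <- NULL
  storage.mode(m) <- "integer"
  m
}

#' Sequence metadata
#'
#' @param fps frame rate, frames per second.
#' @param sensor_height_mm sensor height above the floor, mm.
#' @param frame_count number of frames in the sequence.
#' @param source_id free-text label of the recording.
#' @return A list of class `sequence_meta`.
#' @export
sequence_meta <- function(fps = 30, sensor_height_mm = 3000,
                          frame_count = 0L, source_id = "") {
  if (fps <= 0) stop("fps must be > 0")
  if (sensor_height_mm <= 0) stop("sensor_height_mm must be > 0")
  structure(list(fps = fps, sensor_height_mm = sensor_height_mm,
                 frame_count = as.integer(frame_count),
                 source_id = as.character(source_id)),
            class = "sequence_meta")
}

#' Write a depth sequence to a directory
#'
#' Frames are stored as 16-bit single-channel grayscale TIFF images
#' (`frame_00000.tif`, ...; lossless for the Kinect-v1 depth range) next to a
#' `meta.yaml` sidecar holding fps, sensor height, frame count, image size and
#' the source label.
#'
#' @param frames list of depth frames (integer matrices, mm).
#' @param path directory to create/fill.
#' @param meta a [sequence_meta()] object.
#' @return `path`, invisibly.
#' @export
write_depth_sequence <- function(frames, path, meta = sequence_meta()) {
  if (!length(frames)) stop("no frames to write")
  dims <- dim(frames[[1]])
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(frames)) {
    m <- as_depth_matrix(frames[[i]])
    if (!identical(dim(m), dims))
      stop(sprintf("frame %d has dimensions %dx%d, expected %dx%d",
                   i - 1L, nrow(m), ncol(m), dims[1], dims[2]))
    if (any(m > 65535)) stop("depth exceeds 16-bit range")
    tiff::writeTIFF(m / 65535, file.path(path, sprintf("frame_%05d.tif", i - 1L)),
                    bits.per.sample = 16L, compression = "none")
  }
  meta$frame_count <- length(frames)
  yaml::write_yaml(c(unclass(meta), list(width = dims[2], height = dims[1])),
                   file.path(path, "meta.yaml"))
  invisible(path)
}

#' Read a depth sequence from a directory
#'
#' @param path directory written by [write_depth_sequence()] (16-bit TIFF
#'   stack in lexicographic order plus `meta.yaml`).
#' @return A list with `frames` (list of `depth_frame`) and `meta`
#'   ([sequence_meta()]).
#' @export
read_depth_sequence <- function(path) {
  meta_file <- file.path(path, "meta.yaml")
  if (!file.exists(meta_file))
    stop("missing metadata file: ", meta_file)
  y <- yaml::read_yaml(meta_file)
  meta <- sequence_meta(fps = y$fps, sensor_height_mm = y$sensor_height_mm,
                        frame_count = y$frame_count,
                        source_id = if (is.null(y$source_id)) "" else y$source_id)
  files <- sort(list.files(path, pattern = "\\.tif$", full.names = TRUE))
  if (!length(files)) stop("no frames found in ", path)
  frames <- vector("list", length(files))
  dims <- NULL
  for (i in seq_along(files)) {
    img <- tiff::readTIFF(files[i])
    m <- matrix(as.integer(round(img * 65535)), nrow(img), ncol(img))
    if (is.null(dims)) dims <- dim(m)
    else if (!identical(dim(m), dims))
      stop("inconsistent frame dimensions in ", basename(files[i]))
    frames[[i]] <- depth_frame(m, frame_index = i - 1L)
  }
  list(frames = frames, meta = meta)
}

#' Construct a SetParam session table
#'
#' One row per detected meal segment: test number, start frame (SF) and end
#' frame (EF), 1-based and inclusive. Within a test, segments must be ordered
#' and non-overlapping.
#'
#' @param test_number integer vector of test labels.
#' @param sf,ef 1-based start/end frames, `sf <= ef` per segment.
#' @return A `data.frame` of class `session_table`.
#' @export
session_table <- function(test_number = integer(), sf = integer(),
                          ef = integer()) {
  d <- data.frame(test_number = as.integer(test_number),
                  sf = as.integer(sf), ef = as.integer(ef))
  if (nrow(d)) {
    if (any(d$sf < 1) || any(d$sf > d$ef))
      stop("each segment needs 1 <= sf <= ef")
    for (tn in unique(d$test_number)) {
      seg <- d[d$test_number == tn, , drop = FALSE]
      if (nrow(seg) > 1) {
        if (is.unsorted(seg$sf, strictly = TRUE) ||
            any(seg$sf[-1] <= seg$ef[-nrow(seg)]))
          stop("segments of test ", tn, " must be ordered and non-overlapping")
      }
    }
  }
  class(d) <- c("session_table", "data.frame")
  d
}

#' @export
print.session_table <- function(x, ...) {
  cat(sprintf("SetParam table: %d segment(s)\n", nrow(x)))
  if (nrow(x)) {
    m <- rbind(TN = x$test_number, SF = x$sf, EF = x$ef)
    colnames(m) <- seq_len(nrow(x))
    print(m)
  }
  invisible(x)
}

#' Write a SetParam table
#'
#' Serialized as delimited text with three rows (TN, SF, EF) and one column
#' per segment, matching the 3-by-n layout of the tracker's SetParam matrix.
#' An empty table produces the three row labels with no columns.
#'
#' @param table a [session_table()].
#' @param path output file.
#' @param sep field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_setparam <- function(table, path, sep = ",") {
  rows <- c(paste(c("TN", table$test_number), collapse = sep),
            paste(c("SF", table$sf), collapse = sep),
            paste(c("EF", table$ef), collapse = sep))
  ok <- tryCatch({ writeLines(rows, path); TRUE },
                 error = function(e) stop("cannot write SetParam to ", path,
                                          ": ", conditionMessage(e)))
  invisible(path)
}

#' Read a SetParam table
#'
#' @param path file written by [write_setparam()].
#' @param sep field separator.
#' @return A [session_table()].
#' @export
read_setparam <- function(path, sep = ",") {
  rows <- readLines(path)
  if (length(rows) < 3) stop("SetParam file needs 3 rows (TN, SF, EF)")
  parse_row <- function(line, label) {
    f <- strsplit(line, sep, fixed = TRUE)[[1]]
    if (f[1] != label) stop("expected row label ", label, ", found ", f[1])
    if (length(f) == 1) integer() else as.integer(f[-1])
  }
  session_table(test_number = parse_row(rows[1], "TN"),
                sf = parse_row(rows[2], "SF"),
                ef = parse_row(rows[3], "EF"))
}

#' Read ground-truth annotations
#'
#' Delimited text with columns `test_number`, `sf_gt`, `ef_gt`, `actions_gt`
#' (1-based frames; `1 <= sf_gt <= ef_gt`, `actions_gt >= 0`).
#'
#' @param path annotations file.
#' @return A `data.frame`, one row per test; empty file yields zero rows.
#' @export
read_annotations <- function(path) {
  if (!length(readLines(path, n = 1L)))
    return(data.frame(test_number = integer(), sf_gt = integer(),
                      ef_gt = integer(), actions_gt = integer()))
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("test_number", "sf_gt", "ef_gt", "actions_gt")
  if (!all(need %in% names(d)))
    stop("annotations need columns: ", paste(need, collapse = ", "))
  d <- d[need]
  if (nrow(d)) {
    if (any(d$sf_gt < 1)) stop("sf_gt must be >= 1")
    bad <- which(d$sf_gt > d$ef_gt)
    if (length(bad))
      stop("sf_gt > ef_gt in row(s): ", paste(bad, collapse = ", "))
    if (any(d$actions_gt < 0)) stop("actions_gt must be >= 0")
  }
  d
}

#' Write ground-truth annotations
#'
#' @param annotations data.frame with columns `test_number`, `sf_gt`,
#'   `ef_gt`, `actions_gt`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  write.csv(annotations[c("test_number", "sf_gt", "ef_gt", "actions_gt")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Path to a packaged evaluation fixture
#'
#' Packaged delimited-text fixtures: `"table3"` (per-test automatic, manual
#' and ground-truth SF/EF, 33 tests, 7 subjects), `"table7"` (detected vs
#' ground-truth action counts), `"ground_truth"` (the same ground truth in
#' annotations layout).
#'
#' @param name fixture name.
#' @return Path to the installed file.
#' @export
mealscan_fixture <- function(name = c("table3", "table7", "ground_truth")) {
  name <- match.arg(name)
  f <- system.file("extdata", paste0(name, ".csv"), package = "mealscan")
  if (f == "") stop("fixture not found: ", name)
  f
}
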