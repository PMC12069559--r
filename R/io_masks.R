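#' Construct a label-mask sequence
#'
#' Wraps a stack of per-frame segmentation label masks into the container used
#' by all downstream operations. Labels are 0 = background, 1 = glottis,
#' 2 = right vocal fold, 3 = left vocal fold.
#'
#' @param frames integer or raw array of dimension height x width x time
#'   (a single H x W matrix is treated as one frame).
#' @param fps frame rate in frames per second (> 0).
#' @param dorsal_at_top logical; if `FALSE` the frames are flipped row-wise so
#'   that the dorsal side ends up at row 1, and the flag is set to `TRUE`.
#' @param validate check that all values are in 0..3.
#' @return An object of class `mask_sequence` with elements `frames`
#'   (raw uint8 array), `fps` and `dorsal_at_top`.
#' @export
mask_sequence <- function(frames, fps, dorsal_at_top = TRUE, validate = TRUE) {
  if (is.matrix(frames)) dim(frames) <- c(dim(frames), 1L)
  stopifnot(length(dim(frames)) == 3L)
  if (!is.numeric(fps) || length(fps) != 1L || is.na(fps) || fps <= 0)
    stop("`fps` must be a single positive number", call. = FALSE)
  if (is.raw(frames)) {
    raw_frames <- frames
  } else {
    v <- as.integer(frames)
    if (validate && (anyNA(v) || any(v < 0L | v > 3L)))
      stop("mask labels must be integers in {0, 1, 2, 3}", call. = FALSE)
    raw_frames <- as.raw(v)
    dim(raw_frames) <- dim(frames)
  }
  if (validate && is.raw(frames) && any(as.integer(frames) > 3L))
    stop("mask labels must be integers in {0, 1, 2, 3}", call. = FALSE)
  if (!isTRUE(dorsal_at_top)) {
    raw_frames <- raw_frames[dim(raw_frames)[1]:1, , , drop = FALSE]
    dorsal_at_top <- TRUE
  }
  structure(
    list(frames = raw_frames, fps = as.numeric(fps), dorsal_at_top = TRUE,
         cache = new.env(parent = emptyenv())),
    class = "mask_sequence"
  )
}

#' @export
print.mask_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<mask_sequence> %d frames of %d x %d px @ %g fps\n",
              d[3], d[1], d[2], x$fps))
  invisible(x)
}

#' Number of frames in a mask sequence
#' @param seq a `mask_sequence`.
#' @return integer frame count.
#' @export
n_frames <- function(seq) dim(seq$frames)[3]

#' Extract one frame as an integer label matrix
#' @param seq a `mask_sequence`.
#' @param t frame index (1-based).
#' @return H x W integer matrix of labels.
#' @export
mask_frame <- function(seq, t) {
  d <- dim(seq$frames)
  if (t < 1L || t > d[3]) stop("frame index out of range", call. = FALSE)
  matrix(as.integer(seq$frames[, , t]), d[1], d[2])
}

#' Read a label-mask sequence from a multipage TIFF plus JSON sidecar
#'
#' The TIFF holds one uint8 page per frame with raw label values; the JSON
#' sidecar supplies `{"fps": <number>, "dorsal_at_top": <bool>}`. Orientation
#' is normalized so that the dorsal side is at row 1.
#'
#' @param path path to the multipage TIFF.
#' @param meta_path path to the JSON metadata; defaults to `path` with a
#'   `.json` extension.
#' @return a [mask_sequence()].
#' @export
read_mask_sequence <- function(path, meta_path = NULL) {
  if (is.null(meta_path)) meta_path <- sub("\\.tiff?$", ".json", path)
  if (!file.exists(path)) stop("mask container not found: ", path, call. = FALSE)
  if (!file.exists(meta_path)) stop("metadata sidecar not found: ", meta_path, call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (is.null(meta$fps)) stop("metadata error: missing `fps`", call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- vapply(pages, function(m) {
    storage.mode(m) <- "integer"
    m
  }, matrix(0L, nrow(pages[[1]]), ncol(pages[[1]])))
  if (any(frames < 0L | frames > 3L))
    stop("format error: unknown label value in mask container", call. = FALSE)
  mask_sequence(frames, fps = meta$fps,
                dorsal_at_top = !isFALSE(meta$dorsal_at_top))
}

#' Write a label-mask sequence to a multipage TIFF plus JSON sidecar
#'
#' @param seq a [mask_sequence()].
#' @param path output TIFF path.
#' @param meta_path output JSON path; defaults to `path` with `.json`.
#' @return invisibly, the TIFF path.
#' @export
write_mask_sequence <- function(seq, path, meta_path = NULL) {
  if (is.null(meta_path)) meta_path <- sub("\\.tiff?$", ".json", path)
  d <- dim(seq$frames)
  pages <- lapply(seq_len(d[3]), function(t) {
    m <- matrix(as.integer(seq$frames[, , t]), d[1], d[2])
    m / 255 # writeTIFF stores round(x * 255) as uint8
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  jsonlite::write_json(
    list(fps = seq$fps, dorsal_at_top = seq$dorsal_at_top),
    meta_path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Glottal area waveform
#'
#' Counts glottis-labelled pixels per frame.
#'
#' @param seq a [mask_sequence()].
#' @return object of class `gaw_series`: list with `values` (length-T pixel
#'   counts) and `fps`.
#' @export
compute_gaw <- function(seq) {
  st <- .mask_stats(seq)
  structure(list(values = as.numeric(st$gaw), fps = seq$fps),
            class = "gaw_series")
}

#' @export
print.gaw_series <- function(x, ...) {
  cat(sprintf("<gaw_series> T=%d @ %g fps, range [%g, %g] px\n",
              length(x$values), x$fps, min(x$values), max(x$values)))
  invisible(x)
}

#' Write a glottal area waveform to CSV
#' @param gaw a `gaw_series`.
#' @param path output CSV path (columns frame, area_px).
#' @return invisibly, the path.
#' @export
write_gaw_csv <- function(gaw, path) {
  write.csv(data.frame(frame = seq_along(gaw$values), area_px = gaw$values),
            path, row.names = FALSE)
  invisible(path)
}

# cached full-stack pixel pass (GAW, raw landmarks, bounding boxes); the
# cache environment is shared by reference across copies of the sequence
.mask_stats <- function(seq) {
  if (!is.null(seq$cache) && !is.null(seq$cache$stats)) return(seq$cache$stats)
  d <- dim(seq$frames)
  st <- mask_stats_cpp(seq$frames, d[1], d[2], d[3])
  if (!is.null(seq$cache)) seq$cache$stats <- st
  st
}

# largest closed contour of a binary region, traced at level 0.5.
# m: logical/numeric matrix (possibly a cropped window), offset: c(row0, col0)
# subtracted... added back to coordinates. Returns N x 2 matrix (row, col),
# closed loop without duplicated end vertex, oriented counter-clockwise when
# viewed with columns as x and rows increasing downwards.
.trace_region <- function(m, offset = c(0, 0), warn_multi = TRUE) {
  if (!any(m > 0)) return(NULL)
  cl <- grDevices::contourLines(x = seq_len(nrow(m)), y = seq_len(ncol(m)),
                                z = m + 0, levels = 0.5)
  if (length(cl) == 0L) return(NULL)
  areas <- vapply(cl, function(p) abs(.signed_area(p$x, p$y)), 0)
  if (length(cl) > 1L && warn_multi)
    warning("region has multiple connected components; keeping largest",
            call. = FALSE)
  p <- cl[[which.max(areas)]]
  pts <- cbind(row = p$x + offset[1], col = p$y + offset[2])
  n <- nrow(pts)
  if (n > 1L && all(pts[1, ] == pts[n, ])) pts <- pts[-n, , drop = FALSE]
  # normalize orientation: CCW on screen (x = col, y = row pointing down)
  if (.signed_area(pts[, 2], -pts[, 1]) < 0) pts <- pts[nrow(pts):1, , drop = FALSE]
  pts
}

.signed_area <- function(x, y) {
  n <- length(x)
  0.5 * sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)
}

#' Extract region contours for one frame
#'
#' Traces the glottis and both vocal-fold regions of a single frame with
#' marching squares at level 0.5, giving closed polylines at half-pixel
#' precision. If a fold label forms several connected components, the largest
#' is kept with a warning.
#'
#' @param seq a [mask_sequence()].
#' @param t frame index (1-based).
#' @return object of class `contour_set`: list with `glottis` (N x 2 matrix of
#'   (row, col) vertices or `NULL` when the glottis is closed), `left`,
#'   `right` (fold contours) and `frame`.
#' @export
extract_contours <- function(seq, t) {
  f <- mask_frame(seq, t)
  left <- .trace_region(f == LBL_LEFT)
  right <- .trace_region(f == LBL_RIGHT)
  if (is.null(left) || is.null(right))
    stop(sprintf("missing structure in frame %d: both vocal folds must be visible", t),
         call. = FALSE)
  # several glottal openings (e.g. hourglass closure) are physiological:
  # keep the largest without complaint
  glottis <- .trace_region(f == LBL_GLOTTIS, warn_multi = FALSE)
  structure(list(glottis = glottis, left = left, right = right, frame = t),
            class = "contour_set")
}
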