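# LVG construction: fold-edge splitting, signed normalized deflection
# profiles, assembly of the 512 x T matrix, and rendering.

#' Closed-form point-to-segment distances with side information
#'
#' Distance from each point to the continuous segment `a`-`b` (the minimum
#' over all real positions along the axis, evaluated in closed form), plus the
#' sign of the perpendicular offset relative to the segment direction.
#'
#' @param pts N x 2 matrix of (row, col) points.
#' @param a,b segment endpoints, `c(row, col)`.
#' @return list with `d` (distances) and `side` (+1 left of a->b direction in
#'   screen coordinates, -1 right, 0 on the line within 1e-9).
#' @export
point_segment_distance <- function(pts, a, b) {
  pts <- rbind(pts) # tolerate a single point given as a vector
  u <- b - a
  L2 <- sum(u^2)
  if (L2 <= 0) stop("degenerate segment", call. = FALSE)
  w1 <- pts[, 1] - a[1]
  w2 <- pts[, 2] - a[2]
  tt <- pmin(1, pmax(0, (w1 * u[1] + w2 * u[2]) / L2))
  dr <- w1 - tt * u[1]
  dc <- w2 - tt * u[2]
  crossz <- u[1] * w2 - u[2] * w1
  side <- sign(crossz)
  side[abs(crossz) < 1e-9] <- 0
  list(d = unname(sqrt(dr^2 + dc^2)), side = unname(side))
}

# polyline arc length (cumulative, starting at 0)
.arclength <- function(pts) {
  if (nrow(pts) < 2L) return(0)
  c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
}

#' Split a fold contour into its medial edge from P to A
#'
#' Cuts the closed fold contour at the vertices nearest to the posterior point
#' and the anterior commissure and keeps the arc that runs closer to the
#' glottal midline (the segment joining the midpoint of the posterior points
#' to the anterior commissure), ordered posterior to anterior.
#'
#' @param contour closed N x 2 fold contour (row, col).
#' @param P,A the fold's posterior point and the anterior commissure.
#' @param midline_P,midline_A endpoints of the reference midline; default to
#'   `P` and `A` themselves (adequate when the posterior points coincide).
#' @return M x 2 matrix of edge vertices ordered from P to A.
#' @export
fold_edge <- function(contour, P, A, midline_P = P, midline_A = A) {
  n <- nrow(contour)
  d2 <- function(q) (contour[, 1] - q[1])^2 + (contour[, 2] - q[2])^2
  iP <- which.min(d2(P))
  iA <- which.min(d2(A))
  if (iP == iA)
    stop("degenerate contour: P and A map to the same nearest vertex",
         call. = FALSE)
  idx1 <- if (iP <= iA) iP:iA else c(iP:n, 1:iA)
  idx2 <- if (iA <= iP) iA:iP else c(iA:n, 1:iP)
  arc1 <- contour[idx1, , drop = FALSE]
  arc2 <- contour[rev(idx2), , drop = FALSE] # reorder P -> A
  score <- function(arc)
    mean(point_segment_distance(arc, midline_P, midline_A)$d)
  if (score(arc1) <= score(arc2)) arc1 else arc2
}

#' Signed normalized deflection profile of one fold edge
#'
#' For every vertex of the medial edge, computes the exact point-to-segment
#' distance to the fold's vibrational axis, normalizes it by the axis length,
#' assigns a sign (+ lateral, - contralateral, with the lateral half-plane
#' defined per side), and resamples the signed values by cumulative arc length
#' to `n` equidistant positions from posterior (p = 0) to anterior (p = 1).
#'
#' @param edge M x 2 medial edge vertices ordered P to A (see [fold_edge()]).
#' @param P,A axis endpoints.
#' @param side `"left"` or `"right"`; decides which half-plane is lateral.
#' @param n number of resampled positions.
#' @return numeric vector of length `n`, dimensionless fractions of the axis
#'   length.
#' @export
deflection_profile <- function(edge, P, A, side = c("left", "right"), n = 256L) {
  side <- match.arg(side)
  L <- sqrt(sum((A - P)^2))
  if (L <= 0) stop("degenerate axis", call. = FALSE)
  ds <- point_segment_distance(edge, P, A)
  # axis direction points ventral (increasing row); a positive cross product
  # is the high-column half-plane, which is lateral for the left fold
  lateral <- if (side == "left") ds$side else -ds$side
  delta <- lateral * ds$d / L
  s <- .arclength(edge)
  if (length(s) == 1L || s[length(s)] <= 0)
    return(rep(delta[1], n))
  approx(s, delta, xout = seq(0, s[length(s)], length.out = n), ties = "ordered")$y
}

#' Per-frame fold-edge geometry for a whole sequence
#'
#' Extracts, for every frame, both medial fold edges together with the
#' smoothed landmarks. This intermediate form feeds [lvg_from_geometry()] and
#' makes geometric transformations (scaling, rotation) of a sequence testable
#' without re-rasterizing masks.
#'
#' @param seq a [mask_sequence()].
#' @param landmarks optional smoothed `landmark_track`; computed (tracked and
#'   smoothed with `window`/`overlap`) when missing.
#' @param window,overlap sliding-window parameters for [smooth_landmarks()].
#' @return list with `frames` (per-frame lists: `left`, `right` edge matrices,
#'   `P_r`, `P_l`, `A`), `fps`, `landmarks`.
#' @export
lvg_geometry <- function(seq, landmarks = NULL, window = 150L, overlap = 25L) {
  T <- n_frames(seq)
  if (is.null(landmarks)) {
    gaw <- compute_gaw(seq)
    landmarks <- smooth_landmarks(track_landmarks(seq), gaw, window, overlap)
  }
  st <- .mask_stats(seq)
  d <- dim(seq$frames)
  frames <- vector("list", T)
  failed <- integer(0)
  for (t in seq_len(T)) {
    # crop to the mask bounding box (plus margin) before tracing
    bb <- st$bbox[t, ]
    r0 <- max(1L, bb[1] - 2L); r1 <- min(d[1], bb[2] + 2L)
    c0 <- max(1L, bb[3] - 2L); c1 <- min(d[2], bb[4] + 2L)
    f <- matrix(as.integer(seq$frames[r0:r1, c0:c1, t]), r1 - r0 + 1L)
    off <- c(r0 - 1L, c0 - 1L)
    left <- .trace_region(f == LBL_LEFT, off)
    right <- .trace_region(f == LBL_RIGHT, off)
    if (is.null(left) || is.null(right)) {
      failed <- c(failed, t)
      next
    }
    P_r <- landmarks$P_r[t, ]; P_l <- landmarks$P_l[t, ]; A <- landmarks$A[t, ]
    mid_P <- (P_r + P_l) / 2
    frames[[t]] <- list(
      left = fold_edge(left, P_l, A, mid_P, A),
      right = fold_edge(right, P_r, A, mid_P, A),
      P_r = P_r, P_l = P_l, A = A
    )
  }
  if (length(failed) > 0L)
    stop("fold extraction failed in frame(s): ",
         paste(utils::head(failed, 10), collapse = ", "),
         if (length(failed) > 10) " ...", call. = FALSE)
  list(frames = frames, fps = seq$fps, landmarks = landmarks)
}

#' Assemble an LVG matrix from fold-edge geometry
#'
#' @param geom output of [lvg_geometry()] (possibly transformed).
#' @param n positions per fold.
#' @return an `lvg_matrix`: list with `D` ((2n) x T signed normalized
#'   deflections; rows 1..n left fold posterior to anterior, rows n+1..2n
#'   right fold posterior to anterior), `n`, `fps`.
#' @export
lvg_from_geometry <- function(geom, n = 256L) {
  T <- length(geom$frames)
  D <- matrix(NA_real_, 2L * n, T)
  for (t in seq_len(T)) {
    g <- geom$frames[[t]]
    D[1:n, t] <- deflection_profile(g$left, g$P_l, g$A, "left", n)
    D[(n + 1):(2 * n), t] <- deflection_profile(g$right, g$P_r, g$A, "right", n)
  }
  structure(list(D = D, n = n, fps = geom$fps, layout = "left-top"),
            class = "lvg_matrix")
}

#' Build the Laryngovibrogram from a mask sequence
#'
#' Full construction: glottal area waveform, raw landmark tracking,
#' sliding-window stabilization, per-fold vibrational axes, medial fold edges,
#' signed normalized deflection profiles resampled to `n` positions per fold,
#' concatenated over time.
#'
#' @param seq a [mask_sequence()].
#' @param window,overlap sliding-window parameters (frames) for landmark
#'   stabilization.
#' @param n resampled positions per fold.
#' @return an `lvg_matrix` (see [lvg_from_geometry()]); its attribute
#'   `landmarks` carries the smoothed landmark track.
#' @export
build_lvg <- function(seq, window = 150L, overlap = 25L, n = 256L) {
  geom <- lvg_geometry(seq, window = window, overlap = overlap)
  M <- lvg_from_geometry(geom, n = n)
  attr(M, "landmarks") <- geom$landmarks
  M
}

#' @export
print.lvg_matrix <- function(x, ...) {
  cat(sprintf("<lvg_matrix> %d x %d (2 folds x %d positions, %d frames) @ %g fps\n",
              nrow(x$D), ncol(x$D), x$n, ncol(x$D), x$fps))
  cat(sprintf("  deflection range [%.4f, %.4f] (fraction of axis length)\n",
              min(x$D), max(x$D)))
  invisible(x)
}

#' Write an LVG or PVG matrix as CSV (rows = positions, columns = frames)
#' @param M an `lvg_matrix` or `pvg_matrix`.
#' @param path output CSV path.
#' @return invisibly, the path.
#' @export
write_lvg_csv <- function(M, path) {
  write.csv(as.data.frame(M$D), path, row.names = FALSE)
  invisible(path)
}

#' Read an LVG or PVG matrix back from CSV + JSON sidecar
#'
#' Counterpart of [write_lvg_csv()]; the sidecar (as written by
#' [run_pipeline()]) carries `fps`, `n`, `layout`, `kind`.
#'
#' @param path CSV path.
#' @param meta_path JSON sidecar path; defaults to `path` with the extension
#'   replaced by `.json`.
#' @return an `lvg_matrix` (a `pvg_matrix` if the sidecar says `kind: pvg`).
#' @export
read_lvg_csv <- function(path, meta_path = NULL) {
  if (is.null(meta_path)) meta_path <- sub("\\.csv$", ".json", path)
  if (!file.exists(path) || !file.exists(meta_path))
    stop("format error: missing LVG CSV or JSON sidecar", call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (f in c("fps", "n", "layout"))
    if (is.null(meta[[f]]))
      stop("format error: sidecar lacks field '", f, "'", call. = FALSE)
  D <- as.matrix(utils::read.csv(path))
  dimnames(D) <- NULL
  n <- as.integer(meta$n)
  if (nrow(D) != 2L * n)
    stop("format error: matrix has ", nrow(D), " rows, expected ", 2L * n,
         call. = FALSE)
  cls <- if (identical(meta$kind, "pvg")) c("pvg_matrix", "lvg_matrix")
         else "lvg_matrix"
  structure(list(D = D, n = n, fps = meta$fps, layout = meta$layout),
            class = cls)
}

#' Render an LVG (or PVG) matrix to PNG
#'
#' Diverging colormap: warm colors are lateral (positive), cold colors
#' contralateral (negative) deflections; axes annotated in milliseconds and
#' percent of fold length.
#'
#' @param M an `lvg_matrix` or `pvg_matrix`.
#' @param path output PNG path.
#' @param width,height device size in pixels.
#' @return invisibly, the path.
#' @export
render_lvg <- function(M, path, width = max(480L, ncol(M$D)), height = 560L) {
  D <- M$D
  lim <- max(abs(range(D)), 1e-12)
  pal <- hcl.colors(255, "Blue-Red 2")
  T <- ncol(D)
  grDevices::png(path, width = width, height = height)
  op <- graphics::par(mar = c(4.2, 4.2, 2, 1))
  on.exit({ graphics::par(op); dev.off() }, add = TRUE)
  # image(): x = time, y = position; flip rows so row 1 renders at the top
  image(x = (seq_len(T) - 0.5) / M$fps * 1000,
        y = seq_len(nrow(D)),
        z = t(D[nrow(D):1, , drop = FALSE]),
        zlim = c(-lim, lim), col = pal, useRaster = TRUE,
        xlab = "time [ms]", ylab = "", yaxt = "n",
        main = if (inherits(M, "pvg_matrix")) "PVG" else "LVG")
  n <- M$n
  at <- c(1, n / 2, n, n + n / 2, 2 * n)
  axis(2, at = 2 * n + 1 - at,
       labels = c("0%", "50% L", "100%", "50% R", "100%"), las = 2)
  box()
  invisible(path)
}
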