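# Phonovibrogram baseline: deflections of the glottal contour relative to the
# glottal symmetry axis, normalized by glottal axis length.

#' Build the Phonovibrogram from a mask sequence
#'
#' The glottal symmetry axis joins the most dorsal and most ventral vertices
#' of the per-frame glottis contour, stabilized with the same sliding-window
#' median as the landmark tracks. The glottis outline is split at the vertices
#' nearest the axis endpoints into a left and a right edge, whose distances to
#' the axis are normalized by the glottal axis length and resampled to `n`
#' positions per side. Frames with a closed glottis give zero columns.
#'
#' @param seq a [mask_sequence()].
#' @param window,overlap sliding-window parameters (frames).
#' @param n resampled positions per side.
#' @return a `pvg_matrix` (also an `lvg_matrix` for rendering/export): list
#'   with `D` ((2n) x T), `n`, `fps`, `axis_P`, `axis_A` (smoothed glottal
#'   axis endpoint tracks, T x 2) and `open` (logical, glottis visible).
#' @export
build_pvg <- function(seq, window = 150L, overlap = 25L, n = 256L) {
  T <- n_frames(seq)
  st <- .mask_stats(seq)
  d <- dim(seq$frames)
  contours <- vector("list", T)
  rawP <- matrix(NA_real_, T, 2)
  rawA <- matrix(NA_real_, T, 2)
  for (t in seq_len(T)) {
    if (st$gaw[t] == 0L) next
    bb <- st$bbox[t, ]
    r0 <- max(1L, bb[1] - 2L); r1 <- min(d[1], bb[2] + 2L)
    c0 <- max(1L, bb[3] - 2L); c1 <- min(d[2], bb[4] + 2L)
    f <- matrix(as.integer(seq$frames[r0:r1, c0:c1, t]), r1 - r0 + 1L)
    g <- .trace_region(f == LBL_GLOTTIS, c(r0 - 1L, c0 - 1L), warn_multi = FALSE)
    if (is.null(g)) next
    contours[[t]] <- g
    iP <- which.min(g[, 1]); iA <- which.max(g[, 1])
    rawP[t, ] <- g[iP, ]
    rawA[t, ] <- g[iA, ]
  }
  open <- !is.na(rawP[, 1])
  if (!any(open)) {
    D <- matrix(0, 2L * n, T)
    return(structure(list(D = D, n = n, fps = seq$fps, layout = "left-top",
                          axis_P = rawP, axis_A = rawA, open = open),
                     class = c("pvg_matrix", "lvg_matrix")))
  }
  sm <- .smooth_track_na(list(rawP, rawA), window, overlap)
  axP <- sm[[1]]; axA <- sm[[2]]
  D <- matrix(0, 2L * n, T)
  for (t in seq_len(T)) {
    g <- contours[[t]]
    if (is.null(g)) next
    P <- axP[t, ]; A <- axA[t, ]
    L <- sqrt(sum((A - P)^2))
    if (L <= 0) next
    iP <- which.min((g[, 1] - P[1])^2 + (g[, 2] - P[2])^2)
    iA <- which.min((g[, 1] - A[1])^2 + (g[, 2] - A[2])^2)
    if (iP == iA) next
    m <- nrow(g)
    idx1 <- if (iP <= iA) iP:iA else c(iP:m, 1:iA)
    idx2 <- if (iA <= iP) iA:iP else c(iA:m, 1:iP)
    arc1 <- g[idx1, , drop = FALSE]
    arc2 <- g[rev(idx2), , drop = FALSE]
    left_first <- mean(arc1[, 2]) >= mean(arc2[, 2])
    left <- if (left_first) arc1 else arc2
    right <- if (left_first) arc2 else arc1
    D[1:n, t] <- deflection_profile(left, P, A, "left", n)
    D[(n + 1):(2 * n), t] <- deflection_profile(right, P, A, "right", n)
  }
  structure(list(D = D, n = n, fps = seq$fps, layout = "left-top",
                 axis_P = axP, axis_A = axA, open = open),
            class = c("pvg_matrix", "lvg_matrix"))
}

# sliding-window median smoothing of (possibly NA-gapped) T x 2 tracks
.smooth_track_na <- function(tracks, window, overlap) {
  T <- nrow(tracks[[1]])
  starts <- .window_starts(T, window, overlap)
  ends <- pmin(starts + window - 1L, T)
  centers <- (starts + ends) / 2
  lapply(tracks, function(tr) {
    m <- t(vapply(seq_along(starts), function(i) {
      rows <- starts[i]:ends[i]
      c(median(tr[rows, 1], na.rm = TRUE), median(tr[rows, 2], na.rm = TRUE))
    }, numeric(2)))
    keep <- !is.na(m[, 1])
    if (!any(keep)) return(matrix(NA_real_, T, 2))
    if (sum(keep) == 1L)
      return(matrix(m[keep, ], T, 2, byrow = TRUE))
    cbind(.interp_extrap(centers[keep], m[keep, 1], seq_len(T)),
          .interp_extrap(centers[keep], m[keep, 2], seq_len(T)))
  })
}

#' Position of the medial glottal (PVG) trajectory along the vocal fold
#'
#' Projects the time-averaged midpoint of the glottal symmetry axis onto the
#' vocal-fold axis parameterization, returning where the PVG's medial
#' trajectory sits as a fraction of fold length. Quantifies how much of the
#' fold the glottal opening actually covers, and where.
#'
#' @param pvg a `pvg_matrix` from [build_pvg()].
#' @param axes an `axis_track` from [vibrational_axes()] on the same sequence.
#' @return scalar fraction in `[0, 1]`.
#' @export
pvg_medial_position <- function(pvg, axes) {
  if (!any(pvg$open))
    stop("undefined position: the glottis never opens in this sequence",
         call. = FALSE)
  mid_g <- colMeans((pvg$axis_P[pvg$open, , drop = FALSE] +
                     pvg$axis_A[pvg$open, , drop = FALSE]) / 2)
  P <- colMeans((axes$P_r + axes$P_l) / 2)
  A <- colMeans(axes$A)
  u <- A - P
  p <- sum((mid_g - P) * u) / sum(u^2)
  min(1, max(0, p))
}
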