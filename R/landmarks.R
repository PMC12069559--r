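# Landmark detection, sliding-window stabilization, vibrational axes and the
# glottal opening angle.

# 8-neighborhood dilation of a logical matrix
.dilate8 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  p <- matrix(FALSE, H + 2L, W + 2L)
  p[2:(H + 1), 2:(W + 1)] <- m
  out <- p[1:H, 1:W]
  for (dr in 0:2) for (dc in 0:2) {
    if (dr == 0 && dc == 0) next
    out <- out | p[(1 + dr):(H + dr), (1 + dc):(W + dc)]
  }
  out
}

.extreme_point <- function(mask, ventral = FALSE) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NULL)
  r <- if (ventral) max(idx[, 1]) else min(idx[, 1])
  c(r, mean(idx[idx[, 1] == r, 2]))
}

#' Detect raw per-frame landmarks from a label frame
#'
#' Posterior points `P_r`, `P_l` are the most dorsal pixels of the respective
#' fold that are 8-adjacent to the other fold or to the glottis; the anterior
#' commissure `A` is the most ventral pixel of the fold-fold adjacency set
#' (falling back to the most ventral fold pixel adjacent to the glottis when
#' the folds never touch). Ties are resolved by averaging columns. When the
#' frame contains no glottis pixels, full closure is assumed and `P_r = P_l`
#' (their midpoint).
#'
#' This is the reference implementation; [track_landmarks()] uses a compiled
#' equivalent for whole sequences.
#'
#' @param frame H x W integer label matrix (or a `mask_sequence` plus `t`).
#' @param t frame index when `frame` is a `mask_sequence`.
#' @return list with numeric `(row, col)` points `P_r`, `P_l`, `A`.
#' @export
detect_endpoints <- function(frame, t = NULL) {
  if (inherits(frame, "mask_sequence")) frame <- mask_frame(frame, t)
  right <- frame == LBL_RIGHT
  left <- frame == LBL_LEFT
  glottis <- frame == LBL_GLOTTIS
  if (!any(right) || !any(left))
    stop("landmark failure: both vocal folds must be present", call. = FALSE)
  bd_r <- right & .dilate8(left | glottis)
  bd_l <- left & .dilate8(right | glottis)
  contact <- (right & .dilate8(left)) | (left & .dilate8(right))
  if (!any(bd_r) || !any(bd_l))
    stop("landmark failure: folds share no adjacency and no glottis is present",
         call. = FALSE)
  P_r <- .extreme_point(bd_r)
  P_l <- .extreme_point(bd_l)
  A <- if (any(contact)) .extreme_point(contact, ventral = TRUE)
       else .extreme_point(bd_r | bd_l, ventral = TRUE)
  if (!any(glottis)) P_r <- P_l <- (P_r + P_l) / 2
  list(P_r = P_r, P_l = P_l, A = A)
}

#' Track raw landmarks over a whole sequence
#'
#' @param seq a [mask_sequence()].
#' @return object of class `landmark_track` with T x 2 matrices `P_r`, `P_l`,
#'   `A` (columns row, col), `fps`, and `smoothed = FALSE`.
#' @export
track_landmarks <- function(seq) {
  st <- .mask_stats(seq)
  if (!all(st$ok)) {
    bad <- which(!st$ok)
    stop("landmark failure in frame(s): ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) " ...", call. = FALSE)
  }
  lm <- st$landmarks
  structure(list(
    P_r = lm[, 1:2, drop = FALSE], P_l = lm[, 3:4, drop = FALSE],
    A = lm[, 5:6, drop = FALSE], fps = seq$fps, smoothed = FALSE
  ), class = "landmark_track")
}

# linear interpolation through (x, y) with linear extrapolation beyond the
# first/last support points (clamping would flatten slow drifts at the ends)
.interp_extrap <- function(x, y, xout) {
  k <- length(x)
  if (k == 1L) return(rep(y, length(xout)))
  out <- approx(x, y, xout = xout, rule = 2)$y
  lo <- xout < x[1]
  hi <- xout > x[k]
  if (any(lo))
    out[lo] <- y[1] + (y[2] - y[1]) / (x[2] - x[1]) * (xout[lo] - x[1])
  if (any(hi))
    out[hi] <- y[k] + (y[k] - y[k - 1]) / (x[k] - x[k - 1]) * (xout[hi] - x[k])
  out
}

# sliding-window start indices for window size w, overlap o
.window_starts <- function(T, w, o) {
  if (T <= w) return(1L)
  stride <- w - o
  starts <- seq(1L, T - w + 1L, by = stride)
  if (utils::tail(starts, 1L) + w - 1L < T) starts <- c(starts, T - w + 1L)
  starts
}

#' Stabilize landmark tracks with a sliding-window median
#'
#' Landmarks drift slowly over a recording; per-window coordinate-wise medians
#' are assigned to the window centers and linearly interpolated in between
#' (edge frames take the nearest center value). Within any window where the
#' glottal area waveform reaches zero, complete closure is assumed and both
#' posterior points are replaced by the midpoint of their window medians.
#'
#' @param lm a raw `landmark_track` from [track_landmarks()].
#' @param gaw the matching [compute_gaw()] series.
#' @param window window size in frames.
#' @param overlap overlap between consecutive windows in frames.
#' @param closure_tol glottal areas at or below this pixel count count as
#'   full closure.
#' @return a smoothed `landmark_track`.
#' @export
smooth_landmarks <- function(lm, gaw, window = 150L, overlap = 25L,
                             closure_tol = 0) {
  stopifnot(window > overlap)
  T <- nrow(lm$P_r)
  starts <- .window_starts(T, window, overlap)
  ends <- pmin(starts + window - 1L, T)
  centers <- (starts + ends) / 2
  med <- function(track) {
    t(vapply(seq_along(starts), function(i) {
      rows <- starts[i]:ends[i]
      c(median(track[rows, 1]), median(track[rows, 2]))
    }, numeric(2)))
  }
  m_pr <- med(lm$P_r); m_pl <- med(lm$P_l); m_a <- med(lm$A)
  closed <- vapply(seq_along(starts), function(i)
    min(gaw$values[starts[i]:ends[i]]) <= closure_tol, logical(1))
  if (any(closed)) {
    mid <- (m_pr[closed, , drop = FALSE] + m_pl[closed, , drop = FALSE]) / 2
    m_pr[closed, ] <- mid
    m_pl[closed, ] <- mid
  }
  interp <- function(m) {
    if (nrow(m) == 1L)
      return(matrix(m, T, 2, byrow = TRUE))
    cbind(.interp_extrap(centers, m[, 1], seq_len(T)),
          .interp_extrap(centers, m[, 2], seq_len(T)))
  }
  structure(list(P_r = interp(m_pr), P_l = interp(m_pl), A = interp(m_a),
                 fps = lm$fps, smoothed = TRUE),
            class = "landmark_track")
}

#' Per-fold vibrational axes
#'
#' The vibrational axis of each fold is the oriented segment from its
#' posterior point to the anterior commissure; deflections are measured
#' against it and normalized by its length.
#'
#' @param lm a (smoothed) `landmark_track`.
#' @return object of class `axis_track`: `P_r`, `P_l`, `A` (T x 2) and
#'   Euclidean lengths `L_r`, `L_l` (length T), plus `fps`.
#' @export
vibrational_axes <- function(lm) {
  L_r <- sqrt(rowSums((lm$A - lm$P_r)^2))
  L_l <- sqrt(rowSums((lm$A - lm$P_l)^2))
  if (any(L_r <= 0) || any(L_l <= 0))
    stop("degenerate axis: posterior point coincides with anterior commissure",
         call. = FALSE)
  structure(list(P_r = lm$P_r, P_l = lm$P_l, A = lm$A,
                 L_r = L_r, L_l = L_l, fps = lm$fps),
            class = "axis_track")
}

#' Glottal opening angle series
#'
#' The opening angle is the unsigned angle enclosed by the two vibrational
#' axes, hinged at the anterior commissure.
#'
#' @param ax an `axis_track`.
#' @return object of class `opening_angle`: `gamma` (degrees, length T), `fps`.
#' @export
opening_angle <- function(ax) {
  u <- ax$P_r - ax$A
  v <- ax$P_l - ax$A
  cosang <- rowSums(u * v) / (sqrt(rowSums(u^2)) * sqrt(rowSums(v^2)))
  gamma <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  structure(list(gamma = gamma, fps = ax$fps), class = "opening_angle")
}

#' Export landmarks, axis lengths and opening angle as CSV
#'
#' @param lm a `landmark_track`.
#' @param path output CSV path.
#' @return invisibly, the path.
#' @export
write_landmarks_csv <- function(lm, path) {
  ax <- vibrational_axes(lm)
  gamma <- opening_angle(ax)
  write.csv(data.frame(
    frame = seq_len(nrow(lm$P_r)),
    Pr_row = lm$P_r[, 1], Pr_col = lm$P_r[, 2],
    Pl_row = lm$P_l[, 1], Pl_col = lm$P_l[, 2],
    A_row = lm$A[, 1], A_col = lm$A[, 2],
    L_r = ax$L_r, L_l = ax$L_l, gamma_deg = gamma$gamma
  ), path, row.names = FALSE)
  invisible(path)
}
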