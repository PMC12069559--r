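# Quantitative vibratory measures computed from LVG motion trajectories:
# cycle segmentation, relative normalized deflection (RND), shimmer, jitter,
# amplitude-symmetry quotient, F0, instantaneous phase and lateral phase
# difference.

#' Extract a motion trajectory from an LVG matrix
#'
#' Each LVG row is a motion trajectory: the signed normalized deflection of
#' one fold at a fixed relative position over time. The row nearest to the
#' requested position fraction is selected within the requested half.
#'
#' @param M an `lvg_matrix`.
#' @param side `"left"` or `"right"`.
#' @param p position as a fraction of fold length in `[0, 1]`
#'   (0 = posterior, 1 = anterior); the medial position is `p = 0.5`.
#' @return object of class `lvg_trajectory`: `values` (length T), `fps`,
#'   `side`, `p`.
#' @export
extract_trajectory <- function(M, side = c("left", "right"), p = 0.5) {
  side <- match.arg(side)
  stopifnot(p >= 0, p <= 1)
  row <- round(p * (M$n - 1)) + 1L
  if (side == "right") row <- row + M$n
  structure(list(values = M$D[row, ], fps = M$fps, side = side, p = p),
            class = "lvg_trajectory")
}

#' Construct a trajectory from a plain numeric series
#' @param values numeric deflection series.
#' @param fps frame rate.
#' @param side,p bookkeeping metadata.
#' @return an `lvg_trajectory`.
#' @export
as_trajectory <- function(values, fps, side = "left", p = 0.5) {
  structure(list(values = as.numeric(values), fps = fps, side = side, p = p),
            class = "lvg_trajectory")
}

# local minima of y with prominence (of the negated series) of at least
# prom_frac * peak-to-peak range; returns integer indices
.local_minima <- function(y, prom_frac = 0.1) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  z <- -y
  cand <- which(z[2:(n - 1)] > z[1:(n - 2)] & z[2:(n - 1)] >= z[3:n]) + 1L
  if (length(cand) == 0L) return(integer(0))
  rng <- diff(range(y))
  if (rng <= 0) return(integer(0))
  keep <- vapply(cand, function(i) {
    lo_l <- z[i]; j <- i
    while (j > 1L && z[j - 1L] <= z[i]) { j <- j - 1L; lo_l <- min(lo_l, z[j]) }
    if (j == 1L) lo_l <- min(z[1:i])
    lo_r <- z[i]; j <- i
    while (j < n && z[j + 1L] <= z[i]) { j <- j + 1L; lo_r <- min(lo_r, z[j]) }
    if (j == n) lo_r <- min(z[i:n])
    (z[i] - max(lo_l, lo_r)) >= prom_frac * rng
  }, logical(1))
  cand[keep]
}

# sub-sample refinement of an extremum position by a parabola through the
# three samples around it
.refine_extremum <- function(y, i) {
  n <- length(y)
  if (i <= 1L || i >= n) return(as.numeric(i))
  a <- y[i - 1L]; b <- y[i]; cc <- y[i + 1L]
  den <- a - 2 * b + cc
  if (abs(den) < 1e-12) return(as.numeric(i))
  i + 0.5 * (a - cc) / den
}

# sub-sample refinement of a minimum on the raw series: re-locate the raw
# argmin near the coarse (smoothed) index, then fit a cubic by least squares
# over a fixed window (about an eighth of a period each side) around it and
# take the nearest local minimum of the fit (a plain quadratic vertex is the
# fallback for short windows). Fitting the raw series avoids the systematic
# boundary shift that pre-smoothing introduces when the local period changes
# across the minimum; the fixed window keeps the fit local so neighbouring
# cycles do not leak in. The window must be wide enough that mask-derived
# trajectories, which are value-quantized and flatten into a plateau around
# closure, still show both rising flanks (see segment_cycles).
.refine_min_raw <- function(x, i, h) {
  n <- length(x)
  lo <- max(1L, i - h); hi <- min(n, i + h)
  i <- lo - 1L + which.min(x[lo:hi])
  lo <- max(1L, i - h); hi <- min(n, i + h)
  tt <- (lo:hi) - i # centered abscissa for numerical stability
  yy <- x[lo:hi]
  m <- length(tt)
  if (m < 3L) return(as.numeric(i))
  # Cubic fit: the flanks left and right of a minimum generally have unequal
  # curvature, which contributes an odd component ~ t|t| to the local shape.
  # A quadratic-only fit aliases that component onto its linear term and
  # pulls the vertex toward the shallower flank, systematically shrinking
  # period differences; the cubic basis absorbs most of it.
  if (m >= 5L) {
    X <- cbind(1, tt, tt^2, tt^3)
    cf <- tryCatch(qr.solve(crossprod(X), crossprod(X, yy)),
                   error = function(e) NULL)
    if (!is.null(cf) && all(is.finite(cf))) {
      b <- cf[2]; c2 <- cf[3]; d <- cf[4]
      if (abs(d) < 1e-14) {
        if (c2 > 1e-12) return(i + min(max(-b / (2 * c2), -h), h))
      } else {
        disc <- 4 * c2^2 - 12 * b * d
        if (disc >= 0) {
          r <- c(-2 * c2 + sqrt(disc), -2 * c2 - sqrt(disc)) / (6 * d)
          r <- r[2 * c2 + 6 * d * r > 0] # local minima only
          if (length(r))
            return(i + min(max(r[which.min(abs(r))], -h), h))
        }
      }
    }
  }
  s1 <- sum(tt); s2 <- sum(tt^2); s3 <- sum(tt^3); s4 <- sum(tt^4)
  XtX <- matrix(c(m, s1, s2, s1, s2, s3, s2, s3, s4), 3)
  Xty <- c(sum(yy), sum(tt * yy), sum(tt^2 * yy))
  cf <- tryCatch(solve(XtX, Xty), error = function(e) NULL)
  if (is.null(cf) || !is.finite(cf[3]) || cf[3] <= 1e-12)
    return(as.numeric(i))
  v <- -cf[2] / (2 * cf[3])
  i + min(max(v, -h), h)
}

#' Segment a motion trajectory into oscillation cycles
#'
#' Cycles are delimited at successive minima of the lightly smoothed series
#' (moving-average width of about a quarter period). Minima are detected with
#' a prominence threshold relative to the series' peak-to-peak range and
#' refined to sub-frame precision by parabolic interpolation. Partial leading
#' and trailing cycles are discarded; only complete cycles are kept.
#'
#' @param tr an `lvg_trajectory` (or numeric vector together with `fps`).
#' @param fps frame rate, required when `tr` is a bare numeric vector.
#' @param f0_hint fundamental frequency in Hz; estimated from the trajectory's
#'   periodogram when missing.
#' @param prominence minimum prominence of cycle minima as a fraction of the
#'   trajectory's peak-to-peak range.
#' @param refine logical; sub-frame boundary refinement.
#' @return object of class `cycle_segmentation`: `J` (number of complete
#'   cycles), `boundaries` (length J+1, frames, possibly fractional),
#'   `amplitude` (per-cycle max - min of the raw trajectory), `period`
#'   (frames), `fps`. `J = 0` when fewer than two minima are found.
#' @export
segment_cycles <- function(tr, fps = NULL, f0_hint = NULL, prominence = 0.1,
                           refine = TRUE) {
  if (inherits(tr, "lvg_trajectory")) {
    x <- tr$values
    fps <- tr$fps
  } else {
    x <- as.numeric(tr)
    if (is.null(fps)) stop("`fps` is required for a bare numeric trajectory",
                           call. = FALSE)
  }
  empty <- structure(list(J = 0L, boundaries = numeric(0),
                          amplitude = numeric(0), period = numeric(0),
                          fps = fps), class = "cycle_segmentation")
  if (length(x) < 3L || diff(range(x)) <= 0) return(empty)
  f0 <- f0_hint
  if (is.null(f0)) {
    f0 <- tryCatch(estimate_f0(x, fps)$f0, error = function(e) NULL)
    if (is.null(f0)) return(empty)
  }
  w <- max(1L, round(fps / (4 * f0)))
  y <- if (w > 1L) {
    sm <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
    ifelse(is.na(sm), x, sm)
  } else x
  mins <- .local_minima(y, prominence)
  if (length(mins) < 2L) return(empty)
  h <- max(3L, round(fps / (8 * f0)))
  b <- if (refine)
    vapply(mins, function(i) .refine_min_raw(x, i, h), 0)
  else as.numeric(mins)
  J <- length(b) - 1L
  amplitude <- numeric(J)
  for (j in seq_len(J)) {
    idx <- seq(max(1L, ceiling(b[j])), min(length(x), floor(b[j + 1L])))
    amplitude[j] <- max(x[idx]) - min(x[idx])
  }
  structure(list(J = J, boundaries = b, amplitude = amplitude,
                 period = diff(b), fps = fps),
            class = "cycle_segmentation")
}

#' @export
print.cycle_segmentation <- function(x, ...) {
  cat(sprintf("<cycle_segmentation> J=%d cycles, mean period %.2f frames\n",
              x$J, if (x$J > 0) mean(x$period) else NA))
  invisible(x)
}

#' Relative normalized deflection (RND) per cycle
#'
#' The per-cycle peak-to-peak value of the normalized deflection trajectory,
#' in percent of axis length; the sequence average is the mean over complete
#' cycles.
#'
#' @param cycles a `cycle_segmentation` of an LVG trajectory.
#' @return list with `per_cycle` (percent, length J) and `mean` (percent);
#'   both `NA` when no complete cycles exist.
#' @export
rnd <- function(cycles) {
  if (cycles$J < 1L)
    return(list(per_cycle = NA_real_, mean = NA_real_))
  per <- 100 * cycles$amplitude
  list(per_cycle = per, mean = mean(per))
}

.cycle_values <- function(x, field) {
  if (inherits(x, "cycle_segmentation")) x[[field]] else as.numeric(x)
}

#' Relative shimmer of a motion trajectory
#'
#' Mean absolute difference of consecutive per-cycle amplitudes, divided by
#' the mean amplitude, in percent. Zero for perfectly stable amplitudes.
#'
#' @param x a `cycle_segmentation`, or a numeric vector of per-cycle
#'   amplitudes.
#' @return shimmer in percent; `NA` with fewer than two cycles or a zero mean
#'   amplitude.
#' @export
relative_shimmer <- function(x) {
  a <- .cycle_values(x, "amplitude")
  J <- length(a)
  if (J < 2L) return(NA_real_)
  m <- mean(a)
  if (m <= 0) return(NA_real_)
  100 * mean(abs(diff(a))) / m
}

#' Relative jitter of a motion trajectory
#'
#' Mean absolute difference of consecutive cycle periods, divided by the mean
#' period, in percent. Zero for perfectly stable periods.
#'
#' @param x a `cycle_segmentation`, or a numeric vector of per-cycle periods.
#' @return jitter in percent; `NA` with fewer than two cycles.
#' @export
relative_jitter <- function(x) {
  p <- .cycle_values(x, "period")
  J <- length(p)
  if (J < 2L) return(NA_real_)
  100 * mean(abs(diff(p))) / mean(p)
}

#' Amplitude-symmetry quotient of paired per-cycle RNDs
#'
#' For each paired cycle, the ratio of the smaller to the larger of the two
#' folds' RNDs; 1 means perfectly symmetric amplitudes. Pairs where both RNDs
#' are zero are skipped (and counted).
#'
#' @param rnd_r,rnd_l numeric vectors of per-cycle RNDs, paired by index.
#' @return list with `per_cycle`, `mean`, and `n_skipped`.
#' @export
q_rnd <- function(rnd_r, rnd_l) {
  stopifnot(length(rnd_r) == length(rnd_l))
  hi <- pmax(rnd_r, rnd_l)
  lo <- pmin(rnd_r, rnd_l)
  valid <- hi > 0
  q <- lo[valid] / hi[valid]
  list(per_cycle = q,
       mean = if (length(q) > 0) mean(q) else NA_real_,
       n_skipped = sum(!valid))
}

#' Paired per-cycle RNDs of both folds at one position
#'
#' Joint cycle segmentation on the summed unsigned deflection of both folds
#' (so that the quotient compares the same oscillation cycle on both sides),
#' then per-cycle peak-to-peak RNDs of each fold within the joint boundaries.
#'
#' @param M an `lvg_matrix`.
#' @param p position fraction.
#' @param ... passed to [segment_cycles()].
#' @return list with `cycles` (joint `cycle_segmentation`), `rnd_l`, `rnd_r`
#'   (percent, per joint cycle) and `q` (the [q_rnd()] result).
#' @export
paired_rnd <- function(M, p = 0.5, ...) {
  tl <- extract_trajectory(M, "left", p)
  tr <- extract_trajectory(M, "right", p)
  joint <- as_trajectory(abs(tl$values) + abs(tr$values), M$fps)
  cyc <- segment_cycles(joint, ...)
  per_side <- function(x) {
    vapply(seq_len(cyc$J), function(j) {
      idx <- seq(max(1L, ceiling(cyc$boundaries[j])),
                 min(length(x), floor(cyc$boundaries[j + 1L])))
      100 * (max(x[idx]) - min(x[idx]))
    }, 0)
  }
  rnd_l <- per_side(tl$values)
  rnd_r <- per_side(tr$values)
  list(cycles = cyc, rnd_l = rnd_l, rnd_r = rnd_r, q = q_rnd(rnd_r, rnd_l))
}

#' Fundamental frequency from a periodic series
#'
#' Frequency of the dominant periodogram peak of the mean-removed series
#' within `band`, refined by parabolic interpolation of the log-periodogram.
#'
#' @param x a `gaw_series`, `lvg_trajectory`, or numeric vector.
#' @param fps frame rate (taken from the object when available).
#' @param band search band in Hz.
#' @return list with `f0` (Hz) and `peak_power`.
#' @export
estimate_f0 <- function(x, fps = NULL, band = c(50, 500)) {
  if (inherits(x, c("gaw_series", "lvg_trajectory"))) {
    fps <- x$fps
    x <- x$values
  }
  if (is.null(fps)) stop("`fps` is required", call. = FALSE)
  x <- x - mean(x)
  if (sd(x) == 0)
    stop("undefined F0: series is constant", call. = FALSE)
  n <- length(x)
  nfft <- max(4096L, 2L^ceiling(log2(n)) * 4L)
  P <- Mod(fft(c(x, rep(0, nfft - n))))^2
  freq <- (seq_len(nfft) - 1L) * fps / nfft
  sel <- which(freq >= band[1] & freq <= band[2])
  if (length(sel) < 3L) stop("band too narrow for this frame rate", call. = FALSE)
  k <- sel[which.max(P[sel])]
  if (P[k] < 10 * median(P[sel]))
    stop("undefined F0: no dominant periodogram peak above the noise floor",
         call. = FALSE)
  lp <- log(pmax(P[(k - 1):(k + 1)], .Machine$double.xmin))
  den <- lp[1] - 2 * lp[2] + lp[3]
  off <- if (abs(den) < 1e-12) 0 else 0.5 * (lp[1] - lp[3]) / den
  list(f0 = (k - 1 + off) * fps / nfft, peak_power = P[k])
}

#' Instantaneous phase of a motion trajectory
#'
#' Phase of the mean-removed trajectory at the oscillation frequency, either
#' as the argument of a complex Morlet wavelet transform at the scale matching
#' `f0` (default, center-frequency parameter `omega0 = 6`), or of the analytic
#' signal (Hilbert transform) as a cross-check backend.
#'
#' @param tr an `lvg_trajectory` or numeric vector.
#' @param f0 carrier frequency in Hz, inside `(0, fps/2)`.
#' @param fps frame rate, required for bare numeric input.
#' @param method `"morlet"` or `"hilbert"`.
#' @param omega0 Morlet center-frequency parameter.
#' @return numeric phase series in `(-pi, pi]`.
#' @export
instantaneous_phase <- function(tr, f0, fps = NULL,
                                method = c("morlet", "hilbert"), omega0 = 6) {
  method <- match.arg(method)
  if (inherits(tr, "lvg_trajectory")) {
    x <- tr$values
    fps <- tr$fps
  } else {
    x <- as.numeric(tr)
    if (is.null(fps)) stop("`fps` is required", call. = FALSE)
  }
  stopifnot(f0 > 0, f0 < fps / 2)
  x <- x - mean(x)
  N <- length(x)
  X <- fft(x)
  k <- 0:(N - 1)
  om <- 2 * pi * ifelse(k <= N / 2, k, k - N) / N # rad/sample
  if (method == "morlet") {
    s <- omega0 / (2 * pi * f0 / fps)
    filt <- exp(-0.5 * (s * om - omega0)^2) * (om > 0)
    W <- fft(X * filt, inverse = TRUE) / N
    Arg(W)
  } else {
    h <- numeric(N)
    h[1] <- 1
    if (N %% 2 == 0) {
      h[2:(N / 2)] <- 2
      h[N / 2 + 1] <- 1
    } else {
      h[2:((N + 1) / 2)] <- 2
    }
    z <- fft(X * h, inverse = TRUE) / N
    Arg(z)
  }
}

#' Lateral phase difference between the two folds
#'
#' Time-averaged circular difference between matched left and right phase
#' series: the phase differences are mapped to the complex unit circle,
#' averaged over time, and the absolute argument of the average is returned.
#' Zero for perfectly synchronous vibration; bounded by pi.
#'
#' @param phi_l,phi_r phase series in radians, equal length.
#' @return scalar in `[0, pi]`.
#' @export
lateral_phase_difference <- function(phi_l, phi_r) {
  stopifnot(length(phi_l) == length(phi_r))
  abs(Arg(mean(exp(1i * (phi_l - phi_r)))))
}

#' Positions covered by the glottal opening
#'
#' A position counts as inside the opening range when the maximal unsigned
#' gap between the two folds' deflection profiles over time exceeds the
#' threshold fraction of axis length.
#'
#' @param M an `lvg_matrix`.
#' @param threshold gap threshold as a fraction of axis length.
#' @return logical vector of length `M$n`.
#' @export
opening_range <- function(M, threshold = 0.01) {
  n <- M$n
  gap <- M$D[1:n, , drop = FALSE] + M$D[(n + 1):(2 * n), , drop = FALSE]
  apply(gap, 1, max) > threshold
}

#' Lateral phase difference profile and aggregates
#'
#' Computes the per-position lateral phase difference for all positions and
#' its arithmetic means over the glottal opening range and over the entire
#' LVG.
#'
#' @param M an `lvg_matrix`.
#' @param f0 carrier frequency in Hz (estimated from the medial joint
#'   trajectory when missing).
#' @param opening logical opening-range vector; computed by [opening_range()]
#'   when missing.
#' @param method phase backend, see [instantaneous_phase()].
#' @return list with `per_position` (length n, radians), `op` (mean over the
#'   opening range; `NA` if the range is empty), `lvg` (mean over all
#'   positions), `opening`.
#' @export
phase_difference_profile <- function(M, f0 = NULL, opening = NULL,
                                     method = "morlet") {
  n <- M$n
  if (is.null(f0)) {
    joint <- abs(M$D[round(n / 2), ]) + abs(M$D[n + round(n / 2), ])
    f0 <- estimate_f0(joint, M$fps)$f0
  }
  if (is.null(opening)) opening <- opening_range(M)
  per <- vapply(seq_len(n), function(k) {
    phi_l <- instantaneous_phase(M$D[k, ], f0, M$fps, method = method)
    phi_r <- instantaneous_phase(M$D[n + k, ], f0, M$fps, method = method)
    lateral_phase_difference(phi_l, phi_r)
  }, 0)
  list(per_position = per,
       op = if (any(opening)) mean(per[opening]) else NA_real_,
       lvg = mean(per),
       opening = opening)
}

#' Full measure report at one fold position
#'
#' Computes, at position `p`: per-side cycle segmentations, per-cycle and mean
#' RND, relative shimmer and jitter, the amplitude-symmetry quotient from
#' jointly segmented cycles, the lateral phase difference (at `p`, over the
#' opening range, and over the whole LVG), and the fundamental frequency.
#'
#' @param M an `lvg_matrix`.
#' @param gaw optional `gaw_series`; used for the F0 estimate when given.
#' @param p evaluation position (default medial).
#' @param f0 optional known fundamental frequency in Hz.
#' @param phase_method phase backend.
#' @param opening_threshold opening-range threshold, see [opening_range()].
#' @param ... passed to [segment_cycles()].
#' @return object of class `lvg_measures`; the per-side `cycle_segmentation`s
#'   are kept in the `cycles` field.
#' @export
measure_report <- function(M, gaw = NULL, p = 0.5, f0 = NULL,
                           phase_method = "morlet", opening_threshold = 0.01,
                           ...) {
  if (is.null(f0)) {
    src <- if (!is.null(gaw)) gaw else {
      n <- M$n
      as_trajectory(abs(M$D[round(p * (n - 1)) + 1, ]) +
                    abs(M$D[n + round(p * (n - 1)) + 1, ]), M$fps)
    }
    f0 <- estimate_f0(src)$f0
  }
  tl <- extract_trajectory(M, "left", p)
  tr <- extract_trajectory(M, "right", p)
  cyc_l <- segment_cycles(tl, f0_hint = f0, ...)
  cyc_r <- segment_cycles(tr, f0_hint = f0, ...)
  pr <- paired_rnd(M, p, f0_hint = f0, ...)
  phi_l <- instantaneous_phase(tl, f0, method = phase_method)
  phi_r <- instantaneous_phase(tr, f0, method = phase_method)
  prof <- phase_difference_profile(M, f0,
                                   opening = opening_range(M, opening_threshold),
                                   method = phase_method)
  structure(list(
    p = p, f0 = f0,
    cycles = list(left = cyc_l, right = cyc_r),
    J_l = cyc_l$J, J_r = cyc_r$J,
    rnd_l = rnd(cyc_l), rnd_r = rnd(cyc_r),
    shimmer_l = relative_shimmer(cyc_l), shimmer_r = relative_shimmer(cyc_r),
    jitter_l = relative_jitter(cyc_l), jitter_r = relative_jitter(cyc_r),
    q_rnd = pr$q,
    delta_theta_p = lateral_phase_difference(phi_l, phi_r),
    delta_theta_op = prof$op,
    delta_theta_lvg = prof$lvg
  ), class = "lvg_measures")
}

#' @export
print.lvg_measures <- function(x, ...) {
  cat(sprintf("<lvg_measures> at p = %.0f%% (F0 = %.1f Hz)\n", 100 * x$p, x$f0))
  cat(sprintf("  RND    left %6.2f %%   right %6.2f %%  (J = %d / %d)\n",
              x$rnd_l$mean, x$rnd_r$mean, x$J_l, x$J_r))
  cat(sprintf("  shim   left %6.2f %%   right %6.2f %%\n",
              x$shimmer_l, x$shimmer_r))
  cat(sprintf("  jit    left %6.2f %%   right %6.2f %%\n",
              x$jitter_l, x$jitter_r))
  cat(sprintf("  Q_RND  %.3f   dTheta(p) %.3f rad   op %.3f   LVG %.3f\n",
              x$q_rnd$mean, x$delta_theta_p, x$delta_theta_op,
              x$delta_theta_lvg))
  invisible(x)
}

#' Write a measure report as JSON
#'
#' Percentages are reported to 2 decimals, radians and quotients to 3.
#'
#' @param m an `lvg_measures`.
#' @param path output JSON path.
#' @return invisibly, the path.
#' @export
write_measures_json <- function(m, path) {
  r2 <- function(v) if (is.na(v)) NA else round(v, 2)
  r3 <- function(v) if (is.na(v)) NA else round(v, 3)
  out <- list(
    p = m$p, f0_hz = r2(m$f0), J_left = m$J_l, J_right = m$J_r,
    rnd_mean_left_pct = r2(m$rnd_l$mean), rnd_mean_right_pct = r2(m$rnd_r$mean),
    shimmer_left_pct = r2(m$shimmer_l), shimmer_right_pct = r2(m$shimmer_r),
    jitter_left_pct = r2(m$jitter_l), jitter_right_pct = r2(m$jitter_r),
    q_rnd_mean = r3(m$q_rnd$mean),
    delta_theta_p_rad = r3(m$delta_theta_p),
    delta_theta_op_rad = r3(m$delta_theta_op),
    delta_theta_lvg_rad = r3(m$delta_theta_lvg)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Consensus cycle segmentation across fold positions
#'
#' Oscillation cycle boundaries fall on the same frames at every position
#' along the folds (up to a constant lateral phase shift), so averaging the
#' refined boundaries of many trajectories cancels the per-boundary
#' quantization noise of any single one. Trajectories at the positions `ps`
#' of both folds are segmented individually; their boundaries are matched to
#' the boundaries of a reference segmentation (the summed unsigned medial
#' deflection of both folds), centred per trajectory to remove constant
#' phase-shift offsets, and averaged. Period-based measures such as jitter
#' are substantially more accurate on the consensus boundaries than at any
#' single position.
#'
#' @param M an `lvg_matrix`.
#' @param ps position fractions contributing to the consensus.
#' @param f0_hint fundamental frequency in Hz; estimated from the medial
#'   joint trajectory when missing.
#' @param ... passed to [segment_cycles()].
#' @return a `cycle_segmentation` with consensus boundaries and periods;
#'   amplitudes are those of the medial joint trajectory.
#' @export
consensus_cycles <- function(M, ps = seq(0.3, 0.7, by = 0.1), f0_hint = NULL,
                             ...) {
  n <- M$n
  row <- function(p) round(p * (n - 1)) + 1L
  joint <- as_trajectory(abs(M$D[row(0.5), ]) + abs(M$D[n + row(0.5), ]),
                         M$fps)
  if (is.null(f0_hint)) f0_hint <- estimate_f0(joint)$f0
  ref <- segment_cycles(joint, f0_hint = f0_hint, ...)
  if (ref$J < 2L) return(ref)
  rb <- ref$boundaries
  per <- mean(diff(rb))
  acc <- list()
  for (p in ps) for (s in c("left", "right")) {
    cyc <- segment_cycles(extract_trajectory(M, s, p), f0_hint = f0_hint, ...)
    if (cyc$J < 1L) next
    b <- cyc$boundaries
    m <- vapply(rb, function(x) {
      v <- b[which.min(abs(b - x))]
      if (abs(v - x) > per / 4) NA_real_ else v
    }, 0)
    if (sum(!is.na(m)) < 2L) next
    # remove this trajectory's constant offset to the reference, so that
    # missing boundaries do not bias the average
    acc[[length(acc) + 1L]] <- m - mean(m - rb, na.rm = TRUE)
  }
  if (length(acc) == 0L) return(ref)
  A <- do.call(rbind, acc)
  bavg <- colMeans(A, na.rm = TRUE)
  bad <- !is.finite(bavg)
  bavg[bad] <- rb[bad]
  structure(list(J = ref$J, boundaries = bavg,
                 amplitude = ref$amplitude, period = diff(bavg),
                 fps = M$fps),
            class = "cycle_segmentation")
}
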