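# Voice-onset analysis: phase segmentation of non-stationary recordings from
# the glottal area waveform, and adduction quantification by linear regression
# of the opening angle.

# analytic signal via FFT
.analytic <- function(x) {
  N <- length(x)
  X <- fft(x)
  h <- numeric(N)
  h[1] <- 1
  if (N %% 2 == 0) {
    h[2:(N / 2)] <- 2
    h[N / 2 + 1] <- 1
  } else {
    h[2:((N + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / N
}

#' Segment a recording into pre-phonatory, onset, and sustained phases
#'
#' The start of oscillation is the first frame where the envelope (magnitude
#' of the analytic signal) of the band-passed glottal area waveform exceeds a
#' fraction of its sustained-phase median and stays above it briefly. The
#' onset phase then runs until the end of the first oscillation cycle whose
#' GAW minimum reaches full closure; everything after is sustained phonation.
#' The pre-phonatory phase is the fixed window (default 1000 frames, 250 ms at
#' 4000 fps) before the start of oscillation.
#'
#' @param gaw a `gaw_series`.
#' @param band oscillation band in Hz for the band-pass filter.
#' @param threshold_frac envelope threshold as a fraction of the
#'   sustained-phase median envelope.
#' @param pre_window length of the pre-phonatory window in frames.
#' @param closure_tol GAW values at or below this count as full closure (px).
#' @param hold minimum number of consecutive frames above threshold.
#' @return object of class `onset_phases`: `t_osc_start`, `t_first_closure`
#'   (`NA` if the glottis never fully closes, with `open_ended = TRUE`),
#'   `n_onset_cycles` (complete cycles before the first full-closure cycle),
#'   `phases` (list of `pre`, `onset`, `sustained` index ranges), `fps`.
#' @export
segment_onset_phases <- function(gaw, band = c(50, 500), threshold_frac = 0.1,
                                 pre_window = 1000L, closure_tol = 0,
                                 hold = 20L) {
  x <- gaw$values
  fps <- gaw$fps
  T <- length(x)
  if (T < 3L * hold) stop("sequence too short for onset analysis", call. = FALSE)
  bf <- signal::butter(2, band / (fps / 2), type = "pass")
  bp <- signal::filtfilt(bf, x - mean(x))
  env <- Mod(.analytic(bp))
  ref <- median(env[max(1L, floor(0.75 * T)):T])
  th <- threshold_frac * ref
  above <- env > th
  # a quiet stretch (envelope below threshold for `hold` frames) must precede
  # the onset; this also rejects the zero-phase filter's edge transient
  below_runs <- as.numeric(stats::filter(!above, rep(1, hold), sides = 1))
  t_quiet <- which(below_runs >= hold)[1]
  if (is.na(t_quiet))
    stop("no onset found: the sequence oscillates from the first frame",
         call. = FALSE)
  runs <- as.numeric(stats::filter(above, rep(1, hold), sides = 1))
  t0 <- which(runs >= hold & seq_len(T) > t_quiet)[1]
  if (is.na(t0)) stop("no onset found: the sequence never starts oscillating",
                      call. = FALSE)
  t0 <- t0 - hold + 1L
  # oscillation cycles of the GAW after onset
  post <- x[t0:T]
  f0 <- tryCatch(estimate_f0(post, fps)$f0, error = function(e) NULL)
  cyc <- segment_cycles(post, fps, f0_hint = f0)
  open_ended <- TRUE
  t_first_closure <- NA_real_
  n_open <- NA_integer_
  if (cyc$J > 0L) {
    mins <- vapply(seq_len(cyc$J), function(j) {
      idx <- seq(max(1L, ceiling(cyc$boundaries[j])),
                 min(length(post), floor(cyc$boundaries[j + 1L])))
      min(post[idx])
    }, 0)
    jc <- which(mins <= closure_tol)[1]
    if (!is.na(jc)) {
      open_ended <- FALSE
      t_first_closure <- t0 - 1L + ceiling(cyc$boundaries[jc + 1L])
      n_open <- jc - 1L
    }
  }
  if (open_ended)
    warning("the glottis never fully closes: onset phase is open-ended",
            call. = FALSE)
  phases <- list(
    pre = c(max(1L, t0 - pre_window), t0),
    onset = c(t0, if (open_ended) T else t_first_closure),
    sustained = if (open_ended) NULL else c(t_first_closure + 1L, T)
  )
  structure(list(t_osc_start = t0, t_first_closure = t_first_closure,
                 n_onset_cycles = n_open, open_ended = open_ended,
                 phases = phases, fps = fps),
            class = "onset_phases")
}

#' Angular velocity of vocal-fold adduction
#'
#' Ordinary least-squares slope of the opening angle over physical time,
#' evaluated on the window immediately preceding `window_end` (typically the
#' start of oscillation). Negative values indicate adduction.
#'
#' @param gamma an `opening_angle` series (or numeric degrees with `fps`).
#' @param window_end frame index just after the regression window.
#' @param window window length in frames.
#' @param fps frame rate, required for bare numeric input.
#' @return slope in degrees per second.
#' @export
angular_velocity <- function(gamma, window_end, window = 1000L, fps = NULL) {
  if (inherits(gamma, "opening_angle")) {
    y <- gamma$gamma
    fps <- gamma$fps
  } else {
    y <- as.numeric(gamma)
    if (is.null(fps)) stop("`fps` is required", call. = FALSE)
  }
  start <- window_end - window
  if (start < 1L) {
    warning("regression window exceeds available frames; shortened",
            call. = FALSE)
    start <- 1L
  }
  idx <- start:(window_end - 1L)
  tsec <- (idx - 1) / fps
  unname(coef(lm(y[idx] ~ tsec))[2])
}

#' Full voice-onset analysis of a mask sequence
#'
#' Computes the glottal area waveform, segments the recording into
#' pre-phonatory / onset / sustained phases, extracts the opening-angle
#' series from the smoothed vibrational axes, regresses the adduction
#' velocity over the pre-phonatory window, and estimates the sustained-phase
#' fundamental frequency.
#'
#' @param seq a [mask_sequence()].
#' @param window,overlap landmark smoothing parameters (frames).
#' @param regression_window pre-phonatory regression window in frames.
#' @param ... passed to [segment_onset_phases()].
#' @return object of class `lvg_onset`: `phases` (an `onset_phases`), `gamma`
#'   (an `opening_angle`), `gamma_slope` (deg/s), `f0_sustained` (Hz or `NA`),
#'   `gaw`.
#' @export
analyze_onset <- function(seq, window = 150L, overlap = 25L,
                          regression_window = 1000L, ...) {
  gaw <- compute_gaw(seq)
  ph <- segment_onset_phases(gaw, pre_window = regression_window, ...)
  lm_raw <- track_landmarks(seq)
  lm_sm <- smooth_landmarks(lm_raw, gaw, window, overlap)
  gamma <- opening_angle(vibrational_axes(lm_sm))
  slope <- angular_velocity(gamma, window_end = ph$t_osc_start,
                            window = regression_window)
  f0 <- if (!ph$open_ended) {
    sus <- gaw$values[ph$phases$sustained[1]:ph$phases$sustained[2]]
    tryCatch(estimate_f0(sus, gaw$fps)$f0, error = function(e) NA_real_)
  } else NA_real_
  structure(list(phases = ph, gamma = gamma, gamma_slope = slope,
                 f0_sustained = f0, gaw = gaw),
            class = "lvg_onset")
}

#' @export
print.lvg_onset <- function(x, ...) {
  ph <- x$phases
  cat(sprintf("<lvg_onset> oscillation from frame %d; first full closure %s\n",
              ph$t_osc_start,
              if (ph$open_ended) "never (open-ended)" else
                sprintf("frame %d (%d open cycles)", ph$t_first_closure,
                        ph$n_onset_cycles)))
  cat(sprintf("  adduction velocity %.2f deg/s; sustained F0 %.1f Hz\n",
              x$gamma_slope, x$f0_sustained))
  invisible(x)
}

#' Write an onset analysis as JSON plus CSV series
#'
#' @param onset an `lvg_onset`.
#' @param json_path output JSON path for the scalar profile.
#' @param csv_path optional CSV path for the per-frame series
#'   (frame, gamma_deg, gaw_px).
#' @return invisibly, `json_path`.
#' @export
write_onset_json <- function(onset, json_path, csv_path = NULL) {
  ph <- onset$phases
  out <- list(
    t_osc_start = ph$t_osc_start,
    t_first_closure = if (ph$open_ended) NA else ph$t_first_closure,
    open_ended = ph$open_ended,
    n_onset_cycles = ph$n_onset_cycles,
    gamma_slope_deg_per_s = round(onset$gamma_slope, 2),
    f0_sustained_hz = if (is.na(onset$f0_sustained)) NA
                      else round(onset$f0_sustained, 1),
    phases = ph$phases
  )
  jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  if (!is.null(csv_path))
    write.csv(data.frame(frame = seq_along(onset$gamma$gamma),
                         gamma_deg = onset$gamma$gamma,
                         gaw_px = onset$gaw$values),
              csv_path, row.names = FALSE)
  invisible(json_path)
}
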