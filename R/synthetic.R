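# Synthetic vocal-fold kinematics: label-mask sequences with exact ground
# truth, emulating sustained phonation (with configurable asymmetry and
# perturbation), polyp, paresis, overshoot, and voice onset.

#' Specification of a synthetic kinematics scenario
#'
#' Builds the parameter set for [generate_sequence()]. Scenario presets:
#' \describe{
#'   \item{healthy}{symmetric sinusoidal medial bulging with kissing closure.}
#'   \item{paresis}{amplitude asymmetry, a static paramedian bow, and a phase
#'     offset on the affected (right) fold.}
#'   \item{polyp}{static medial bump on the right fold blocking the glottal
#'     opening from the bump to the ventral end.}
#'   \item{overshoot}{joint excursion of both medial edges beyond the axes
#'     toward one side during the closed phase, giving opposite-sign
#'     deflection bands.}
#'   \item{onset}{linear adduction ramp of the opening angle over a
#'     pre-phonatory window, followed by oscillation whose residual medial gap
#'     decays so that full closure first occurs after `onset$open_cycles`
#'     open cycles.}
#' }
#'
#' Defaults mirror typical acquisition (256 x 256 px at 4000 fps) and healthy
#' sustained phonation; fractions are relative to the axis length.
#'
#' @param scenario preset name.
#' @param ... overrides of any spec field (see the function body for the full
#'   list: `width`, `height`, `fps`, `frames`, `row_P`, `row_A`,
#'   `fold_width_px`, `f0`, `amp_left`, `amp_right`, `rest`, `bow_left`,
#'   `bow_right`, `phase_offset`, `amp_jitter`, `period_jitter`, `overshoot`,
#'   `polyp`, `onset`, `noise_px`, `seed`).
#' @return object of class `synth_spec`.
#' @export
synth_spec <- function(scenario = c("healthy", "paresis", "polyp",
                                    "overshoot", "onset"), ...) {
  scenario <- match.arg(scenario)
  spec <- list(
    scenario = scenario,
    width = 256L, height = 256L, fps = 4000, frames = 2000L,
    row_P = 48L, row_A = 208L, fold_width_px = 48L,
    f0 = 160,
    amp_left = 0.05, amp_right = 0.05,
    rest = 0,
    bow_left = 0, bow_right = 0,
    phase_offset = 0,
    amp_jitter = 0, period_jitter = 0,
    overshoot = 0,
    polyp = NULL,
    onset = NULL,
    noise_px = 0,
    seed = 1L
  )
  preset <- switch(scenario,
    healthy = list(),
    paresis = list(amp_right = 0.025, bow_right = 0.06, phase_offset = 0.4),
    polyp = list(polyp = list(side = "right", p0 = 0.6, extent = 0.18,
                              height = 0.22, blocked = TRUE)),
    overshoot = list(overshoot = 0.03),
    onset = list(frames = 1400L, f0 = 210,
                 amp_left = 0.035, amp_right = 0.035,
                 onset = list(pre_frames = 1000L, gamma0 = 24.22,
                              rate = -85.35, residual = 0.03,
                              open_cycles = 4L))
  )
  spec[names(preset)] <- preset
  dots <- list(...)
  unknown <- setdiff(names(dots), names(spec))
  if (length(unknown) > 0L)
    stop("unknown spec field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  spec[names(dots)] <- dots
  # geometric feasibility
  L <- spec$row_A - spec$row_P
  mc <- (spec$width + 1) / 2
  maxdefl <- spec$rest + max(spec$bow_left, spec$bow_right) +
    2 * max(spec$amp_left, spec$amp_right) * (1 + 4 * spec$amp_jitter) +
    spec$overshoot
  if (mc + L * maxdefl + spec$fold_width_px >= spec$width ||
      mc - L * maxdefl - spec$fold_width_px <= 1)
    stop("geometrically impossible spec: folds do not fit in the frame",
         call. = FALSE)
  if (spec$f0 >= spec$fps / 2)
    stop("f0 must be below the Nyquist frequency", call. = FALSE)
  stopifnot(spec$amp_left >= 0, spec$amp_left < 1,
            spec$amp_right >= 0, spec$amp_right < 1,
            spec$frames >= 1L, spec$row_A > spec$row_P)
  structure(spec, class = "synth_spec")
}

# one-sided polyp bump profile over positions pp (Gaussian shoulder toward
# the dorsal side, plateau from p0 to the ventral end when blocked)
.polyp_bump <- function(pp, polyp) {
  sigma <- polyp$extent / 2
  bump <- polyp$height * exp(-0.5 * ((pp - polyp$p0) / sigma)^2)
  if (isTRUE(polyp$blocked)) bump[pp >= polyp$p0] <- polyp$height
  bump
}

#' Generate a synthetic label-mask sequence with ground truth
#'
#' Medial fold edges are drawn as the vibrational axis plus a half-sine
#' spatial bulge (zero deflection at both axis endpoints) with time-varying
#' amplitude; regions are rasterized as fold labels with the inter-fold gap
#' labelled glottis. The manifest records the exact cycle schedule (fractional
#' periods and per-cycle amplitudes per side), geometry, and all imposed
#' parameters, so pipeline output can be checked against analytic values.
#'
#' @param spec a [synth_spec()].
#' @return list with `seq` (a [mask_sequence()]) and `manifest` (list).
#' @export
generate_sequence <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  H <- spec$height; W <- spec$width; Tn <- spec$frames
  rp <- spec$row_P; ra <- spec$row_A
  L <- ra - rp
  mc <- (W + 1) / 2
  w <- spec$fold_width_px
  rows <- rp:ra
  pp <- (rows - rp) / L
  mode <- sin(pi * pp)
  bump_l <- if (!is.null(spec$polyp) && spec$polyp$side == "left")
    .polyp_bump(pp, spec$polyp) else numeric(length(pp))
  bump_r <- if (!is.null(spec$polyp) && spec$polyp$side == "right")
    .polyp_bump(pp, spec$polyp) else numeric(length(pp))

  t_on <- if (is.null(spec$onset)) 1L else spec$onset$pre_frames + 1L
  n_osc <- Tn - t_on + 1L
  T0 <- spec$fps / spec$f0

  # cycle schedule (periods in frames, possibly fractional); extend until the
  # schedule covers the whole oscillation span
  ncyc <- ceiling(n_osc / T0) + 5L
  repeat {
    Tj <- pmax(4, T0 * (1 + stats::rnorm(ncyc, 0, spec$period_jitter)))
    aL <- pmax(0, spec$amp_left * (1 + stats::rnorm(ncyc, 0, spec$amp_jitter)))
    aR <- pmax(0, spec$amp_right * (1 + stats::rnorm(ncyc, 0, spec$amp_jitter)))
    if (sum(Tj) > n_osc) break
    ncyc <- ncyc * 2L
  }
  cumT <- c(0, cumsum(Tj))
  tau <- 0:(n_osc - 1L)
  jj <- findInterval(tau, cumT, rightmost.closed = FALSE) # cycle index per frame
  phi <- 2 * pi * (jj - 1) + 2 * pi * (tau - cumT[jj]) / Tj[jj]

  # per-frame modulation factors (fractions of axis length)
  fL <- spec$rest + spec$bow_left +
    aL[jj] * (1 + sin(phi + spec$phase_offset - pi / 2))
  fR <- spec$rest + spec$bow_right +
    aR[jj] * (1 + sin(phi - pi / 2))
  ov <- spec$overshoot * pmax(0, -sin(phi - pi / 2))
  g_res <- if (is.null(spec$onset)) numeric(n_osc) else
    spec$onset$residual *
      pmax(0, 1 - tau / ((spec$onset$open_cycles + 0.5) * T0))

  frames <- array(as.raw(0L), c(H, W, Tn))
  Cfull <- matrix(seq_len(W), H, W, byrow = TRUE)
  Cband <- Cfull[rows, , drop = FALSE]
  nb <- length(rows)

  rasterize <- function(el, er, band_rows, Cm) {
    bad <- el < er
    if (any(bad)) {
      m2 <- (el[bad] + er[bad]) / 2
      el[bad] <- m2
      er[bad] <- m2
    }
    sub <- matrix(0L, length(band_rows), W)
    sub[Cm >= ceiling(el) & Cm <= floor(el + w)] <- LBL_LEFT
    sub[Cm <= floor(er) & Cm >= ceiling(er - w)] <- LBL_RIGHT
    sub[Cm > er & Cm < el] <- LBL_GLOTTIS
    sub
  }

  gamma_true <- numeric(Tn)
  if (!is.null(spec$onset)) {
    on <- spec$onset
    for (t in seq_len(t_on - 1L)) {
      gamma_true[t] <- on$gamma0 + on$rate * (t - 1) / spec$fps
      h <- gamma_true[t] * pi / 360 # half-angle in radians
      rowP_t <- ra - L * cos(h)
      band <- seq(ceiling(rowP_t), ra)
      q <- (ra - band) / (L * cos(h))
      halfgap <- q * L * sin(h)
      el <- mc + halfgap
      er <- mc - halfgap
      if (spec$noise_px > 0) {
        el <- el + stats::rnorm(length(band), 0, spec$noise_px)
        er <- er + stats::rnorm(length(band), 0, spec$noise_px)
      }
      frames[band, , t] <- as.raw(rasterize(el, er, band,
                                            Cfull[band, , drop = FALSE]))
    }
  }
  for (i in seq_len(n_osc)) {
    t <- t_on + i - 1L
    el <- mc + L * ((fL[i] + g_res[i]) * mode - bump_l + ov[i] * mode)
    er <- mc - L * ((fR[i] + g_res[i]) * mode - bump_r - ov[i] * mode)
    if (spec$noise_px > 0) {
      el <- el + stats::rnorm(nb, 0, spec$noise_px)
      er <- er + stats::rnorm(nb, 0, spec$noise_px)
    }
    frames[rows, , t] <- as.raw(rasterize(el, er, rows, Cband))
  }

  seq <- mask_sequence(frames, fps = spec$fps, validate = FALSE)
  complete <- which(t_on - 1 + cumT[-1] <= Tn)
  manifest <- list(
    scenario = spec$scenario, seed = spec$seed,
    fps = spec$fps, f0 = spec$f0, frames = Tn, t_osc_start = t_on,
    geometry = list(row_P = rp, row_A = ra, axis_length = L, midline = mc,
                    fold_width_px = w),
    amp_left = spec$amp_left, amp_right = spec$amp_right,
    rest = spec$rest, bow_left = spec$bow_left, bow_right = spec$bow_right,
    phase_offset = spec$phase_offset, overshoot = spec$overshoot,
    amp_jitter = spec$amp_jitter, period_jitter = spec$period_jitter,
    noise_px = spec$noise_px,
    polyp = spec$polyp, onset = spec$onset,
    cycles = list(
      boundaries = t_on + cumT[seq_len(length(complete) + 1L)],
      periods = Tj[complete],
      amp_left = aL[complete],
      amp_right = aR[complete]
    ),
    gamma_true = if (is.null(spec$onset)) NULL else gamma_true[seq_len(t_on - 1L)]
  )
  list(seq = seq, manifest = manifest)
}

#' Write the canonical seeded fixture suite
#'
#' Emits eight deterministic sequences (three healthy repeats, paresis, polyp,
#' overshoot, and a normal and a hard voice onset) as multipage TIFF + JSON
#' sidecar pairs plus one ground-truth manifest JSON each.
#'
#' @param out_dir writable output directory (created if missing).
#' @param seed base seed; repeats use consecutive seeds.
#' @param frames frame count for the stationary scenarios (onset scenarios
#'   keep their own default length).
#' @return invisibly, a character vector of the TIFF paths written.
#' @export
write_fixture_suite <- function(out_dir, seed = 1L, frames = 240L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  specs <- list(
    healthy_1 = synth_spec("healthy", seed = seed, frames = frames),
    healthy_2 = synth_spec("healthy", seed = seed + 1L, frames = frames),
    healthy_3 = synth_spec("healthy", seed = seed + 2L, frames = frames),
    paresis = synth_spec("paresis", seed = seed, frames = frames),
    polyp = synth_spec("polyp", seed = seed, frames = frames),
    overshoot = synth_spec("overshoot", seed = seed, frames = frames),
    onset_normal = synth_spec("onset", seed = seed, f0 = 178,
                              onset = list(pre_frames = 1000L, gamma0 = 18.98,
                                           rate = -61.07, residual = 0.03,
                                           open_cycles = 4L)),
    onset_hard = synth_spec("onset", seed = seed)
  )
  paths <- character(0)
  for (nm in names(specs)) {
    gen <- generate_sequence(specs[[nm]])
    tif <- file.path(out_dir, paste0(nm, ".tif"))
    write_mask_sequence(gen$seq, tif)
    jsonlite::write_json(gen$manifest,
                         file.path(out_dir, paste0(nm, "_manifest.json")),
                         auto_unbox = TRUE, digits = NA, null = "null")
    paths <- c(paths, tif)
  }
  invisible(paths)
}
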