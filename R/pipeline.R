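# End-to-end pipeline: masks -> landmarks -> LVG (+ PVG) -> measures
# (-> onset), with reproducible artifact bundle and provenance log.

#' Build a run configuration
#'
#' Defaults reproduce the fixed analysis constants: 150/25 sliding window,
#' 256 positions per fold, 1000-frame onset regression window.
#'
#' @param masks path to a multipage label-mask TIFF.
#' @param meta path to its JSON sidecar (defaults to `<masks>.json` next to it).
#' @param out_dir output directory for the artifact bundle.
#' @param window,overlap landmark smoothing window/overlap (frames).
#' @param n resampled positions per fold.
#' @param p relative fold position for trajectory-based measures.
#' @param prominence cycle-segmentation prominence fraction.
#' @param phase_method `"morlet"` or `"hilbert"` instantaneous-phase backend.
#' @param opening_threshold opening-range threshold (fraction of axis length).
#' @param onset logical: run voice-onset analysis.
#' @param onset_window onset regression window (frames).
#' @param pvg logical: also build the PVG baseline.
#' @param png logical: render PNG images.
#' @param seed integer seed recorded in the provenance log (the analysis
#'   itself is deterministic).
#' @param verbose logical: log progress to stderr.
#' @return list of class `run_config`.
#' @export
run_config <- function(masks, meta = NULL, out_dir = "lvg_out",
                       window = 150L, overlap = 25L, n = 256L, p = 0.5,
                       prominence = 0.1, phase_method = "morlet",
                       opening_threshold = 0.01, onset = FALSE,
                       onset_window = 1000L, pvg = TRUE, png = TRUE,
                       seed = 1L, verbose = TRUE) {
  if (is.null(meta)) meta <- sub("\\.tiff?$", ".json", masks)
  structure(list(masks = masks, meta = meta, out_dir = out_dir,
                 window = as.integer(window), overlap = as.integer(overlap),
                 n = as.integer(n), p = p, prominence = prominence,
                 phase_method = match.arg(phase_method,
                                          c("morlet", "hilbert")),
                 opening_threshold = opening_threshold, onset = onset,
                 onset_window = as.integer(onset_window), pvg = pvg,
                 png = png, seed = as.integer(seed), verbose = verbose),
            class = "run_config")
}

.log <- function(verbose, ...) {
  if (verbose) message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                               sprintf(...)))
}

# wrap a stage so failures carry the stage name (and keep frame indices from
# the underlying error message)
.stage <- function(name, verbose, expr) {
  .log(verbose, "stage %s", name)
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Reads a mask sequence, builds the LVG (and optionally the PVG), computes
#' the measure report, optionally runs onset analysis, and writes the artifact
#' bundle: `lvg.csv` + `lvg.json` (+ `lvg.png`), `pvg.csv`/`pvg.json`
#' (+ `pvg.png`), `gaw.csv`, `landmarks.csv`, `report.json`, per-cycle
#' `cycles_left.csv`/`cycles_right.csv`, optional `onset.json` +
#' `onset_series.csv`, and a `run_log.json` provenance record (config echo,
#' package/R versions, seed, timestamps).
#'
#' @param cfg a [run_config()].
#' @return invisibly, a list with the in-memory results (`lvg`, `pvg`,
#'   `measures`, `onset`, `gaw`) and `paths` (named character vector of
#'   artifacts written).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  t_start <- Sys.time()
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  art <- function(name) {
    p <- file.path(cfg$out_dir, name)
    paths[[name]] <<- p
    p
  }

  seq <- .stage("read_masks", cfg$verbose,
                read_mask_sequence(cfg$masks, cfg$meta))
  gaw <- .stage("gaw", cfg$verbose, compute_gaw(seq))
  write_gaw_csv(gaw, art("gaw.csv"))

  M <- .stage("lvg", cfg$verbose,
              build_lvg(seq, window = cfg$window, overlap = cfg$overlap,
                        n = cfg$n))
  write_lvg_csv(M, art("lvg.csv"))
  jsonlite::write_json(list(kind = "lvg", n = M$n, fps = M$fps,
                            layout = M$layout, frames = ncol(M$D)),
                       art("lvg.json"), auto_unbox = TRUE, digits = NA)
  write_landmarks_csv(attr(M, "landmarks"), art("landmarks.csv"))
  if (cfg$png) render_lvg(M, art("lvg.png"))

  pvg <- NULL
  if (cfg$pvg) {
    pvg <- .stage("pvg", cfg$verbose,
                  build_pvg(seq, window = cfg$window, overlap = cfg$overlap,
                            n = cfg$n))
    write_lvg_csv(pvg, art("pvg.csv"))
    jsonlite::write_json(list(kind = "pvg", n = pvg$n, fps = pvg$fps,
                              layout = pvg$layout, frames = ncol(pvg$D)),
                         art("pvg.json"), auto_unbox = TRUE, digits = NA)
    if (cfg$png) render_lvg(pvg, art("pvg.png"))
  }

  rep <- .stage("measures", cfg$verbose,
                measure_report(M, gaw = gaw, p = cfg$p,
                               phase_method = cfg$phase_method,
                               prominence = cfg$prominence,
                               opening_threshold = cfg$opening_threshold))
  write_measures_json(rep, art("report.json"))
  for (side in c("left", "right")) {
    cyc <- rep$cycles[[side]]
    if (!is.null(cyc) && cyc$J > 0L)
      write.csv(data.frame(cycle = seq_len(cyc$J),
                           period_frames = cyc$period,
                           amplitude = cyc$amplitude),
                art(sprintf("cycles_%s.csv", side)), row.names = FALSE)
  }

  ons <- NULL
  if (cfg$onset) {
    ons <- .stage("onset", cfg$verbose,
                  analyze_onset(seq, window = cfg$window,
                                overlap = cfg$overlap,
                                regression_window = cfg$onset_window))
    write_onset_json(ons, art("onset.json"), art("onset_series.csv"))
  }

  log <- list(
    config = unclass(cfg),
    package_version = as.character(utils::packageVersion("laryngovibro")),
    r_version = R.version.string,
    seed = cfg$seed,
    frames = n_frames(seq),
    fps = seq$fps,
    started = format(t_start, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    artifacts = as.list(paths)
  )
  jsonlite::write_json(log, art("run_log.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  .log(cfg$verbose, "done: %d artifacts in %s", length(paths), cfg$out_dir)
  invisible(list(lvg = M, pvg = pvg, measures = rep, onset = ons, gaw = gaw,
                 paths = unlist(paths)))
}
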