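test_that("onset phases and cycle count are detected on the default scenario", {
  gen <- fixture("onset_normal", {
    generate_sequence(synth_spec("onset", seed = 21L,
                                 f0 = 178,
                                 onset = list(pre_frames = 1000L,
                                              gamma0 = 18.98, rate = -61.07,
                                              residual = 0.03,
                                              open_cycles = 3L)))
  })
  man <- gen$manifest
  ons <- suppressWarnings(analyze_onset(gen$seq))
  ph <- ons$phases
  expect_false(ph$open_ended)
  # envelope-based detection with a zero-phase filter rings slightly early
  expect_lt(abs(ph$t_osc_start - man$t_osc_start), 60)
  expect_gte(ph$n_onset_cycles, 2L)
  expect_lte(ph$n_onset_cycles, 5L)
  expect_equal(ons$f0_sustained, 178, tolerance = 0.02)
  expect_equal(ons$gamma_slope, man$onset$rate, tolerance = 0.02)
  expect_equal(ph$phases$pre[2], ph$t_osc_start)
})

test_that("angular velocity regression is exact on a noiseless ramp", {
  fps <- 4000
  tsec <- (0:999) / fps
  gamma <- 21.5 - 70 * tsec
  expect_equal(angular_velocity(gamma, window_end = 1001L, fps = fps), -70,
               tolerance = 1e-9)
  expect_error(angular_velocity(gamma, 1001L), "fps")
  expect_warning(v <- angular_velocity(gamma, 500L, window = 1000L, fps = fps),
                 "shortened")
  expect_equal(v, -70, tolerance = 1e-9)
})

test_that("a sustained sequence has no onset; a silent one never oscillates", {
  gen <- fx_healthy()
  expect_error(segment_onset_phases(compute_gaw(gen$seq)),
               "oscillates from the first frame")
  silent <- structure(list(values = rep(0, 400), fps = 4000),
                      class = "gaw_series")
  expect_error(segment_onset_phases(silent), "never starts oscillating")
})

test_that("an open-ended onset is flagged with a warning", {
  gen <- fixture("onset_open", {
    generate_sequence(synth_spec("onset", frames = 1250L, seed = 22L,
                                 onset = list(pre_frames = 1000L,
                                              gamma0 = 24.22, rate = -85.35,
                                              residual = 0.2,
                                              open_cycles = 60L)))
  })
  expect_warning(ph <- segment_onset_phases(compute_gaw(gen$seq)),
                 "open-ended")
  expect_true(ph$open_ended)
  expect_true(is.na(ph$t_first_closure))
})

test_that("onset JSON export round-trips the scalar profile", {
  gen <- fixture("onset_normal",
    generate_sequence(synth_spec("onset", seed = 21L, f0 = 178,
                                 onset = list(pre_frames = 1000L,
                                              gamma0 = 18.98, rate = -61.07,
                                              residual = 0.03,
                                              open_cycles = 3L))))
  ons <- suppressWarnings(analyze_onset(gen$seq))
  jp <- tempfile(fileext = ".json"); cp <- tempfile(fileext = ".csv")
  write_onset_json(ons, jp, cp)
  j <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(j$t_osc_start, ons$phases$t_osc_start)
  expect_equal(j$n_onset_cycles, ons$phases$n_onset_cycles)
  expect_equal(nrow(read.csv(cp)), length(ons$gaw$values))
  unlink(c(jp, cp))
})
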