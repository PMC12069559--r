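test_that("cycle segmentation recovers sinusoidal cycles", {
  tr <- sine_trajectory(f0 = 100, fps = 4000, n_cycles = 20)
  cyc <- segment_cycles(tr)
  expect_equal(cyc$J, 18L) # 19 interior minima -> 18 complete cycles
  expect_equal(cyc$period, rep(40, 18), tolerance = 1e-6)
  expect_equal(cyc$amplitude, rep(0.1, 18), tolerance = 1e-3)
  expect_error(segment_cycles(rnorm(10)), "fps")
  flat <- segment_cycles(rep(1, 100), fps = 4000)
  expect_equal(flat$J, 0L)
})

test_that("RND is the per-cycle peak-to-peak deflection in percent", {
  tr <- sine_trajectory(amp = 0.04)
  r <- rnd(segment_cycles(tr))
  expect_equal(r$mean, 8, tolerance = 1e-3) # 2 x 4% of axis length
  expect_true(all(abs(r$per_cycle - 8) < 0.01))
})

test_that("shimmer and jitter match hand-computed alternating examples", {
  expect_equal(relative_shimmer(c(1.0, 0.8, 1.0, 0.8)), 2000 / 90)
  expect_equal(relative_jitter(c(10, 12, 10, 12)), 200 / 11)
  expect_equal(relative_shimmer(c(2, 2, 2)), 0)
  expect_equal(relative_jitter(c(5, 5, 5, 5)), 0)
  expect_true(is.na(relative_jitter(c(5))))
  expect_true(is.na(relative_shimmer(numeric(0))))
})

test_that("the amplitude-symmetry quotient is min/max with skip counting", {
  q <- q_rnd(rnd_r = c(8, 6, 0), rnd_l = c(4, 6, 0))
  expect_equal(q$per_cycle, c(0.5, 1))
  expect_equal(q$mean, 0.75)
  expect_equal(q$n_skipped, 1L)
  expect_equal(q_rnd(5, 5)$mean, 1)
})

test_that("F0 estimation is accurate for clean and noisy sinusoids", {
  t <- 0:7999
  x <- sin(2 * pi * 137.5 * t / 4000)
  expect_equal(estimate_f0(x, 4000)$f0, 137.5, tolerance = 1e-3)
  set.seed(42)
  xn <- x + rnorm(length(x), 0, 0.2)
  expect_equal(estimate_f0(xn, 4000)$f0, 137.5, tolerance = 5e-3)
  expect_error(estimate_f0(rep(1, 4000), 4000), "constant")
  expect_error(estimate_f0(rnorm(100)), "fps")
})

test_that("both phase backends recover an imposed constant phase offset", {
  t <- 0:3999
  x <- sin(2 * pi * 150 * t / 4000)
  y <- sin(2 * pi * 150 * t / 4000 - 0.31)
  for (m in c("morlet", "hilbert")) {
    phi_x <- instantaneous_phase(x, 150, 4000, method = m)
    phi_y <- instantaneous_phase(y, 150, 4000, method = m)
    expect_equal(lateral_phase_difference(phi_x, phi_y), 0.31,
                 tolerance = 5e-3, info = m)
  }
  expect_equal(lateral_phase_difference(c(1, 2), c(1, 2)), 0)
})

test_that("measures computed on a built LVG match the generator manifest", {
  gen <- fx_paresis()
  man <- gen$manifest
  rep <- measure_report(gen$lvg)
  amps_l <- man$cycles$amp_left
  amps_r <- man$cycles$amp_right
  expect_equal(rep$rnd_l$mean, 200 * mean(amps_l), tolerance = 0.05)
  expect_equal(rep$rnd_r$mean, 200 * mean(amps_r), tolerance = 0.05)
  q_true <- mean(pmin(amps_l, amps_r) / pmax(amps_l, amps_r))
  expect_equal(rep$q_rnd$mean, q_true, tolerance = 0.05)
  expect_equal(rep$delta_theta_p, man$phase_offset, tolerance = 0.05)
  expect_equal(rep$f0, gen$seq$fps / mean(man$cycles$periods), tolerance = 0.01)
})

test_that("consensus boundaries agree with single-position segmentation", {
  gen <- fx_healthy()
  cc <- consensus_cycles(gen$lvg)
  med <- segment_cycles(extract_trajectory(gen$lvg, "left", 0.5))
  expect_equal(cc$J, med$J)
  expect_lt(max(abs(cc$boundaries - med$boundaries)), 2)
  expect_equal(mean(cc$period), mean(med$period), tolerance = 1e-3)
})

test_that("the opening range covers the glottal gap and the JSON export works", {
  gen <- fx_healthy()
  op <- opening_range(gen$lvg)
  expect_length(op, 256L)
  expect_true(any(op))
  rep <- measure_report(gen$lvg)
  path <- tempfile(fileext = ".json")
  write_measures_json(rep, path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(j$rnd_mean_left_pct, round(rep$rnd_l$mean, 2))
  unlink(path)
})
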