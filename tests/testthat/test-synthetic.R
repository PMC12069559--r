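test_that("generation is deterministic for a fixed seed and spec", {
  sp <- synth_spec("healthy", frames = 60L, seed = 77L, period_jitter = 0.02,
                   amp_jitter = 0.01)
  g1 <- generate_sequence(sp)
  g2 <- generate_sequence(sp)
  expect_identical(g1$seq$frames, g2$seq$frames)
  expect_identical(g1$manifest, g2$manifest)
  g3 <- generate_sequence(synth_spec("healthy", frames = 60L, seed = 78L,
                                     period_jitter = 0.02, amp_jitter = 0.01))
  expect_false(identical(g1$seq$frames, g3$seq$frames))
})

test_that("generated frames contain only valid labels in sane proportions", {
  gen <- fx_healthy()
  v <- as.integer(gen$seq$frames)
  expect_true(all(v %in% 0:3))
  expect_true(all(c(0L, 1L, 2L, 3L) %in% v))
  # folds occupy comparable areas
  expect_equal(sum(v == 2L), sum(v == 3L), tolerance = 0.05)
})

test_that("infeasible and malformed specs are rejected", {
  expect_error(synth_spec("healthy", amp_left = 0.9), "impossible")
  expect_error(synth_spec("healthy", f0 = 3000), "Nyquist")
  expect_error(synth_spec("healthy", nonsense = 1), "unknown spec field")
})

test_that("the manifest cycle schedule is consistent", {
  gen <- fx_paresis()
  man <- gen$manifest
  cyc <- man$cycles
  expect_equal(diff(cyc$boundaries), cyc$periods)
  expect_true(all(cyc$boundaries <= man$frames + max(cyc$periods)))
  expect_equal(length(cyc$amp_left), length(cyc$periods))
  # paresis: right amplitudes uniformly smaller
  expect_true(all(cyc$amp_right < cyc$amp_left))
  expect_equal(man$phase_offset, 0.4)
})

test_that("manifest amplitudes are recovered by the pipeline (closure test)", {
  gen <- fx_healthy()
  man <- gen$manifest
  rep <- measure_report(gen$lvg)
  expect_equal(rep$rnd_l$mean, 200 * mean(man$cycles$amp_left),
               tolerance = 0.05)
  expect_equal(rep$f0, gen$seq$fps / mean(man$cycles$periods),
               tolerance = 0.01)
})

test_that("the fixture suite writes all sequences with manifests", {
  d <- tempfile("fix")
  files <- write_fixture_suite(d, seed = 5L, frames = 60L)
  expect_true(length(files) >= 8)
  tifs <- list.files(d, pattern = "\\.tif$", full.names = TRUE)
  expect_gte(length(tifs), 8)
  for (tf in tifs[1:2]) {
    s <- read_mask_sequence(tf)
    expect_equal(n_frames(s), 60L)
    mf <- sub("\\.tif$", "_manifest.json", tf)
    expect_true(file.exists(mf))
  }
  unlink(d, recursive = TRUE)
})
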