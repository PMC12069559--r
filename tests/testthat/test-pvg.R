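test_that("the PVG has 2n rows, zero columns when closed, and opens medially", {
  gen <- fx_healthy()
  pvg <- build_pvg(gen$seq)
  expect_s3_class(pvg, "pvg_matrix")
  expect_equal(nrow(pvg$D), 512L)
  expect_equal(ncol(pvg$D), n_frames(gen$seq))
  gaw <- compute_gaw(gen$seq)
  closed <- gaw$values == 0
  expect_true(any(closed))
  expect_equal(max(abs(pvg$D[, closed])), 0)
  expect_equal(pvg$open, !closed)
  # open frames show a positive gap on both sides
  t_open <- which.max(gaw$values)
  expect_gt(max(pvg$D[1:256, t_open]), 0)
  expect_gt(max(pvg$D[257:512, t_open]), 0)
})

test_that("the medial PVG position is central for a healthy glottis", {
  gen <- fx_healthy()
  pvg <- build_pvg(gen$seq)
  ax <- vibrational_axes(
    smooth_landmarks(track_landmarks(gen$seq), compute_gaw(gen$seq)))
  pos <- pvg_medial_position(pvg, ax)
  expect_gt(pos, 0.4)
  expect_lt(pos, 0.6)
})

test_that("a blocking polyp shifts the PVG dorsally (position < 0.5)", {
  gen <- fixture("polyp", {
    g <- generate_sequence(synth_spec("polyp", frames = 240L, seed = 13L))
    g
  })
  pvg <- build_pvg(gen$seq)
  ax <- vibrational_axes(
    smooth_landmarks(track_landmarks(gen$seq), compute_gaw(gen$seq)))
  pos <- pvg_medial_position(pvg, ax)
  expect_lt(pos, 0.45)
})

test_that("a never-opening glottis has an all-zero PVG and undefined position", {
  f <- array(0L, c(32, 32, 6))
  f[8:24, 10:15, ] <- 2L
  f[8:24, 16:21, ] <- 3L
  seq <- mask_sequence(f, fps = 100)
  pvg <- build_pvg(seq)
  expect_equal(max(abs(pvg$D)), 0)
  ax_dummy <- vibrational_axes(
    smooth_landmarks(track_landmarks(seq), compute_gaw(seq)))
  expect_error(pvg_medial_position(pvg, ax_dummy), "never opens")
})
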