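test_that("point-to-segment distance matches hand-computed examples", {
  a <- c(0, 0); b <- c(100, 0) # vertical axis in (row, col) coordinates
  # perpendicular foot inside the segment
  r1 <- point_segment_distance(c(50, 30), a, b)
  expect_equal(r1$d, 30)
  # beyond the ventral endpoint: distance to the endpoint itself
  r2 <- point_segment_distance(c(110, 30), a, b)
  expect_equal(r2$d, sqrt(10^2 + 30^2))
  # side sign: positive cross product half-plane
  expect_equal(point_segment_distance(c(50, 30), a, b)$side, 1)
  expect_equal(point_segment_distance(c(50, -30), a, b)$side, -1)
  expect_equal(point_segment_distance(c(50, 0), a, b)$side, 0)
  expect_error(point_segment_distance(c(1, 1), a, a), "degenerate")
})

test_that("deflection profiles are signed and normalized by axis length", {
  P <- c(0, 0); A <- c(100, 0)
  edge <- cbind(seq(0, 100, length.out = 21),
                10 * sin(pi * seq(0, 1, length.out = 21)))
  d_left <- deflection_profile(edge, P, A, "left", n = 64L)
  expect_length(d_left, 64L)
  expect_equal(max(d_left), 0.1, tolerance = 5e-3) # 10 px / 100 px
  expect_equal(d_left[1], 0)
  # the same edge seen as the right fold lies contralateral: sign flips
  d_right <- deflection_profile(edge, P, A, "right", n = 64L)
  expect_equal(d_right, -d_left)
  # scaling all coordinates leaves the normalized profile unchanged
  d_scaled <- deflection_profile(edge * 3.7, P * 3.7, A * 3.7, "left", 64L)
  expect_equal(d_scaled, d_left, tolerance = 1e-12)
})

test_that("the LVG has 2 x 256 rows and one column per frame", {
  gen <- fx_healthy()
  M <- gen$lvg
  expect_s3_class(M, "lvg_matrix")
  expect_equal(nrow(M$D), 512L)
  expect_equal(ncol(M$D), n_frames(gen$seq))
  expect_equal(M$n, 256L)
  expect_true(all(is.finite(M$D)))
})

test_that("a mirror-symmetric sequence gives mirrored fold halves", {
  gen <- fx_healthy()
  M <- gen$lvg
  n <- M$n
  expect_lt(max(abs(M$D[1:n, ] - M$D[(n + 1):(2 * n), ])), 2e-3)
})

test_that("mirroring the masks swaps the fold halves exactly", {
  gen <- fx_healthy()
  f <- gen$seq$frames[, , 1:40, drop = FALSE]
  fi <- array(as.integer(f), dim(f))
  # mirror columns and swap fold labels
  mir <- fi[, dim(fi)[2]:1, , drop = FALSE]
  tmp <- mir
  mir[tmp == 2L] <- 3L
  mir[tmp == 3L] <- 2L
  M1 <- build_lvg(mask_sequence(fi, gen$seq$fps))
  M2 <- build_lvg(mask_sequence(mir, gen$seq$fps))
  n <- M1$n
  expect_equal(M2$D[1:n, ], M1$D[(n + 1):(2 * n), ])
  expect_equal(M2$D[(n + 1):(2 * n), ], M1$D[1:n, ])
})

test_that("build_lvg equals geometry extraction plus assembly", {
  gen <- fx_healthy()
  geom <- lvg_geometry(gen$seq)
  M <- lvg_from_geometry(geom)
  expect_equal(M$D, gen$lvg$D)
})

test_that("LVG CSV round trip preserves the matrix", {
  gen <- fx_healthy()
  path <- tempfile(fileext = ".csv")
  write_lvg_csv(gen$lvg, path)
  jsonlite::write_json(list(kind = "lvg", n = gen$lvg$n, fps = gen$lvg$fps,
                            layout = gen$lvg$layout),
                       sub("\\.csv$", ".json", path), auto_unbox = TRUE,
                       digits = NA)
  back <- read_lvg_csv(path)
  expect_equal(back$D, unname(gen$lvg$D), tolerance = 1e-12)
  expect_equal(back$fps, gen$lvg$fps)
  expect_error(read_lvg_csv("missing.csv"), "format error")
  unlink(path); unlink(sub("\\.csv$", ".json", path))
})

test_that("render_lvg writes a PNG image", {
  gen <- fx_healthy()
  path <- tempfile(fileext = ".png")
  render_lvg(gen$lvg, path)
  expect_true(file.exists(path) && file.size(path) > 0)
  unlink(path)
})
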