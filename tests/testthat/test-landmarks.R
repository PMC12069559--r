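# tiny hand-drawn frame: right fold cols 2:3, glottis col 4 rows 2:5,
# left fold cols 5:6, folds touch at row 6 (anterior) and row 1 (posterior)
.toy_frame <- function() {
  f <- matrix(0L, 8, 8)
  f[1:6, 2:3] <- 2L  # right fold
  f[1:6, 5:6] <- 3L  # left fold
  f[2:5, 4] <- 1L    # glottis
  f[1, 4] <- 2L      # posterior contact
  f[6, 4] <- 3L      # anterior contact
  f
}

test_that("detect_endpoints finds posterior points and anterior commissure", {
  lm <- detect_endpoints(.toy_frame())
  # most dorsal adjacency row for both folds is row 1
  expect_equal(lm$P_r[1], 1)
  expect_equal(lm$P_l[1], 1)
  expect_lt(lm$P_r[2], lm$P_l[2]) # right fold has lower column index
  expect_equal(lm$A[1], 6)        # most ventral contact row
})

test_that("detect_endpoints merges posterior points on full closure", {
  f <- .toy_frame()
  f[f == 1L] <- 2L # remove the glottis: replace with fold
  f[2:5, 4] <- 2L
  lm <- detect_endpoints(f)
  expect_equal(lm$P_r, lm$P_l)
})

test_that("detect_endpoints errors on missing folds", {
  f <- .toy_frame()
  f[f == 2L] <- 0L
  expect_error(detect_endpoints(f), "both vocal folds")
})

test_that("compiled landmark tracking matches the R reference frame-by-frame", {
  gen <- fx_healthy()
  lm <- track_landmarks(gen$seq)
  for (t in c(1L, 57L, 123L, 240L)) {
    ref <- detect_endpoints(gen$seq, t)
    expect_equal(lm$P_r[t, ], ref$P_r, info = paste("frame", t))
    expect_equal(lm$P_l[t, ], ref$P_l, info = paste("frame", t))
    expect_equal(lm$A[t, ], ref$A, info = paste("frame", t))
  }
})

test_that("smoothing stabilizes landmarks and enforces the closure rule", {
  gen <- fx_healthy()
  lm <- track_landmarks(gen$seq)
  gaw <- compute_gaw(gen$seq)
  sm <- smooth_landmarks(lm, gaw)
  expect_true(sm$smoothed)
  # healthy sequences reach full closure in every window: merged P_r == P_l
  expect_equal(sm$P_r, sm$P_l)
  # smoothed tracks vary less than raw ones
  expect_lte(sd(sm$A[, 1]), sd(lm$A[, 1]) + 1e-12)
  expect_error(smooth_landmarks(lm, gaw, window = 10L, overlap = 10L))
})

test_that("axes and opening angle follow from the landmarks", {
  gen <- fx_healthy()
  man <- gen$manifest
  gaw <- compute_gaw(gen$seq)
  sm <- smooth_landmarks(track_landmarks(gen$seq), gaw)
  ax <- vibrational_axes(sm)
  expect_equal(mean(ax$L_r), man$geometry$axis_length, tolerance = 0.02)
  gam <- opening_angle(ax)
  # sustained phonation with merged posterior points: angle identically 0
  expect_equal(max(abs(gam$gamma)), 0)
})

test_that("rotation leaves axis lengths and opening angle unchanged", {
  th <- 17 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  P_r <- matrix(c(10, 100), 1); P_l <- matrix(c(12, 140), 1)
  A <- matrix(c(170, 120), 1)
  lm <- structure(list(P_r = P_r, P_l = P_l, A = A, fps = 4000,
                       smoothed = TRUE), class = "landmark_track")
  rot <- function(m) t(R %*% t(m))
  lm2 <- structure(list(P_r = rot(P_r), P_l = rot(P_l), A = rot(A),
                        fps = 4000, smoothed = TRUE),
                   class = "landmark_track")
  ax <- vibrational_axes(lm); ax2 <- vibrational_axes(lm2)
  expect_equal(ax2$L_r, ax$L_r)
  expect_equal(ax2$L_l, ax$L_l)
  expect_equal(opening_angle(ax2)$gamma, opening_angle(ax)$gamma)
})

test_that("landmark CSV export writes one row per frame", {
  gen <- fx_healthy()
  sm <- smooth_landmarks(track_landmarks(gen$seq), compute_gaw(gen$seq))
  path <- tempfile(fileext = ".csv")
  write_landmarks_csv(sm, path)
  df <- read.csv(path)
  expect_equal(nrow(df), n_frames(gen$seq))
  expect_true(all(c("Pr_row", "Pl_col", "A_row", "L_r", "gamma_deg")
                  %in% names(df)))
  unlink(path)
})
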