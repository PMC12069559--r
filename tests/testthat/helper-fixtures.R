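# Shared fixtures, memoized per test run so the expensive mask generation and
# LVG builds happen once per session.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixture_cache[[name]]))
    assign(name, force(expr), envir = .fixture_cache)
  .fixture_cache[[name]]
}

# small healthy sequence + derived products used across test files
fx_healthy <- function() fixture("healthy", {
  gen <- generate_sequence(synth_spec("healthy", frames = 240L, seed = 11L))
  gen$lvg <- build_lvg(gen$seq)
  gen
})

fx_paresis <- function() fixture("paresis", {
  gen <- generate_sequence(synth_spec("paresis", frames = 240L, seed = 12L))
  gen$lvg <- build_lvg(gen$seq)
  gen
})

# pure sinusoidal trajectory with known cycle structure; one cycle is
# computed and tiled so the series is bitwise periodic
sine_trajectory <- function(f0 = 100, fps = 4000, n_cycles = 20, amp = 0.05,
                            phase = -pi / 2) {
  P <- fps / f0
  stopifnot(abs(P - round(P)) < 1e-9)
  P <- round(P)
  one <- amp * (1 + sin(2 * pi * (seq_len(P) - 1) / P + phase))
  as_trajectory(rep(one, n_cycles), fps)
}

# similarity transform (scale s, rotation theta, translation shift) of an
# lvg_geometry, applied to edges and landmarks alike
transform_geom <- function(geom, s = 1, theta = 0, shift = c(0, 0)) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  tp <- function(p) as.numeric(s * R %*% p + shift)
  tm <- function(m) t(apply(m, 1, tp))
  geom$frames <- lapply(geom$frames, function(g)
    list(left = tm(g$left), right = tm(g$right),
         P_r = tp(g$P_r), P_l = tp(g$P_l), A = tp(g$A)))
  geom
}

`%||%` <- function(a, b) if (is.null(a)) b else a
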