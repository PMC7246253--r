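# Field and node dynamics: relaxation, interaction, peaks, regimes.

dx <- dim_spec("x", c(0, 100), 51)

test_that("sigmoid is a logistic threshold", {
  expect_equal(sigmoid(0, 2), 0.5)
  expect_equal(sigmoid(1e3, 4), 1)
  expect_equal(sigmoid(-1e3, 4), 0)
  u <- seq(-3, 3, by = 0.5)
  expect_equal(sigmoid(-u, 4), 1 - sigmoid(u, 4))
  expect_true(all(diff(sigmoid(u, 1)) > 0))
  expect_error(sigmoid(0, -1))
})

test_that("a field relaxes to h + s and decays exponentially", {
  f <- dnf_field(dx, h = -5, tau = 100)
  for (i in 1:400) f <- step_field(f, input = 3, dt = 5)
  expect_equal(unname(range(f$u)), c(-2, -2), tolerance = 1e-6)

  # distance to the fixed point shrinks by e^-1 over one tau
  f2 <- dnf_field(dx, h = -5, tau = 100)
  d0 <- abs(f2$u[1] - (-2))
  for (i in 1:20) f2 <- step_field(f2, input = 3, dt = 5)
  expect_equal(abs(f2$u[1] - (-2)) / d0, exp(-1), tolerance = 0.03)

  expect_error(step_field(f, 0, dt = 50), "tau/5")
})

test_that("interaction input matches a direct discrete convolution", {
  k <- dnf_kernel(exc_amp = 3, exc_width = 4, inh_amp = 1.5, inh_width = 12)
  f <- dnf_field(dx, h = -5, kernel = k)
  f$u <- 2 * gauss_bump(dx, 50, 4) - 5 + 7 * gauss_bump(dx, 50, 4)

  # oracle: explicit smoothing-matrix convolution
  out <- sigmoid(f$u, f$beta)
  Me <- exp(-outer(grid_points(dx), grid_points(dx), "-")^2 / (2 * 4^2))
  Me <- Me / rowSums(Me)
  Mi <- exp(-outer(grid_points(dx), grid_points(dx), "-")^2 / (2 * 12^2))
  Mi <- Mi / rowSums(Mi)
  oracle <- 3 * as.vector(Me %*% out) - 1.5 * as.vector(Mi %*% out)
  expect_equal(as.vector(interaction_input(f)), oracle, tolerance = 1e-10)

  # a sub-threshold field contributes (essentially) nothing
  f0 <- dnf_field(dx, h = -5, kernel = k)
  expect_lt(max(abs(interaction_input(f0))), 1e-6)

  # positive at a supra-threshold bump centre, weaker in the surround
  contrib <- interaction_input(f)
  expect_gt(contrib[26], 0)
  expect_gt(contrib[26], contrib[16])
})

test_that("global inhibition reduces net excitation when peaks coexist", {
  k <- dnf_kernel(exc_amp = 3, exc_width = 4, global_inh = 40, global_tau = 0)
  lone <- dnf_field(dx, h = -5, kernel = k)
  lone$u <- -5 + 8 * gauss_bump(dx, 30, 3)
  pair <- dnf_field(dx, h = -5, kernel = k)
  pair$u <- -5 + 8 * gauss_bump(dx, 20, 3) + 8 * gauss_bump(dx, 80, 3)
  i_lone <- interaction_input(lone)[16]
  i_pair <- interaction_input(pair)[11]
  expect_lt(i_pair, i_lone)
})

test_that("detection instability shows hysteresis under input ramps", {
  k <- dnf_kernel(exc_amp = 8, exc_width = 4)
  up_at <- NA
  down_at <- NA
  f <- dnf_field(dx, h = -5, kernel = k)
  for (amp in seq(0, 8, by = 0.25)) {
    for (i in 1:80) f <- step_field(f, amp * gauss_bump(dx, 50, 4), dt = 5)
    if (is.na(up_at) && nrow(detect_peaks(f)) > 0) { up_at <- amp; break }
  }
  for (amp in seq(up_at, 0, by = -0.25)) {
    for (i in 1:80) f <- step_field(f, amp * gauss_bump(dx, 50, 4), dt = 5)
    if (nrow(detect_peaks(f)) == 0) { down_at <- amp; break }
  }
  expect_false(is.na(up_at))
  expect_false(is.na(down_at))
  expect_lt(down_at, up_at)   # maintaining a peak needs less input
})

test_that("node dynamics: fixed point, latch and hysteresis", {
  n <- dnf_node(h = -5, tau = 100, self_exc = 0)
  for (i in 1:400) n <- step_node(n, input = 3, dt = 5)
  expect_equal(n$u, -2, tolerance = 1e-6)

  n0 <- dnf_node(h = -5, tau = 100)
  for (i in 1:100) n0 <- step_node(n0, 0, dt = 5)
  expect_equal(n0$u, -5)

  # bistable node: on-switch needs more input than off-switch
  n <- dnf_node(h = -5, self_exc = 4)
  on_at <- NA; off_at <- NA
  for (s in seq(0, 8, by = 0.25)) {
    for (i in 1:200) n <- step_node(n, s, dt = 5)
    if (is.na(on_at) && node_on(n)) { on_at <- s; break }
  }
  for (s in seq(on_at, 0, by = -0.25)) {
    for (i in 1:200) n <- step_node(n, s, dt = 5)
    if (!node_on(n)) { off_at <- s; break }
  }
  expect_lt(off_at, on_at)
})

test_that("peak detection labels connected supra-threshold regions", {
  f <- dnf_field(dx, h = -5)
  expect_equal(nrow(detect_peaks(f)), 0)

  f$u <- -5 + 7 * gauss_bump(dx, 30, 4)
  p <- detect_peaks(f)
  expect_equal(nrow(p), 1)
  expect_equal(p$x[1], 30, tolerance = 3)
  expect_gt(p$activation[1], 0)

  f$u <- -5 + 7 * gauss_bump(dx, 20, 3) + 7 * gauss_bump(dx, 75, 3)
  expect_equal(nrow(detect_peaks(f)), 2)

  # merged bumps form a single connected component
  f$u <- -5 + 7 * gauss_bump(dx, 45, 6) + 7 * gauss_bump(dx, 55, 6)
  expect_equal(nrow(detect_peaks(f)), 1)

  # wrapped components on a circular dimension
  dc <- dim_spec("hue", c(0, 360), 24, circular = TRUE)
  fc <- dnf_field(dc, h = -5)
  fc$u <- -5 + 7 * gauss_bump(dc, 0, 20)   # peak straddles the wrap
  expect_equal(nrow(detect_peaks(fc)), 1)
})

test_that("sustained regime keeps a peak long after input removal", {
  k <- dnf_kernel(exc_amp = 8, exc_width = 3)
  f <- dnf_field(dx, h = -3, tau = 100, kernel = k, regime = "sustained")
  for (i in 1:200) f <- step_field(f, 6 * gauss_bump(dx, 40, 4), dt = 5)
  expect_gt(nrow(detect_peaks(f)), 0)
  for (i in 1:200) f <- step_field(f, 0, dt = 5)   # 10 tau
  expect_equal(nrow(detect_peaks(f)), 1)
})

test_that("Euler integration converges under dt refinement", {
  k <- dnf_kernel(exc_amp = 6, exc_width = 5)
  run_dt <- function(dt) {
    f <- dnf_field(dx, h = -5, tau = 100, kernel = k)
    for (i in seq_len(round(2000 / dt))) {
      f <- step_field(f, 6.5 * gauss_bump(dx, 52, 5), dt = dt)
    }
    detect_peaks(f)$x[1]
  }
  expect_lt(abs(run_dt(5) - run_dt(2.5)), diff(dx$extent) / (dx$samples - 1))
})

test_that("rng streams replay exactly and are independent", {
  a <- rng_stream(42); b <- rng_stream(42); c <- rng_stream(43)
  xa <- stream_rnorm(a, 10)
  glob <- stats::runif(3)  # interleaved global draws do not disturb streams
  expect_identical(stream_rnorm(b, 10), xa)
  expect_false(all(stream_rnorm(c, 10) == xa))
  expect_true(derive_seed(1, "field_a") != derive_seed(1, "field_b"))
  expect_lt(derive_seed(2^20, "x"), 2^31)
})
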