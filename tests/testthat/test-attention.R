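# Attentional selection, IOR, working memory reset, transient detectors.

test_that("the selection field resolves two equal items fairly", {
  cfg <- test_cfg()
  sal <- two_bump_salience(cfg)
  uniq <- 0; left <- 0
  for (s in 1:60) {
    st <- settle_selection(cfg, sal, s)
    p <- selection_peak(st)
    expect_lte(nrow(p), 1)
    if (nrow(p) == 1) {
      uniq <- uniq + 1
      if (p$x[1] < 250) left <- left + 1
    }
  }
  expect_gte(uniq, 57)
  expect_gt(left / uniq, 0.3)
  expect_lt(left / uniq, 0.7)
})

test_that("an IOR-inhibited item loses the selection to its competitor", {
  cfg <- test_cfg()
  sal <- two_bump_salience(cfg)
  inh <- -5.5 * outer(gauss_bump(cfg$dims$x, 170, 15),
                      gauss_bump(cfg$dims$y, 200, 15))
  right <- 0; n <- 0
  for (s in 1:30) {
    p <- selection_peak(settle_selection(cfg, sal, s, bias = inh))
    if (nrow(p) == 1) { n <- n + 1; right <- right + (p$x[1] > 250) }
  }
  expect_gt(right / n, 0.95)
})

test_that("the IOR trace builds at attended locations and drives coverage", {
  cfg <- test_cfg()
  sal <- two_bump_salience(cfg)
  st <- attention_state(cfg, 3)
  expect_true(all(st$ior_trace == 0))
  for (i in 1:120) {
    st <- step_attention(st, sal, dt = 5,
                         selection_boost = 1.5 * min(1, i * 5 / 80))
  }
  p <- selection_peak(st)
  skip_if(nrow(p) != 1)
  ix <- gidx(p$x[1], cfg$dims$x); iy <- gidx(p$y[1], cfg$dims$y)
  expect_gt(st$ior_trace[ix, iy], 0.3)
  other <- if (p$x[1] < 250) c(330, 200) else c(170, 200)
  expect_lt(st$ior_trace[gidx(other[1], cfg$dims$x),
                         gidx(other[2], cfg$dims$y)], 0.1)
})

test_that("onset detector responds transiently to input steps only", {
  cfg <- test_cfg()
  det <- transient_detector(cfg, "onset")
  z <- matrix(0, cfg$vision$nx, cfg$vision$ny)
  bump <- outer(gauss_bump(cfg$dims$x, 170, 15), gauss_bump(cfg$dims$y, 160, 15))

  # constant input: after the initial transient has passed, no output
  det_c <- det
  late_out <- 0
  for (i in 1:200) {
    r <- detect_onset(det_c, bump, cfg)
    det_c <- r$detector
    if (i * 5 > cfg$transients$window + 100) late_out <- max(late_out, max(r$output))
  }
  expect_equal(late_out, 0)

  # step input: a transient that decays while the input persists
  det_s <- det
  for (i in 1:20) det_s <- detect_onset(det_s, z, cfg)$detector
  peak_seen <- FALSE; gone <- FALSE
  for (i in 1:200) {
    r <- detect_onset(det_s, bump, cfg)
    det_s <- r$detector
    t_after <- i * 5
    if (max(r$output) > 0.5) peak_seen <- TRUE
    if (t_after > cfg$transients$window) gone <- max(r$output) < 0.05
  }
  expect_true(peak_seen)
  expect_true(gone)

  # two simultaneous steps give two transient peaks
  two <- two_bump_salience(cfg)
  det_2 <- det
  seen2 <- FALSE
  for (i in 1:40) {
    r <- detect_onset(det_2, two, cfg)
    det_2 <- r$detector
    f <- dnf_field(space_dims(cfg), h = -1)
    f$u <- array(r$output - 0.5, dim = dim(f$u))
    if (nrow(detect_peaks(f)) == 2) seen2 <- TRUE
  }
  expect_true(seen2)
})

test_that("array offset resets spatial working memory via the offset detector", {
  cfg <- test_cfg()
  sal <- two_bump_salience(cfg)
  st <- attention_state(cfg, 5)
  # attend one location long enough to commit it to SWM
  for (i in 1:160) {
    st <- step_attention(st, sal, dt = 5,
                         selection_boost = 1.5 * min(1, i * 5 / 80))
  }
  skip_if(nrow(detect_peaks(st$swm)) == 0)
  n_before <- nrow(detect_peaks(st$swm))

  # array continuously visible: SWM persists
  st_keep <- st
  for (i in 1:100) st_keep <- step_attention(st_keep, sal, dt = 5)
  expect_gte(nrow(detect_peaks(st_keep$swm)), n_before)

  # blank frame: the offset transient deboosts SWM globally
  z <- matrix(0, cfg$vision$nx, cfg$vision$ny)
  st_blank <- st
  for (i in seq_len(cfg$transients$window / 5)) {
    st_blank <- step_attention(st_blank, z, dt = 5)
  }
  expect_equal(nrow(detect_peaks(st_blank$swm)), 0)
})

test_that("SWM capacity is limited to four of six driven locations", {
  cfg <- test_cfg()
  st <- attention_state(cfg, 1)
  locs <- tile_centers()[tile_centers()$tile %in% c(1, 3, 5, 11, 15, 20), ]
  stepswm <- function(st, inp, dt) {
    v <- st$swm$inh_pool
    if (is.null(v)) v <- 0
    st$swm$inh_pool <- v + (cc2d(st$swm$u > 0) / 100 - v) * min(1, dt / 25)
    st$swm <- step_field(st$swm, inp, dt)
    st
  }
  for (r in seq_len(nrow(locs))) {
    b <- outer(gauss_bump(cfg$dims$x, locs$cx[r], 14),
               gauss_bump(cfg$dims$y, locs$cy[r], 14))
    sb <- sigmoid(8 * b - 4, 1.5); sb[8 * b - 4 <= 0] <- 0
    for (i in 1:50) st <- stepswm(st, cfg$fields$swm$w_sel * sb, 5)
    for (i in 1:10) st <- stepswm(st, 0, 5)
  }
  for (i in 1:100) st <- stepswm(st, 0, 8)
  expect_equal(nrow(detect_peaks(st$swm)), 4)
})
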