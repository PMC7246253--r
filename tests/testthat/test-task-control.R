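# Task-level control: cue retention, guidance normalization, exploration
# coverage, sequencing.

test_that("the n-1 guidance rule holds over the feature-combination classes", {
  cfg <- test_cfg()
  # array built so that all four combination classes are present
  spec <- generate_array(2, 6, seed = 31)
  arch <- architecture(cfg, 31)
  feats <- segment_features(arch, spec, "array_cue")
  tc <- tile_centers()
  ct8 <- tc[tc$tile == cue_tile(), ]
  prof <- extract_attended_features(arch$memory, feats,
                                    data.frame(x = ct8$cx, y = ct8$cy))
  arch$memory <- attr(prof, "memory")
  arch <- store_cue_ns(arch, prof, c("color", "orientation", "size"))
  g <- compute_guidance(arch, feats)
  classify <- function(it) {
    mc <- it$color == spec$target_color
    mo <- it$orientation == spec$target_orientation
    if (mc && mo) "tt" else if (mc) "td" else if (mo) "dt" else "dd"
  }
  for (i in seq_len(nrow(spec$items))) {
    it <- spec$items[i, ]
    ct <- tc[tc$tile == it$tile, ]
    k1 <- g$k1[gidx(ct$cx, cfg$dims$x), gidx(ct$cy, cfg$dims$y)]
    guided <- k1 > 0.5
    expect_equal(guided, classify(it) != "dd",
                 info = paste("class", classify(it)))
  }
  # no cue stored: guidance is identically sub-threshold
  arch0 <- architecture(cfg, 32)
  g0 <- compute_guidance(arch0, feats)
  expect_true(all(g0$bias == 0))
})

test_that("single-feature cue guides full matches only", {
  cfg <- test_cfg()
  spec <- generate_array(1, 8, seed = 11)
  arch <- architecture(cfg, 11)
  feats <- segment_features(arch, spec, "array_cue")
  tc <- tile_centers()
  ct8 <- tc[tc$tile == cue_tile(), ]
  prof <- extract_attended_features(arch$memory, feats,
                                    data.frame(x = ct8$cx, y = ct8$cy))
  arch$memory <- attr(prof, "memory")
  arch <- store_cue_ns(arch, prof, "color")
  g <- compute_guidance(arch, feats)
  for (i in seq_len(nrow(spec$items))) {
    it <- spec$items[i, ]
    ct <- tc[tc$tile == it$tile, ]
    k1 <- g$k1[gidx(ct$cx, cfg$dims$x), gidx(ct$cy, cfg$dims$y)]
    expect_equal(k1 > 0.5, it$color == spec$target_color)
  }
})

test_that("retention stores the cue's features in the search-cue fields", {
  cfg <- test_cfg()
  spec <- generate_array(3, 6, seed = 13)
  arch <- architecture(cfg, 13)
  feats <- segment_features(arch, spec, "array_cue")
  ret <- run_retain(arch, feats, c("color", "orientation", "size"))
  expect_true(ret$stored)
  arch <- ret$arch
  cues <- cue_profiles(arch)
  hue_of <- c(red = 0, green = 120, blue = 240)
  expect_equal(grid_points(cfg$dims$hue)[which.max(cues$color)],
               hue_of[[spec$target_color]])
  expect_equal(grid_points(cfg$dims$ori)[which.max(cues$orientation)],
               spec$target_orientation %% 180)
  # cue content persists after attention is released and time passes
  rel <- if (exists("release_attention", mode = "function")) release_attention
         else getFromNamespace("release_attention", "dnfsearch")
  arch <- rel(arch, feats)
  for (i in 1:100) {
    for (nm in names(arch$cue)) arch$cue[[nm]] <- step_field(arch$cue[[nm]], 0, 5)
  }
  cues2 <- cue_profiles(arch)
  expect_equal(which.max(cues2$color), which.max(cues$color))
})

test_that("exploration visits distinct items without repetition", {
  cfg <- test_cfg()
  for (k in c(4, 6)) {
    spec <- generate_array(3, k, seed = 40 + k)
    arch <- architecture(cfg, 40 + k)
    feats <- segment_features(arch, spec, "array")
    visited <- integer(0)
    for (cyc in seq_len(k)) {
      step <- run_explore_cycle(arch, feats, max_ms = 900)
      arch <- step$arch
      if (is.na(step$tile)) break
      visited <- c(visited, step$tile)
    }
    expect_equal(anyDuplicated(visited), 0)
    expect_gte(length(unique(visited)), k - 1)
    expect_true(all(visited %in% spec$items$tile))
  }
})

test_that("a full trial runs an alternating selection/match sequence", {
  cfg <- test_cfg()
  spec <- generate_array(3, 6, seed = 23)
  res <- run_trial(spec, cfg, seed = 123)
  expect_false(res$aborted)
  expect_true(res$correct)
  expect_gt(res$rt_ms, 0)
  ev <- event_log(res$arch)
  seq_ev <- ev$event[grepl("^(selection|match_|retain_)", ev$event)]
  # every selection is followed by a match/retain outcome before the next
  sel_idx <- which(seq_ev == "selection")
  for (i in sel_idx) {
    if (i < length(seq_ev)) expect_false(seq_ev[i + 1] == "selection")
  }
})

test_that("guided search finds the single-feature target without rejections", {
  cfg <- test_cfg()
  nrej <- vapply(c(4, 18), function(s) {
    spec <- generate_array(1, s, seed = 50 + s)
    res <- run_trial(spec, cfg, seed = 150 + s)
    expect_true(res$correct)
    res$rejections
  }, numeric(1))
  expect_lte(mean(nrej), 1)
})
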