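# Search-array generation, composition rules and rendering.

test_that("conjunction arrays follow the distractor composition rules", {
  for (s in c(4, 6, 8, 14, 18)) {
    spec <- generate_array(2, s, seed = s * 3 + 1)
    it <- spec$items
    expect_equal(nrow(it), s)
    expect_equal(sum(it$is_target), 1)
    expect_false(cue_tile() %in% it$tile)
    expect_equal(anyDuplicated(it$tile), 0)
    ct <- spec$target_color; ot <- spec$target_orientation
    cd <- spec$distractor_color; od <- spec$distractor_orientation
    shared_c <- sum(!it$is_target & it$color == ct & it$orientation == od)
    shared_o <- sum(!it$is_target & it$color == cd & it$orientation == ot)
    distinct <- sum(!it$is_target & it$color == cd & it$orientation == od)
    expect_equal(shared_c, (s - 2) / 2)
    expect_equal(shared_o, (s - 2) / 2)
    expect_equal(distinct, 1)
  }
  expect_error(generate_array(2, 5, seed = 1), "set_size")
})

test_that("feature search uses vertical bars in two colors", {
  spec <- generate_array(1, 8, seed = 5)
  expect_true(all(spec$items$orientation == 90))
  expect_equal(length(unique(spec$items$color)), 2)
  expect_equal(sum(spec$items$color == spec$target_color), 1)
})

test_that("tile usage is near-uniform and composition balanced over seeds", {
  counts <- integer(20)
  for (seed in 1:300) {
    spec <- generate_array(2, 6, seed = seed)
    counts[spec$items$tile] <- counts[spec$items$tile] + 1
    it <- spec$items
    expect_equal(sum(!it$is_target & it$color == spec$target_color),
                 sum(!it$is_target & it$orientation == spec$target_orientation))
  }
  expect_equal(counts[cue_tile()], 0)
  used <- counts[-cue_tile()]
  expect_gt(min(used), 0.6 * mean(used))
  expect_lt(max(used), 1.4 * mean(used))
})

test_that("timelines carry the printed segment durations", {
  t1 <- trial_timeline(1, 2)
  expect_equal(t1$content, c("blank", "preview", "array_cue"))
  expect_equal(t1$duration, c(200, 800, Inf))
  expect_equal(attr(t1, "rt_from"), "array_cue")
  t1b <- trial_timeline(1, 3)
  expect_equal(t1b$content[2], "blank")
  t2 <- trial_timeline(2, 2)
  expect_equal(t2$content,
               c("blank", "preview", "blank", "cue", "blank", "array"))
  expect_equal(t2$duration, c(100, 800, 100, 400, 100, Inf))
  expect_equal(attr(t2, "rt_from"), "array")
})

test_that("rendering is deterministic, white-backed, and round-trips", {
  spec <- generate_array(3, 4, seed = 9)
  fr1 <- render_frame(spec, "array_cue")
  fr2 <- render_frame(spec, "array_cue")
  expect_identical(fr1, fr2)
  expect_true(all(render_frame(spec, "blank") == 1))
  # preview shows the array without the cue tile item
  pv <- render_frame(spec, "preview")
  ct <- tile_centers()[tile_centers()$tile == cue_tile(), ]
  expect_true(all(pv[ct$cy + (-35:35), ct$cx + (-35:35), ] == 1))

  # feature extraction recovers each rendered item's labels
  cfg <- test_cfg()
  feats <- extract_features(render_frame(spec, "array"), cfg)
  hue_of <- c(red = 0, green = 120, blue = 240)
  for (i in seq_len(nrow(spec$items))) {
    r <- item_response(feats, spec$items$tile[i])
    expect_equal(grid_points(cfg$dims$hue)[which.max(r$color)],
                 hue_of[[spec$items$color[i]]])
    expect_equal(grid_points(cfg$dims$ori)[which.max(r$orientation)],
                 spec$items$orientation[i] %% 180)
  }
})

test_that("array specs serialize and restore for trial replay", {
  spec <- generate_array(2, 6, seed = 17)
  path <- tempfile(fileext = ".yaml")
  write_array_spec(spec, path)
  back <- read_array_spec(path)
  expect_equal(back$items$tile, spec$items$tile)
  expect_equal(back$items$color, spec$items$color)
  expect_equal(back$target_color, spec$target_color)
  unlink(path)
})
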