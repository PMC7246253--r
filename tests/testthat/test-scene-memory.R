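# Item-by-item commitment to capacity-limited scene working memory.

test_that("attended features are extracted; empty tiles yield nothing", {
  cfg <- test_cfg()
  sc <- test_scene()
  mem <- memory_maps(cfg, 1)
  tc <- tile_centers()
  it <- sc$spec$items[1, ]
  ct <- tc[tc$tile == it$tile, ]
  prof <- extract_attended_features(mem, sc$feats,
                                    data.frame(x = ct$cx, y = ct$cy))
  hue_of <- c(red = 0, green = 120, blue = 240)
  expect_equal(grid_points(cfg$dims$hue)[which.max(prof$color)],
               hue_of[[it$color]])
  expect_equal(grid_points(cfg$dims$ori)[which.max(prof$orientation)],
               it$orientation %% 180)

  free <- setdiff(tc$tile, c(sc$spec$items$tile, cue_tile()))
  cte <- tc[tc$tile == free[1], ]
  p0 <- extract_attended_features(mem, sc$feats,
                                  data.frame(x = cte$cx, y = cte$cy))
  expect_equal(max(unlist(p0)), 0)

  # with two items present, extraction returns only the attended one
  it2 <- sc$spec$items[2, ]
  expect_false(it2$tile == it$tile)
  prof1 <- extract_attended_features(mem, sc$feats,
                                     data.frame(x = ct$cx, y = ct$cy))
  expect_equal(which.max(prof1$color), which.max(prof$color))
})

test_that("commits persist, bind correctly, and do not duplicate", {
  cfg <- test_cfg()
  sc <- test_scene()
  mem <- memory_maps(cfg, 1)
  tc <- tile_centers()
  commit_at <- function(mem, i) {
    it <- sc$spec$items[i, ]
    ct <- tc[tc$tile == it$tile, ]
    att <- data.frame(x = ct$cx, y = ct$cy)
    prof <- extract_attended_features(mem, sc$feats, att)
    mem <- attr(prof, "memory")
    commit_item(mem, att, prof)
  }
  for (i in 1:3) mem <- commit_at(mem, i)
  expect_equal(memory_item_count(mem), 3)

  # re-attending a stored item merges, not duplicates
  mem <- commit_at(mem, 2)
  expect_equal(memory_item_count(mem), 3)

  # binding: recalled features equal the committed items' features
  snap <- memory_snapshot(mem)
  hue_of <- c(red = 0, green = 120, blue = 240)
  for (r in seq_len(nrow(snap))) {
    tile <- nearest_tile(c(snap$x[r], snap$y[r]))
    it <- sc$spec$items[sc$spec$items$tile == tile, ]
    expect_equal(nrow(it), 1)
    expect_equal(snap$hue[r], hue_of[[it$color]])
    expect_equal(snap$ori[r], it$orientation %% 180)
  }
})

test_that("recall at a stored location returns its features, else nothing", {
  cfg <- test_cfg()
  sc <- test_scene()
  mem <- memory_maps(cfg, 1)
  tc <- tile_centers()
  it <- sc$spec$items[1, ]
  ct <- tc[tc$tile == it$tile, ]
  att <- data.frame(x = ct$cx, y = ct$cy)
  prof <- extract_attended_features(mem, sc$feats, att)
  mem <- attr(prof, "memory")
  mem <- commit_item(mem, att, prof)

  rec <- recall_at_location(mem, att)
  hue_of <- c(red = 0, green = 120, blue = 240)
  expect_equal(grid_points(cfg$dims$hue)[which.max(rec$color)],
               hue_of[[it$color]])

  free <- setdiff(tc$tile, c(sc$spec$items$tile, cue_tile()))
  cte <- tc[tc$tile == free[1], ]
  rec0 <- recall_at_location(attr(rec, "memory"),
                             data.frame(x = cte$cx, y = cte$cy))
  expect_equal(max(unlist(rec0)), 0)
})

test_that("capacity saturates at min(n, 4) and survives a blank frame", {
  cfg <- test_cfg()
  sc <- test_scene()
  tc <- tile_centers()
  commit_first_n <- function(n) {
    mem <- memory_maps(cfg, 1)
    for (i in seq_len(n)) {
      it <- sc$spec$items[i, ]
      ct <- tc[tc$tile == it$tile, ]
      att <- data.frame(x = ct$cx, y = ct$cy)
      prof <- extract_attended_features(mem, sc$feats, att)
      mem <- attr(prof, "memory")
      mem <- commit_item(mem, att, prof)
    }
    mem
  }
  expect_equal(memory_item_count(commit_first_n(2)), 2)
  mem6 <- commit_first_n(6)
  expect_equal(memory_item_count(mem6), 4)

  # the memory maps are not connected to the offset reset: their content
  # is unchanged by a long blank (only the SWM field resets)
  n0 <- memory_item_count(mem6)
  for (i in 1:100) mem6 <- step_mem(mem6, list(), 8)
  expect_equal(memory_item_count(mem6), n0)
})
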