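# Feed-forward feature extraction and salience.

test_that("pure colors land at their HSV hues; background is silent", {
  cfg <- test_cfg()
  hue_pts <- grid_points(cfg$dims$hue)
  for (col in c(red = 0, green = 120, blue = 240)) {
    spec <- generate_array(3, 4, seed = 3)
    spec$items <- data.frame(tile = 13, color = names(which(
      c(red = 0, green = 120, blue = 240) == col)),
      orientation = 0, is_target = TRUE, stringsAsFactors = FALSE)
    fr <- render_frame(spec, "array")
    cm <- extract_color(fr, cfg)
    r <- item_response(list(color = cm, orientation = cm, size = cm,
                            salience = 0 * cm[, , 1]), 13)$color
    expect_equal(hue_pts[which.max(r)], col)
  }
  blank <- render_frame(generate_array(3, 4, seed = 3), "blank")
  expect_equal(max(extract_color(blank, cfg)), 0)
})

test_that("bars drive the orientation channel matching their axis", {
  cfg <- test_cfg()
  ori_pts <- grid_points(cfg$dims$ori)
  for (ang in c(0, 45, 90, 135)) {
    spec <- generate_array(3, 4, seed = 3)
    spec$items <- data.frame(tile = 13, color = "red", orientation = ang,
                             is_target = TRUE, stringsAsFactors = FALSE)
    fr <- render_frame(spec, "array")
    om <- extract_orientation(fr, cfg)
    r <- om[gidx(250, cfg$dims$x), gidx(240, cfg$dims$y), ]
    expect_equal(ori_pts[which.max(r)], ang)
  }
})

test_that("size responses are translation-invariant and grow with extent", {
  cfg <- test_cfg()
  lvl_for <- function(tile, len) {
    spec <- generate_array(3, 4, seed = 3)
    spec$items <- data.frame(tile = tile, color = "red", orientation = 0,
                             is_target = TRUE, stringsAsFactors = FALSE)
    fr <- render_frame(spec, "array", bar_len = len)
    sm <- extract_size(fr, cfg)
    ct <- tile_centers()[tile_centers()$tile == tile, ]
    which.max(sm[gidx(ct$cx, cfg$dims$x), gidx(ct$cy, cfg$dims$y), ])
  }
  expect_equal(lvl_for(13, 60), lvl_for(7, 60))     # same bar, same level
  expect_gte(lvl_for(13, 120), lvl_for(13, 60))     # longer bar, never lower
})

test_that("salience has one local maximum per item and is local", {
  cfg <- test_cfg()
  count_maxima <- function(sal) {
    cnt <- 0
    for (i in 2:(nrow(sal) - 1)) for (j in 2:(ncol(sal) - 1)) {
      if (sal[i, j] > 0.3 &&
          sal[i, j] == max(sal[(i - 1):(i + 1), (j - 1):(j + 1)])) {
        cnt <- cnt + 1
      }
    }
    cnt
  }
  for (k in c(1, 4, 8)) {
    spec <- generate_array(3, if (k == 1) 4 else k, seed = 5)
    spec$items <- spec$items[seq_len(k), ]
    feats <- extract_features(render_frame(spec, "array"), cfg)
    expect_equal(count_maxima(feats$salience), k)
  }
  # deleting an item lowers salience only near its tile
  spec <- generate_array(3, 4, seed = 5)
  f_all <- extract_features(render_frame(spec, "array"), cfg)
  spec_del <- spec; spec_del$items <- spec$items[-2, ]
  f_del <- extract_features(render_frame(spec_del, "array"), cfg)
  diffmap <- abs(f_all$salience - f_del$salience)
  ct <- tile_centers()[tile_centers()$tile == spec$items$tile[2], ]
  far <- sqrt(outer((grid_points(cfg$dims$x) - ct$cx)^2,
                    (grid_points(cfg$dims$y) - ct$cy)^2, "+")) > 80
  expect_lt(max(diffmap[far]), 0.05 * max(diffmap))
})

test_that("feature responses are equivariant and independent", {
  cfg <- test_cfg()
  mk <- function(tile, color = "red", ori = 45) {
    spec <- generate_array(3, 4, seed = 3)
    spec$items <- data.frame(tile = tile, color = color, orientation = ori,
                             is_target = TRUE, stringsAsFactors = FALSE)
    extract_features(render_frame(spec, "array"), cfg)
  }
  # translating by one tile translates the responses by one tile
  fa <- mk(12); fb <- mk(13)
  ra <- item_response(fa, 12); rb <- item_response(fb, 13)
  expect_equal(ra$orientation, rb$orientation, tolerance = 0.12)
  expect_equal(ra$color, rb$color, tolerance = 0.12)
  # changing only the color leaves orientation and size responses unchanged
  f_red <- mk(13, "red"); f_blue <- mk(13, "blue")
  rr <- item_response(f_red, 13); rb2 <- item_response(f_blue, 13)
  expect_equal(rr$orientation, rb2$orientation, tolerance = 0.1)
  expect_equal(rr$size, rb2$size, tolerance = 0.1)
})
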