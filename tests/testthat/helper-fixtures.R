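# Shared fixtures: configurations and pre-extracted feature maps are built
# once per test run (feature extraction calibrates gains on first use).

test_cfg <- local({
  cfg <- NULL
  function() {
    if (is.null(cfg)) cfg <<- dnf_config()
    cfg
  }
})

# One conjunction array with rendered frame and extracted features.
test_scene <- local({
  sc <- NULL
  function() {
    if (is.null(sc)) {
      spec <- generate_array(3, 8, seed = 7)
      frame <- render_frame(spec, "array")
      feats <- extract_features(frame, test_cfg())
      sc <<- list(spec = spec, frame = frame, feats = feats)
    }
    sc
  }
})

# Grid index of a stimulus coordinate on the architecture grid.
gidx <- function(coord, dim) which.min(abs(grid_points(dim) - coord))

# Feature-map responses at an item's tile centre.
item_response <- function(feats, tile, cfg = test_cfg()) {
  ct <- tile_centers()[tile_centers()$tile == tile, ]
  ix <- gidx(ct$cx, cfg$dims$x)
  iy <- gidx(ct$cy, cfg$dims$y)
  list(color = feats$color[ix, iy, ],
       orientation = feats$orientation[ix, iy, ],
       size = feats$size[ix, iy, ],
       salience = feats$salience[ix, iy])
}

# A two-bump synthetic salience input at the given tile centres.
two_bump_salience <- function(cfg, c1 = c(170, 200), c2 = c(330, 200)) {
  outer(gauss_bump(cfg$dims$x, c1[1], 15), gauss_bump(cfg$dims$y, c1[2], 15)) +
    outer(gauss_bump(cfg$dims$x, c2[1], 15), gauss_bump(cfg$dims$y, c2[2], 15))
}

# Settle an attention state on a salience input with the ramped boost.
settle_selection <- function(cfg, salience, seed, ms = 400, bias = 0) {
  st <- attention_state(cfg, seed)
  for (i in seq_len(ms / 5)) {
    st <- step_attention(st, salience, bias_excite = bias, dt = 5,
                         selection_boost = 1.5 * min(1, i * 5 / 80))
  }
  st
}

# Internal helpers reachable both when sourcing R/ in development and when
# testing the installed namespace.
cc2d <- function(mask) {
  if (exists("count_components_2d", mode = "function")) {
    count_components_2d(mask)
  } else {
    getFromNamespace("count_components_2d", "dnfsearch")(mask)
  }
}

step_mem <- function(mem, inputs, dt) {
  if (exists("step_memory_maps", mode = "function")) {
    step_memory_maps(mem, inputs, dt)
  } else {
    getFromNamespace("step_memory_maps", "dnfsearch")(mem, inputs, dt)
  }
}

attention_run_ns <- function(arch, feats, ms, boost) {
  f <- if (exists("attention_run", mode = "function")) attention_run
       else getFromNamespace("attention_run", "dnfsearch")
  f(arch, feats, ms, boost)
}

store_cue_ns <- function(arch, profiles, cue_dims) {
  f <- if (exists("store_cue", mode = "function")) store_cue
       else getFromNamespace("store_cue", "dnfsearch")
  f(arch, profiles, cue_dims)
}
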