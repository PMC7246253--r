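# Task-level organization: Explore / Retain / Search task nodes with
# mutual inhibition, search-cue fields (I) and retain gates (I1), the
# scene (K/K1) and memory (J/J1) guidance pathways with the resting-level
# normalization rule, and the autonomous trial driver that sequences
# attentional selection, memory commitment, cue retention and guided
# search through condition-of-satisfaction / dissatisfaction events.

#' Assemble the full architecture
#'
#' @param config a [dnf_config()].
#' @param seed trial seed; every field/node RNG stream derives from it.
#' @return list of class `dnf_architecture`.
#' @export
architecture <- function(config, seed = 1) {
  fd <- feature_dims(config)
  fs <- config$fields
  lw <- c(color = config$feat_width_latch$hue,
          orientation = config$feat_width_latch$ori,
          size = config$feat_width_latch$size)
  cue_fields <- lapply(names(fd), function(nm)
    dnf_field(fd[[nm]], h = fs$cue$h, tau = fs$cue$tau, noise = fs$cue$noise,
              kernel = dnf_kernel(exc_amp = 5, exc_width = lw[[nm]]),
              regime = "sustained", name = paste0("cue_", nm),
              stream = rng_stream(derive_seed(seed, paste0("cue_", nm)))))
  names(cue_fields) <- names(fd)
  gate_fields <- lapply(names(fd), function(nm)
    dnf_field(fd[[nm]], h = fs$gate$h, tau = fs$gate$tau, noise = fs$gate$noise,
              name = paste0("gate_", nm),
              stream = rng_stream(derive_seed(seed, paste0("gate_", nm)))))
  names(gate_fields) <- names(fd)
  mknode <- function(nm) dnf_node(h = config$task$node_h, tau = 60,
                                  self_exc = config$task$node_self, name = nm,
                                  stream = rng_stream(derive_seed(seed, nm)))
  arch <- list(
    config = config, seed = seed,
    attention = attention_state(config, seed),
    memory = memory_maps(config, seed),
    match = match_network(config, seed),
    cue = cue_fields, gates = gate_fields,
    explore_node = mknode("explore"), retain_node = mknode("retain"),
    search_node = mknode("search"),
    guidance = NULL,            # cached (K1, J1) states for the current phase
    t_ms = 0,
    events = list(),
    feature_cache = new.env(parent = emptyenv())
  )
  class(arch) <- "dnf_architecture"
  arch
}

log_event <- function(arch, event, detail = NA_character_, x = NA, y = NA) {
  arch$events[[length(arch$events) + 1]] <-
    data.frame(t_ms = arch$t_ms, event = event, detail = detail,
               x = x, y = y, stringsAsFactors = FALSE)
  arch
}

#' Event log of a trial
#' @param arch a [architecture()] after running a trial.
#' @return data.frame of timestamped events.
#' @export
event_log <- function(arch) do.call(rbind, arch$events)

#' Write the event log as JSON lines
#' @param arch a run architecture.
#' @param path output file.
#' @export
write_event_log <- function(arch, path) {
  log <- event_log(arch)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(log)))
    writeLines(jsonlite::toJSON(as.list(log[i, ]), auto_unbox = TRUE), con)
  invisible(path)
}

# Features of a rendered segment, cached per trial.
segment_features <- function(arch, spec, content) {
  key <- content
  f <- arch$feature_cache[[key]]
  if (is.null(f)) {
    fr <- render_frame(spec, content)
    f <- extract_features(fr, arch$config)
    arch$feature_cache[[key]] <- f
  }
  f
}

blank_features <- function(config) {
  z <- matrix(0, config$vision$nx, config$vision$ny)
  zf <- function(n3) array(0, dim = c(config$vision$nx, config$vision$ny, n3))
  structure(list(color = zf(config$vision$nhue),
                 orientation = zf(config$vision$nori),
                 size = zf(config$vision$nsize), salience = z),
            class = "feature_maps")
}

# --- node bookkeeping -------------------------------------------------------

# Step the three task nodes under mutual inhibition with the given drives;
# precedence retain > search > explore is carried by the drive magnitudes.
step_task_nodes <- function(arch, drive_explore, drive_retain, drive_search,
                            dt) {
  mi <- arch$config$task$mutual_inh
  so <- function(n) sigmoid(n$u, n$beta) * (n$u > 0)
  e <- so(arch$explore_node); r <- so(arch$retain_node); s <- so(arch$search_node)
  arch$explore_node <- step_node(arch$explore_node,
                                 drive_explore - mi * (r + s), dt)
  arch$retain_node <- step_node(arch$retain_node, drive_retain - mi * 0, dt)
  arch$search_node <- step_node(arch$search_node,
                                drive_search - mi * r, dt)
  arch
}

# --- attention episodes -----------------------------------------------------

# Step the attention subsystem for `ms`, with boost profile and bias,
# advancing the architecture clock.
attention_run <- function(arch, feats, ms, boost, bias = 0, ramp_from = 0,
                          pin_cue_tile = FALSE) {
  cfg <- arch$config
  dt <- cfg$dt
  n <- max(1, round(ms / dt))
  ramp <- cfg$fields$selection$boost_ramp
  for (i in seq_len(n)) {
    b <- if (ramp_from >= 0 && boost > 0)
      boost * min(1, (ramp_from + i * dt) / ramp) else boost
    arch$attention <- step_attention(arch$attention, feats$salience,
                                     bias_excite = bias, dt = dt,
                                     selection_boost = b)
    if (pin_cue_tile) arch$attention$ior_trace <- pin_tile(arch, cue_tile())
    arch$t_ms <- arch$t_ms + dt
  }
  arch
}

# Keep the IOR trace saturated at a tile (instructed exclusion of the
# black-bordered cue tile during search).
pin_tile <- function(arch, tile) {
  cfg <- arch$config
  tc <- tile_centers()
  ct <- tc[tc$tile == tile, ]
  gx <- gauss_bump(cfg$dims$x, ct$cx, 20)
  gy <- gauss_bump(cfg$dims$y, ct$cy, 20)
  pmax(arch$attention$ior_trace, outer(gx, gy))
}

# Run a selection episode: ramped boost until a unique selection peak has
# been held for `select_hold_ms`. Returns the peak (zero rows on timeout).
run_selection_episode <- function(arch, feats, bias = 0, max_ms = 900,
                                  pin_cue_tile = FALSE) {
  cfg <- arch$config
  dt <- cfg$dt
  boost <- cfg$fields$selection$boost
  hold_needed <- cfg$task$select_hold_ms
  held <- 0
  t0 <- arch$t_ms
  ramp0 <- arch$t_ms
  stuck <- 0
  peak <- NULL
  while (arch$t_ms - t0 < max_ms) {
    arch <- attention_run(arch, feats, dt, boost, bias,
                          ramp_from = arch$t_ms - ramp0,
                          pin_cue_tile = pin_cue_tile)
    p <- selection_peak(arch$attention)
    # deadlocked competition (several items established): a graded deboost
    # lowers all peaks toward the reverse detection instability; the
    # weakest die first and the survivor resumes when the boost returns
    stuck <- if (nrow(p) > 1) stuck + dt else 0
    if (stuck > 120) {
      tdb <- arch$t_ms
      while (arch$t_ms - tdb < 300) {
        arch <- attention_run(arch, feats, dt, boost = -2.5, bias = bias,
                              ramp_from = -1, pin_cue_tile = pin_cue_tile)
        if (nrow(selection_peak(arch$attention)) <= 1) break
      }
      ramp0 <- arch$t_ms
      stuck <- 0
      next
    }
    if (nrow(p) == 1) {
      if (!is.null(peak) && abs(p$x - peak$x) < 25 && abs(p$y - peak$y) < 25) {
        held <- held + dt
      } else {
        held <- 0
      }
      peak <- p
      if (held >= hold_needed) {
        p <- attended_location(arch, feats, p)
        return(list(arch = arch, peak = p))
      }
    } else {
      held <- 0; peak <- NULL
    }
  }
  list(arch = arch, peak = p_empty())
}

# The attended location handed to the space/feature columns: centroid of
# the selection output weighted by the salience input, i.e. the overlap
# that actually drives the downstream projections. This reads out the
# attended item's position from a broad selection peak.
attended_location <- function(arch, feats, peak) {
  cfg <- arch$config
  sel <- arch$attention$selection
  w <- sigmoid(sel$u, sel$beta)
  w[sel$u <= 0] <- 0
  # the readout follows the salience landscape under and just around the
  # attended peak (half a tile): a peak sitting on the skirt of an item
  # still reads out the item's centre
  supra <- w > 0
  xs <- grid_points(cfg$dims$x); ys <- grid_points(cfg$dims$y)
  near_peak <- outer((xs - peak$x[1])^2, (ys - peak$y[1])^2, "+") <= 35^2
  w <- (supra | near_peak) * (feats$salience + 0.02)
  if (sum(w) <= 0) return(peak)
  xs <- grid_points(cfg$dims$x); ys <- grid_points(cfg$dims$y)
  imax <- arrayInd(which.max(w), dim(w))
  peak$x <- xs[imax[1]]
  peak$y <- ys[imax[2]]
  peak
}

p_empty <- function() {
  structure(data.frame(x = numeric(0), y = numeric(0),
                       activation = numeric(0), mass = numeric(0)),
            class = c("peak_set", "data.frame"))
}

# Release attention: deboost the selection field through the reverse
# detection instability until its peak is extinguished, then a short
# refractory pause.
release_attention <- function(arch, feats) {
  cfg <- arch$config
  t0 <- arch$t_ms
  repeat {
    arch <- attention_run(arch, feats, cfg$dt, boost = -10)
    if (nrow(selection_peak(arch$attention)) == 0) break
    if (arch$t_ms - t0 > 400) break
  }
  attention_run(arch, feats, cfg$task$refractory_ms, boost = 0, ramp_from = -1)
}

# --- cue retention ----------------------------------------------------------

# Store the attended feature profiles in the search-cue fields through the
# boosted retain gates.
store_cue <- function(arch, profiles, cue_dims, ms = NULL) {
  cfg <- arch$config
  dt <- cfg$dt
  ms <- ms %||% (cfg$task$retain_store_ms %||% 150)
  fs <- cfg$fields
  for (i in seq_len(max(1, round(ms / dt)))) {
    for (nm in names(arch$cue)) {
      gate_boost <- if (nm %in% cue_dims) fs$gate$boost else 0
      arch$gates[[nm]]$drive <- gate_boost
      g_in <- fs$gate$w_input * (profiles[[nm]] %||% 0)
      arch$gates[[nm]] <- step_field(arch$gates[[nm]], g_in, dt)
      g_out <- sigmoid(arch$gates[[nm]]$u, arch$gates[[nm]]$beta)
      g_out[arch$gates[[nm]]$u <= 0] <- 0
      arch$cue[[nm]] <- step_field(arch$cue[[nm]], fs$cue$w_input * g_out, dt)
    }
  }
  # gates close when the retain boost is withdrawn
  for (nm in names(arch$gates)) {
    arch$gates[[nm]]$drive <- 0
    arch$gates[[nm]]$u[] <- arch$gates[[nm]]$h
  }
  arch$t_ms <- arch$t_ms + ms
  arch
}

#' Current content of the search-cue fields
#'
#' @param arch a [architecture()].
#' @return named list of 1-D profiles (normalized thresholded output);
#'   dimensions without a sustained peak are absent.
#' @export
cue_profiles <- function(arch) {
  out <- list()
  for (nm in names(arch$cue)) {
    f <- arch$cue[[nm]]
    o <- sigmoid(f$u, f$beta)
    o[f$u <= 0] <- 0
    if (max(o) > 0.5) out[[nm]] <- o / max(o)
  }
  out
}

# --- guidance ---------------------------------------------------------------

#' Compute the top-down guidance bias for the spatial selection field
#'
#' Overlap fields combine sub-threshold input from the scene space/feature
#' maps (K) or the memory maps (J) with ridge input from the search-cue
#' fields; supra-threshold peaks mark items carrying a cued feature. The
#' peaks are projected into the 2-D spatial guidance fields. The scene
#' guidance field's resting level is down-regulated by each cued feature so
#' that with one cued feature full matches are guided, and with n cued
#' features items sharing at least n-1 of them are guided; the memory
#' guidance field is normalized to full matches only.
#'
#' @param arch a [architecture()] (cue stored).
#' @param feats the current segment's [extract_features()] maps.
#' @param settle_ms settling time per overlap field.
#' @return list with `bias` (the combined excitatory bias grid for the
#'   selection field), `k1`, `j1` (guidance field activations).
#' @export
compute_guidance <- function(arch, feats, settle_ms = 120) {
  cfg <- arch$config
  cues <- cue_profiles(arch)
  if (length(cues) == 0) {
    z <- matrix(0, cfg$vision$nx, cfg$vision$ny)
    return(list(bias = z, k1 = z, j1 = z))
  }
  md <- mem_dims(cfg)
  ov <- cfg$fields$overlap
  dt <- cfg$dt
  nsteps <- max(1, round(settle_ms / dt))
  n_cued <- length(cues)
  maps <- list(color = feats$color, orientation = feats$orientation,
               size = feats$size)

  spatial_overlap <- function(src_map, nm) {
    f <- dnf_field(md[[nm]], h = ov$h, tau = ov$tau, noise = 0,
                   kernel = dnf_kernel(exc_amp = ov$kernel$exc_amp,
                                       exc_width = ov$kernel$exc_width),
                   name = paste0("ov_", nm))
    inp <- ov$w_maps * pmin(src_map, 1) +
      ridge_input(cues[[nm]], md[[nm]], amp = ov$w_cue)
    for (i in seq_len(nsteps)) f <- step_field(f, inp, dt)
    out <- sigmoid(f$u, f$beta)
    out[f$u <= 0] <- 0
    apply(out, c(1, 2), max)
  }

  guide_field <- function(sum_overlaps, p) {
    h_eff <- p$h0 - p$per_cue_drop * n_cued
    f <- dnf_field(space_dims(cfg), h = h_eff, tau = p$tau, noise = 0,
                   kernel = dnf_kernel(exc_amp = p$kernel$exc_amp,
                                       exc_width = p$kernel$exc_width),
                   name = "guide")
    inp <- p$w_overlap * sum_overlaps
    for (i in seq_len(nsteps)) f <- step_field(f, inp, dt)
    out <- sigmoid(f$u, f$beta)
    out[f$u <= 0] <- 0
    out
  }

  k_sum <- 0
  for (nm in names(cues)) k_sum <- k_sum + spatial_overlap(maps[[nm]], nm)
  k1 <- guide_field(k_sum, cfg$fields$guidance_scene)

  j_sum <- 0
  for (nm in names(cues)) {
    fmem <- arch$memory$memory[[nm]]
    mo <- sigmoid(fmem$u, fmem$beta)
    mo[fmem$u <= 0] <- 0
    j_sum <- j_sum + spatial_overlap(mo, nm)
  }
  j1 <- guide_field(j_sum, cfg$fields$guidance_memory)

  at <- cfg$attention
  list(bias = at$w_guide * k1 + at$w_mem_guide * j1, k1 = k1, j1 = j1)
}

# --- explore ----------------------------------------------------------------

#' Run one exploration cycle (attend, bind, commit, verify)
#'
#' The default behavior of the architecture: an attentional selection is
#' made, the attended item's features are extracted through the scene
#' space/feature selection fields, committed to the memory maps, read back
#' through the memory selection fields, and verified by the match network;
#' the resulting condition of satisfaction releases attention, concluding
#' the cycle.
#'
#' @param arch a [architecture()].
#' @param feats current segment feature maps.
#' @param max_ms selection timeout (ms); an empty salience input idles.
#' @return list `(arch, committed, tile, outcome)`.
#' @export
run_explore_cycle <- function(arch, feats, max_ms = 700) {
  cfg <- arch$config
  if (max(feats$salience) < 0.3)
    return(list(arch = arch, committed = FALSE, tile = NA, outcome = "idle"))
  sel <- run_selection_episode(arch, feats, max_ms = max_ms)
  arch <- sel$arch
  if (nrow(sel$peak) != 1) {
    arch <- release_attention(arch, feats)
    return(list(arch = arch, committed = FALSE, tile = NA, outcome = "timeout"))
  }
  arch <- log_event(arch, "selection", "explore", sel$peak$x, sel$peak$y)

  prof <- extract_attended_features(arch$memory, feats, sel$peak)
  arch$memory <- attr(prof, "memory")
  if (max(unlist(prof)) < 0.5) {
    # an empty location was attended: nothing to bind or commit
    arch <- log_event(arch, "empty_selection", "explore")
    arch <- release_attention(arch, feats)
    return(list(arch = arch, committed = FALSE,
                tile = nearest_tile(sel$peak), outcome = "empty"))
  }
  arch$memory <- commit_item(arch$memory, sel$peak, prof)
  rec <- recall_at_location(arch$memory, sel$peak)
  arch$memory <- attr(rec, "memory")
  mt <- if (max(unlist(rec)) < 0.5) {
    # commitment failed to consolidate (capacity exceeded): no CoS
    list(outcome = "CoD", t_ms = 0, net = arch$match)
  } else {
    evaluate_match(arch$match, prof, rec)
  }
  arch$match <- mt$net
  # concurrent episodes: feature binding, memory consolidation and
  # verification all overlap; the attentional dwell advances by the binding
  # window while consolidation completes within the memory maps' own episode
  # and the verification's CoS arrives during the release
  bind_ms <- cfg$memory_commit$bind_ms %||% 120
  arch <- attention_run(arch, feats, bind_ms, boost = cfg$fields$selection$boost,
                        ramp_from = -1)
  arch <- log_event(arch, paste0("match_", mt$outcome), "explore")
  # a committed item leaves a full inhibition-of-return mark (the short
  # attentional dwell alone under-marks it)
  arch$attention$ior_trace <- pmax(arch$attention$ior_trace,
                                   0.9 * outer(
                                     gauss_bump(arch$config$dims$x, sel$peak$x, 25),
                                     gauss_bump(arch$config$dims$y, sel$peak$y, 25)))
  arch <- release_attention(arch, feats)
  tile <- nearest_tile(sel$peak)
  list(arch = arch, committed = mt$outcome == "CoS", tile = tile,
       outcome = mt$outcome)
}

#' Tile index nearest to a spatial peak
#' @param peak one-row `peak_set` or xy vector.
#' @export
nearest_tile <- function(peak) {
  if (is.data.frame(peak)) peak <- c(peak$x[1], peak$y[1])
  tc <- tile_centers()
  tc$tile[which.min((tc$cx - peak[1])^2 + (tc$cy - peak[2])^2)]
}

# --- retain -----------------------------------------------------------------

#' Retain the cue item's features in the search-cue fields
#'
#' Attention is drawn to the cue location (by the onset transient, or by the
#' instructed localized boost for the black-bordered cue tile when cue and
#' array appear simultaneously), the features at that location are
#' extracted, forwarded through the boosted retain gates into the sustained
#' search-cue fields, and the retention is verified against the attended
#' item by the match network; its condition of satisfaction ends the retain
#' state.
#'
#' @param arch a [architecture()].
#' @param feats feature maps of the cue-bearing segment.
#' @param cue_dims feature dimensions the task cues (color only in
#'   single-feature search).
#' @return list `(arch, stored, outcome)`.
#' @export
run_retain <- function(arch, feats, cue_dims = c("color", "orientation", "size")) {
  cfg <- arch$config
  tc <- tile_centers()
  ct <- tc[tc$tile == cue_tile(), ]
  bias <- 8 * outer(gauss_bump(cfg$dims$x, ct$cx, 15),
                    gauss_bump(cfg$dims$y, ct$cy, 15))
  sel <- run_selection_episode(arch, feats, bias = bias)
  arch <- sel$arch
  if (nrow(sel$peak) != 1 || nearest_tile(sel$peak) != cue_tile()) {
    # mis-selection: release and retry once (the instructed boost then
    # faces no competing established peak)
    arch <- release_attention(arch, feats)
    sel <- run_selection_episode(arch, feats, bias = bias)
    arch <- sel$arch
  }
  if (nrow(sel$peak) != 1 || nearest_tile(sel$peak) != cue_tile()) {
    arch <- log_event(arch, "retain_failed")
    return(list(arch = arch, stored = FALSE, outcome = "timeout"))
  }
  arch <- log_event(arch, "selection", "retain", sel$peak$x, sel$peak$y)
  prof <- extract_attended_features(arch$memory, feats, sel$peak)
  arch$memory <- attr(prof, "memory")
  arch <- store_cue(arch, prof, cue_dims)
  cues <- cue_profiles(arch)
  mt <- evaluate_match(arch$match, prof, cues)
  arch$match <- mt$net
  arch <- attention_run(arch, feats,
                        max(cfg$memory_commit$extract_ms, mt$t_ms),
                        boost = cfg$fields$selection$boost, ramp_from = -1)
  arch <- log_event(arch, paste0("retain_", mt$outcome))
  arch <- release_attention(arch, feats)
  list(arch = arch, stored = mt$outcome == "CoS", outcome = mt$outcome)
}

# --- search -----------------------------------------------------------------

#' Run the guided visual search until a match is found
#'
#' Repeated cycles of guided attentional selection and feature-match
#' evaluation: the condition of dissatisfaction rejects a mismatching item
#' (destabilizing the selection and leaving an inhibition-of-return trace on
#' it) and re-selects; the condition of satisfaction terminates the search.
#' The model reaction time is the model time elapsed from search initiation
#' to the CoS event.
#'
#' @param arch a [architecture()] with a stored cue and a visible array.
#' @param feats feature maps of the search-array segment.
#' @param max_rejections abort threshold (defaults to 3 x set size).
#' @param set_size used for the default abort threshold.
#' @return list `(arch, tile, rt_ms, rejections, aborted)`; `rt_ms` is model
#'   time from search start to match.
#' @export
run_search <- function(arch, feats, set_size = 18, max_rejections = NULL) {
  cfg <- arch$config
  max_rejections <- max_rejections %||%
    (cfg$task$max_rejections_factor * set_size)
  t_start <- arch$t_ms
  g <- compute_guidance(arch, feats)
  # instructed exclusion of the black-bordered cue tile: its item carries
  # the cued features by construction and must not be reported
  tc <- tile_centers()
  ct <- tc[tc$tile == cue_tile(), ]
  cue_inh <- 8 * outer(gauss_bump(cfg$dims$x, ct$cx, 20),
                       gauss_bump(cfg$dims$y, ct$cy, 20))
  g$bias <- g$bias - cue_inh
  arch <- log_event(arch, "search_start")
  rejections <- 0
  # accumulating within-trial suppression of rejected items: every
  # condition-of-dissatisfaction deepens the refractory inhibition at the
  # rejected location, so repeatedly rejected items cannot dominate
  rej_inh <- matrix(0, cfg$vision$nx, cfg$vision$ny)
  repeat {
    sel <- run_selection_episode(arch, feats, bias = g$bias - 4 * rej_inh,
                                 max_ms = 1500, pin_cue_tile = TRUE)
    arch <- sel$arch
    if (nrow(sel$peak) != 1) {
      # unresolved competition: release and re-enter the race
      arch <- release_attention(arch, feats)
      rejections <- rejections + 1
      if (rejections >= max_rejections) {
        arch <- log_event(arch, "search_timeout")
        return(list(arch = arch, tile = NA, rt_ms = NA,
                    rejections = rejections, aborted = TRUE))
      }
      next
    }
    arch <- log_event(arch, "selection", "search", sel$peak$x, sel$peak$y)
    ixy <- c(which.min(abs(grid_points(cfg$dims$x) - sel$peak$x)),
             which.min(abs(grid_points(cfg$dims$y) - sel$peak$y)))
    if (feats$salience[ixy[1], ixy[2]] < 0.3) {
      # an empty inter-item location was attended (skirt of suppressed
      # items): release without marking, so neighbours are not poisoned
      arch <- log_event(arch, "empty_selection", "search")
      arch <- release_attention(arch, feats)
      rejections <- rejections + 1
      if (rejections >= max_rejections) {
        arch <- log_event(arch, "search_aborted")
        return(list(arch = arch, tile = NA, rt_ms = NA,
                    rejections = rejections, aborted = TRUE))
      }
      next
    }
    prof <- extract_attended_features(arch$memory, feats, sel$peak)
    arch$memory <- attr(prof, "memory")
    mt <- evaluate_match(arch$match, prof, cue_profiles(arch))
    arch$match <- mt$net
    arch <- attention_run(arch, feats,
                          max(cfg$memory_commit$extract_ms, mt$t_ms),
                          boost = cfg$fields$selection$boost, ramp_from = -1,
                          pin_cue_tile = TRUE)
    arch <- log_event(arch, paste0("match_", mt$outcome),
                      sprintf("search p=%.2f/%.2f/%.2f at %.0f,%.0f",
                              max(prof$color), max(prof$orientation),
                              max(prof$size), sel$peak$x, sel$peak$y))
    if (mt$outcome == "CoS") {
      rt <- arch$t_ms - t_start
      return(list(arch = arch, tile = nearest_tile(sel$peak), rt_ms = rt,
                  rejections = rejections, aborted = FALSE))
    }
    # CoD (or pending): reject, leave a refractory IOR mark, re-select
    bump <- outer(gauss_bump(cfg$dims$x, sel$peak$x, 30),
                  gauss_bump(cfg$dims$y, sel$peak$y, 30))
    arch$attention$ior_trace <- pmax(arch$attention$ior_trace, 0.95 * bump)
    rej_inh <- rej_inh + bump
    arch <- release_attention(arch, feats)
    rejections <- rejections + 1
    if (rejections >= max_rejections) {
      arch <- log_event(arch, "search_aborted")
      return(list(arch = arch, tile = NA, rt_ms = NA,
                  rejections = rejections, aborted = TRUE))
    }
  }
}

# --- full trial -------------------------------------------------------------

#' Run one full trial through its presentation timeline
#'
#' Plays the trial's segments (blanks, preview, cue, search array) through
#' the architecture: exploration and memory commitment run autonomously
#' while an array is visible and no other task is active; the cue onset
#' triggers retention of the cue features; a stored cue plus a visible
#' array triggers the guided search, whose match terminates the trial.
#'
#' @param spec a [generate_array()] stimulus specification.
#' @param config a [dnf_config()].
#' @param seed trial seed.
#' @return a `trial_result` list: `condition`, `set_size`, `seed`,
#'   `rt_ms` (model reaction time from the condition's clock-start segment),
#'   `selected_tile`, `target_tile`, `correct`, `rejections`, `aborted`,
#'   `n_retained_at_search` (memory items when search began), and the
#'   architecture (for event-log inspection).
#' @export
run_trial <- function(spec, config = dnf_config(), seed = 1) {
  arch <- architecture(config, seed)
  tl <- trial_timeline(spec$experiment, spec$condition)
  rt_from <- attr(tl, "rt_from")
  cue_dims <- if (spec$condition == 1) "color" else
    c("color", "orientation", "size")
  clock0 <- NA
  res <- list(tile = NA, rt_ms = NA, rejections = 0, aborted = TRUE)
  n_retained <- NA

  for (seg in seq_len(nrow(tl))) {
    content <- tl$content[seg]
    dur <- tl$duration[seg]
    feats <- if (content == "blank") blank_features(config)
             else segment_features(arch, spec, content)
    if (seg > 1 && nrow(selection_peak(arch$attention)) > 0)
      arch <- release_attention(arch, feats)
    arch <- log_event(arch, "segment", content)
    if (content == rt_from) clock0 <- arch$t_ms
    seg_end <- arch$t_ms + dur

    if (content == "blank") {
      arch <- attention_run(arch, feats, dur, boost = 0)
    } else if (content == "preview") {
      # the array stays visible across the preview/search boundary, so an
      # exploration cycle in flight at the boundary completes while the cue
      # onset is still being detected
      while (arch$t_ms < seg_end) {
        step <- run_explore_cycle(arch, feats,
                                  max_ms = min(700, seg_end + 250 - arch$t_ms))
        arch <- step$arch
        if (step$outcome == "idle") {
          arch <- attention_run(arch, feats, seg_end - arch$t_ms, boost = 0)
        }
      }
    } else if (content == "cue") {
      ret <- run_retain(arch, feats, cue_dims)
      arch <- ret$arch
      if (arch$t_ms < seg_end)
        arch <- attention_run(arch, feats, seg_end - arch$t_ms, boost = 0)
    } else if (content %in% c("array_cue", "array")) {
      if (content == "array_cue" && length(cue_profiles(arch)) == 0) {
        ret <- run_retain(arch, feats, cue_dims)
        arch <- ret$arch
      }
      n_retained <- memory_item_count(arch$memory)
      if (length(cue_profiles(arch)) > 0) {
        res <- run_search(arch, feats, set_size = spec$set_size)
        arch <- res$arch
      }
      break
    }
    if (is.finite(seg_end) && arch$t_ms < seg_end)
      arch <- attention_run(arch, feats, seg_end - arch$t_ms, boost = 0)
  }

  target_tile <- spec$items$tile[spec$items$is_target]
  rt <- if (!res$aborted && !is.na(clock0)) arch$t_ms - clock0 else NA
  structure(list(
    experiment = spec$experiment, condition = spec$condition,
    set_size = spec$set_size, seed = seed,
    rt_ms = rt, selected_tile = res$tile, target_tile = target_tile,
    correct = !res$aborted && !is.na(res$tile) && res$tile == target_tile,
    rejections = res$rejections, aborted = res$aborted,
    n_retained_at_search = n_retained,
    arch = arch), class = "trial_result")
}
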