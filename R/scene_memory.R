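# Capacity-limited scene working memory: per feature dimension a
# three-dimensional scene space/feature selection field (E), a sustained
# memory space/feature map (F) whose accumulating global inhibition sets the
# capacity limit, and a memory space/feature selection field (G) that reads
# out the stored item at the attended location.

mem_dims <- function(config) {
  fd <- feature_dims(config)
  lapply(fd, function(d) list(config$dims$x, config$dims$y, d))
}

#' Construct the scene-memory maps
#'
#' One triple (selection E, memory F, memory selection G) per feature
#' dimension (color, orientation, size). The memory maps are in the
#' sustained-activation regime; the number of spatial locations they can
#' hold simultaneously is restricted by the accumulation of global
#' inhibition as peaks are added, and is calibrated to four items.
#'
#' @param config a [dnf_config()].
#' @param seed integer seed for the per-field RNG streams.
#' @return list of class `memory_maps` with elements `selection`, `memory`,
#'   `mem_selection`, each a named list over feature dimensions.
#' @export
memory_maps <- function(config, seed = 1) {
  md <- mem_dims(config)
  fs <- config$fields
  fw <- config$feat_width
  mk <- function(nm, d, p, extra_kernel = NULL) {
    kk <- p$kernel
    fwl <- config$feat_width_latch
    featw <- if (isTRUE(kk$latch))
      c(hue = fwl$hue, ori = fwl$ori, size = fwl$size)[[d[[3]]$name]]
    else c(hue = fw$hue, ori = fw$ori, size = fw$size)[[d[[3]]$name]]
    g <- kk$global_inh %||%
      (if (is.null(p$pool_ratio)) 0 else config$capacity_gain * p$pool_ratio)
    kern <- dnf_kernel(exc_amp = kk$exc_amp %||% 0,
                       exc_width = c(kk$exc_width, kk$exc_width, featw),
                       inh_amp = kk$inh_amp %||% 0,
                       inh_width = c(kk$inh_width %||% kk$exc_width,
                                     kk$inh_width %||% kk$exc_width, featw * 2),
                       global_inh = g)
    dnf_field(d, h = p$h, tau = p$tau, beta = p$beta %||% 4,
              noise = p$noise, kernel = kern,
              name = nm, stream = rng_stream(derive_seed(seed, nm)))
  }
  dims_names <- names(md)
  sel <- stats::setNames(lapply(dims_names, function(nm)
    mk(paste0("E_", nm), md[[nm]], fs$scene_selection)), dims_names)
  mem <- stats::setNames(lapply(dims_names, function(nm) {
    f <- mk(paste0("F_", nm), md[[nm]], fs$memory)
    f$regime <- "sustained"
    f$pool_external <- TRUE
    f
  }), dims_names)
  msel <- stats::setNames(lapply(dims_names, function(nm)
    mk(paste0("G_", nm), md[[nm]], fs$mem_selection)), dims_names)
  structure(list(selection = sel, memory = mem, mem_selection = msel,
                 config = config), class = "memory_maps")
}

#' Extract the attended item's feature values (scene route)
#'
#' The attended location provides a column input to the scene space/feature
#' selection fields; peaks form where the (sub-threshold) scene maps overlap
#' the column, and the resulting activation is integrated across space into
#' a one-dimensional activation profile per feature dimension. An empty
#' attended tile yields sub-threshold (empty) activations.
#'
#' @param memory a [memory_maps()].
#' @param scene_maps a [extract_features()] result (the scene space/feature
#'   maps).
#' @param attended one-row `peak_set` (or length-2 xy vector): the attended
#'   location.
#' @param settle_ms how long to relax the selection fields (ms).
#' @param dt Euler step (ms).
#' @return named list over feature dimensions of 1-D activation vectors
#'   (thresholded output integrated over space, unit peak height for a
#'   present feature).
#' @export
extract_attended_features <- function(memory, scene_maps, attended,
                                      settle_ms = NULL, dt = 5) {
  cfg <- memory$config
  p <- cfg$fields$scene_selection
  settle_ms <- settle_ms %||% cfg$memory_commit$extract_ms
  md <- mem_dims(cfg)
  maps <- list(color = scene_maps$color, orientation = scene_maps$orientation,
               size = scene_maps$size)
  out <- list()
  for (nm in names(md)) {
    f <- memory$selection[[nm]]
    f$u[] <- f$h
    f$inh_pool <- NULL
    col <- column_input(attended, md[[nm]], width = cfg$space_width,
                        amp = p$w_column)
    inp <- p$w_maps * pmin(maps[[nm]], 1) + col
    for (i in seq_len(max(1, round(settle_ms / dt))))
      f <- step_field(f, inp, dt)
    memory$selection[[nm]] <- f
    out[[nm]] <- feature_profile(f)
  }
  attr(out, "memory") <- memory
  out
}

# Marginalize a 3-D field's thresholded output over space into a 1-D
# feature profile normalized to unit peak height.
feature_profile <- function(field) {
  out <- sigmoid(field$u, field$beta)
  out[field$u <= 0] <- 0
  prof <- apply(out, 3, sum)
  if (max(prof) > 0) {
    prof <- prof / max(prof)
    prof <- prof^3  # sharpen: commits span a consistent 1-2 feature bins
  }
  prof
}

# Shared spatial inhibitory pool of the memory maps: each distinct spatial
# peak location (supra-threshold footprint pooled over the feature axis and
# across the three maps) contributes one unit of inhibition, so capacity is
# set by the number of stored items, not by their activation footprints,
# and is shared across the three maps.
memory_pool_target <- function(memory) {
  spat <- NULL
  for (nm in names(memory$memory)) {
    f <- memory$memory[[nm]]
    m <- apply(f$u, c(1, 2), max)
    spat <- if (is.null(spat)) m else pmax(spat, m)
  }
  count_components_2d(spat > 0) / 100
}

# Connected supra-threshold components of a 2-D mask (orthogonal adjacency).
count_components_2d <- function(mask) {
  idx <- which(mask)
  if (length(idx) == 0) return(0L)
  max(label_components(idx, dim(mask), c(FALSE, FALSE)))
}

# Advance all three memory maps one step under the shared spatial pool.
step_memory_maps <- function(memory, inputs, dt) {
  tgt <- memory_pool_target(memory)
  for (nm in names(memory$memory)) {
    f <- memory$memory[[nm]]
    v <- f$inh_pool %||% 0
    f$inh_pool <- v + (tgt - v) * min(1, dt / (f$kernel$global_tau %||% 25))
    memory$memory[[nm]] <- step_field(f, inputs[[nm]] %||% 0, dt)
  }
  memory
}

#' Commit the attended item to the memory space/feature maps
#'
#' The extracted feature profiles provide slice input, and the attended
#' location provides column input, to the sustained memory maps; a peak
#' forms at their intersection and persists after the inputs are removed.
#' Existing peaks for other items persist unless the capacity limit is
#' exceeded, in which case the incoming item fails to consolidate.
#'
#' @param memory a [memory_maps()].
#' @param attended one-row `peak_set` or xy vector.
#' @param feature_profiles result of [extract_attended_features()].
#' @param settle_ms commit episode duration (ms).
#' @param dt Euler step (ms).
#' @return the updated [memory_maps()].
#' @export
commit_item <- function(memory, attended, feature_profiles, settle_ms = NULL,
                        dt = 5) {
  cfg <- memory$config
  mc <- cfg$memory_commit
  settle_ms <- settle_ms %||% mc$settle_ms
  md <- mem_dims(cfg)
  n_on <- max(1, round(settle_ms / dt))
  n_off <- max(1, round((mc$release_ms %||% 100) / dt))
  inputs <- list()
  for (nm in names(md)) {
    # narrow column: only the attended centre cell reaches threshold, so a
    # stored item occupies a single well-defined spatial site
    col <- column_input(attended, md[[nm]], width = mc$col_width %||% 12,
                        amp = mc$w_column)
    inputs[[nm]] <- col + ridge_input(feature_profiles[[nm]], md[[nm]],
                                      amp = mc$w_ridge)
  }
  for (i in seq_len(n_on)) memory <- step_memory_maps(memory, inputs, dt)
  for (i in seq_len(n_off)) memory <- step_memory_maps(memory, list(), dt)
  memory
}

#' Recall the stored item at a location (memory route)
#'
#' The memory maps provide sub-threshold input to the memory space/feature
#' selection fields; combined with the attended column, an isolated
#' representation of the stored item at that location comes up, and its
#' feature profile is read out. An unstored location yields empty profiles.
#'
#' @inheritParams extract_attended_features
#' @return named list of 1-D feature activation vectors.
#' @export
recall_at_location <- function(memory, attended, settle_ms = NULL, dt = 5) {
  cfg <- memory$config
  p <- cfg$fields$mem_selection
  settle_ms <- settle_ms %||% cfg$memory_commit$extract_ms
  md <- mem_dims(cfg)
  out <- list()
  for (nm in names(md)) {
    f <- memory$mem_selection[[nm]]
    f$u[] <- f$h
    f$inh_pool <- NULL
    mem_out <- sigmoid(memory$memory[[nm]]$u, memory$memory[[nm]]$beta)
    mem_out[memory$memory[[nm]]$u <= 0] <- 0
    col <- column_input(attended, md[[nm]], width = cfg$space_width,
                        amp = p$w_column)
    inp <- p$w_maps * mem_out + col
    for (i in seq_len(max(1, round(settle_ms / dt))))
      f <- step_field(f, inp, dt)
    memory$mem_selection[[nm]] <- f
    out[[nm]] <- feature_profile(f)
  }
  attr(out, "memory") <- memory
  out
}

#' Spatial locations currently retained in the memory maps
#'
#' Marginalizes the memory maps' thresholded output over the feature
#' dimensions, sums the three maps, and returns the distinct spatial peak
#' locations.
#'
#' @param memory a [memory_maps()].
#' @return a `peak_set` over (x, y).
#' @export
memory_locations <- function(memory) {
  cfg <- memory$config
  acc <- 0
  for (nm in names(memory$memory)) {
    f <- memory$memory[[nm]]
    out <- sigmoid(f$u, f$beta)
    out[f$u <= 0] <- 0
    acc <- acc + apply(out, c(1, 2), max)
  }
  probe <- dnf_field(space_dims(cfg), h = -1, name = "memloc")
  probe$u <- array(acc - 0.5, dim = dim(probe$u))
  detect_peaks(probe)
}

#' Number of items retained in scene working memory
#' @param memory a [memory_maps()].
#' @export
memory_item_count <- function(memory) nrow(memory_locations(memory))

#' Export the retained items as a table
#'
#' One row per retained spatial location with the peak feature value per
#' dimension (hue and orientation in degrees, size as a level index).
#'
#' @param memory a [memory_maps()].
#' @param path optional TSV output path.
#' @return data.frame with columns `x`, `y`, `hue`, `ori`, `size`.
#' @export
memory_snapshot <- function(memory, path = NULL) {
  cfg <- memory$config
  locs <- memory_locations(memory)
  fd <- feature_dims(cfg)
  res <- locs[, c("x", "y"), drop = FALSE]
  for (nm in names(fd)) {
    pts <- grid_points(fd[[nm]])
    vals <- numeric(nrow(locs))
    f <- memory$memory[[nm]]
    for (r in seq_len(nrow(locs))) {
      ix <- which.min(abs(grid_points(cfg$dims$x) - locs$x[r]))
      iy <- which.min(abs(grid_points(cfg$dims$y) - locs$y[r]))
      vals[r] <- pts[which.max(f$u[ix, iy, ])]
    }
    res[[c(color = "hue", orientation = "ori", size = "size")[[nm]]]] <- vals
  }
  if (!is.null(path))
    utils::write.table(res, path, sep = "\t", row.names = FALSE, quote = FALSE)
  res
}
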