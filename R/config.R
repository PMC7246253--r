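#' Build the architecture configuration
#'
#' Collects every dynamic parameter of the architecture: grid resolutions,
#' per-field resting levels, time constants, interaction kernels, projection
#' gains, detector windows and the task-level settings. Values are the
#' package's calibrated defaults; any entry can be overridden via `...` using
#' nested lists, or loaded from a YAML file with [read_config()].
#'
#' Two resolutions are provided: `"standard"` (space sampled at one sample
#' per 10 stimulus pixels, 15-degree hue bins) and `"coarse"` (one sample per
#' 20 pixels, 30-degree hue bins), the desk-scale grid used for the
#' experiment simulations.
#'
#' @param resolution `"coarse"` (default) or `"standard"`.
#' @param ... named overrides merged into the configuration, e.g.
#'   `task = list(max_rejections_factor = 4)`.
#' @return a list of class `dnf_config`.
#' @export
dnf_config <- function(resolution = c("coarse", "standard"), ...) {
  resolution <- match.arg(resolution)
  std <- resolution == "standard"
  # spatial grids are chosen so that the 80-pixel tile centres of the
  # stimulus display fall exactly on grid points
  nx <- if (std) 53L else 27L
  ny <- if (std) 41L else 21L
  nhue <- if (std) 24L else 12L
  nori <- 8L
  nsize <- 5L

  dims <- list(
    x = dim_spec("x", c(-10, 510), nx),
    y = dim_spec("y", c(0, 400), ny),
    hue = dim_spec("hue", c(0, 360), nhue, circular = TRUE),
    ori = dim_spec("ori", c(0, 180), nori, circular = TRUE),
    size = dim_spec("size", c(1, 5), nsize)
  )

  cfg <- list(
    resolution = resolution,
    dt = 5, tau = 100,
    dims = dims,
    vision = list(
      nx = nx, ny = ny, nhue = nhue, nori = nori, nsize = nsize,
      sat_threshold = 0.2, ds_factor = 4L,
      ori_channels = c(0, 45, 90, 135),
      ori_sigma_long = 6, ori_sigma_short = 1.6, ori_tuning = 14,
      ori_cross = 1.2,
      size_sigmas = c(1.5, 3, 6, 12, 24), size_oneway = 0.5,
      gain_env = new.env(parent = emptyenv())
    ),
    # spatial widths in pixels; feature widths in degrees / size levels
    space_width = 22, feat_width = list(hue = 25, ori = 18, size = 0.8),
    # narrow per-dimension widths for the cell-local latch kernels of the
    # sustained fields (identity-like smoothing on each axis)
    feat_width_latch = list(hue = 8, ori = 6, size = 0.4),
    fields = list(
      salience = list(h = -5, tau = 80, noise = 0.02, w_input = 7,
                      kernel = list(exc_amp = 1.5, exc_width = 15)),
      selection = list(h = -5, tau = 60, beta = 1.5, noise = 0.05,
                       w_sal = 4.2, boost = 1.5, boost_ramp = 50,
                       quench_sd = 1.0, sal_mix = 0.5,
                       kernel = list(exc_amp = 80, exc_width = 30,
                                     inh_amp = 0, inh_width = 60,
                                     global_inh = 850)),
      # sustained (memory) fields use self-excitation at the sampling
      # width: activation latches cell-locally, so stored peaks neither
      # drift nor spread, and the capacity limit comes entirely from the
      # shared global-inhibition pool
      swm = list(h = -3.2, tau = 100, beta = 10, noise = 0.02, w_sel = 5.3,
                 pool_ratio = 4.6,
                 kernel = list(exc_amp = 7, exc_width = 6)),
      # the memory maps consolidate within their own episode, concurrently
      # with the next attentional selection
      memory = list(h = -3.2, tau = 100, beta = 10, noise = 0.02,
                    pool_ratio = 5,
                    kernel = list(exc_amp = 7, exc_width = 6, latch = TRUE)),
      scene_selection = list(h = -5, tau = 40, noise = 0.01, w_maps = 3,
                             w_column = 3.5,
                             kernel = list(exc_amp = 2, exc_width = 20)),
      mem_selection = list(h = -5, tau = 40, noise = 0.01, w_maps = 3,
                           w_column = 3.5,
                           kernel = list(exc_amp = 2, exc_width = 20)),
      cue = list(h = -3, tau = 60, noise = 0.01, w_input = 8,
                 kernel = list(exc_amp = 5, exc_width_deg = 20,
                               global_inh = 60)),
      gate = list(h = -7, tau = 60, noise = 0.01, w_input = 4, boost = 5),
      overlap = list(h = -5, tau = 60, noise = 0.01, w_maps = 3,
                     w_cue = 3.5, kernel = list(exc_amp = 2, exc_width = 14)),
      guidance_scene = list(h0 = -0.5, per_cue_drop = 1.4, w_overlap = 4,
                            tau = 60, noise = 0.01,
                            kernel = list(exc_amp = 1.5, exc_width = 14)),
      # per_cue_drop 3.2 normalizes the memory guidance to full matches
      # only: with n cued features, only items matching all n cross
      guidance_memory = list(h0 = -0.5, per_cue_drop = 3.6, w_overlap = 5,
                             tau = 60, noise = 0.01,
                             kernel = list(exc_amp = 1.5, exc_width = 14))
    ),
    # shared gain of the capacity-setting global inhibition of the memory
    # space/feature maps and the spatial working memory field; calibrated so
    # that a six-item commit sequence retains exactly four items
    capacity_gain = 13,
    transients = list(tau_fast = 40, tau_slow = 250, h = -5,
                      w_in = 9, w_slow = 9, window = 500, reset_mass = 300),
    ior = list(tau_build = 80, tau_decay = 20000, w = 5.5,
               reset_at_offset = FALSE),
    attention = list(w_onset = 2, w_swm = 1.5, w_guide = 3, w_mem_guide = 14,
                     input_clamp = 10),
    matching = list(tau = 40, w_att = 7, w_exp = 6, w_gate = 6,
                    tol = list(hue = 60, ori = 22.5, size = 1.2),
                    pd_thresh = 4, node_self = 4, w_cos = 4, w_cod = 6,
                    max_wait_tau = 12),
    memory_commit = list(w_ridge = 2.5, w_column = 2.5, col_width = 10,
                         settle_ms = 500,
                         release_ms = 100, extract_ms = 80, bind_ms = 30),
    task = list(node_self = 4, node_h = -2, mutual_inh = 6,
                cue_localization = "instructed", max_rejections_factor = 3,
                select_hold_ms = 15, refractory_ms = 10,
                retain_store_ms = 200,
                explore_timeout_ms = 1500, search_timeout_ms = 20000),
    experiment = list(set_sizes = c(4, 6, 8, 14, 18), trials_per_cell = 40,
                      rt_scale_gain = 1, rt_scale_offset = 0)
  )
  cfg <- modify_list_deep(cfg, list(...))
  class(cfg) <- "dnf_config"
  cfg
}

# Recursive modifyList that keeps nested defaults.
modify_list_deep <- function(base, upd) {
  for (nm in names(upd)) {
    if (is.list(upd[[nm]]) && is.list(base[[nm]]) && !is.null(names(upd[[nm]]))) {
      base[[nm]] <- modify_list_deep(base[[nm]], upd[[nm]])
    } else {
      base[[nm]] <- upd[[nm]]
    }
  }
  base
}

#' Read / write a configuration as structured text (YAML)
#'
#' Field and kernel parameters are keyed by field name; the file stores only
#' overrides relative to the defaults of [dnf_config()].
#'
#' @param path YAML file path.
#' @param resolution base resolution the overrides apply to.
#' @export
read_config <- function(path, resolution = "coarse") {
  ov <- yaml::read_yaml(path)
  do.call(dnf_config, c(list(resolution = resolution), ov))
}

#' @rdname read_config
#' @param overrides named nested list of overrides to store.
#' @export
write_config <- function(overrides, path) {
  yaml::write_yaml(overrides, path)
  invisible(path)
}

# Spatial dim pair helper.
space_dims <- function(config) list(config$dims$x, config$dims$y)

# The three feature dimensions, keyed by map name.
feature_dims <- function(config) {
  list(color = config$dims$hue, orientation = config$dims$ori,
       size = config$dims$size)
}
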