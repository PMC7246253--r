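# Attentional selection subsystem: scene spatial salience field (C), scene
# spatial selection field (D, winner-take-all), inhibition-of-return memory
# trace (D2), spatial working memory field (D1, sustained and
# capacity-limited), and the two-layer onset (D3) and offset (D4) transient
# detectors.

# A two-layer transient detector: a fast layer that fires and a slow layer
# that tracks the input and shuts the fast layer down, so tonic input shifts
# produce only a transient supra-threshold response.
transient_detector <- function(config, kind = c("onset", "offset"),
                               name = kind, seed = 0) {
  kind <- match.arg(kind)
  tr <- config$transients
  sd2 <- space_dims(config)
  list(kind = kind,
       fast = dnf_field(sd2, h = tr$h, tau = tr$tau_fast, noise = 0,
                        name = paste0(name, "_fast"),
                        stream = rng_stream(derive_seed(seed, paste0(name, "f")))),
       slow = dnf_field(sd2, h = tr$h, tau = tr$tau_slow, noise = 0,
                        name = paste0(name, "_slow"),
                        stream = rng_stream(derive_seed(seed, paste0(name, "s")))))
}

# Advance a transient detector one step for the current input grid.
step_transient <- function(det, input, config, dt) {
  tr <- config$transients
  sv <- sigmoid(det$slow$u, det$slow$beta)
  drive <- if (det$kind == "onset") {
    tr$w_in * input - tr$w_slow * sv
  } else {
    tr$w_slow * sv - tr$w_in * input
  }
  det$fast <- step_field(det$fast, drive, dt)
  det$slow <- step_field(det$slow, tr$w_in * input, dt)
  det
}

transient_output <- function(det) {
  out <- sigmoid(det$fast$u, det$fast$beta)
  out[det$fast$u <= 0] <- 0
  out
}

#' Construct the attentional selection state
#'
#' Builds the salience field (detection regime, multi-peak), the spatial
#' selection field (selection regime: at most one peak), the
#' inhibition-of-return memory trace, the sustained spatial working memory
#' field whose global inhibition sets its capacity, and the onset and offset
#' transient detectors.
#'
#' @param config a [dnf_config()].
#' @param seed integer seed from which all per-field RNG streams derive.
#' @return list of class `attention_state`.
#' @export
attention_state <- function(config, seed = 1) {
  sd2 <- space_dims(config)
  fs <- config$fields
  mk_kernel <- function(k, pool_ratio = NULL) dnf_kernel(
    exc_amp = k$exc_amp %||% 0, exc_width = k$exc_width %||% 1,
    inh_amp = k$inh_amp %||% 0, inh_width = k$inh_width %||% (k$exc_width %||% 1),
    global_inh = k$global_inh %||%
      (if (is.null(pool_ratio)) 0 else config$capacity_gain * pool_ratio))
  st <- list(
    salience = dnf_field(sd2, h = fs$salience$h, tau = fs$salience$tau,
                         noise = fs$salience$noise,
                         kernel = mk_kernel(fs$salience$kernel),
                         regime = "detection", name = "salience",
                         stream = rng_stream(derive_seed(seed, "salience"))),
    selection = dnf_field(sd2, h = fs$selection$h, tau = fs$selection$tau,
                          beta = fs$selection$beta %||% 4,
                          noise = fs$selection$noise,
                          kernel = mk_kernel(fs$selection$kernel),
                          regime = "selection", name = "selection",
                          stream = rng_stream(derive_seed(seed, "selection"))),
    swm = {
      f <- dnf_field(sd2, h = fs$swm$h, tau = fs$swm$tau,
                     beta = fs$swm$beta %||% 4, noise = fs$swm$noise,
                     kernel = mk_kernel(fs$swm$kernel, fs$swm$pool_ratio),
                     regime = "sustained", name = "swm",
                     stream = rng_stream(derive_seed(seed, "swm")))
      f$pool_external <- TRUE
      f
    },
    ior_trace = matrix(0, config$vision$nx, config$vision$ny),
    onset = transient_detector(config, "onset", seed = seed),
    offset = transient_detector(config, "offset", seed = seed),
    config = config)
  # quenched per-trial spatial noise: a frozen realization that staggers
  # threshold crossings so equal inputs are resolved by noise, never by
  # index order
  q <- matrix(stream_rnorm(st$selection$stream,
                           config$vision$nx * config$vision$ny),
              config$vision$nx, config$vision$ny)
  q <- smooth_axis(q, gauss_matrix(config$dims$x, 15), 1)
  q <- smooth_axis(q, gauss_matrix(config$dims$y, 15), 2)
  q <- q / stats::sd(q)
  q[q > 2] <- 2; q[q < -2] <- -2   # bound the per-site bias
  if (isTRUE(fs$selection$quench_flip)) q <- -q
  st$quench <- (fs$selection$quench_rel %||% 0.23) * q
  class(st) <- "attention_state"
  st
}


salience_input_norm <- function(s) pmin(s, 1.5)

# Cached smoothing matrices for the salience -> selection projection.
sal_sm_cache <- new.env(parent = emptyenv())
sal_sm <- function(cfg, axis) {
  key <- paste0(cfg$resolution, "_", axis)
  m <- sal_sm_cache[[key]]
  if (is.null(m)) {
    d <- if (axis == 1) cfg$dims$x else cfg$dims$y
    m <- gauss_matrix(d, 15)
    sal_sm_cache[[key]] <- m
  }
  m
}

#' Advance the attention subsystem one time step
#'
#' The selection field receives the salience field's output plus excitatory
#' biases (top-down guidance, onset transients) minus inhibitory biases (the
#' inhibition-of-return trace and spatial working memory); at steady state it
#' carries at most one supra-threshold peak. The SWM field receives input
#' from the selection peak, and is globally deboosted (reset) whenever the
#' offset detector signals that salient input vanished or moved.
#'
#' @param state an [attention_state()].
#' @param salience_input nx x ny non-negative grid (see [salience_input()]).
#' @param bias_excite optional excitatory bias grid for the selection field
#'   (guidance input).
#' @param dt time step (ms).
#' @param selection_boost homogeneous drive on the selection field (the task
#'   node's boost; ramped by the caller).
#' @param swm_gate logical; when `FALSE` the SWM field receives no new input
#'   (used outside attention episodes).
#' @return the updated state.
#' @export
step_attention <- function(state, salience_input, bias_excite = 0, dt = 5,
                           selection_boost = 0, swm_gate = TRUE) {
  cfg <- state$config
  fs <- cfg$fields
  at <- cfg$attention

  state$salience <- step_field(state$salience,
                               fs$salience$w_input * salience_input, dt)
  state$onset <- step_transient(state$onset, salience_input, cfg, dt)
  state$offset <- step_transient(state$offset, salience_input, cfg, dt)

  off_out <- transient_output(state$offset)
  state <- apply_offset_reset(state, off_out)
  # vanishing or moving input also destabilizes the current attentional
  # selection (the stale peak cannot persist without bottom-up support)
  if (state$swm$drive < 0) selection_boost <- selection_boost - 8

  # graded salience drive: mixture of the stabilized salience-field output
  # and the raw conspicuity input, so the selection race is resolved by
  # salience differences and noise rather than by saturated equal drives
  mix <- fs$selection$sal_mix %||% 0.5
  sal_out <- (1 - mix) * sigmoid(state$salience$u, state$salience$beta) +
    mix * salience_input_norm(salience_input)
  # the bottom-up drive saturates (so simultaneous-onset bursts cannot
  # ignite the whole field) before the top-down guidance biases are added:
  # guidance from working memory must be able to outweigh bottom-up ties
  bottom_up <- pmin(fs$selection$w_sal * sal_out +
                      at$w_onset * transient_output(state$onset),
                    at$input_clamp %||% 10)
  excit <- bottom_up + bias_excite
  # multiplicative quenched noise: tie-breaking fluctuations scale with the
  # drive, so equal inputs are resolved by noise while empty regions of the
  # field stay quiet
  excit <- excit * pmax(0, 1 + state$quench)
  sel_in <- excit -
    cfg$ior$w * state$ior_trace -
    at$w_swm * sigmoid(state$swm$u, state$swm$beta)
  state$selection$drive <- selection_boost
  state$selection <- step_field(state$selection, sel_in, dt)

  sel_out <- sigmoid(state$selection$u, state$selection$beta)
  sel_out[state$selection$u <= 0] <- 0
  swm_in <- if (swm_gate) fs$swm$w_sel * sel_out else 0
  # per-peak (count-based) capacity pool, like the memory maps
  tgt <- count_components_2d(state$swm$u > 0) / 100
  v <- state$swm$inh_pool %||% 0
  state$swm$inh_pool <- v +
    (tgt - v) * min(1, dt / (state$swm$kernel$global_tau %||% 25))
  state$swm <- step_field(state$swm, swm_in, dt)

  # the trace reflects settled attentional selections: it builds only while
  # the selection field carries a single supra-threshold peak (not during
  # the transient competition phase), and only around the peak's centre,
  # so neighbouring items covered by the peak's skirt are not marked
  if (count_components_2d(state$selection$u > 0) == 1) {
    imax <- arrayInd(which.max(sel_out), dim(sel_out))
    xs <- grid_points(cfg$dims$x); ys <- grid_points(cfg$dims$y)
    near <- outer((xs - xs[imax[1]])^2, (ys - ys[imax[2]])^2, "+") <= 30^2
    state$ior_trace <- update_ior_trace(state$ior_trace, sel_out * near, dt, cfg)
  } else {
    state$ior_trace <- update_ior_trace(state$ior_trace, sel_out * 0, dt, cfg)
  }
  state
}

# Global SWM deboost while the offset detector carries a supra-threshold
# transient; optionally also clears the IOR trace (config switch).
apply_offset_reset <- function(state, off_out) {
  cfg <- state$config
  if (sum(off_out) * grid_step(cfg$dims$x) * grid_step(cfg$dims$y) >
      cfg$transients$reset_mass %||% 200) {
    state$swm$drive <- -10
    if (isTRUE(cfg$ior$reset_at_offset)) state$ior_trace[] <- 0
  } else {
    state$swm$drive <- 0
  }
  state
}

#' Update the inhibition-of-return memory trace
#'
#' The trace rises toward 1 where the selection field is supra-threshold
#' (build time constant `ior$tau_build`) and decays slowly elsewhere
#' (`ior$tau_decay`), reflecting the recent history of attentional
#' selections.
#'
#' @param trace current trace grid in [0, 1].
#' @param selection_output thresholded selection-field output grid.
#' @param dt time step (ms).
#' @param config a [dnf_config()].
#' @return updated trace grid.
#' @export
update_ior_trace <- function(trace, selection_output, dt, config) {
  on <- selection_output > 0.5
  trace[on] <- trace[on] + (1 - trace[on]) * dt / config$ior$tau_build
  trace[!on] <- trace[!on] * (1 - dt / config$ior$tau_decay)
  trace
}

#' Onset-detector response to a salience input (stand-alone)
#'
#' Steps a fresh onset detector through a constant-then-step input sequence;
#' exposed for direct use and testing. Most callers use [step_attention()],
#' which advances the embedded detectors.
#'
#' @param detector a detector from [attention_state()] (`$onset`).
#' @param salience_input current input grid.
#' @param config a [dnf_config()].
#' @param dt time step.
#' @return list `(detector, output)` with the transient output grid.
#' @export
detect_onset <- function(detector, salience_input, config, dt = 5) {
  detector <- step_transient(detector, salience_input, config, dt)
  list(detector = detector, output = transient_output(detector))
}

#' Offset-detector step with SWM reset
#'
#' Advances the offset detector and applies the global SWM deboost when the
#' disappearance (or displacement) of salient input produces a transient:
#' all SWM peaks are extinguished within the transient window. The memory
#' space/feature maps are not connected to this reset.
#'
#' @param detector the offset detector (`$offset` of an [attention_state()]).
#' @param salience_input current input grid.
#' @param swm the SWM [dnf_field()].
#' @param config a [dnf_config()].
#' @param dt time step.
#' @return list `(detector, output, swm)`.
#' @export
detect_offset_and_reset_swm <- function(detector, salience_input, swm, config,
                                        dt = 5) {
  detector <- step_transient(detector, salience_input, config, dt)
  out <- transient_output(detector)
  if (sum(out) * grid_step(config$dims$x) * grid_step(config$dims$y) >
      config$transients$reset_mass %||% 200) {
    swm$drive <- -10
  } else {
    swm$drive <- 0
  }
  swm <- step_field(swm, 0, dt)
  list(detector = detector, output = out, swm = swm)
}

#' Current selection peak (at most one)
#' @param state an [attention_state()].
#' @return a `peak_set` with zero or one row.
#' @export
selection_peak <- function(state) detect_peaks(state$selection)
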