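# Match/mismatch detection sub-network: per feature dimension an attended
# field, an expected field and a mismatch detection field, with peak
# detector nodes; a condition-of-satisfaction (CoS) node that fires only
# when every cued dimension matches, and a condition-of-dissatisfaction
# (CoD) node for which a single mismatching dimension is sufficient.

#' Construct the match-detection network
#'
#' @param config a [dnf_config()].
#' @param seed integer seed for the per-field RNG streams.
#' @return list of class `match_network`: per feature dimension the three
#'   1-D fields and peak-detector nodes, plus the CoS and CoD nodes.
#' @export
match_network <- function(config, seed = 1) {
  m <- config$matching
  fd <- feature_dims(config)
  mkf <- function(nm, d) dnf_field(d, h = -5, tau = m$tau, noise = 0,
                                   name = nm,
                                   stream = rng_stream(derive_seed(seed, nm)))
  mkn <- function(nm) dnf_node(h = -2.5, tau = max(25, m$tau / 2), self_exc = 1,
                               name = nm,
                               stream = rng_stream(derive_seed(seed, nm)))
  per_dim <- lapply(names(fd), function(nm) {
    list(attended = mkf(paste0("att_", nm), fd[[nm]]),
         expected = mkf(paste0("exp_", nm), fd[[nm]]),
         mismatch = mkf(paste0("mm_", nm), fd[[nm]]),
         pd_att = mkn(paste0("pd_att_", nm)),
         pd_exp = mkn(paste0("pd_exp_", nm)),
         pd_mm = mkn(paste0("pd_mm_", nm)))
  })
  names(per_dim) <- names(fd)
  structure(list(dims = per_dim,
                 cos = dnf_node(h = -2, tau = m$tau, self_exc = m$node_self,
                                name = "cos",
                                stream = rng_stream(derive_seed(seed, "cos"))),
                 cod = dnf_node(h = -2, tau = max(25, m$tau / 2), self_exc = m$node_self,
                                name = "cod",
                                stream = rng_stream(derive_seed(seed, "cod"))),
                 config = config),
            class = "match_network")
}

# Supra-threshold output sum of a 1-D field (resolution-light peak signal).
supra_sum <- function(field) {
  out <- sigmoid(field$u, field$beta)
  out[field$u <= 0] <- 0
  sum(out)
}

#' Evaluate the match between attended and expected feature values
#'
#' Runs the match sub-network's dynamics for the given 1-D activation
#' profiles. Dimensions without an expected peak are unspecified and are
#' not compared. Each specified dimension's mismatch field receives
#' excitatory input from the attended field and broad inhibitory
#' (inverted-overlap) input from the expected field, calibrated so that
#' co-located peaks cancel; a peak forms exactly when the attended and
#' expected values are metrically distinct. The CoD fires if any mismatch
#' peak forms; the CoS fires only when every specified dimension carries
#' attended and expected peaks and no mismatch peak.
#'
#' @param net a [match_network()].
#' @param attended named list (over feature dimensions) of 1-D activation
#'   profiles of the attended item.
#' @param expected named list of 1-D cue profiles; entries that are `NULL`
#'   or entirely (near-)zero are unspecified dimensions.
#' @param dt Euler step (ms).
#' @param max_ms maximum settling time before `"pending"` is returned.
#' @return list with `outcome` (`"CoS"`, `"CoD"` or `"pending"`), `t_ms`
#'   (model time used), and the updated network `net`.
#' @export
evaluate_match <- function(net, attended, expected, dt = 5, max_ms = NULL) {
  cfg <- net$config
  m <- cfg$matching
  max_ms <- max_ms %||% (m$max_wait_tau * m$tau)
  fd <- feature_dims(cfg)
  tolw <- c(color = m$tol$hue, orientation = m$tol$ori, size = m$tol$size)

  specified <- names(fd)[vapply(names(fd), function(nm) {
    e <- expected[[nm]]
    !is.null(e) && max(e) > 0.1
  }, logical(1))]
  if (length(specified) == 0)
    stop("the cue must specify at least one feature dimension")

  # reset transient state
  for (nm in names(net$dims)) {
    for (k in c("attended", "expected", "mismatch"))
      net$dims[[nm]][[k]]$u[] <- net$dims[[nm]][[k]]$h
    for (k in c("pd_att", "pd_exp", "pd_mm"))
      net$dims[[nm]][[k]]$u <- net$dims[[nm]][[k]]$h
  }
  net$cos$u <- net$cos$h
  net$cod$u <- net$cod$h

  # broadening width calibrated per dimension so the CoS/CoD crossover of
  # the mismatch drive sits at the configured tolerance offset (the factor
  # compensates the finite width of the attended/expected peaks)
  tolfac <- c(color = 0.45, orientation = 0.68, size = 0.68)
  smooth_tol <- lapply(names(fd), function(nm)
    gauss_matrix(fd[[nm]], tolfac[[nm]] * tolw[[nm]]))
  names(smooth_tol) <- names(fd)

  t_ms <- 0
  outcome <- "pending"
  while (t_ms < max_ms) {
    n_match <- 0
    any_mm <- 0
    for (nm in specified) {
      dm <- net$dims[[nm]]
      a_in <- m$w_att * (attended[[nm]] %||% 0)
      e_in <- m$w_att * expected[[nm]]
      dm$attended <- step_field(dm$attended, a_in, dt)
      dm$expected <- step_field(dm$expected, e_in, dt)

      a_out <- sigmoid(dm$attended$u, dm$attended$beta)
      a_out[dm$attended$u <= 0] <- 0
      e_out <- sigmoid(dm$expected$u, dm$expected$beta)
      e_out[dm$expected$u <= 0] <- 0

      # mismatch drive: attended excitation minus broadened expected
      # inhibition; gated off unless the expected field carries a peak
      e_broad <- as.vector(smooth_tol[[nm]] %*% e_out)
      if (max(e_broad) > 0) e_broad <- e_broad / max(e_broad)
      gate <- sigmoid(dm$pd_exp$u, dm$pd_exp$beta)
      mm_in <- m$w_att * a_out - m$w_exp * e_broad - m$w_gate * (1 - gate)
      dm$mismatch <- step_field(dm$mismatch, mm_in, dt)

      dm$pd_att <- step_node(dm$pd_att, m$pd_thresh * min(1, supra_sum(dm$attended)), dt)
      dm$pd_exp <- step_node(dm$pd_exp, m$pd_thresh * min(1, supra_sum(dm$expected)), dt)
      dm$pd_mm <- step_node(dm$pd_mm, m$pd_thresh * min(1, supra_sum(dm$mismatch)), dt)

      net$dims[[nm]] <- dm
      match_d <- node_on(dm$pd_att) && node_on(dm$pd_exp) && !node_on(dm$pd_mm)
      n_match <- n_match + match_d
      # a cued feature that is absent at the attended location (no attended
      # peak well after the fields have settled) is a mismatch
      absent <- t_ms > 250 && node_on(dm$pd_exp) && !node_on(dm$pd_att)
      any_mm <- any_mm + (node_on(dm$pd_mm) || absent)
    }
    # CoS: all specified dimensions match; resting level adapts to the
    # number of cued dimensions (same normalization idea as the guidance
    # fields). CoD: a single mismatch suffices; mutual inhibition keeps the
    # two nodes exclusive.
    cos_in <- m$w_cos * (n_match - length(specified) + 0.5) -
      8 * sigmoid(net$cod$u, net$cod$beta)
    cod_in <- m$w_cod * (any_mm - 0.5) - 8 * sigmoid(net$cos$u, net$cos$beta)
    net$cos <- step_node(net$cos, cos_in, dt)
    net$cod <- step_node(net$cod, cod_in, dt)
    t_ms <- t_ms + dt

    if (node_on(net$cos) && node_on(net$cod))
      stop("invariant violation: CoS and CoD simultaneously active")
    if (t_ms > 10 * dt) {
      if (node_on(net$cod)) { outcome <- "CoD"; break }
      if (node_on(net$cos)) { outcome <- "CoS"; break }
    }
  }
  list(outcome = outcome, t_ms = t_ms, net = net)
}

#' Build a 1-D feature profile for a nominal feature value
#'
#' Convenience for tests and cue construction: a unit-height Gaussian bump
#' at the given value on the named feature axis.
#'
#' @param config a [dnf_config()].
#' @param dim_name `"color"`, `"orientation"` or `"size"`.
#' @param value hue or orientation in degrees, or size level.
#' @param width bump width (defaults to the configured smoothing width).
#' @export
feature_bump <- function(config, dim_name, value, width = NULL) {
  fd <- feature_dims(config)[[dim_name]]
  w <- width %||% c(color = config$feat_width$hue,
                    orientation = config$feat_width$ori,
                    size = config$feat_width$size)[[dim_name]]
  gauss_bump(fd, value, w)
}
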