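# Experiment harness: run the preview / conjunction-search experiments
# through the full architecture, collect model reaction times, fit set-size
# slopes, and calibrate the working-memory capacity.

#' Run a simulated search experiment
#'
#' For every set size and trial, generates a search array, plays the
#' condition's presentation timeline through the architecture, and records
#' the model reaction time (model time from the condition's clock-start
#' segment to the match event). Aborted trials are excluded from the slope
#' fit and reported.
#'
#' @param experiment 1 or 2.
#' @param condition 1, 2 or 3 (experiment 2 simulates condition 2; its
#'   conditions 1 and 3 are identical to experiment 1's and are not re-run).
#' @param set_sizes integer vector (default the experiment's 4, 6, 8, 14, 18).
#' @param trials_per_cell trials per set size.
#' @param seed master seed; trial seeds derive from it.
#' @param config a [dnf_config()].
#' @param verbose print per-trial progress.
#' @return list of class `experiment_result`: `trials` (one row per trial),
#'   `means` (per-set-size mean/sem of RT), `fit` (slope, intercept),
#'   `condition`, `experiment`.
#' @export
run_experiment <- function(experiment, condition, set_sizes = NULL,
                           trials_per_cell = NULL, seed = 1,
                           config = dnf_config(), verbose = FALSE) {
  set_sizes <- set_sizes %||% config$experiment$set_sizes
  trials_per_cell <- trials_per_cell %||% config$experiment$trials_per_cell
  rows <- list()
  for (s in set_sizes) {
    for (k in seq_len(trials_per_cell)) {
      # arrays and trial noise streams depend on set size and trial index
      # only, so conditions (and experiments) are compared on the same
      # stimuli under the same noise realizations: condition contrasts are
      # fully paired. Trials additionally come in antithetic pairs: every
      # second trial reruns the previous trial's seed with the frozen
      # selection noise negated, which reverses the examination order and
      # cancels most of the serial-position variance from cell means.
      kk <- ceiling(k / 2)
      flip <- k %% 2 == 0
      aseed <- derive_seed(seed, sprintf("s%dk%d", s, kk))
      tseed <- derive_seed(seed, sprintf("t_s%dk%d", s, kk))
      spec <- generate_array(condition, s, seed = aseed,
                             experiment = experiment)
      cfg_k <- if (flip) {
        cf <- modify_list_deep(config,
                               list(fields = list(selection = list(quench_flip = TRUE))))
        class(cf) <- "dnf_config"
        cf$vision$gain_env <- config$vision$gain_env
        cf
      } else config
      res <- run_trial(spec, cfg_k, seed = tseed)
      rows[[length(rows) + 1]] <- data.frame(
        experiment = experiment, condition = condition, set_size = s,
        seed = tseed, rt_ms = res$rt_ms,
        correct = res$correct, rejections = res$rejections,
        aborted = res$aborted,
        n_retained_at_search = res$n_retained_at_search)
      if (verbose)
        message(sprintf("cond %d s=%2d trial %2d: rt=%s correct=%s",
                        condition, s, k,
                        format(res$rt_ms), format(res$correct)))
    }
  }
  trials <- do.call(rbind, rows)
  structure(c(list(trials = trials), summarize_experiment(trials),
              list(condition = condition, experiment = experiment)),
            class = "experiment_result")
}

# Per-set-size means (correct, non-aborted trials) and the OLS slope fit.
summarize_experiment <- function(trials) {
  ok <- trials[!trials$aborted & trials$correct, ]
  means <- do.call(rbind, lapply(split(ok, ok$set_size), function(d)
    data.frame(set_size = d$set_size[1], n = nrow(d),
               mean_rt = mean(d$rt_ms),
               sem_rt = stats::sd(d$rt_ms) / sqrt(nrow(d)))))
  rownames(means) <- NULL
  fit <- if (nrow(means) >= 2) ols_slope(means$set_size, means$mean_rt)
         else list(slope = NA, intercept = NA)
  list(means = means, fit = fit,
       error_rate = mean(!trials$correct),
       abort_rate = mean(trials$aborted))
}

#' Standard error of an experiment's fitted slope
#'
#' Residual-based OLS standard error from the per-trial regression of model
#' RT on set size (non-aborted, correct trials).
#'
#' @param result an [run_experiment()] result.
#' @export
experiment_slope_se <- function(result) {
  ok <- result$trials[!result$trials$aborted & result$trials$correct, ]
  fit <- stats::lm(rt_ms ~ set_size, ok)
  unname(sqrt(diag(stats::vcov(fit)))[2])
}

#' Monte-Carlo standard error of a percent slope reduction
#'
#' First-order error propagation of the two slope standard errors through
#' `100 * (1 - slope_effect / slope_baseline)`.
#'
#' @inheritParams experiment_slope_reduction
#' @export
experiment_slope_reduction_se <- function(result_effect, result_baseline) {
  b2 <- result_effect$fit$slope; b3 <- result_baseline$fit$slope
  se2 <- experiment_slope_se(result_effect)
  se3 <- experiment_slope_se(result_baseline)
  100 * sqrt((se2 / b3)^2 + (b2 * se3 / b3^2)^2)
}

#' Percent slope reduction between two experiment results
#'
#' `100 * (slope_baseline - slope_effect) / slope_baseline`, the
#' scale-invariant efficiency gain of `result_effect` (e.g. the preview
#' condition) over `result_baseline` (the no-preview condition).
#'
#' @param result_effect,result_baseline [run_experiment()] results.
#' @export
experiment_slope_reduction <- function(result_effect, result_baseline) {
  100 * (result_baseline$fit$slope - result_effect$fit$slope) /
    result_baseline$fit$slope
}

#' Affine scaling of model RTs to display milliseconds
#'
#' A single gain and offset mapping model reaction times onto the scale of
#' human data, fit once against a reference slope and intercept and applied
#' to all conditions. Used for display only; slope-ratio comparisons are
#' scale-invariant and never use it.
#'
#' @param result an [run_experiment()] result (the reference condition).
#' @param ref_slope,ref_intercept reference values in display ms.
#' @return list with `gain` and `offset`.
#' @export
fit_rt_scaling <- function(result, ref_slope = 34, ref_intercept = 600) {
  gain <- ref_slope / result$fit$slope
  offset <- ref_intercept - gain * result$fit$intercept
  list(gain = gain, offset = offset)
}

#' Calibrate the working-memory capacity to a target item count
#'
#' Bisects the shared capacity gain (the global-inhibition strength of the
#' memory space/feature maps and the spatial working memory field) until a
#' six-item commit sequence retains exactly the target number of items on
#' at least `min_pass` of `n_seeds` runs (each run a different array and
#' stream seed).
#'
#' @param target_capacity target retained-item count (default 4).
#' @param lo,hi bracketing gains (retention decreases with the gain).
#' @param n_seeds runs per evaluation.
#' @param min_pass required number of runs retaining exactly the target.
#' @param config base configuration.
#' @param max_iter bisection iterations.
#' @return list with `gain` (calibrated value), `retained` (counts at the
#'   calibrated gain), `trace` (bisection history).
#' @export
calibrate_capacity <- function(target_capacity = 4, lo = 2, hi = 40,
                               n_seeds = 20, min_pass = 18,
                               config = dnf_config(), max_iter = 8) {
  retained_at <- function(gain, n_runs) {
    vapply(seq_len(n_runs), function(i) {
      cfg <- modify_list_deep(config, list(capacity_gain = gain))
      class(cfg) <- "dnf_config"
      commit_six(cfg, array_seed = 11 + 13 * i, seed = i)
    }, numeric(1))
  }
  probe <- function(gain, n_runs = 6) stats::median(retained_at(gain, n_runs))
  if (!(probe(lo) > target_capacity && probe(hi) < target_capacity))
    stop("capacity calibration range does not bracket the target")
  trace <- list()
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    m <- probe(mid)
    trace[[it]] <- c(gain = mid, median_retained = m)
    if (m > target_capacity) lo <- mid else if (m < target_capacity) hi <- mid
    else {
      ret <- retained_at(mid, n_seeds)
      if (sum(ret == target_capacity) >= min_pass)
        return(list(gain = mid, retained = ret,
                    trace = do.call(rbind, trace)))
      # exactly-at-target median but too noisy: tighten around mid
      lo <- (lo + mid) / 2; hi <- (hi + mid) / 2
    }
  }
  mid <- (lo + hi) / 2
  list(gain = mid, retained = retained_at(mid, n_seeds),
       trace = do.call(rbind, trace))
}

# One six-item commit sequence on a generated conjunction array; returns
# the number of retained memory locations after a quiet period.
commit_six <- function(config, array_seed, seed = 1) {
  spec <- generate_array(3, 8, seed = array_seed)
  feats <- extract_features(render_frame(spec, "array"), config)
  mem <- memory_maps(config, seed)
  tc <- tile_centers()
  for (i in 1:6) {
    it <- spec$items[i, ]
    ct <- tc[tc$tile == it$tile, ]
    att <- data.frame(x = ct$cx, y = ct$cy)
    prof <- extract_attended_features(mem, feats, att)
    mem <- attr(prof, "memory")
    mem <- commit_item(mem, att, prof)
  }
  for (i in 1:100) mem <- step_memory_maps(mem, list(), 8)
  memory_item_count(mem)
}
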