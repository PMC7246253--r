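# Closed-form capacity-limited serial-search models and set-size slope
# analytics.

#' Expected number of examined items with memory guidance
#'
#' With set size `s` and working-memory capacity `c`, the target is in
#' memory with probability `p = min(c / s, 1)` and is then found
#' immediately (one examined item); otherwise the searcher examines
#' uniformly ordered items, `(s + 1) / 2` on average:
#' `p + (1 - p) (s + 1) / 2`.
#'
#' @param s set size (>= 1); vectorized.
#' @param c capacity (>= 0).
#' @return expected number of examined items.
#' @export
expected_items_eq1 <- function(s, c) {
  stopifnot(all(s >= 1), c >= 0)
  p <- pmin(c / s, 1)
  p + (1 - p) * (s + 1) / 2
}

#' Expected examined items with guidance and memory-based inhibition
#'
#' As [expected_items_eq1()], but memorized distractors are additionally
#' excluded from examination, leaving `s - c` candidates:
#' `p + (1 - p) (s - c + 1) / 2`. The slope in `s` is shallower even beyond
#' the capacity limit.
#'
#' @inheritParams expected_items_eq1
#' @export
expected_items_eq2 <- function(s, c) {
  stopifnot(all(s >= 1), c >= 0)
  p <- pmin(c / s, 1)
  p + (1 - p) * (s - c + 1) / 2
}

#' Ordinary least-squares slope of values against set size
#'
#' @param set_sizes numeric vector.
#' @param values numeric vector (same length).
#' @return list with `slope` and `intercept`.
#' @export
ols_slope <- function(set_sizes, values) {
  stopifnot(length(set_sizes) == length(values))
  fit <- stats::lm(values ~ set_sizes)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]))
}

#' Percent slope reduction between two set-size series
#'
#' Fits OLS lines to both series over the same set sizes and returns
#' `100 * (slope_without - slope_with) / slope_without`: the relative
#' shallowing of the `with` series against the `without` baseline.
#'
#' @param set_sizes set sizes of both series.
#' @param values_with series with the effect (e.g. memory inhibition).
#' @param values_without baseline series.
#' @export
slope_reduction_percent <- function(set_sizes, values_with, values_without) {
  sw <- ols_slope(set_sizes, values_with)$slope
  so <- ols_slope(set_sizes, values_without)$slope
  if (abs(so) < .Machine$double.eps)
    stop("baseline series has zero slope")
  100 * (so - sw) / so
}

#' Monte-Carlo serial-search oracle
#'
#' Direct simulation of capacity-limited serial search: on each replicate,
#' `c` of the `s` items are drawn into memory; if the target is among them
#' one item is examined; otherwise the remaining candidates (all `s` for
#' the guidance-only model, the `s - c` unmemorized ones under memory
#' inhibition) are examined in uniformly random order until the target is
#' found.
#'
#' @param s set size.
#' @param c capacity.
#' @param inhibition logical; exclude memorized distractors from
#'   examination (the shallower-slope model).
#' @param reps number of replicates.
#' @return list with `mean` and `se` of the examined-item count.
#' @export
serial_search_mc <- function(s, c, inhibition = FALSE, reps = 1e5) {
  c_eff <- min(c, s)
  in_mem <- stats::runif(reps) < c_eff / s
  n_seq <- ifelse(inhibition, s - c_eff, s)
  pos <- 1 + floor(stats::runif(reps) * n_seq)   # uniform serial position
  examined <- ifelse(in_mem, 1, pos)
  list(mean = mean(examined), se = stats::sd(examined) / sqrt(reps))
}
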