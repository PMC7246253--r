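#' Named reproducible RNG streams
#'
#' Each field or node in an architecture draws its noise from its own named
#' stream so that a trial is exactly replayable from a single trial seed,
#' independently of how many draws other components make.
#'
#' A stream is a mutable environment holding a saved `.Random.seed`; drawing
#' swaps the saved state in, samples, and swaps the previous global state back.
#'
#' @param seed integer seed for this stream (kept below 2^31).
#' @return an object of class `rng_stream`.
#' @export
rng_stream <- function(seed) {
  old <- get_rseed()
  set.seed(as.integer(seed %% .Machine$integer.max))
  st <- new.env(parent = emptyenv())
  st$state <- get_rseed()
  set_rseed(old)
  class(st) <- "rng_stream"
  st
}

get_rseed <- function() {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  get(".Random.seed", envir = globalenv(), inherits = FALSE)
}

set_rseed <- function(state) {
  if (is.null(state)) return(invisible(NULL))
  assign(".Random.seed", state, envir = globalenv())
  invisible(NULL)
}

#' Draw standard normal deviates from a named stream
#'
#' @param stream an [rng_stream()] (or `NULL`, in which case the global RNG
#'   is used).
#' @param n number of deviates.
#' @return numeric vector of length `n`.
#' @export
stream_rnorm <- function(stream, n) {
  if (is.null(stream)) return(stats::rnorm(n))
  old <- get_rseed()
  set_rseed(stream$state)
  x <- stats::rnorm(n)
  stream$state <- get_rseed()
  set_rseed(old)
  x
}

#' Draw uniform deviates from a named stream
#' @inheritParams stream_rnorm
#' @export
stream_runif <- function(stream, n) {
  if (is.null(stream)) return(stats::runif(n))
  old <- get_rseed()
  set_rseed(stream$state)
  x <- stats::runif(n)
  stream$state <- get_rseed()
  set_rseed(old)
  x
}

#' Derive a child stream seed from a parent seed and a component name
#'
#' Stable string hash (djb2 folded into 31 bits) so every field in an
#' architecture gets a distinct, reproducible stream from one trial seed.
#'
#' @param seed parent integer seed.
#' @param name component name.
#' @return integer seed below 2^31.
#' @export
derive_seed <- function(seed, name) {
  h <- 5381
  for (cc in utf8ToInt(name)) h <- (h * 33 + cc) %% 2147483647
  as.integer((h + as.numeric(seed) * 2654435761) %% 2147483647)
}
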