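#' Specify one dimension of a dynamic neural field
#'
#' A field is defined over an ordered stack of labelled dimensions: visual
#' space in stimulus pixels, hue in degrees on a 360-degree circle,
#' orientation in degrees on a 180-degree circle, or a log-size index.
#'
#' @param name dimension label, e.g. `"x"`, `"hue"`.
#' @param extent numeric length-2 interval in stimulus units. For circular
#'   dimensions the upper bound is exclusive (the dimension wraps).
#' @param samples positive integer number of grid points (at least 3).
#' @param circular logical; circular dimensions wrap distance computations.
#' @return object of class `dim_spec`.
#' @export
dim_spec <- function(name, extent, samples, circular = FALSE) {
  stopifnot(is.character(name), length(extent) == 2, extent[2] > extent[1])
  samples <- as.integer(samples)
  if (samples < 3) stop("a dimension needs at least 3 samples")
  structure(
    list(name = name, extent = as.numeric(extent), samples = samples,
         circular = isTRUE(circular)),
    class = "dim_spec"
  )
}

#' Grid coordinates of a dimension
#'
#' Bounded dimensions sample the closed interval; circular dimensions sample
#' `[lo, hi)` so that the first and last points are one step apart across the
#' wrap.
#'
#' @param dim a [dim_spec()].
#' @return numeric vector of length `dim$samples`.
#' @export
grid_points <- function(dim) {
  lo <- dim$extent[1]; hi <- dim$extent[2]
  if (dim$circular) {
    lo + (seq_len(dim$samples) - 1) * (hi - lo) / dim$samples
  } else {
    seq(lo, hi, length.out = dim$samples)
  }
}

#' Grid step of a dimension, in dimension units
#' @param dim a [dim_spec()].
#' @export
grid_step <- function(dim) {
  L <- diff(dim$extent)
  if (dim$circular) L / dim$samples else L / (dim$samples - 1)
}

#' Pairwise distance on a dimension (wrapped for circular dimensions)
#' @param dim a [dim_spec()].
#' @param a,b coordinate vectors in dimension units.
#' @return |a - b| respecting circular topology.
#' @export
dim_dist <- function(dim, a, b) {
  d <- abs(a - b)
  if (dim$circular) {
    L <- diff(dim$extent)
    d <- pmin(d, L - d)
  }
  d
}

# Row-normalized Gaussian smoothing matrix along one dimension.  Left-
# multiplying a field unfolded on this axis convolves it with a unit-mass
# Gaussian of the given width; circular dimensions use the wrapped distance,
# bounded dimensions renormalize at the edges (reflecting mass conservation).
gauss_matrix <- function(dim, width) {
  x <- grid_points(dim)
  n <- dim$samples
  D <- abs(outer(x, x, "-"))
  if (dim$circular) {
    L <- diff(dim$extent)
    D <- pmin(D, L - D)
  }
  M <- exp(-D^2 / (2 * width^2))
  M / rowSums(M)
}

# Apply a smoothing matrix along the given axis of an array (vector / matrix /
# 3-D array), preserving shape and dimension order.
smooth_axis <- function(arr, M, axis) {
  d <- dim(arr)
  if (is.null(d)) return(as.vector(M %*% arr))
  nd <- length(d)
  if (axis == 1L) {
    out <- M %*% matrix(arr, d[1], prod(d[-1]))
    return(array(out, d))
  }
  perm <- c(axis, seq_len(nd)[-axis])
  a <- aperm(arr, perm)
  da <- dim(a)
  a <- M %*% matrix(a, da[1], prod(da[-1]))
  a <- array(a, da)
  aperm(a, order(perm))
}

# Smooth an array along every axis with per-axis Gaussian matrices (a list,
# NULL entries skip an axis).
smooth_all <- function(arr, mats) {
  for (k in seq_along(mats)) {
    if (!is.null(mats[[k]])) arr <- smooth_axis(arr, mats[[k]], k)
  }
  arr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Gaussian bump over the grid of one dimension, max 1 at `center`.
gauss_bump <- function(dim, center, width) {
  exp(-dim_dist(dim, grid_points(dim), center)^2 / (2 * width^2))
}
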