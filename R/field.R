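#' Lateral interaction kernel (difference of Gaussians plus global inhibition)
#'
#' Local excitation over short distances, surround inhibition over longer
#' distances, and a constant global-inhibition term proportional to the
#' supra-threshold fraction of the field. The kernel is symmetric in its
#' argument.
#'
#' @param exc_amp excitatory gain (>= 0).
#' @param exc_width excitation width in dimension units (scalar, or one value
#'   per field dimension).
#' @param inh_amp surround-inhibition gain (>= 0).
#' @param inh_width surround width; must not be narrower than `exc_width`.
#' @param global_inh global-inhibition gain (>= 0); multiplies the mean
#'   supra-threshold output of the whole field, so a field in which a
#'   fraction f of sites is supra-threshold receives a homogeneous
#'   `-global_inh * f`.
#' @param global_tau time constant (ms) of the shared inhibitory pool that
#'   mediates global inhibition; `0` makes it instantaneous. A finite pool
#'   damps the excitation--inhibition loop.
#' @return object of class `dnf_kernel`.
#' @export
dnf_kernel <- function(exc_amp = 0, exc_width = 1, inh_amp = 0,
                       inh_width = exc_width, global_inh = 0,
                       global_tau = 25) {
  stopifnot(exc_amp >= 0, inh_amp >= 0, global_inh >= 0, global_tau >= 0,
            all(exc_width > 0), all(inh_width > 0))
  if (any(inh_width < exc_width))
    stop("surround inhibition must be at least as wide as local excitation")
  structure(list(exc_amp = exc_amp, exc_width = exc_width,
                 inh_amp = inh_amp, inh_width = inh_width,
                 global_inh = global_inh, global_tau = global_tau),
            class = "dnf_kernel")
}

#' Construct a dynamic neural field
#'
#' Activation u(x, t) over the grid spanned by `dims` relaxes, under
#' [step_field()], toward the resting level plus its inputs, with optional
#' lateral interaction and additive noise. With zero input and no interaction
#' the stable state is `u = h < 0`.
#'
#' @param dims a [dim_spec()] or list of them (ordered).
#' @param h resting level (activation units; negative at rest).
#' @param tau relaxation time constant in ms.
#' @param beta sigmoid steepness (1/activation).
#' @param noise standard deviation of the additive noise per sqrt(ms).
#' @param kernel optional [dnf_kernel()].
#' @param regime descriptive label: `"detection"`, `"selection"`,
#'   `"sustained"` or `"transient"`.
#' @param name field name (used to derive its RNG stream).
#' @param stream optional [rng_stream()] for the field's noise.
#' @return object of class `dnf_field`.
#' @export
dnf_field <- function(dims, h = -5, tau = 100, beta = 4, noise = 0,
                      kernel = NULL, regime = "detection", name = "field",
                      stream = NULL) {
  if (inherits(dims, "dim_spec")) dims <- list(dims)
  stopifnot(length(dims) >= 1, tau > 0, beta > 0, noise >= 0)
  regime <- match.arg(regime, c("detection", "selection", "sustained",
                                "transient"))
  shape <- vapply(dims, function(d) d$samples, integer(1))
  u <- array(h, dim = shape)
  f <- list(dims = dims, u = u, h = h, tau = tau, beta = beta, noise = noise,
            kernel = kernel, regime = regime, name = name, drive = 0,
            stream = stream, cache = NULL)
  class(f) <- "dnf_field"
  if (!is.null(kernel)) f <- cache_kernel(f)
  f
}

# Precompute per-axis smoothing matrices for the field's kernel widths.
cache_kernel <- function(field) {
  k <- field$kernel
  nd <- length(field$dims)
  ew <- rep_len(k$exc_width, nd)
  iw <- rep_len(k$inh_width, nd)
  field$cache <- list(
    exc = if (k$exc_amp > 0) lapply(seq_len(nd), function(i)
      gauss_matrix(field$dims[[i]], ew[i])) else NULL,
    inh = if (k$inh_amp > 0) lapply(seq_len(nd), function(i)
      gauss_matrix(field$dims[[i]], iw[i])) else NULL
  )
  field
}

#' Logistic threshold function
#'
#' Maps activation to an output rate in (0, 1); strictly increasing, with
#' `sigmoid(0) = 0.5`. Only this thresholded output is transmitted between
#' fields.
#'
#' @param u activation (any numeric array).
#' @param beta steepness (> 0).
#' @export
sigmoid <- function(u, beta = 4) {
  stopifnot(beta > 0)
  1 / (1 + exp(-beta * u))
}

#' Thresholded output of a field
#' @param field a [dnf_field()].
#' @return array of the same shape as `field$u`.
#' @export
field_output <- function(field) sigmoid(field$u, field$beta)

#' Lateral interaction contribution of a field
#'
#' Convolves the field's sigmoided output with its difference-of-Gaussians
#' kernel (wrapped on circular dimensions, mass-renormalized at bounded
#' edges) and subtracts global inhibition proportional to the mean
#' supra-threshold output.
#'
#' @param field a [dnf_field()] with a kernel.
#' @return contribution grid, same shape as `field$u`.
#' @export
interaction_input <- function(field) {
  k <- field$kernel
  if (is.null(k)) stop("field '", field$name, "' has no interaction kernel")
  if (is.null(field$cache)) field <- cache_kernel(field)
  out <- sigmoid(field$u, field$beta)
  contrib <- 0
  if (k$exc_amp > 0) contrib <- contrib + k$exc_amp * smooth_all(out, field$cache$exc)
  if (k$inh_amp > 0) contrib <- contrib - k$inh_amp * smooth_all(out, field$cache$inh)
  if (k$global_inh > 0) {
    pool <- field$inh_pool
    if (is.null(pool)) pool <- mean(out)
    contrib <- contrib - k$global_inh * pool
  }
  contrib
}

#' Advance a field by one explicit-Euler step
#'
#' `tau * du = (-u + h + drive + input + interaction) dt` plus additive
#' Gaussian noise scaled by `sqrt(dt)`. Deterministic given the field's RNG
#' stream.
#'
#' @param field a [dnf_field()].
#' @param input external input grid (scalar or array matching `field$u`).
#' @param dt time step in ms; must satisfy `dt <= tau / 5`.
#' @return the updated field.
#' @export
step_field <- function(field, input = 0, dt = 5) {
  if (dt > field$tau / 5)
    stop("dt must not exceed tau/5 for a stable Euler step")
  k <- field$kernel
  if (!is.null(k) && k$global_inh > 0 && (k$global_tau %||% 0) > 0 &&
      !isTRUE(field$pool_external)) {
    tgt <- mean(sigmoid(field$u, field$beta))
    v <- field$inh_pool %||% 0
    field$inh_pool <- v + (tgt - v) * min(1, dt / k$global_tau)
  }
  inter <- if (!is.null(field$kernel)) interaction_input(field) else 0
  du <- (-field$u + field$h + field$drive + input + inter) * (dt / field$tau)
  if (field$noise > 0) {
    du <- du + field$noise * sqrt(dt) *
      array(stream_rnorm(field$stream, length(field$u)), dim = dim(field$u))
  }
  u <- field$u + du
  if (!all(is.finite(u)))
    stop("numerical instability: non-finite activation in field '",
         field$name, "'")
  field$u <- u
  field
}

#' Construct a neural dynamic node (zero-dimensional field)
#'
#' @param h,tau,beta,noise as in [dnf_field()].
#' @param self_exc self-excitation gain c; large enough values make the node
#'   bistable over a range of inputs (hysteresis).
#' @param name node name.
#' @param stream optional [rng_stream()].
#' @return object of class `dnf_node`.
#' @export
dnf_node <- function(h = -5, tau = 100, beta = 4, noise = 0, self_exc = 0,
                     name = "node", stream = NULL) {
  stopifnot(tau > 0, beta > 0, self_exc >= 0)
  structure(list(u = h, h = h, tau = tau, beta = beta, noise = noise,
                 self_exc = self_exc, name = name, drive = 0,
                 stream = stream),
            class = "dnf_node")
}

#' Advance a node by one explicit-Euler step
#'
#' Node dynamics: `tau * du = -u + h + drive + input + c * sigmoid(u)` plus
#' sqrt(dt)-scaled noise.
#'
#' @param node a [dnf_node()].
#' @param input scalar input.
#' @param dt time step in ms (`dt <= tau / 5`).
#' @export
step_node <- function(node, input = 0, dt = 5) {
  if (dt > node$tau / 5)
    stop("dt must not exceed tau/5 for a stable Euler step")
  du <- (-node$u + node$h + node$drive + input +
           node$self_exc * sigmoid(node$u, node$beta)) * (dt / node$tau)
  if (node$noise > 0) du <- du + node$noise * sqrt(dt) * stream_rnorm(node$stream, 1)
  u <- node$u + du
  if (!is.finite(u))
    stop("numerical instability: non-finite activation in node '",
         node$name, "'")
  node$u <- u
  node
}

#' Is a node in its on-state?
#' @param node a [dnf_node()].
#' @export
node_on <- function(node) node$u > 0

#' Homogeneous boost or deboost of a field or node
#'
#' Sets a homogeneous additive drive that shifts the effective resting level
#' while active. Positive amounts ("boosts") enable peak formation; strong
#' negative amounts ("deboosts") extinguish all peaks through the reverse
#' detection instability. `boost(x, 0)` restores the unmodified dynamics.
#'
#' @param x a [dnf_field()] or [dnf_node()].
#' @param amount scalar drive in activation units.
#' @export
boost <- function(x, amount) {
  stopifnot(inherits(x, "dnf_field") || inherits(x, "dnf_node"))
  x$drive <- amount
  x
}

#' Detect supra-threshold peaks of a field
#'
#' Connected supra-threshold regions (u > 0, orthogonal adjacency, wrapped on
#' circular dimensions) are reported with the location and activation of
#' their maximum and their supra-threshold mass (sum of sigmoided output times
#' the grid cell volume).
#'
#' @param field a [dnf_field()].
#' @return a `data.frame` of class `peak_set` with one coordinate column per
#'   dimension (named by the dimension labels), plus `activation` and `mass`;
#'   zero rows when the field is entirely sub-threshold.
#' @export
detect_peaks <- function(field) {
  u <- field$u
  dims <- field$dims
  shape <- vapply(dims, function(d) d$samples, integer(1))
  supra <- which(u > 0)
  dimnm <- vapply(dims, function(d) d$name, character(1))
  empty <- as.data.frame(c(stats::setNames(rep(list(numeric(0)), length(dims)), dimnm),
                           list(activation = numeric(0), mass = numeric(0))))
  class(empty) <- c("peak_set", "data.frame")
  if (length(supra) == 0) return(empty)

  lab <- label_components(supra, shape, vapply(dims, function(d) d$circular, logical(1)))
  sig <- sigmoid(u, field$beta)
  cellvol <- prod(vapply(dims, grid_step, numeric(1)))
  coords <- arrayInd(supra, .dim = shape)
  pts <- lapply(dims, grid_points)

  comps <- split(seq_along(supra), lab)
  rows <- lapply(comps, function(idx) {
    cells <- supra[idx]
    imax <- idx[which.max(u[cells])]
    w <- sig[cells]
    loc <- vapply(seq_along(dims), function(k) {
      if (dims[[k]]$circular) {
        pts[[k]][coords[imax, k]]
      } else {
        # output-weighted centroid within the component
        sum(w * pts[[k]][coords[idx, k]]) / sum(w)
      }
    }, numeric(1))
    c(loc, u[supra[imax]], sum(sig[cells]) * cellvol)
  })
  m <- do.call(rbind, rows)
  res <- as.data.frame(m)
  names(res) <- c(dimnm, "activation", "mass")
  rownames(res) <- NULL
  class(res) <- c("peak_set", "data.frame")
  res
}

# Connected-component labelling of supra-threshold cells on an n-D grid with
# orthogonal adjacency; circular axes wrap. Union-find over axis-neighbour
# edges.
label_components <- function(supra, shape, circular) {
  n <- length(supra)
  pos <- integer(prod(shape)); pos[supra] <- seq_len(n)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  coords <- arrayInd(supra, .dim = shape)
  strides <- cumprod(c(1, shape[-length(shape)]))
  for (ax in seq_along(shape)) {
    nx <- shape[ax]
    cx <- coords[, ax]
    nb_lin <- supra + strides[ax]          # neighbour at +1 along axis
    ok <- cx < nx
    if (circular[ax] && nx > 1) {
      wrap <- cx == nx
      nb_lin[wrap] <- supra[wrap] - (nx - 1) * strides[ax]
      ok <- ok | wrap
    }
    ok <- ok & nb_lin >= 1 & nb_lin <= length(pos)
    j <- which(ok)
    j <- j[pos[nb_lin[j]] > 0]
    for (i in j) {
      a <- find(i); b <- find(pos[nb_lin[i]])
      if (a != b) parent[b] <- a
    }
  }
  vapply(seq_len(n), find, integer(1))
}
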