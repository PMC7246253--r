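#' Specify a directed, signed, gated projection between fields
#'
#' Projections carry the thresholded output of a source field into the input
#' of a target field of possibly different dimensionality. Dimensions present
#' only in the source are marginalized by integration; dimensions present
#' only in the target receive constant "ridge"/"slice" input by broadcasting.
#'
#' @param source,target field names (labels; used for graph validation).
#' @param source_dims,target_dims lists of [dim_spec()] describing the two
#'   fields. Shared dimensions (same name) must agree in extent and samples.
#' @param sign `"excitatory"` or `"inhibitory"`.
#' @param gain positive scalar gain.
#' @param smoothing optional named numeric vector of smoothing widths (in
#'   dimension units) applied along shared dimensions.
#' @param gate optional name of a node whose supra-threshold output enables
#'   transmission; a closed gate transmits zeros.
#' @return object of class `projection_spec`.
#' @export
projection_spec <- function(source, target, source_dims, target_dims,
                            sign = c("excitatory", "inhibitory"), gain = 1,
                            smoothing = NULL, gate = NULL) {
  sign <- match.arg(sign)
  if (inherits(source_dims, "dim_spec")) source_dims <- list(source_dims)
  if (inherits(target_dims, "dim_spec")) target_dims <- list(target_dims)
  sn <- vapply(source_dims, function(d) d$name, character(1))
  tn <- vapply(target_dims, function(d) d$name, character(1))
  shared <- intersect(sn, tn)
  for (nm in shared) {
    a <- source_dims[[match(nm, sn)]]; b <- target_dims[[match(nm, tn)]]
    if (!isTRUE(all.equal(a$extent, b$extent)) || a$samples != b$samples)
      stop("shared dimension '", nm, "' differs between source and target")
  }
  structure(list(source = source, target = target,
                 source_dims = source_dims, target_dims = target_dims,
                 marginalized = setdiff(sn, tn), expanded = setdiff(tn, sn),
                 sign = sign, gain = gain, smoothing = smoothing, gate = gate),
            class = "projection_spec")
}

#' Apply a projection to a source field's thresholded output
#'
#' Marginalization integrates (sum times grid step) over source-only
#' dimensions; expansion broadcasts constant input along target-only
#' dimensions; the signed gain and optional smoothing along shared dimensions
#' are then applied. A closed gate yields identically zero input.
#'
#' @param source_output thresholded output grid shaped like the source field.
#' @param spec a [projection_spec()].
#' @param gate_open logical; supply the gating node's state when the spec
#'   names a gate.
#' @return input grid shaped like the target field.
#' @export
project <- function(source_output, spec, gate_open = TRUE) {
  sdims <- spec$source_dims; tdims <- spec$target_dims
  sn <- vapply(sdims, function(d) d$name, character(1))
  tn <- vapply(tdims, function(d) d$name, character(1))
  tshape <- vapply(tdims, function(d) d$samples, integer(1))
  if (!is.null(spec$gate) && !gate_open)
    return(array(0, dim = tshape))
  sshape <- vapply(sdims, function(d) d$samples, integer(1))
  a <- array(source_output, dim = sshape)

  # marginalize source-only dimensions (integral: sum * grid step)
  keep <- which(sn %in% tn)
  drop_ <- which(!(sn %in% tn))
  if (length(drop_) > 0) {
    vol <- prod(vapply(sdims[drop_], grid_step, numeric(1)))
    if (length(keep) == 0) {
      a <- sum(a) * vol
    } else {
      a <- apply(a, keep, sum) * vol
      if (length(keep) == 1) a <- array(a, dim = sshape[keep])
    }
    sn <- sn[keep]
  }

  # expand to the target stack: permute shared dims into target order, then
  # broadcast along target-only dimensions
  shared_t <- which(tn %in% sn)
  if (length(sn) > 0) {
    a <- aperm(array(a, dim = vapply(sdims[keep], function(d) d$samples, integer(1))),
               match(tn[shared_t], sn))
  } else {
    a <- as.numeric(a)  # fully marginalized: scalar ridge
  }
  out <- array(0, dim = tshape)
  if (length(shared_t) == 0) {
    out[] <- a
  } else {
    # build by replication: order target dims as (shared..., expanded...),
    # fill, then permute back
    exp_t <- setdiff(seq_along(tn), shared_t)
    perm <- c(shared_t, exp_t)
    block <- array(rep(a, times = prod(tshape[exp_t])), dim = tshape[perm])
    out <- aperm(block, order(perm))
  }

  if (!is.null(spec$smoothing)) {
    for (nm in names(spec$smoothing)) {
      ax <- match(nm, tn)
      if (!is.na(ax)) {
        M <- gauss_matrix(tdims[[ax]], spec$smoothing[[nm]])
        out <- smooth_axis(out, M, ax)
      }
    }
  }
  s <- if (spec$sign == "inhibitory") -spec$gain else spec$gain
  out * s
}

#' Column input at an attended location
#'
#' A spatial tube: Gaussian in the two spatial dimensions, constant along the
#' feature dimension. Used by the attended location to select the matching
#' space/feature conjunction in three-dimensional fields.
#'
#' @param location numeric length-2, attended (x, y) in stimulus pixels;
#'   typically one row of a [detect_peaks()] result. Exactly one attended
#'   peak must be supplied.
#' @param target_dims list of [dim_spec()] of the 3-D target (x, y, feature).
#' @param width spatial width of the tube in pixels.
#' @param amp amplitude of the tube.
#' @return 3-D input grid for the target.
#' @export
column_input <- function(location, target_dims, width = 25, amp = 1) {
  if (is.data.frame(location)) {
    if (nrow(location) != 1)
      stop("column input requires exactly one attended peak, got ",
           nrow(location))
    location <- c(location$x[1], location$y[1])
  }
  stopifnot(length(location) == 2, length(target_dims) == 3)
  gx <- gauss_bump(target_dims[[1]], location[1], width)
  gy <- gauss_bump(target_dims[[2]], location[2], width)
  tube <- outer(gx, gy)
  amp * array(rep(tube, target_dims[[3]]$samples),
              dim = vapply(target_dims, function(d) d$samples, integer(1)))
}

#' Ridge (slice) input from a 1-D feature activation
#'
#' Broadcasts a feature-space activation profile across all spatial locations
#' of a 3-D (x, y, feature) field.
#'
#' @param feature_activation numeric vector over the feature grid.
#' @param target_dims list of [dim_spec()] of the 3-D target.
#' @param amp amplitude scaling.
#' @return 3-D input grid constant over space.
#' @export
ridge_input <- function(feature_activation, target_dims, amp = 1) {
  stopifnot(length(target_dims) == 3,
            length(feature_activation) == target_dims[[3]]$samples)
  shape <- vapply(target_dims, function(d) d$samples, integer(1))
  amp * aperm(array(rep(feature_activation, times = shape[1] * shape[2]),
                    dim = c(shape[3], shape[1], shape[2])), c(2, 3, 1))
}
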