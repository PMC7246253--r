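# Feed-forward feature extraction: hue, orientation and size maps plus the
# summed salience input. All maps are sampled on the architecture's spatial
# grid and calibrated so a single standard bar produces a unit-amplitude
# response.

# Circular 2-D convolution via FFT; the filter is given centred and is
# wrapped onto the image grid. Stimuli keep a margin wider than the filter
# support, so wrap-around is immaterial.
fft_conv2 <- function(img, filt) {
  d <- dim(img)
  pf <- array(0, dim = d)
  fd <- dim(filt)
  cy <- (fd[1] + 1) %/% 2; cx <- (fd[2] + 1) %/% 2
  ys <- ((seq_len(fd[1]) - cy) %% d[1]) + 1
  xs <- ((seq_len(fd[2]) - cx) %% d[2]) + 1
  for (i in seq_len(fd[1])) pf[ys[i], xs] <- pf[ys[i], xs] + filt[i, ]
  Re(stats::fft(stats::fft(img) * stats::fft(pf), inverse = TRUE)) / prod(d)
}

# Unit-mass anisotropic Gaussian filter, long axis at `angle` degrees
# (0 = horizontal).
oriented_gaussian <- function(sigma_long, sigma_short, angle, half = NULL) {
  if (is.null(half)) half <- ceiling(3 * sigma_long)
  xs <- -half:half
  th <- angle * pi / 180
  dx <- outer(rep(1, length(xs)), xs)
  dy <- outer(xs, rep(1, length(xs)))
  a <- dx * cos(th) + dy * sin(th)
  b <- -dx * sin(th) + dy * cos(th)
  g <- exp(-a^2 / (2 * sigma_long^2) - b^2 / (2 * sigma_short^2))
  g / sum(g)
}

iso_gaussian <- function(sigma, half = NULL) {
  if (is.null(half)) half <- ceiling(3 * sigma)
  xs <- -half:half
  g <- exp(-outer(xs^2, xs^2, "+") / (2 * sigma^2))
  g / sum(g)
}

# Block-reduce an image by an integer factor (mean pooling).
block_mean <- function(img, f) {
  d <- dim(img)
  ny <- d[1] %/% f; nx <- d[2] %/% f
  img <- img[seq_len(ny * f), seq_len(nx * f)]
  a <- array(img, dim = c(f, ny, f * nx))
  a <- colMeans(a)                       # ny x (f*nx)
  a <- array(a, dim = c(ny, f, nx))
  apply(a, c(1, 3), mean)
}

# Nearest grid index on a bounded dimension for a stimulus coordinate.
grid_index <- function(coord, extent, n) {
  pmin(n, pmax(1, round((coord - extent[1]) * (n - 1) /
                          diff(extent)) + 1))
}

# Max-pool a downsampled working image onto the nx x ny architecture grid
# (transposing image row/col into (x, y) order); each working pixel is
# assigned to its nearest grid point.
pool_to_grid <- function(img, config) {
  v <- config$vision
  d <- dim(img)
  f <- v$ds_factor
  ixv <- grid_index((seq_len(d[2]) - 0.5) * f, config$dims$x$extent, v$nx)
  iyv <- grid_index((seq_len(d[1]) - 0.5) * f, config$dims$y$extent, v$ny)
  out <- matrix(0, v$nx, v$ny)
  for (r in seq_len(d[1])) {
    m <- tapply(img[r, ], ixv, max)
    j <- iyv[r]
    out[as.integer(names(m)), j] <- pmax(out[as.integer(names(m)), j], m)
  }
  out
}

#' Extract the hue (color) space/feature map from a frame
#'
#' Every sufficiently saturated pixel contributes its saturation as mass at
#' its hue bin and spatial cell; the white background (zero saturation)
#' contributes nothing. The map is smoothed along the circular hue axis.
#'
#' @param frame a [render_frame()] raster (H x W x 3 in [0, 1]).
#' @param config a [dnf_config()].
#' @return 3-D array over (x, y, hue).
#' @export
extract_color <- function(frame, config) {
  v <- config$vision
  H <- dim(frame)[1]; W <- dim(frame)[2]
  m <- grDevices::rgb2hsv(r = as.vector(frame[, , 1]),
                          g = as.vector(frame[, , 2]),
                          b = as.vector(frame[, , 3]), maxColorValue = 1)
  sat <- m[2, ]; val <- m[3, ]
  keep <- which(sat > v$sat_threshold & val > 0.15)
  out <- array(0, dim = c(v$nx, v$ny, v$nhue))
  if (length(keep) > 0) {
    hue <- m[1, keep] * 360
    py <- ((keep - 1) %% H) + 1
    px <- ((keep - 1) %/% H) + 1
    ix <- grid_index(px, config$dims$x$extent, v$nx)
    iy <- grid_index(py, config$dims$y$extent, v$ny)
    ih <- (round(hue / (360 / v$nhue)) %% v$nhue) + 1
    idx <- ix + (iy - 1) * v$nx + (ih - 1) * v$nx * v$ny
    acc <- rowsum(sat[keep], idx)
    out[as.integer(rownames(acc))] <-
      acc / ((diff(config$dims$x$extent) / (v$nx - 1)) *
               (diff(config$dims$y$extent) / (v$ny - 1)))
  }
  hd <- config$dims$hue
  out <- smooth_axis(out, gauss_matrix(hd, grid_step(hd)), 3)
  out * vision_gains(config)$color
}

# Saturation mask of a frame, downsampled by the working factor.
sat_mask <- function(frame, config) {
  v <- config$vision
  m <- grDevices::rgb2hsv(r = as.vector(frame[, , 1]),
                          g = as.vector(frame[, , 2]),
                          b = as.vector(frame[, , 3]), maxColorValue = 1)
  sat <- matrix(m[2, ], dim(frame)[1], dim(frame)[2])
  block_mean((sat > v$sat_threshold) * 1, v$ds_factor)
}

#' Extract the orientation space/feature map from a frame
#'
#' Four elongate centre-surround filters (at 0, 45, 90 and 135 degrees) are
#' applied to the thresholded saturation of the frame; each channel's
#' response is interpolated onto the circular 180-degree orientation axis.
#' A bar responds maximally in the channel matching its axis.
#'
#' @inheritParams extract_color
#' @return 3-D array over (x, y, orientation).
#' @export
extract_orientation <- function(frame, config) {
  v <- config$vision
  mask <- sat_mask(frame, config)
  gains <- vision_gains(config)$orientation
  surround <- fft_conv2(mask, iso_gaussian(v$ori_sigma_long))
  od <- config$dims$ori
  pts <- grid_points(od)
  out <- array(0, dim = c(v$nx, v$ny, v$nori))
  for (k in seq_along(v$ori_channels)) {
    ang <- v$ori_channels[k]
    r <- fft_conv2(mask, oriented_gaussian(v$ori_sigma_long, v$ori_sigma_short,
                                           ang)) - surround
    r <- pool_to_grid(pmax(r, 0), config) * gains[k]
    w <- exp(-dim_dist(od, pts, ang)^2 / (2 * v$ori_tuning^2))
    for (b in which(w > 0.01))
      out[, , b] <- out[, , b] + r * w[b]
  }
  # cross-channel sharpening: a bar drives its own channel far more strongly
  # than the off-axis channels; subtract a fraction of the mean response
  m <- apply(out, c(1, 2), mean)
  out <- pmax(out - v$ori_cross * as.vector(m), 0)
  out
}

#' Extract the size space/feature map from a frame
#'
#' A pyramid of centre-surround (difference-of-Gaussians) filters of
#' increasing scale is applied to the thresholded saturation; responses at
#' larger scales suppress responses at smaller scales at the same location
#' (one-way inhibition along the scale axis), so each item activates the
#' pyramid level matching its extent. Width and length enter jointly through
#' the log-area this bandpass pyramid responds to.
#'
#' @inheritParams extract_color
#' @return 3-D array over (x, y, size level).
#' @export
extract_size <- function(frame, config) {
  v <- config$vision
  mask <- sat_mask(frame, config)
  ns <- length(v$size_sigmas)
  p <- lapply(v$size_sigmas, function(s) fft_conv2(mask, iso_gaussian(s)))
  bands <- vector("list", ns)
  for (k in seq_len(ns)) {
    nxt <- if (k < ns) p[[k + 1]] else 0
    bands[[k]] <- pmax(p[[k]] - nxt, 0)
  }
  # one-way inhibition: larger-scale responses suppress smaller scales
  for (k in rev(seq_len(ns - 1))) {
    bands[[k]] <- pmax(bands[[k]] - v$size_oneway * bands[[k + 1]], 0)
  }
  out <- array(0, dim = c(v$nx, v$ny, v$nsize))
  for (k in seq_len(ns))
    out[, , k] <- pool_to_grid(bands[[k]], config)
  out * vision_gains(config)$size
}

#' Extract all feature maps and the salience input from a frame
#'
#' @inheritParams extract_color
#' @return list of class `feature_maps` with elements `color`,
#'   `orientation`, `size` (3-D arrays) and `salience` (nx x ny matrix):
#'   the scene space/feature maps and the summed conspicuity input to the
#'   salience field.
#' @export
extract_features <- function(frame, config) {
  col <- extract_color(frame, config)
  ori <- extract_orientation(frame, config)
  siz <- extract_size(frame, config)
  structure(list(color = col, orientation = ori, size = siz,
                 salience = salience_input(list(color = col, orientation = ori,
                                                size = siz), config)),
            class = "feature_maps")
}

#' Salience input: summed conspicuity over color, orientation and size
#'
#' Each space/feature map is marginalized along its feature dimension
#' (conspicuity) and the three conspicuity maps are summed and scaled so a
#' single standard item yields a unit salience peak.
#'
#' @param maps list with elements `color`, `orientation`, `size`.
#' @param config a [dnf_config()].
#' @return nx x ny non-negative matrix.
#' @export
salience_input <- function(maps, config) {
  consp <- function(a) apply(a, c(1, 2), max)
  s <- consp(maps$color) + consp(maps$orientation) + consp(maps$size)
  s <- smooth_axis(smooth_axis(s, gauss_matrix(config$dims$x, 12), 1),
                   gauss_matrix(config$dims$y, 12), 2)
  s * vision_gains(config)$salience
}

# Calibration: gains such that one standard bar (rendered alone at a centre
# tile) produces unit-amplitude responses in every map and in the salience
# input. Computed once per configuration and cached.
vision_gains <- function(config) {
  env <- config$vision$gain_env
  if (!is.null(env$gains)) return(env$gains)
  env$gains <- list(color = 1, orientation = rep(1, length(config$vision$ori_channels)),
                    size = 1, salience = 1)
  probe <- list(items = data.frame(tile = 13, color = "red", orientation = 0,
                                   is_target = TRUE, stringsAsFactors = FALSE),
                target_color = "red", target_orientation = 0,
                condition = 3, experiment = 1, set_size = 1, seed = 0)
  class(probe) <- "stimulus_array"
  g <- list()
  fr <- render_frame(probe, "array")
  g$color <- 1 / max(extract_color(fr, config))
  og <- numeric(length(config$vision$ori_channels))
  for (k in seq_along(config$vision$ori_channels)) {
    probe$items$orientation <- config$vision$ori_channels[k]
    frk <- render_frame(probe, "array")
    raw <- extract_orientation(frk, config)
    og[k] <- 1 / max(raw)
  }
  g$orientation <- og
  probe$items$orientation <- 0
  g$size <- 1 / max(extract_size(fr, config))
  env$gains <- c(g, list(salience = 1))
  s <- max(salience_input(list(color = extract_color(fr, config),
                               orientation = extract_orientation(fr, config),
                               size = extract_size(fr, config)), config))
  env$gains$salience <- 1 / s
  env$gains
}
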