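#' Tile geometry of the search display
#'
#' Items live on a 5-column by 4-row grid of 80x80-pixel tiles centred in a
#' 500x400-pixel display on a white background. The black-bordered middle
#' tile of the second row is reserved for the visual cue. Tiles are indexed
#' row-major, 1..20.
#'
#' @return data.frame with columns `tile`, `col`, `row`, `cx`, `cy` (pixel
#'   centres).
#' @export
tile_centers <- function() {
  g <- expand.grid(col = 1:5, row = 1:4)
  data.frame(tile = seq_len(nrow(g)), col = g$col, row = g$row,
             cx = 50 + (g$col - 1) * 80 + 40,
             cy = 40 + (g$row - 1) * 80 + 40)
}

#' Index of the reserved cue tile (middle of row 2)
#' @export
cue_tile <- function() 8L

stim_colors <- c("red", "green", "blue")
stim_orients <- c(0, 45, 90, 135)
color_rgb <- function(col) switch(col, red = c(1, 0, 0), green = c(0, 1, 0),
                                  blue = c(0, 0, 1))
color_hue <- function(col) switch(col, red = 0, green = 120, blue = 240)

#' Generate one trial's search array
#'
#' Condition 1 is single-feature search: vertical bars, one in the target
#' color and the rest in a single distractor color. Conditions 2 and 3 are
#' conjunction search: a target with feature conjunction (c_t, o_t);
#' (set_size - 2) / 2 distractors of each of the shared-feature combinations
#' (c_t, o_d) and (c_d, o_t); and exactly one distractor with the distinct
#' conjunction (c_d, o_d), which keeps the distractor count odd and prevents
#' guessing the target from a preview. Item tiles are sampled uniformly from
#' the free tiles; the cue tile is never occupied.
#'
#' @param condition 1 (feature search), 2 (conjunction with preview) or 3
#'   (conjunction without preview).
#' @param set_size total number of array items: one of 4, 6, 8, 14, 18.
#' @param seed integer trial seed.
#' @param experiment 1 or 2 (stored for the timeline; stimuli are identical).
#' @return object of class `stimulus_array`: list with `items` (data.frame
#'   `tile`, `color`, `orientation`, `is_target`), `target_color`,
#'   `target_orientation`, `condition`, `experiment`, `set_size`, `seed`.
#' @export
generate_array <- function(condition, set_size, seed, experiment = 1) {
  if (!set_size %in% c(4, 6, 8, 14, 18))
    stop("set_size must be one of 4, 6, 8, 14, 18")
  stopifnot(condition %in% 1:3, experiment %in% 1:2)
  stream <- rng_stream(derive_seed(seed, "array"))
  pick <- function(v, n) v[order(stream_runif(stream, length(v)))][seq_len(n)]

  free <- setdiff(tile_centers()$tile, cue_tile())
  tiles <- pick(free, set_size)
  cols <- pick(stim_colors, 2)
  c_t <- cols[1]; c_d <- cols[2]
  if (condition == 1) {
    o_t <- 90; o_d <- 90
    color <- c(c_t, rep(c_d, set_size - 1))
    orient <- rep(90, set_size)
  } else {
    os <- pick(stim_orients, 2)
    o_t <- os[1]; o_d <- os[2]
    nsh <- (set_size - 2) / 2
    color <- c(c_t, rep(c_t, nsh), rep(c_d, nsh), c_d)
    orient <- c(o_t, rep(o_d, nsh), rep(o_t, nsh), o_d)
  }
  items <- data.frame(tile = tiles, color = color, orientation = orient,
                      is_target = c(TRUE, rep(FALSE, set_size - 1)),
                      stringsAsFactors = FALSE)
  structure(list(items = items, target_color = c_t, target_orientation = o_t,
                 distractor_color = c_d,
                 distractor_orientation = if (condition == 1) 90 else o_d,
                 condition = condition, experiment = experiment,
                 set_size = set_size, seed = seed),
            class = "stimulus_array")
}

#' Trial timeline for an experiment and condition
#'
#' Experiment 1: blank 200 ms; preview of the search array (condition 2) or
#' blank (conditions 1 and 3) for 800 ms; then search array plus cue until
#' response. The reaction-time clock starts at cue onset.
#' Experiment 2: blank 100 ms; preview or blank 800 ms; blank 100 ms; cue
#' alone 400 ms; blank 100 ms; then the search array (without the cue) until
#' response. The clock starts at array onset.
#'
#' @param experiment 1 or 2.
#' @param condition 1, 2 or 3.
#' @return data.frame with columns `content` (one of `"blank"`, `"preview"`,
#'   `"cue"`, `"array_cue"`, `"array"`) and `duration` (ms; `Inf` for the
#'   response segment), plus attribute `rt_from` naming the segment whose
#'   onset starts the clock.
#' @export
trial_timeline <- function(experiment, condition) {
  pv <- if (condition == 2) "preview" else "blank"
  if (experiment == 1) {
    tl <- data.frame(content = c("blank", pv, "array_cue"),
                     duration = c(200, 800, Inf),
                     stringsAsFactors = FALSE)
    attr(tl, "rt_from") <- "array_cue"
  } else {
    tl <- data.frame(content = c("blank", pv, "blank", "cue", "blank", "array"),
                     duration = c(100, 800, 100, 400, 100, Inf),
                     stringsAsFactors = FALSE)
    attr(tl, "rt_from") <- "array"
  }
  tl
}

# Paint one anti-aliased bar (len x wid pixels, rotated by `angle` degrees,
# 0 = horizontal) into the canvas around pixel centre (cx, cy).
paint_bar <- function(canvas, cx, cy, angle, rgbcol, len = 60, wid = 12) {
  th <- angle * pi / 180
  r <- ceiling(len / 2) + 2
  W <- dim(canvas)[2]; H <- dim(canvas)[1]
  xs <- max(1, round(cx - r)):min(W, round(cx + r))
  ys <- max(1, round(cy - r)):min(H, round(cy + r))
  dx <- outer(rep(1, length(ys)), xs - cx)
  dy <- outer(ys - cy, rep(1, length(xs)))
  a <- dx * cos(th) + dy * sin(th)
  b <- -dx * sin(th) + dy * cos(th)
  cov <- pmax(0, pmin(1, len / 2 + 0.5 - abs(a))) *
    pmax(0, pmin(1, wid / 2 + 0.5 - abs(b)))
  for (ch in 1:3) {
    old <- canvas[ys, xs, ch]
    canvas[ys, xs, ch] <- old * (1 - cov) + rgbcol[ch] * cov
  }
  canvas
}

#' Render one timeline segment of a trial to a raster frame
#'
#' Deterministic rasterization of the printed stimulus layout: colored bars
#' (default 60x12 pixels) centred in their tiles on a white 500x400 canvas;
#' during cue segments the cue item is drawn inside the black-bordered cue
#' tile.
#'
#' @param spec a [generate_array()] result.
#' @param content segment content: `"blank"`, `"preview"`, `"cue"`,
#'   `"array_cue"` or `"array"`.
#' @param bar_len,bar_wid bar geometry in pixels.
#' @param border_px cue-tile border thickness in pixels.
#' @return an H x W x 3 numeric array in [0, 1] (rows are image rows, top
#'   first), class `stimulus_frame`.
#' @export
render_frame <- function(spec, content, bar_len = 60, bar_wid = 12,
                         border_px = 3) {
  H <- 400L; W <- 500L
  canvas <- array(1, dim = c(H, W, 3))
  draw_items <- content %in% c("preview", "array_cue", "array")
  draw_cue <- content %in% c("cue", "array_cue")
  tc <- tile_centers()
  if (draw_items) {
    for (i in seq_len(nrow(spec$items))) {
      it <- spec$items[i, ]
      ct <- tc[tc$tile == it$tile, ]
      canvas <- paint_bar(canvas, ct$cx, ct$cy, it$orientation,
                          color_rgb(it$color), bar_len, bar_wid)
    }
  }
  if (draw_cue) {
    ct <- tc[tc$tile == cue_tile(), ]
    xs <- (ct$cx - 40):(ct$cx + 39); ys <- (ct$cy - 40):(ct$cy + 39)
    ring <- c(seq_len(border_px), length(xs) - seq_len(border_px) + 1)
    canvas[ys[ring], xs, ] <- 0
    canvas[ys, xs[ring], ] <- 0
    canvas <- paint_bar(canvas, ct$cx, ct$cy, spec$target_orientation,
                        color_rgb(spec$target_color), bar_len, bar_wid)
  }
  structure(canvas, class = "stimulus_frame")
}

#' Write a frame as a PNG file
#' @param frame a [render_frame()] result.
#' @param path output file path.
#' @export
write_frame_png <- function(frame, path) {
  grDevices::png(path, width = dim(frame)[2], height = dim(frame)[1])
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit({ graphics::par(op); grDevices::dev.off() }, add = TRUE)
  graphics::plot.new()
  graphics::rasterImage(grDevices::as.raster(unclass(frame)), 0, 0, 1, 1)
  invisible(path)
}

#' Serialize / restore an array spec for trial replay
#' @param spec a [generate_array()] result.
#' @param path file path for the YAML serialization.
#' @export
write_array_spec <- function(spec, path) {
  yaml::write_yaml(list(
    condition = spec$condition, experiment = spec$experiment,
    set_size = spec$set_size, seed = spec$seed,
    target_color = spec$target_color,
    target_orientation = spec$target_orientation,
    distractor_color = spec$distractor_color,
    distractor_orientation = spec$distractor_orientation,
    items = lapply(seq_len(nrow(spec$items)), function(i) as.list(spec$items[i, ]))
  ), path)
  invisible(path)
}

#' @rdname write_array_spec
#' @export
read_array_spec <- function(path) {
  y <- yaml::read_yaml(path)
  items <- do.call(rbind, lapply(y$items, function(it)
    data.frame(tile = it$tile, color = it$color, orientation = it$orientation,
               is_target = it$is_target, stringsAsFactors = FALSE)))
  y$items <- items
  class(y) <- "stimulus_array"
  y
}
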