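# Synthetic phantom generator. Renders placido-disk interference imagery:
# concentric bright rings whose pixels carry the interference color of a
# known ground-truth LLT field, over a dark-brown ring background, with
# optional Gaussian sensor noise and eyelash-like occluding strokes. Every
# pipeline stage can be validated against the phantom's ground truth.

#' Phantom specification
#'
#' @param image_size `(rows, cols)` in pixels (default 240 x 320).
#' @param center Ring pattern center `(row, col)`; default the image
#'   center.
#' @param n_rings Number of bright rings (>= 3, so excluding the central 2
#'   leaves analyzable rings).
#' @param ring_width_px,ring_gap_px Bright ring width and dark gap (px).
#' @param inner_radius_px Inner radius of the innermost bright ring.
#' @param llt_field Ground-truth thickness field: a `function(row, col)`
#'   returning nm, or a named profile list — `list(profile = "uniform",
#'   value = 60)`, `list(profile = "vertical_gradient", from = 40, to =
#'   80)` (top to bottom edge), or `list(profile = "radial", center = 80,
#'   edge = 40)`.
#' @param background_rgb Dark ring background color; default `c(60, 40,
#'   20)`, a dark brown.
#' @param noise_sd Gaussian channel noise standard deviation (8-bit
#'   units, >= 0).
#' @param occluders List of eyelash-like strokes, each `list(from =
#'   c(row, col), to = c(row, col), width_px = w)`, rendered at the
#'   background color.
#' @param seed RNG seed for the noise (`NULL` = leave RNG state alone).
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(image_size = c(240, 320),
                         center = NULL,
                         n_rings = 8,
                         ring_width_px = 6,
                         ring_gap_px = 8,
                         inner_radius_px = 14,
                         llt_field = list(profile = "uniform", value = 60),
                         background_rgb = c(60, 40, 20),
                         noise_sd = 0,
                         occluders = list(),
                         seed = NULL) {
  if (n_rings < 3)
    stop("need at least 3 rings (central 2 are excluded)", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (is.null(center)) center <- image_size / 2
  structure(list(image_size = image_size, center = center,
                 n_rings = n_rings, ring_width_px = ring_width_px,
                 ring_gap_px = ring_gap_px,
                 inner_radius_px = inner_radius_px,
                 llt_field = llt_field, background_rgb = background_rgb,
                 noise_sd = noise_sd, occluders = occluders, seed = seed),
            class = "phantom_spec")
}

llt_field_fn <- function(spec) {
  f <- spec$llt_field
  if (is.function(f)) return(f)
  rows <- spec$image_size[1]
  switch(f$profile,
    uniform = function(r, c) rep(f$value, length(r)),
    vertical_gradient = function(r, c)
      f$from + (f$to - f$from) * (r - 1) / (rows - 1),
    radial = function(r, c) {
      rad <- sqrt((r - spec$center[1])^2 + (c - spec$center[2])^2)
      rmax <- spec$inner_radius_px +
        (spec$n_rings - 1) * (spec$ring_width_px + spec$ring_gap_px) +
        spec$ring_width_px
      f$edge + (f$center - f$edge) * pmax(0, 1 - rad / rmax)
    },
    stop("unknown llt_field profile: ", f$profile, call. = FALSE)
  )
}

phantom_geometry <- function(spec) {
  pitch <- spec$ring_width_px + spec$ring_gap_px
  ring_geometry(
    center = spec$center,
    inner_exclusion_radius_px = spec$inner_radius_px + pitch +
      spec$ring_width_px,
    outer_radius_px = spec$inner_radius_px + (spec$n_rings - 1) * pitch +
      spec$ring_width_px)
}

#' Render a phantom placido interference image
#'
#' Bright ring pixels take the look-up table color of the entry nearest
#' their ground-truth LLT (so a noiseless phantom is an exact fixed point
#' of the color-to-thickness inversion); dark ring background and occluder
#' pixels take `background_rgb`; Gaussian noise is then added per channel
#' and clipped to 0--255. Deterministic given `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @param table A `lookup_table`; the ground-truth field must lie within
#'   its thickness range.
#' @return A `phantom_truth`: list with `image` (rendered frame),
#'   `llt_field` (nm matrix), `bright_mask` (ground-truth ring pixels,
#'   occluders excluded) and `geometry` (a [ring_geometry()]).
#' @export
render_phantom <- function(spec, table) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_lookup_table(table)
  h <- spec$image_size[1]; w <- spec$image_size[2]
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  field <- matrix(llt_field_fn(spec)(as.numeric(rows), as.numeric(cols)),
                  h, w)
  rng <- range(table$llt_nm)
  if (any(field < rng[1] - 0.5 | field > rng[2] + 0.5))
    stop("llt_field outside the look-up table range [", rng[1], ", ",
         rng[2], "] nm", call. = FALSE)
  rad <- sqrt((rows - spec$center[1])^2 + (cols - spec$center[2])^2)
  pitch <- spec$ring_width_px + spec$ring_gap_px
  rel <- rad - spec$inner_radius_px
  in_band <- rel >= 0 & rel %% pitch < spec$ring_width_px
  ring_idx <- floor(rel / pitch)
  bright <- in_band & ring_idx < spec$n_rings
  occ <- matrix(FALSE, h, w)
  for (o in spec$occluders)
    occ <- occ | stroke_mask(rows, cols, o$from, o$to, o$width_px)
  bright_mask <- bright & !occ
  # snap ground truth to the nearest table thickness for the color
  snap_idx <- matrix(
    findInterval(field, table$llt_nm + c(diff(table$llt_nm) / 2, Inf)) + 1L,
    h, w)
  img <- array(0L, c(h, w, 3))
  for (ch in 1:3) {
    plane <- matrix(spec$background_rgb[ch], h, w)
    tab_ch <- as.matrix(table[c("R", "G", "B")])[, ch]
    plane[bright_mask] <- tab_ch[snap_idx[bright_mask]]
    img[, , ch] <- plane
  }
  if (spec$noise_sd > 0) {
    if (!is.null(spec$seed)) set.seed(spec$seed)
    img <- img + array(stats::rnorm(length(img), 0, spec$noise_sd),
                       dim(img))
    img <- pmin(pmax(round(img), 0), 255)
  }
  storage.mode(img) <- "integer"
  structure(list(image = img, llt_field = field,
                 bright_mask = bright_mask,
                 geometry = phantom_geometry(spec)),
            class = "phantom_truth")
}

# Pixels within width/2 of the segment from -> to.
stroke_mask <- function(rows, cols, from, to, width_px) {
  vx <- to[1] - from[1]; vy <- to[2] - from[2]
  len2 <- vx^2 + vy^2
  if (len2 == 0) {
    d2 <- (rows - from[1])^2 + (cols - from[2])^2
  } else {
    t <- ((rows - from[1]) * vx + (cols - from[2]) * vy) / len2
    t <- pmin(pmax(t, 0), 1)
    d2 <- (rows - (from[1] + t * vx))^2 + (cols - (from[2] + t * vy))^2
  }
  d2 <= (width_px / 2)^2
}

#' Render a blink-cycle sequence with an advancing lipid front
#'
#' Emulates the upward spread of the lipid layer after eye opening: below
#' a front row the ground truth follows `spec$llt_field`; above it the
#' layer is still thin (`thin_llt_nm`). The front's covered fraction
#' follows a logistic curve in time and freezes after `settle_s` (the
#' layer becomes static roughly a second after opening). A rate of 0
#' yields identical frames.
#'
#' @param spec A [phantom_spec()] (its `llt_field` is the settled field).
#' @param table A `lookup_table`.
#' @param n_frames Number of frames (>= 1).
#' @param interval_s Frame interval in seconds (default 0.05).
#' @param spread List: `rate` (logistic steepness, 1/s, default 6),
#'   `t_mid_s` (half-coverage time, default 0.25), `settle_s` (freeze
#'   time, default 1.1), `thin_llt_nm` (uncovered thickness, default the
#'   table minimum).
#' @return List of `phantom_truth`, one per frame, each with a `t_s`
#'   element; convert with [phantoms_to_cycle()].
#' @export
render_blink_sequence <- function(spec, table, n_frames = 41,
                                  interval_s = 0.05,
                                  spread = list()) {
  if (n_frames < 1) stop("need n_frames >= 1", call. = FALSE)
  rate <- spread$rate %||% 6
  t_mid <- spread$t_mid_s %||% 0.25
  settle <- spread$settle_s %||% 1.1
  thin <- spread$thin_llt_nm %||% min(table$llt_nm)
  if (rate < 0 || settle < 0)
    stop("invalid spread parameters", call. = FALSE)
  settled_fn <- llt_field_fn(spec)
  h <- spec$image_size[1]
  lapply(seq_len(n_frames) - 1L, function(k) {
    t <- k * interval_s
    te <- min(t, settle)
    frac <- stats::plogis(rate * (te - t_mid))
    front_row <- h - frac * (h - 1)      # front advances upward from bottom
    fld <- function(r, c)
      ifelse(r >= front_row, settled_fn(r, c), thin)
    sp <- spec
    sp$llt_field <- fld
    if (!is.null(spec$seed)) sp$seed <- spec$seed + k
    out <- render_phantom(sp, table)
    out$t_s <- t
    out
  })
}

#' Convert rendered phantoms to a blink cycle
#'
#' @param phantoms List from [render_blink_sequence()].
#' @param duration_s Cycle duration; default just past the last frame.
#' @return A `blink_cycle`.
#' @export
phantoms_to_cycle <- function(phantoms, duration_s = NULL) {
  frames <- lapply(phantoms, function(p) tear_frame(p$t_s, p$image))
  if (is.null(duration_s))
    duration_s <- frames[[length(frames)]]$t_s + 0.05
  blink_cycle(frames, duration_s)
}

#' Ground-truth mean LLT over a mask
#'
#' @param truth A `phantom_truth`.
#' @param mask A `roi_mask` or logical matrix.
#' @return Mean of the ground-truth thickness field over the masked
#'   pixels, nm.
#' @export
truth_mean_llt <- function(truth, mask) {
  m <- if (inherits(mask, "roi_mask")) mask$mask else mask
  if (!any(m)) stop("empty mask", call. = FALSE)
  mean(truth$llt_field[m])
}
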