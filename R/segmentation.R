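# ROI construction and maximum-entropy segmentation. The pre-segmentation
# ROI is the inferior-half corneal annulus with the central 2 placido rings
# removed; the post-segmentation ROI keeps only the bright interference
# rings, discarding the dark ring background (and dark occluders such as
# eyelashes) by Kapur entropy thresholding of the ROI luminance histogram.

#' 8-bit luminance of an RGB image
#'
#' Rec. 601 luma weights (0.299, 0.587, 0.114), rounded to integers 0--255.
#'
#' @param image Integer array `rows x cols x 3`, 0--255.
#' @return Integer matrix `rows x cols`.
#' @export
luminance <- function(image) {
  image <- validate_image(image)
  g <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  g <- round(g)
  storage.mode(g) <- "integer"
  g
}

#' Placido ring geometry
#'
#' @param center Numeric `(row, col)` of the ring pattern center, in pixel
#'   coordinates (1-based, origin top-left).
#' @param inner_exclusion_radius_px Radius (px) enclosing the central 2
#'   rings, which are excluded from analysis.
#' @param outer_radius_px Outermost analyzed radius (px).
#' @return A `ring_geometry` object.
#' @export
ring_geometry <- function(center, inner_exclusion_radius_px,
                          outer_radius_px) {
  stopifnot(length(center) == 2)
  if (!(inner_exclusion_radius_px > 0 &&
        inner_exclusion_radius_px < outer_radius_px))
    stop("need 0 < inner_exclusion_radius < outer_radius", call. = FALSE)
  structure(list(center = as.numeric(center),
                 inner_exclusion_radius_px = inner_exclusion_radius_px,
                 outer_radius_px = outer_radius_px),
            class = "ring_geometry")
}

#' Detect placido ring geometry from an image
#'
#' Automates the ROI placement that the original protocol performed by
#' hand: the center is the luminance-weighted centroid of the bright ring
#' pixels (above the image's Kapur threshold); the inner exclusion radius
#' is the outer edge of the 2nd bright ring along the radial bright-pixel
#' profile; the outer radius is the outer edge of the last ring.
#'
#' @param image Integer RGB array.
#' @param override A [ring_geometry()] returned unchanged when supplied
#'   (manual geometry is authoritative).
#' @return A `ring_geometry`.
#' @export
detect_ring_geometry <- function(image, override = NULL) {
  if (!is.null(override)) {
    stopifnot(inherits(override, "ring_geometry"))
    return(override)
  }
  image <- validate_image(image)
  g <- luminance(image)
  t <- tryCatch(kapur_threshold(as.integer(g)),
                error = function(e) stop("no ring structure found: ",
                                         conditionMessage(e), call. = FALSE))
  bright <- g > t
  if (sum(bright) < 50)
    stop("no ring structure found: too few bright pixels", call. = FALSE)
  w <- as.numeric(g) * bright
  rows <- row(g); cols <- col(g)
  cr <- sum(rows * w) / sum(w)
  cc <- sum(cols * w) / sum(w)
  r <- sqrt((rows - cr)^2 + (cols - cc)^2)
  rbin <- floor(r) + 1L
  nmax <- max(rbin)
  frac <- tapply(as.numeric(bright), rbin, mean)
  prof <- numeric(nmax)
  prof[as.integer(names(frac))] <- frac
  band <- prof > 0.5
  if (!any(band))
    stop("no ring structure found: no radial bright bands", call. = FALSE)
  runs <- rle(band)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  bright_runs <- which(runs$values)
  if (length(bright_runs) < 3)
    stop("no ring structure found: fewer than 3 rings", call. = FALSE)
  inner <- ends[bright_runs[2]]          # outer edge of 2nd bright ring
  outer <- ends[bright_runs[length(bright_runs)]]
  ring_geometry(c(cr, cc), inner, outer)
}

#' Pre-segmentation ROI: inferior half-annulus
#'
#' Pixels with radius in `(inner_exclusion, outer]` of the geometry center
#' and row at or below the center row — the inferior half of the cornea in
#' upright image coordinates — with the central 2 rings removed. The mask
#' depends only on geometry and image size, not on pixel content.
#'
#' @param image Integer RGB array (only its dimensions are used).
#' @param geometry A [ring_geometry()].
#' @return A `roi_mask`: list with logical matrix `mask`, `stage = "pre"`,
#'   and `pixel_count`.
#' @export
make_pre_roi <- function(image, geometry) {
  image <- validate_image(image)
  stopifnot(inherits(geometry, "ring_geometry"))
  h <- dim(image)[1]; w <- dim(image)[2]
  cr <- geometry$center[1]; cc <- geometry$center[2]
  if (cr < 1 || cr > h || cc < 1 || cc > w)
    stop("geometry center outside image bounds", call. = FALSE)
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  r <- sqrt((rows - cr)^2 + (cols - cc)^2)
  mask <- r > geometry$inner_exclusion_radius_px &
          r <= geometry$outer_radius_px &
          rows >= cr
  if (!any(mask))
    stop("pre-segmentation ROI is empty for this geometry", call. = FALSE)
  new_roi_mask(mask, "pre")
}

new_roi_mask <- function(mask, stage) {
  structure(list(mask = mask, stage = stage, pixel_count = sum(mask)),
            class = "roi_mask")
}

#' Kapur maximum-entropy threshold
#'
#' Threshold maximizing the sum of Shannon entropies of the background
#' (levels `0..t`) and foreground (levels `t+1..255`) partitions of the
#' normalized gray-level histogram. Ties are broken toward the smallest
#' threshold. Intended for 8-bit luminance values of ROI pixels only.
#'
#' @param gray_values Integer vector of gray levels in 0--255 with at least
#'   two distinct values.
#' @return The threshold level `t` (0--254); foreground is `gray > t`.
#' @export
kapur_threshold <- function(gray_values) {
  gray_values <- as.integer(round(gray_values))
  if (any(gray_values < 0 | gray_values > 255))
    stop("gray values must lie in [0, 255]", call. = FALSE)
  if (length(unique(gray_values)) < 2)
    stop("degenerate histogram: fewer than two distinct gray levels",
         call. = FALSE)
  p <- tabulate(gray_values + 1L, nbins = 256L) / length(gray_values)
  P <- cumsum(p)                      # background mass for t = 0..255
  plogp <- ifelse(p > 0, p * log(p), 0)
  S <- cumsum(plogp)
  Stot <- S[256]
  t_cand <- 0:254
  Pb <- P[t_cand + 1L]
  Pf <- 1 - Pb
  ok <- Pb > 0 & Pf > 0
  Hb <- ifelse(ok, log(Pb) - S[t_cand + 1L] / Pb, -Inf)
  Hf <- ifelse(ok, log(Pf) - (Stot - S[t_cand + 1L]) / Pf, -Inf)
  H <- Hb + Hf
  t_cand[which.max(H)]               # which.max -> first max = smallest t
}

#' Post-segmentation ROI: bright ring pixels
#'
#' Restricts a pre-segmentation ROI to its bright ring pixels: luminance
#' strictly above the Kapur threshold computed from the pre-ROI pixel
#' population. Removes the dark placido ring background and dark occluders
#' (eyelashes). Always a subset of the pre-ROI.
#'
#' @param image Integer RGB array.
#' @param pre_roi The matching `roi_mask` with `stage = "pre"`.
#' @return A `roi_mask` with `stage = "post"`.
#' @export
make_post_roi <- function(image, pre_roi) {
  image <- validate_image(image)
  stopifnot(inherits(pre_roi, "roi_mask"))
  if (pre_roi$stage != "pre")
    stop("post-segmentation requires a pre-stage ROI", call. = FALSE)
  if (pre_roi$pixel_count == 0)
    stop("pre-segmentation ROI is empty", call. = FALSE)
  g <- luminance(image)
  t <- kapur_threshold(g[pre_roi$mask])
  mask <- pre_roi$mask & g > t
  new_roi_mask(mask, "post")
}
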