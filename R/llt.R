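# Per-pixel LLT estimation. Each ROI pixel's 8-bit (r, g, b) is matched to
# the look-up table reference point minimizing the Euclidean RGB distance
# sqrt((r - R_j)^2 + (g - G_j)^2 + (b - B_j)^2); the pixel's LLT is that of
# the matched reference point. Distances are taken on the gamma-encoded
# 8-bit values, matching the 8-bit split of the ROI image in the protocol.

#' Nearest-reference-color LLT of a single pixel
#'
#' @param color Numeric triple `(r, g, b)` with channels in 0--255.
#' @param table A `lookup_table`.
#' @return The `llt_nm` of the reference point at minimal Euclidean RGB
#'   distance; ties resolve to the smallest thickness.
#' @export
nearest_llt <- function(color, table) {
  stopifnot(length(color) == 3)
  if (any(color < 0 | color > 255))
    stop("color channels must lie in [0, 255]", call. = FALSE)
  validate_lookup_table(table)
  drop(lookup_llt(matrix(color, nrow = 1), table))
}

# Vectorized nearest-neighbor lookup: colors is n x 3, table sorted by
# ascending llt_nm so the first minimum is the smallest thickness.
# Exactly equivalent to a per-pixel linear scan.
lookup_llt <- function(colors, table) {
  ref <- as.matrix(table[c("R", "G", "B")])
  llt <- table$llt_nm
  n <- nrow(colors)
  out <- numeric(n)
  ref_sq <- rowSums(ref^2)
  chunk <- 20000L
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    x <- colors[s:e, , drop = FALSE]
    # squared distance = |x|^2 - 2 x.ref + |ref|^2; |x|^2 constant per row
    d2 <- sweep(-2 * x %*% t(ref), 2, ref_sq, "+")
    out[s:e] <- llt[max.col(-d2, ties.method = "first")]
  }
  out
}

#' Per-pixel LLT map over an ROI
#'
#' @param frame A [tear_frame()] or a raw RGB image array.
#' @param roi A non-empty `roi_mask` congruent with the image.
#' @param table A `lookup_table`.
#' @return An `llt_map`: list with numeric matrix `values` (NA outside the
#'   mask), the `mask`, and `t_s` (NA for a raw image).
#' @export
estimate_llt_map <- function(frame, roi, table) {
  if (inherits(frame, "tear_frame")) {
    image <- frame$image; t_s <- frame$t_s
  } else {
    image <- validate_image(frame); t_s <- NA_real_
  }
  stopifnot(inherits(roi, "roi_mask"))
  if (!identical(dim(roi$mask), dim(image)[1:2]))
    stop("ROI mask not congruent with the image", call. = FALSE)
  if (roi$pixel_count == 0) stop("empty ROI", call. = FALSE)
  validate_lookup_table(table)
  idx <- which(roi$mask)
  colors <- cbind(image[, , 1][idx], image[, , 2][idx], image[, , 3][idx])
  vals <- lookup_llt(colors, table)
  values <- matrix(NA_real_, nrow(roi$mask), ncol(roi$mask))
  values[idx] <- vals
  structure(list(values = values, mask = roi, t_s = t_s),
            class = "llt_map")
}

#' ROI-average LLT
#'
#' The arithmetic mean of the per-pixel LLTs over the ROI: the sum of LLT
#' at every masked pixel divided by the ROI pixel count.
#'
#' @param map An `llt_map`.
#' @return An `llt_summary`: list with `mean_llt_nm`, `pixel_count`,
#'   `stage`, `t_s`.
#' @export
average_llt <- function(map) {
  stopifnot(inherits(map, "llt_map"))
  vals <- map$values[map$mask$mask]
  if (length(vals) == 0) stop("empty ROI", call. = FALSE)
  structure(list(mean_llt_nm = mean(vals),
                 pixel_count = length(vals),
                 stage = map$mask$stage,
                 t_s = map$t_s),
            class = "llt_summary")
}

#' Serial LLT over a blink cycle
#'
#' Decomposes the cycle at the requested timepoints (default the 0--2 s
#' window at 0.05-s intervals, 41 frames) and returns one ROI-average LLT
#' per frame for the requested segmentation stage. The ring geometry is
#' detected once, from the first decomposed frame, and reused for every
#' frame — one ROI selection per cycle, as in the manual protocol.
#'
#' @param cycle A `blink_cycle` (or frame directory path).
#' @param geometry Optional [ring_geometry()] override.
#' @param table A `lookup_table`.
#' @param stage `"pre"` or `"post"`.
#' @param timepoints_s Frame times in seconds (default `seq(0, 2, 0.05)`).
#' @return List of `llt_summary`, one per timepoint.
#' @export
llt_timeseries <- function(cycle, geometry = NULL, table,
                           stage = c("post", "pre"),
                           timepoints_s = seq(0, 2, by = 0.05)) {
  stage <- match.arg(stage)
  frames <- if (is.list(cycle) && !inherits(cycle, "blink_cycle")) cycle
            else decompose(cycle,
                           t_start_s = min(timepoints_s),
                           t_end_s = max(timepoints_s),
                           interval_s = if (length(timepoints_s) > 1)
                             min(diff(sort(timepoints_s))) else 0.05)
  frames <- Filter(function(f)
    any(abs(f$t_s - timepoints_s) < 1e-6), frames)
  if (is.null(geometry))
    geometry <- detect_ring_geometry(frames[[1]]$image)
  lapply(frames, function(f) {
    tryCatch({
      pre <- make_pre_roi(f$image, geometry)
      roi <- if (stage == "post") make_post_roi(f$image, pre) else pre
      m <- estimate_llt_map(f, roi, table)
      average_llt(m)
    }, error = function(e)
      stop(sprintf("frame t=%.2f s: %s", f$t_s, conditionMessage(e)),
           call. = FALSE))
  })
}

#' Summaries as a data frame
#'
#' @param summaries List of `llt_summary`.
#' @return Data frame with columns `t_s`, `stage`, `mean_llt_nm`,
#'   `pixel_count`.
#' @export
summaries_df <- function(summaries) {
  data.frame(
    t_s = vapply(summaries, `[[`, numeric(1), "t_s"),
    stage = vapply(summaries, `[[`, character(1), "stage"),
    mean_llt_nm = vapply(summaries, `[[`, numeric(1), "mean_llt_nm"),
    pixel_count = vapply(summaries, `[[`, numeric(1), "pixel_count")
  )
}
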