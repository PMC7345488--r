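# Frame sequences and blink-cycle handling. A frame is a timestamped 8-bit
# RGB image; a blink cycle is the ordered frame sequence from one eye
# opening (t = 0) to the next blink. Frame directories with a manifest.csv
# (columns filename,t_s) are the on-disk exchange format.

#' Construct a timestamped frame
#'
#' @param t_s Time in seconds relative to eye opening (>= 0 within a
#'   qualified cycle).
#' @param image Integer array `rows x cols x 3`, channel values 0--255,
#'   row-major with origin at the top-left (row 1 is the superior edge).
#' @return A `tear_frame` object.
#' @export
tear_frame <- function(t_s, image) {
  stopifnot(is.numeric(t_s), length(t_s) == 1)
  image <- validate_image(image)
  structure(list(t_s = as.numeric(t_s), image = image),
            class = "tear_frame")
}

validate_image <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3 || dim(image)[3] != 3)
    stop("image must be a rows x cols x 3 array", call. = FALSE)
  if (any(dim(image)[1:2] == 0))
    stop("image must be non-empty", call. = FALSE)
  if (any(image < 0 | image > 255))
    stop("image channels must lie in [0, 255]", call. = FALSE)
  storage.mode(image) <- "integer"
  image
}

#' Construct a blink cycle from frames
#'
#' @param frames List of [tear_frame()] objects with strictly increasing
#'   timestamps.
#' @param duration_s Seconds from eye opening to the next blink; defaults
#'   to the last frame time.
#' @return A `blink_cycle` object.
#' @export
blink_cycle <- function(frames, duration_s = NULL) {
  if (length(frames) == 0) stop("cycle needs at least one frame", call. = FALSE)
  times <- vapply(frames, function(f) f$t_s, numeric(1))
  if (any(diff(times) <= 0))
    stop("frame times must be strictly increasing", call. = FALSE)
  if (is.null(duration_s)) duration_s <- times[length(times)]
  if (duration_s <= 0) stop("duration must be positive", call. = FALSE)
  structure(list(frames = frames, duration_s = as.numeric(duration_s),
                 qualification = NULL),
            class = "blink_cycle")
}

frame_times <- function(cycle) {
  vapply(cycle$frames, function(f) f$t_s, numeric(1))
}

#' Decompose a source into frames at fixed intervals
#'
#' Emulates the standard examination protocol: the qualified blink cycle is
#' decomposed at a fixed time interval (0.05 s by default elsewhere in the
#' pipeline), each target time taking the source frame whose timestamp is
#' nearest. The frame count is `floor((t_end - t_start)/interval) + 1`;
#' 0--2 s at 0.05 s yields 41 frames.
#'
#' @param source A `blink_cycle`, or the path to a frame directory
#'   containing PNG frames and a `manifest.csv` with columns
#'   `filename,t_s`. Video containers are not decoded; extract frames to a
#'   directory first (see the package vignette).
#' @param t_start_s,t_end_s Window in seconds, `t_end_s >= t_start_s`.
#' @param interval_s Positive sampling interval in seconds.
#' @return List of [tear_frame()] at the target times.
#' @export
decompose <- function(source, t_start_s = 0, t_end_s = 2, interval_s = 0.05) {
  if (t_end_s < t_start_s) stop("t_end must be >= t_start", call. = FALSE)
  if (interval_s <= 0) stop("interval must be positive", call. = FALSE)
  cycle <- as_cycle_source(source)
  times <- frame_times(cycle)
  n <- floor((t_end_s - t_start_s) / interval_s + 1e-9) + 1
  targets <- t_start_s + interval_s * (seq_len(n) - 1)
  if (max(targets) > max(times) + interval_s / 2) {
    missing <- targets[targets > max(times) + interval_s / 2]
    stop("source ends at ", max(times), " s; missing timepoints: ",
         paste(signif(missing, 4), collapse = ", "), call. = FALSE)
  }
  lapply(targets, function(tt) {
    i <- which.min(abs(times - tt))
    tear_frame(tt, cycle$frames[[i]]$image)
  })
}

as_cycle_source <- function(source) {
  if (inherits(source, "blink_cycle")) return(source)
  if (is.character(source) && length(source) == 1) {
    if (dir.exists(source)) return(read_frame_dir(source))
    if (grepl("\\.(mp4|avi|mov|mkv)$", source, ignore.case = TRUE))
      stop("video containers are not decoded by this package; extract ",
           "frames to a PNG directory with a manifest.csv first",
           call. = FALSE)
    stop("unreadable source: ", source, call. = FALSE)
  }
  stop("source must be a blink_cycle or a frame directory path",
       call. = FALSE)
}

#' Read or write a frame directory
#'
#' A frame directory holds one PNG per frame plus `manifest.csv`
#' (`filename,t_s`). Written frames are named `frame_<t_ms>.png`.
#'
#' @param path Directory path.
#' @param frames List of [tear_frame()].
#' @return `read_frame_dir()` returns a `blink_cycle`; `write_frame_dir()`
#'   returns `path` invisibly.
#' @export
read_frame_dir <- function(path) {
  manifest <- file.path(path, "manifest.csv")
  if (!file.exists(manifest))
    stop("no manifest.csv in ", path, call. = FALSE)
  man <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  if (!all(c("filename", "t_s") %in% names(man)))
    stop("manifest needs columns filename,t_s", call. = FALSE)
  man <- man[order(man$t_s), ]
  frames <- lapply(seq_len(nrow(man)), function(i) {
    img <- png::readPNG(file.path(path, man$filename[i]))
    tear_frame(man$t_s[i], png_to_image8(img))
  })
  blink_cycle(frames)
}

#' @rdname read_frame_dir
#' @export
write_frame_dir <- function(frames, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  fn <- vapply(frames, function(f)
    sprintf("frame_%04d.png", round(f$t_s * 1000)), character(1))
  for (i in seq_along(frames))
    png::writePNG(image8_to_png(frames[[i]]$image), file.path(path, fn[i]))
  man <- data.frame(filename = fn,
                    t_s = vapply(frames, function(f) f$t_s, numeric(1)))
  utils::write.csv(man, file.path(path, "manifest.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

png_to_image8 <- function(img) {
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  arr <- round(img * 255)
  storage.mode(arr) <- "integer"
  arr
}

image8_to_png <- function(image) {
  arr <- image / 255
  storage.mode(arr) <- "double"
  arr
}

#' Qualify a blink cycle for analysis
#'
#' Applies the selection criteria for an analyzable opening blink cycle:
#' (1) optional sharpness floor (variance of the luminance Laplacian; off by
#' default because the original criterion is an examiner's visual
#' judgment), (2) the inferior-half placido ring reflection must stay
#' visible in every frame (bright-pixel coverage of the pre-segmentation
#' ROI never below `ring_coverage_floor`), and (3) the cycle duration must
#' be strictly greater than `min_duration_s` (2 s).
#'
#' @param cycle A `blink_cycle`.
#' @param config List of options: `min_duration_s` (default 2),
#'   `ring_coverage_floor` (default 0.1), `sharpness_floor` (default
#'   `NULL`, disabled), `geometry` (a [ring_geometry()]; detected from the
#'   first frame when `NULL`).
#' @return List with logical elements `duration`, `ring_visibility`,
#'   `focus` (NA when disabled), and `pass`.
#' @export
qualify_cycle <- function(cycle, config = list()) {
  stopifnot(inherits(cycle, "blink_cycle"))
  min_dur <- config$min_duration_s %||% 2
  floor_cov <- config$ring_coverage_floor %||% 0.1
  sharp_floor <- config$sharpness_floor
  dur_ok <- cycle$duration_s > min_dur
  geom <- config$geometry
  vis_ok <- tryCatch({
    if (is.null(geom)) geom <- detect_ring_geometry(cycle$frames[[1]]$image)
    cov <- vapply(cycle$frames, function(f)
      ring_coverage(f$image, geom), numeric(1))
    all(cov >= floor_cov)
  }, error = function(e) FALSE)
  focus_ok <- NA
  if (!is.null(sharp_floor)) {
    sharp <- vapply(cycle$frames, function(f)
      laplacian_sharpness(f$image), numeric(1))
    focus_ok <- all(sharp >= sharp_floor)
  }
  pass <- dur_ok && vis_ok && (is.na(focus_ok) || focus_ok)
  list(duration = dur_ok, ring_visibility = vis_ok, focus = focus_ok,
       pass = pass)
}

# Fraction of pre-ROI pixels above the frame's Kapur threshold.
ring_coverage <- function(image, geometry) {
  roi <- make_pre_roi(image, geometry)
  lum <- luminance(image)[roi$mask]
  t <- tryCatch(kapur_threshold(lum), error = function(e) return(NA_real_))
  if (is.na(t)) return(0)
  mean(lum > t)
}

# Variance of a 4-neighbor Laplacian of the luminance; a standard focus proxy.
laplacian_sharpness <- function(image) {
  g <- luminance(image)
  h <- nrow(g); w <- ncol(g)
  if (h < 3 || w < 3) return(0)
  core <- g[2:(h - 1), 2:(w - 1)]
  lap <- g[1:(h - 2), 2:(w - 1)] + g[3:h, 2:(w - 1)] +
         g[2:(h - 1), 1:(w - 2)] + g[2:(h - 1), 3:w] - 4 * core
  stats::var(as.numeric(lap))
}

#' Select the first qualified blink cycle
#'
#' Returns the earliest cycle passing all enabled criteria, after skipping
#' a configurable number of initial cycles (the initial blink cycles of an
#' examination are conventionally excluded; default skip 1).
#'
#' @param cycles List of `blink_cycle` objects in recording order.
#' @param config Passed to [qualify_cycle()].
#' @param skip_initial Number of leading cycles to skip (default 1).
#' @return The selected `blink_cycle`, with its qualification attached.
#' @export
select_first_qualified <- function(cycles, config = list(),
                                   skip_initial = 1) {
  if (length(cycles) == 0) stop("no cycles supplied", call. = FALSE)
  results <- lapply(cycles, qualify_cycle, config = config)
  eligible <- seq_along(cycles) > skip_initial
  pass <- vapply(results, `[[`, logical(1), "pass") & eligible
  if (!any(pass)) {
    msgs <- vapply(seq_along(cycles), function(i) {
      r <- results[[i]]
      sprintf("cycle %d: duration=%s visibility=%s%s", i,
              r$duration, r$ring_visibility,
              if (!eligible[i]) " (skipped: initial cycle)" else "")
    }, character(1))
    stop("no qualifying blink cycle:\n", paste(msgs, collapse = "\n"),
         call. = FALSE)
  }
  i <- which(pass)[1]
  out <- cycles[[i]]
  out$qualification <- results[[i]]
  out
}

#' Detect the eye-opening frame (t = 0)
#'
#' Heuristic opening detector: the first frame whose inferior-half
#' bright-ring coverage rises to `coverage_floor` or above after at least
#' one frame below it (the lid occludes the rings while closed). A manual
#' index override is authoritative when supplied.
#'
#' @param frames List of [tear_frame()].
#' @param geometry A [ring_geometry()]; detected from the last frame when
#'   `NULL` (the eye is most open late in a cycle).
#' @param coverage_floor Minimum bright-pixel coverage (default 0.1).
#' @param override Optional frame index to return unchanged.
#' @return Index of the opening frame.
#' @export
detect_eye_opening <- function(frames, geometry = NULL,
                               coverage_floor = 0.1, override = NULL) {
  if (!is.null(override)) return(override)
  if (length(frames) == 0) stop("no frames", call. = FALSE)
  if (is.null(geometry))
    geometry <- detect_ring_geometry(frames[[length(frames)]]$image)
  cov <- vapply(frames, function(f)
    ring_coverage(f$image, geometry), numeric(1))
  below <- cov < coverage_floor
  idx <- which(!below & c(TRUE, below[-length(below)]))
  idx <- idx[idx > 1 | !any(below)]
  if (length(idx) == 0) {
    if (!below[1]) return(1L)  # already open throughout
    stop("no opening transition found", call. = FALSE)
  }
  idx[1]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
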