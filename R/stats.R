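# Statistical layer: the per-timepoint linear transform predicting
# post-segmentation LLT from pre-segmentation LLT, plus the reliability and
# comparison statistics (Pearson r, paired t, ICC(2,1)) used to validate
# the quantification method.

#' Linear pre-to-post segmentation transform
#'
#' A per-timepoint linear model `transformed = slope * pre + intercept`
#' predicting the post-segmentation LLT from the pre-segmentation LLT, so
#' the representative LLT can be read off without running segmentation.
#'
#' @param t_s Timepoint in seconds the model applies to.
#' @param slope Dimensionless slope.
#' @param intercept Intercept in nm.
#' @param source `"fitted"`, `"paper-fixed"` or `"simplified"`.
#' @return A `transform_model` object.
#' @export
transform_model <- function(t_s, slope, intercept,
                            source = "fitted") {
  if (!is.finite(slope) || !is.finite(intercept))
    stop("slope and intercept must be finite", call. = FALSE)
  structure(list(t_s = t_s, slope = slope, intercept = intercept,
                 source = source),
            class = "transform_model")
}

#' Reference transform models for the 0.5 / 1.0 / 2.0 s timepoints
#'
#' The published per-timepoint coefficients for a Keratograph 5M-style
#' analyzer: slope 0.65, intercept 8.73 nm at 0.5 s; 0.58, 11.27 nm at
#' 1.0 s; 0.55, 11.01 nm at 2.0 s. With `simplified = TRUE`, the single
#' rounded rule `0.6 * pre + 10` is returned for all three timepoints.
#'
#' @param simplified Use the simplified common model (default `FALSE`).
#' @return Named list of [transform_model()] keyed by `"0.5"`, `"1"`, `"2"`.
#' @export
k5m_transforms <- function(simplified = FALSE) {
  if (simplified) {
    tp <- c(0.5, 1, 2)
    out <- lapply(tp, function(t)
      transform_model(t, 0.6, 10, source = "simplified"))
  } else {
    out <- list(transform_model(0.5, 0.65, 8.73, source = "paper-fixed"),
                transform_model(1.0, 0.58, 11.27, source = "paper-fixed"),
                transform_model(2.0, 0.55, 11.01, source = "paper-fixed"))
  }
  names(out) <- c("0.5", "1", "2")
  out
}

#' Apply a pre-to-post transform
#'
#' @param pre_llt_nm Pre-segmentation LLT (nm), vectorized.
#' @param model A [transform_model()].
#' @return `slope * pre + intercept` in nm.
#' @export
apply_transform <- function(pre_llt_nm, model) {
  stopifnot(inherits(model, "transform_model"))
  model$slope * pre_llt_nm + model$intercept
}

#' Fit the pre-to-post transform by ordinary least squares
#'
#' @param pre_values,post_values Paired pre-/post-segmentation LLTs (nm),
#'   equal length >= 3, predictor non-constant.
#' @param t_s Timepoint label for the fitted model.
#' @return A [transform_model()] with `source = "fitted"`.
#' @export
fit_transform <- function(pre_values, post_values, t_s = NA_real_) {
  if (length(pre_values) != length(post_values))
    stop("pre and post must have equal length", call. = FALSE)
  if (length(pre_values) < 3)
    stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(pre_values) == 0)
    stop("singular fit: constant predictor", call. = FALSE)
  fit <- stats::lm(post_values ~ pre_values)
  co <- stats::coef(fit)
  transform_model(t_s, slope = unname(co[2]), intercept = unname(co[1]),
                  source = "fitted")
}

#' Pearson correlation with two-tailed p-value
#'
#' @param x,y Equal-length numeric vectors (>= 3), both non-constant.
#' @return List with `r`, `p_value`, `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("unequal lengths", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate correlation: constant input", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson",
                        alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Paired t-test on two measurement series
#'
#' Two-tailed paired t-test on the differences `a - b`.
#'
#' @param a,b Equal-length numeric vectors (>= 2 pairs) whose differences
#'   are not all identical.
#' @return A `paired_comparison`: list with `mean_a`, `mean_b`, `t_stat`,
#'   `p_value`, `df`, `n`.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b)) stop("unequal lengths", call. = FALSE)
  if (length(a) < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- a - b
  if (stats::sd(d) == 0)
    stop("degenerate test: zero-variance differences", call. = FALSE)
  tt <- stats::t.test(a, b, paired = TRUE, alternative = "two.sided")
  structure(list(mean_a = mean(a), mean_b = mean(b),
                 t_stat = unname(tt$statistic),
                 p_value = tt$p.value,
                 df = unname(tt$parameter), n = length(a)),
            class = "paired_comparison")
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measure intraclass
#' correlation from the two-way ANOVA decomposition of an `n x k` ratings
#' matrix (rows = subjects, columns = raters/replicates):
#' \deqn{ICC(2,1) = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E +
#'   \frac{k}{n}(MS_C - MS_E)}}
#' where \eqn{MS_R}, \eqn{MS_C}, \eqn{MS_E} are the subject, rater and
#' residual mean squares.
#'
#' @param ratings Numeric matrix, `n >= 2` subjects by `k >= 2` raters, no
#'   missing cells.
#' @return A `reliability_result`: list with `icc`, `model = "ICC(2,1)"`,
#'   `n_subjects`, `n_raters` and the mean squares.
#' @export
icc <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (anyNA(ratings))
    stop("incomplete design: missing cells", call. = FALSE)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2 || k < 2)
    stop("need >= 2 subjects and >= 2 raters", call. = FALSE)
  grand <- mean(ratings)
  row_m <- rowMeans(ratings)
  col_m <- colMeans(ratings)
  ss_r <- k * sum((row_m - grand)^2)
  ss_c <- n * sum((col_m - grand)^2)
  ss_t <- sum((ratings - grand)^2)
  ss_e <- ss_t - ss_r - ss_c
  ms_r <- ss_r / (n - 1)
  ms_c <- ss_c / (k - 1)
  ms_e <- ss_e / ((n - 1) * (k - 1))
  denom <- ms_r + (k - 1) * ms_e + (k / n) * (ms_c - ms_e)
  val <- if (denom == 0) 1 else (ms_r - ms_e) / denom
  structure(list(icc = val, model = "ICC(2,1)",
                 n_subjects = n, n_raters = k,
                 ms = c(subjects = ms_r, raters = ms_c, error = ms_e)),
            class = "reliability_result")
}

#' Reliability report across replicate runs
#'
#' Computes the test-retest ICC(2,1) of mean LLT for each replicate kind
#' (e.g. repeated ROI selections, consecutive blink cycles) at each
#' timepoint, from a long-format table of replicate measurements.
#'
#' @param llt_runs Data frame with columns `subject_id`, `t_s`, `kind`
#'   (replicate kind, e.g. `"roi"` / `"blink"`), `replicate` (1, 2, ...)
#'   and `mean_llt_nm`.
#' @param timepoints_s Timepoints to report (default `c(0.5, 1, 2)` s).
#' @return Data frame with columns `kind`, `t_s`, `icc`, `n_subjects`,
#'   `n_raters`.
#' @export
reliability_report <- function(llt_runs, timepoints_s = c(0.5, 1, 2)) {
  need <- c("subject_id", "t_s", "kind", "replicate", "mean_llt_nm")
  if (!all(need %in% names(llt_runs)))
    stop("llt_runs needs columns ", paste(need, collapse = ","),
         call. = FALSE)
  out <- list()
  for (kd in unique(llt_runs$kind)) {
    for (tp in timepoints_s) {
      sub <- llt_runs[llt_runs$kind == kd &
                      abs(llt_runs$t_s - tp) < 1e-9, ]
      wide <- stats::reshape(
        sub[c("subject_id", "replicate", "mean_llt_nm")],
        idvar = "subject_id", timevar = "replicate",
        direction = "wide")
      mat <- as.matrix(wide[-1])
      if (nrow(mat) < 2 || ncol(mat) < 2 || anyNA(mat))
        stop(sprintf(
          "incomplete design for kind '%s' at t=%g s (need >= 2 subjects with all replicates)",
          kd, tp), call. = FALSE)
      r <- icc(mat)
      out[[length(out) + 1]] <- data.frame(
        kind = kd, t_s = tp, icc = r$icc,
        n_subjects = r$n_subjects, n_raters = r$n_raters)
    }
  }
  do.call(rbind, out)
}
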