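# End-to-end orchestration: decompose -> qualify -> ROI -> segmentation ->
# per-pixel look-up -> ROI averages -> transform, with CSV reporting, plus
# the before/after-lubrication comparison and the reliability workflow.

#' Run the LLT estimation pipeline on one blink cycle
#'
#' Executes the full quantification chain at the configured timepoints and
#' returns a tidy report with pre- and post-segmentation ROI-average LLT
#' and the transformed LLT (the post-segmentation prediction computed from
#' the pre-segmentation value).
#'
#' @param config List with elements:
#'   \describe{
#'     \item{input}{A `blink_cycle` or frame-directory path.}
#'     \item{table}{A `lookup_table`, or a path to a look-up CSV.}
#'     \item{subject_id}{Identifier recorded in the report (default
#'       `"subject1"`).}
#'     \item{timepoints_s}{Timepoints in seconds on the 0.05-s grid within
#'       0--2 s (default `c(0.5, 1, 2)`).}
#'     \item{stages}{Character subset of `c("pre", "post")` (default
#'       both).}
#'     \item{transform}{`"paper"` (per-timepoint reference coefficients),
#'       `"simplified"` (0.6 x pre + 10), `"fitted"` models supplied as a
#'       named list like [k5m_transforms()], or `NULL` to skip.}
#'     \item{geometry}{Optional [ring_geometry()] override.}
#'     \item{output_csv}{Optional path; the report is written there.}
#'   }
#' @return Data frame with columns `subject_id`, `t_s`, `stage`,
#'   `mean_llt_nm`, `pixel_count`, `transform_source`,
#'   `transformed_llt_nm` (transform columns are filled on `"pre"` rows).
#' @export
run_estimate <- function(config) {
  if (is.null(config$input)) stop("config$input is required", call. = FALSE)
  table <- config$table
  if (is.character(table)) table <- read_lookup_table(table)
  if (is.null(table)) stop("config$table is required", call. = FALSE)
  tp <- config$timepoints_s %||% c(0.5, 1, 2)
  if (any(tp < 0 | tp > 2) ||
      any(abs(tp / 0.05 - round(tp / 0.05)) > 1e-9))
    stop("timepoints must lie in [0, 2] s on the 0.05-s grid",
         call. = FALSE)
  stages <- config$stages %||% c("pre", "post")
  subject <- config$subject_id %||% "subject1"
  models <- resolve_transforms(config$transform %||% "paper")
  rows <- list()
  for (st in stages) {
    ss <- llt_timeseries(config$input, geometry = config$geometry,
                         table = table, stage = st, timepoints_s = tp)
    df <- summaries_df(ss)
    df$subject_id <- subject
    df$transform_source <- NA_character_
    df$transformed_llt_nm <- NA_real_
    if (st == "pre" && !is.null(models)) {
      for (i in seq_len(nrow(df))) {
        m <- models[[as.character(df$t_s[i])]]
        if (!is.null(m)) {
          df$transform_source[i] <- m$source
          df$transformed_llt_nm[i] <- apply_transform(df$mean_llt_nm[i], m)
        }
      }
    }
    rows[[st]] <- df
  }
  report <- do.call(rbind, rows)
  report <- report[c("subject_id", "t_s", "stage", "mean_llt_nm",
                     "pixel_count", "transform_source",
                     "transformed_llt_nm")]
  rownames(report) <- NULL
  if (!is.null(config$output_csv))
    utils::write.csv(report, config$output_csv, row.names = FALSE,
                     quote = FALSE)
  report
}

resolve_transforms <- function(transform) {
  if (is.null(transform)) return(NULL)
  if (is.list(transform) && !inherits(transform, "transform_model"))
    return(transform)
  if (inherits(transform, "transform_model")) {
    out <- list(transform)
    names(out) <- as.character(transform$t_s)
    return(out)
  }
  switch(transform,
    paper = k5m_transforms(),
    simplified = k5m_transforms(simplified = TRUE),
    none = NULL,
    stop("unknown transform: ", transform, call. = FALSE))
}

#' Compare LLT before and after lubricant instillation
#'
#' Paired t-test at each timepoint on the transformed LLT (pre-segmentation
#' values passed through the per-timepoint transform), paired by subject
#' id, plus the per-subject delta table.
#'
#' @param report_before,report_after Reports from [run_estimate()] (rows
#'   from several subjects may be concatenated). Subject sets must match.
#' @param timepoints_s Timepoints to compare (default `c(0.5, 1, 2)`).
#' @return List with `tests` (data frame: `t_s`, `mean_before`,
#'   `mean_after`, `t_stat`, `p_value`, `n`) and `deltas` (data frame:
#'   `subject_id`, `t_s`, `delta_llt_nm`).
#' @export
compare_lubrication <- function(report_before, report_after,
                                timepoints_s = c(0.5, 1, 2)) {
  pick <- function(rep) {
    rows <- rep[rep$stage == "pre" & !is.na(rep$transformed_llt_nm), ]
    rows[c("subject_id", "t_s", "transformed_llt_nm")]
  }
  b <- pick(report_before); a <- pick(report_after)
  sb <- unique(b$subject_id); sa <- unique(a$subject_id)
  if (!setequal(sb, sa))
    stop("subject sets differ: only-before = {",
         paste(setdiff(sb, sa), collapse = ","), "}, only-after = {",
         paste(setdiff(sa, sb), collapse = ","), "}", call. = FALSE)
  tests <- list(); deltas <- list()
  for (tp in timepoints_s) {
    bt <- b[abs(b$t_s - tp) < 1e-9, ]
    at <- a[abs(a$t_s - tp) < 1e-9, ]
    merged <- merge(bt, at, by = "subject_id",
                    suffixes = c("_before", "_after"))
    if (nrow(merged) < 2)
      stop("fewer than 2 paired subjects at t=", tp, " s", call. = FALSE)
    pt <- paired_t(merged$transformed_llt_nm_after,
                   merged$transformed_llt_nm_before)
    tests[[length(tests) + 1]] <- data.frame(
      t_s = tp, mean_before = pt$mean_b, mean_after = pt$mean_a,
      t_stat = pt$t_stat, p_value = pt$p_value, n = pt$n)
    deltas[[length(deltas) + 1]] <- data.frame(
      subject_id = merged$subject_id, t_s = tp,
      delta_llt_nm = merged$transformed_llt_nm_after -
        merged$transformed_llt_nm_before)
  }
  list(tests = do.call(rbind, tests), deltas = do.call(rbind, deltas))
}

#' Reliability of the quantification across replicate runs
#'
#' Assembles replicate [run_estimate()] reports into the long format
#' expected by [reliability_report()] and returns the per-kind,
#' per-timepoint ICC(2,1) table. Typical replicate kinds are `"roi"`
#' (repeated ROI selections on the same cycle) and `"blink"` (consecutive
#' opening blink cycles).
#'
#' @param runs Data frame with columns `subject_id`, `kind`, `replicate`
#'   and a report per row is inconvenient — instead supply the
#'   concatenation of reports, each augmented with `kind` and `replicate`
#'   columns; `stage` is filtered to `stage_for` first.
#' @param stage_for Stage whose mean LLT is assessed (default `"post"`).
#' @param timepoints_s Timepoints (default `c(0.5, 1, 2)`).
#' @return Data frame from [reliability_report()].
#' @export
run_reliability <- function(runs, stage_for = "post",
                            timepoints_s = c(0.5, 1, 2)) {
  need <- c("subject_id", "t_s", "stage", "mean_llt_nm", "kind",
            "replicate")
  if (!all(need %in% names(runs)))
    stop("runs needs columns ", paste(need, collapse = ","),
         call. = FALSE)
  sub <- runs[runs$stage == stage_for, ]
  reliability_report(
    sub[c("subject_id", "t_s", "kind", "replicate", "mean_llt_nm")],
    timepoints_s = timepoints_s)
}
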