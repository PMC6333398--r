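#' Build summary report tables from pipeline products
#'
#' Turns per-slice electrophysiology metrics and per-animal imaging
#' metrics into long-format summary tables keyed by grouping columns
#' (typically genotype and region). Electrophysiology is summarized as
#' median and interquartile range; imaging as mean and standard error —
#' the reporting conventions of the respective experiments. Slices that
#' failed the inclusion rule are listed in an exclusion table and do not
#' contribute to summaries.
#'
#' @param ephys Optional data.frame of per-slice values: grouping columns
#'   plus numeric metric columns; optional `accepted` (logical) and
#'   `rejection_reason` columns drive the exclusion table.
#' @param imaging Optional data.frame of per-animal values, same layout.
#' @param group_cols Character vector of grouping column names present in
#'   the inputs (default `c("genotype", "region")`).
#' @return List of class `slice_report`: `summary` (long data.frame with
#'   columns `source`, grouping columns, `metric`, `n`, `center`,
#'   `spread`, `summary_type`) and `exclusions` (data.frame of excluded
#'   ephys rows with reasons). Row order is deterministic, so rebuilding
#'   from the same inputs reproduces the tables exactly.
#' @export
build_report <- function(ephys = NULL, imaging = NULL,
                         group_cols = c("genotype", "region")) {
  if (is.null(ephys) && is.null(imaging)) {
    stop("at least one analysis product required", call. = FALSE)
  }
  summarize_block <- function(df, source, center_fun, spread_fun,
                              summary_type) {
    gc <- intersect(group_cols, names(df))
    metric_cols <- names(df)[vapply(df, is.numeric, logical(1))]
    metric_cols <- setdiff(metric_cols, gc)
    key <- if (length(gc)) {
      interaction(df[gc], drop = TRUE, lex.order = TRUE)
    } else factor(rep("all", nrow(df)))
    rows <- list()
    for (metric in sort(metric_cols)) {
      for (cell in levels(key)) {
        v <- df[[metric]][key == cell]
        v <- v[is.finite(v)]
        row <- df[key == cell, gc, drop = FALSE][1, , drop = FALSE]
        for (missing_col in setdiff(group_cols, gc)) {
          row[[missing_col]] <- NA_character_
        }
        row <- row[, group_cols, drop = FALSE]
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(source = source, stringsAsFactors = FALSE),
          row,
          data.frame(metric = metric, n = length(v),
                     center = if (length(v)) center_fun(v) else NA_real_,
                     spread = if (length(v) > 1L) spread_fun(v) else NA_real_,
                     summary_type = summary_type,
                     stringsAsFactors = FALSE))
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  }
  summary_tabs <- list()
  exclusions <- NULL
  if (!is.null(ephys)) {
    if ("accepted" %in% names(ephys)) {
      excl <- ephys[!ephys$accepted, , drop = FALSE]
      if (nrow(excl)) {
        keep_cols <- intersect(c(group_cols, "slice_id", "rejection_reason"),
                               names(excl))
        exclusions <- excl[, keep_cols, drop = FALSE]
        rownames(exclusions) <- NULL
      }
      ephys <- ephys[ephys$accepted, , drop = FALSE]
      ephys$accepted <- NULL
      ephys$rejection_reason <- NULL
    }
    if (nrow(ephys)) {
      summary_tabs$ephys <- summarize_block(
        ephys, "ephys", stats::median, stats::IQR, "median_iqr")
    }
  }
  if (!is.null(imaging) && nrow(imaging)) {
    sem <- function(v) stats::sd(v) / sqrt(length(v))
    summary_tabs$imaging <- summarize_block(
      imaging, "imaging", mean, sem, "mean_sem")
  }
  structure(
    list(summary = do.call(rbind, unname(summary_tabs)),
         exclusions = exclusions),
    class = "slice_report")
}

#' Write report tables to disk
#'
#' @param report A `slice_report` from [build_report()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly. Writes `summary.tsv` and, when any slice was
#'   excluded, `exclusions.tsv`.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "slice_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report$summary, file.path(dir, "summary.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(report$exclusions)) {
    utils::write.table(report$exclusions, file.path(dir, "exclusions.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' Write an event table as TSV
#'
#' Writes the per-event table with the canonical column order
#' `t_peak_s, t_start_s, t_end_s, amplitude_mv, duration_ms,
#' ripple_count, ripple_freq_hz, auc_mv_ms`.
#'
#' @param events Populated events from [event_metrics()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(events, path) {
  cols <- c("t_peak_s", "t_start_s", "t_end_s", "amplitude_mv",
            "duration_ms", "ripple_count", "ripple_freq_hz", "auc_mv_ms")
  utils::write.table(events[, cols], path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
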