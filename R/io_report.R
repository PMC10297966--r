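#' Write the per-arm report and genome-level summary
#'
#' The TSV mirrors the per-arm appendix layout: one row per arm, fixed
#' column order, kb and percentages to 1 decimal (CV to 3). The JSON carries
#' the genome-level summary, the ALT call, and full configuration echo.
#' Rows violating the count-partition invariant (overall != sum of
#' categories, or percentages not summing to 100) are refused.
#'
#' @param arm_table per-arm table from [arm_stats_table()].
#' @param summary a `telomap_summary`.
#' @param tsv_path,json_path output paths.
#' @param alt an optional `telomap_altcall`.
#' @param config optional list echoed into the JSON (seeds, thresholds).
#' @return invisible list of the two paths.
#' @export
write_report <- function(arm_table, summary, tsv_path, json_path,
                         alt = NULL, config = NULL) {
  validate_report_rows(arm_table)
  out <- arm_table[, REPORT_COLUMNS]
  kb_cols <- grep("_kb$", REPORT_COLUMNS, value = TRUE)
  pct_cols <- grep("_pct$", REPORT_COLUMNS, value = TRUE)
  out[kb_cols] <- lapply(out[kb_cols], round, 1)
  out[pct_cols] <- lapply(out[pct_cols], round, 1)
  out$cv <- round(out$cv, 3)
  write.table(out, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)

  payload <- list(summary = summary_as_list(summary),
                  arm_table = arm_table)
  if (!is.null(alt))
    payload$alt_call <- list(call = alt$call, n_positive = alt$n_positive,
                             flags = as.list(alt$flags),
                             thresholds = alt$thresholds)
  if (!is.null(config)) payload$config <- config
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(list(tsv = tsv_path, json = json_path))
}

summary_as_list <- function(summary) {
  x <- unclass(summary)
  x$per_arm_cvs <- as.numeric(x$per_arm_cvs)
  x
}

validate_report_rows <- function(arm_table) {
  miss <- setdiff(REPORT_COLUMNS, names(arm_table))
  if (length(miss))
    stop("report table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  with(arm_table, {
    if (any(overall_count != endtel_count + tfe_count + its_plus_count +
            its_minus_count))
      stop("consistency error: overall_count != sum of category counts",
           call. = FALSE)
    if (any(its_count != its_plus_count + its_minus_count))
      stop("consistency error: its_count != its_plus + its_minus",
           call. = FALSE)
    pct_sum <- endtel_pct + tfe_pct + its_plus_pct + its_minus_pct
    if (any(abs(pct_sum - 100) > 0.05))
      stop("consistency error: category percentages do not sum to 100",
           call. = FALSE)
  })
  invisible(TRUE)
}

#' Read back a per-arm report TSV
#' @param path file path.
#' @return data.frame in the report column layout.
#' @export
read_report <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Read back a summary JSON
#' @param path file path.
#' @return list with `summary`, `arm_table`, and (if present) `alt_call`.
#' @export
read_summary_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
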