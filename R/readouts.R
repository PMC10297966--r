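REPORT_COLUMNS <- c("arm_id", "overall_count", "endtel_count", "tfe_count",
                    "its_count", "its_plus_count", "its_minus_count",
                    "overall_mean_kb", "overall_sd_kb", "overall_max_kb",
                    "endtel_mean_kb", "endtel_sd_kb", "its_plus_mean_kb",
                    "endtel_pct", "tfe_pct", "its_pct", "its_plus_pct",
                    "its_minus_pct", "cv")

#' Per-arm readout statistics
#'
#' Counts are per sighting: a fusion whose two segments end-anchor on two
#' arms appears once under each arm, and a same-arm fusion twice under that
#' arm. Overall mean/sd pool end-telomere and fusion/ITS+ lengths with the
#' 0-kb convention for TFE and fusion/ITS-; the end-telomere mean excludes
#' TFE and ITS- (and ITS+) molecules. Standard deviations are sample (n-1)
#' deviations. The per-arm CV is overall_sd / overall_mean, reported as NA
#' when the overall mean is 0.
#'
#' @param classified_df output of [classified_table()].
#' @param arm_id the arm to summarize.
#' @return a one-row data.frame (columns as the report layout), or NULL when
#'   the arm has no sightings (unmeasurable arms are dropped).
#' @export
arm_stats <- function(classified_df, arm_id) {
  mult <- vapply(classified_df$arms, function(a) sum(a == arm_id), integer(1))
  ix <- rep(seq_len(nrow(classified_df)), mult)
  if (!length(ix)) return(NULL)
  cat <- classified_df$category[ix]
  len <- classified_df$telomere_length_kb[ix]
  n <- length(ix)
  n_end <- sum(cat == "END_TEL")
  n_tfe <- sum(cat == "TFE")
  n_itsp <- sum(cat == "FUSION_ITS_PLUS")
  n_itsm <- sum(cat == "FUSION_ITS_MINUS")
  end_len <- len[cat == "END_TEL"]
  itsp_len <- len[cat == "FUSION_ITS_PLUS"]
  mean0 <- function(x) if (length(x)) mean(x) else NA_real_
  sd1 <- function(x) if (length(x) >= 2) sd(x) else NA_real_
  overall_mean <- mean(len)
  overall_sd <- sd1(len)
  data.frame(
    arm_id = arm_id,
    overall_count = n, endtel_count = n_end, tfe_count = n_tfe,
    its_count = n_itsp + n_itsm, its_plus_count = n_itsp,
    its_minus_count = n_itsm,
    overall_mean_kb = overall_mean, overall_sd_kb = overall_sd,
    overall_max_kb = max(len),
    endtel_mean_kb = mean0(end_len), endtel_sd_kb = sd1(end_len),
    its_plus_mean_kb = mean0(itsp_len),
    endtel_pct = 100 * n_end / n, tfe_pct = 100 * n_tfe / n,
    its_pct = 100 * (n_itsp + n_itsm) / n,
    its_plus_pct = 100 * n_itsp / n, its_minus_pct = 100 * n_itsm / n,
    cv = if (!is.na(overall_sd) && overall_mean > 0)
      overall_sd / overall_mean else NA_real_)
}

#' Per-arm report table over all arms with sightings
#'
#' @param classified list of `telomap_classified` or a [classified_table()].
#' @param arms optional arm ordering (e.g. `names(reference$arms)`); default
#'   is the sorted set of arms observed.
#' @return data.frame, one row per measurable arm.
#' @export
arm_stats_table <- function(classified, arms = NULL) {
  df <- as_classified_df(classified)
  seen <- unique(unlist(df$arms))
  if (is.null(arms)) arms <- sort(seen) else arms <- intersect(arms, seen)
  out <- do.call(rbind, lapply(arms, function(a) arm_stats(df, a)))
  if (is.null(out)) out <- stats::setNames(
    data.frame(matrix(nrow = 0, ncol = length(REPORT_COLUMNS))),
    REPORT_COLUMNS)
  out
}

as_classified_df <- function(classified) {
  if (is.data.frame(classified)) classified else classified_table(classified)
}

#' Genome-wide readout summary
#'
#' Pooled over arm-anchored molecules, each counted once regardless of how
#' many arms record it: overall mean/sd/CV of telomere length (end-telomere
#' and fusion/ITS+ lengths plus 0 kb for TFE and fusion/ITS-), category
#' percentages, the percent of measured telomeres above 15 kb, the share of
#' measurable arms whose longest telomere exceeds 10 kb, per-arm CVs with
#' their median, and the ECTR count.
#'
#' @param classified list of `telomap_classified` or a [classified_table()].
#' @param arm_table optional precomputed [arm_stats_table()].
#' @return an object of class `telomap_summary`.
#' @export
genome_summary <- function(classified, arm_table = NULL) {
  df <- as_classified_df(classified)
  if (is.null(arm_table)) arm_table <- arm_stats_table(df)
  anchored <- df[df$category %in% c("END_TEL", "TFE", "FUSION_ITS_PLUS",
                                    "FUSION_ITS_MINUS"), ]
  if (!nrow(anchored))
    stop("no arm-anchored molecules to summarize", call. = FALSE)
  len <- anchored$telomere_length_kb
  cat <- anchored$category
  n <- nrow(anchored)
  measured <- len[cat %in% c("END_TEL", "FUSION_ITS_PLUS")]
  end_len <- len[cat == "END_TEL"]
  itsp_len <- len[cat == "FUSION_ITS_PLUS"]
  sd1 <- function(x) if (length(x) >= 2) sd(x) else NA_real_
  mean0 <- function(x) if (length(x)) mean(x) else NA_real_
  overall_mean <- mean(len)
  overall_sd <- sd1(len)
  pcts <- 100 * c(endtel = sum(cat == "END_TEL"), tfe = sum(cat == "TFE"),
                  its_plus = sum(cat == "FUSION_ITS_PLUS"),
                  its_minus = sum(cat == "FUSION_ITS_MINUS")) / n
  cvs <- arm_table$cv[!is.na(arm_table$cv)]
  structure(list(
    n_anchored = n,
    n_arms = nrow(arm_table),
    overall_mean_kb = overall_mean, overall_sd_kb = overall_sd,
    endtel_mean_kb = mean0(end_len), endtel_sd_kb = sd1(end_len),
    its_plus_mean_kb = mean0(itsp_len), its_plus_sd_kb = sd1(itsp_len),
    cv = if (!is.na(overall_sd) && overall_mean > 0)
      overall_sd / overall_mean else NA_real_,
    endtel_pct = unname(pcts["endtel"]), tfe_pct = unname(pcts["tfe"]),
    its_plus_pct = unname(pcts["its_plus"]),
    its_minus_pct = unname(pcts["its_minus"]),
    fusion_pct = unname(pcts["its_plus"] + pcts["its_minus"]),
    pct_gt_15kb = if (length(measured)) 100 * mean(measured > 15) else 0,
    frac_arms_max_gt_10kb = if (nrow(arm_table))
      mean(arm_table$overall_max_kb > 10) else NA_real_,
    per_arm_cvs = cvs,
    median_cv = if (length(cvs)) median(cvs) else NA_real_,
    ectr_count = sum(df$category == "ECTR"),
    unclassified_count = sum(df$category == "UNCLASSIFIED")),
    class = "telomap_summary")
}

#' @export
print.telomap_summary <- function(x, ...) {
  cat(sprintf(
    paste0("<telomap_summary: n=%d | overall %.2f +/- %.2f kb (CV %.2f) | ",
           "EndTel %.2f kb | ITS+ %.1f%% ITS- %.1f%% TFE %.1f%% | ",
           ">15 kb %.2f%% | ECTR %d>\n"),
    x$n_anchored, x$overall_mean_kb, x$overall_sd_kb, x$cv, x$endtel_mean_kb,
    x$its_plus_pct, x$its_minus_pct, x$tfe_pct, x$pct_gt_15kb, x$ectr_count))
  invisible(x)
}

#' Two-tailed unequal-variance (Welch) t-test
#'
#' Welch statistic with Welch-Satterthwaite degrees of freedom and a
#' two-tailed p-value. Degenerate samples with zero variance in both groups
#' give t = 0, p = 1 when the means agree (and t = +/-Inf, p = 0 otherwise).
#'
#' @param sample_a,sample_b numeric vectors with at least 2 finite values.
#' @return an object of class `telomap_ttest`: list(t_statistic,
#'   degrees_of_freedom, p_value_two_tailed).
#' @export
welch_t_test <- function(sample_a, sample_b) {
  sample_a <- sample_a[is.finite(sample_a)]
  sample_b <- sample_b[is.finite(sample_b)]
  if (length(sample_a) < 2 || length(sample_b) < 2)
    stop("insufficient data: each sample needs >= 2 finite values",
         call. = FALSE)
  va <- stats::var(sample_a); vb <- stats::var(sample_b)
  if (va == 0 && vb == 0) {
    d <- mean(sample_a) - mean(sample_b)
    t <- if (d == 0) 0 else sign(d) * Inf
    return(structure(list(t_statistic = t,
                          degrees_of_freedom = length(sample_a) +
                            length(sample_b) - 2,
                          p_value_two_tailed = if (d == 0) 1 else 0),
                     class = "telomap_ttest"))
  }
  tt <- t.test(sample_a, sample_b, var.equal = FALSE)
  structure(list(t_statistic = unname(tt$statistic),
                 degrees_of_freedom = unname(tt$parameter),
                 p_value_two_tailed = tt$p.value),
            class = "telomap_ttest")
}

#' @export
print.telomap_ttest <- function(x, ...) {
  cat(sprintf("<welch t = %.4f, df = %.2f, p = %.4g>\n",
              x$t_statistic, x$degrees_of_freedom, x$p_value_two_tailed))
  invisible(x)
}

COMPARE_METRICS <- c(its_plus_pct_by_arm = "its_plus_pct",
                     its_minus_pct_by_arm = "its_minus_pct",
                     tfe_pct_by_arm = "tfe_pct",
                     endtel_mean_by_arm = "endtel_mean_kb",
                     overall_max_by_arm = "overall_max_kb",
                     cv_by_arm = "cv")

#' Pairwise Welch tests of a per-arm metric between cell lines
#'
#' For each pair of cell lines the per-arm metric vectors are restricted to
#' arms analyzed in both lines (dropping arms where the metric is
#' undefined) and compared with [welch_t_test()].
#'
#' @param tables named list of per-arm report tables ([arm_stats_table()]).
#' @param metric one of `names(telomap:::COMPARE_METRICS)` or a report
#'   column name.
#' @return list with symmetric matrices `t`, `df`, `p` and the metric name.
#' @export
compare_cell_lines <- function(tables, metric = "its_plus_pct_by_arm") {
  if (length(tables) < 2)
    stop("need at least 2 cell lines to compare", call. = FALSE)
  col <- if (metric %in% names(COMPARE_METRICS)) COMPARE_METRICS[[metric]]
  else metric
  if (!col %in% REPORT_COLUMNS)
    stop("unknown metric: ", metric, call. = FALSE)
  nm <- names(tables)
  k <- length(tables)
  t_m <- df_m <- p_m <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    shared <- intersect(tables[[i]]$arm_id, tables[[j]]$arm_id)
    a <- tables[[i]][[col]][match(shared, tables[[i]]$arm_id)]
    b <- tables[[j]][[col]][match(shared, tables[[j]]$arm_id)]
    keep <- is.finite(a) & is.finite(b)
    if (sum(keep) < 2)
      stop("insufficient data: fewer than 2 shared arms for ",
           nm[i], " vs ", nm[j], call. = FALSE)
    res <- welch_t_test(a[keep], b[keep])
    t_m[i, j] <- res$t_statistic
    df_m[i, j] <- res$degrees_of_freedom
    p_m[i, j] <- res$p_value_two_tailed
  }
  list(metric = metric, t = t_m, df = df_m, p = p_m)
}

#' Thresholds for the five-readout ALT-positivity vote
#'
#' Defaults sit between the published ALT+ minima (ITS+ 8.6%, ITS- 0.5%,
#' TFE 6.3%, CV 1.1, >15 kb 1.0%) and the telomerase-positive / senescent
#' maxima (fusions and TFE absent, CV 0.8, >15 kb 0.4%); a 3-of-5 vote keeps
#' a single noisy readout from flipping the call.
#'
#' @param its_plus_pct,its_minus_pct,tfe_pct,cv,pct_gt_15kb flag thresholds.
#' @param votes flags required for an ALT_positive call.
#' @return a list of thresholds.
#' @export
alt_thresholds <- function(its_plus_pct = 1.0, its_minus_pct = 0.25,
                           tfe_pct = 1.0, cv = 1.0, pct_gt_15kb = 0.5,
                           votes = 3L) {
  list(its_plus_pct = its_plus_pct, its_minus_pct = its_minus_pct,
       tfe_pct = tfe_pct, cv = cv, pct_gt_15kb = pct_gt_15kb,
       votes = as.integer(votes))
}

#' Call ALT positivity from the five readouts
#'
#' Five flags — abundance of fusion/ITS+, fusion/ITS-, telomere-free ends,
#' super-long telomeres, and telomere-length heterogeneity (CV) — vote on
#' the telomere maintenance mechanism.
#'
#' @param summary a `telomap_summary`.
#' @param thresholds see [alt_thresholds()].
#' @return an object of class `telomap_altcall`.
#' @export
call_alt <- function(summary, thresholds = alt_thresholds()) {
  flags <- c(its_plus = summary$its_plus_pct >= thresholds$its_plus_pct,
             its_minus = summary$its_minus_pct >= thresholds$its_minus_pct,
             tfe = summary$tfe_pct >= thresholds$tfe_pct,
             cv = !is.na(summary$cv) && summary$cv >= thresholds$cv,
             super_long = summary$pct_gt_15kb >= thresholds$pct_gt_15kb)
  n_pos <- sum(flags)
  structure(list(flags = flags, thresholds = thresholds,
                 n_positive = n_pos,
                 call = if (n_pos >= thresholds$votes) "ALT_positive"
                 else "ALT_negative"),
            class = "telomap_altcall")
}

#' @export
print.telomap_altcall <- function(x, ...) {
  cat(sprintf("<telomap_altcall: %s (%d/5 flags: %s)>\n", x$call,
              x$n_positive,
              paste(names(x$flags)[x$flags], collapse = ", ")))
  invisible(x)
}
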