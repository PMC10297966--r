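#' Simulate a cell line and write its files
#'
#' Writes the molecule set (simplified BNX), the reference (simplified
#' CMAP), and the truth sidecar TSV. The seed and profile are echoed in the
#' BNX header, so every run is reproducible from its outputs.
#'
#' @param profile a `telomap_profile` or a packaged profile name.
#' @param out_dir output directory (created if needed).
#' @param seed integer seed.
#' @param reference optional `telomap_reference`; by default a fresh default
#'   reference is generated from `seed`.
#' @param noise noise model override; defaults to the profile's.
#' @param quiet suppress the per-category log.
#' @return invisible list with paths, molecules, and the reference.
#' @export
run_simulation <- function(profile, out_dir, seed = 1L, reference = NULL,
                           noise = NULL, quiet = FALSE) {
  if (is.character(profile)) profile <- profile_from_table1(profile)
  if (is.null(reference)) reference <- make_reference(seed = seed)
  if (is.null(noise)) noise <- profile$noise
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mols <- simulate_cell_line(profile, reference, seed = seed, noise = noise)
  paths <- list(bnx = file.path(out_dir, "molecules.bnx"),
                cmap = file.path(out_dir, "reference.cmap"),
                truth = file.path(out_dir, "truth.tsv"),
                profile = file.path(out_dir, "profile.yaml"))
  write_bnx(mols, paths$bnx,
            header_extra = c(profile = profile$name, seed = seed))
  write_cmap(reference, paths$cmap)
  write_truth(mols, paths$truth)
  write_profile_yaml(profile, paths$profile)
  if (!quiet) {
    tab <- table(vapply(mols, function(m) m$truth$category, character(1)))
    message(sprintf("[telomap] simulated %d molecules (%s): %s",
                    length(mols), profile$name,
                    paste(names(tab), tab, sep = "=", collapse = ", ")))
  }
  invisible(c(paths, list(molecules = mols, reference = reference)))
}

#' Run the full analysis pipeline on molecule and reference files
#'
#' align -> classify -> per-arm stats -> genome summary -> ALT call, then
#' writes the per-arm report TSV and the summary JSON.
#'
#' @param bnx_path molecules (simplified BNX).
#' @param cmap_path reference (simplified CMAP).
#' @param out_dir output directory.
#' @param align_params,params,cal,thresholds pipeline settings.
#' @param quiet suppress stage logs.
#' @return invisible list: classified table, arm table, summary, alt call,
#'   paths.
#' @export
run_analysis <- function(bnx_path, cmap_path, out_dir,
                         align_params = alignment_params(),
                         params = classify_params(),
                         cal = calibration_model(),
                         thresholds = alt_thresholds(),
                         quiet = FALSE) {
  mols <- read_bnx(bnx_path)
  if (!length(mols)) stop("empty BNX: no molecules to analyze", call. = FALSE)
  reference <- read_cmap(cmap_path)
  classified <- classify_molecules(mols, reference, align_params, params, cal)
  df <- classified_table(classified)
  arm_table <- arm_stats_table(df, arms = names(reference$arms))
  summary <- genome_summary(df, arm_table)
  alt <- call_alt(summary, thresholds)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(report = file.path(out_dir, "report.tsv"),
                json = file.path(out_dir, "summary.json"))
  write_report(arm_table, summary, paths$report, paths$json, alt = alt,
               config = list(align_params = unclass(align_params),
                             classify_params = unclass(params),
                             calibration = unclass(cal),
                             alt_thresholds = thresholds))
  if (!quiet) {
    message(sprintf(
      "[telomap] %d molecules read, %d arm-anchored, %d ECTR, %d unclassified",
      length(mols), summary$n_anchored, summary$ectr_count,
      summary$unclassified_count))
    message(sprintf("[telomap] ALT call: %s (%d/5 flags)", alt$call,
                    alt$n_positive))
  }
  invisible(list(classified = df, arm_table = arm_table, summary = summary,
                 alt = alt, paths = paths))
}

#' Pairwise cell-line comparison from report files
#'
#' @param report_paths named character vector of per-arm report TSV paths
#'   (>= 2).
#' @param metrics metrics to test (see [compare_cell_lines()]).
#' @param out_dir optional directory; one TSV matrix of p-values per metric.
#' @return invisible named list of comparison results.
#' @export
run_comparison <- function(report_paths,
                           metrics = names(COMPARE_METRICS),
                           out_dir = NULL) {
  if (length(report_paths) < 2)
    stop("need at least 2 report files", call. = FALSE)
  if (is.null(names(report_paths)) || any(!nzchar(names(report_paths))))
    names(report_paths) <- basename(report_paths)
  tables <- lapply(report_paths, read_report)
  out <- lapply(metrics, function(m) compare_cell_lines(tables, m))
  names(out) <- metrics
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (m in metrics)
      write.table(out[[m]]$p, file.path(out_dir, paste0("pvalues_", m, ".tsv")),
                  sep = "\t", quote = FALSE, col.names = NA)
  }
  invisible(out)
}
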