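#' Measurement noise model for simulated molecules
#'
#' @param sizing_sd_bp Gaussian sd of each observed nick-label position (bp).
#' @param dropout_prob per-label probability that a true nick label is missed.
#' @param false_label_rate_per_100kb Poisson rate of spurious nick labels.
#' @param intensity_cv multiplicative Gaussian coefficient of variation on
#'   telomere-label intensity.
#' @param detection_floor_kb minimum detectable telomere length in kb.
#' @return an object of class `telomap_noise`.
#' @export
noise_model <- function(sizing_sd_bp = 250, dropout_prob = 0.10,
                        false_label_rate_per_100kb = 1, intensity_cv = 0.10,
                        detection_floor_kb = 0.1) {
  if (sizing_sd_bp < 0 || false_label_rate_per_100kb < 0 || intensity_cv < 0)
    stop("noise rates must be >= 0", call. = FALSE)
  if (dropout_prob < 0 || dropout_prob >= 1)
    stop("dropout_prob must be in [0, 1)", call. = FALSE)
  if (detection_floor_kb < 0)
    stop("detection_floor_kb must be >= 0", call. = FALSE)
  structure(list(sizing_sd_bp = sizing_sd_bp, dropout_prob = dropout_prob,
                 false_label_rate_per_100kb = false_label_rate_per_100kb,
                 intensity_cv = intensity_cv,
                 detection_floor_kb = detection_floor_kb),
            class = "telomap_noise")
}

#' @rdname noise_model
#' @export
noise_off <- function(detection_floor_kb = 0.1) {
  noise_model(0, 0, 0, 0, detection_floor_kb = detection_floor_kb)
}

#' Cell-line simulation profile
#'
#' A profile fixes the category mixture over arm-anchored molecules, the
#' per-category telomere length distributions, the relative abundance of
#' extrachromosomal telomeric repeats (ECTRs), the per-arm coverage, and
#' the noise model.
#'
#' @param name profile label.
#' @param frac_endtel,frac_tfe,frac_its_plus,frac_its_minus category mixture
#'   fractions; must sum to 1 (within 1e-9).
#' @param endtel_len,its_plus_len,ectr_len `telomap_lengthdist` objects
#'   (`its_plus_len` may be NULL when `frac_its_plus == 0`).
#' @param ectr_per_100_molecules ECTR molecules emitted per 100 arm-anchored
#'   molecules.
#' @param mean_molecules_per_arm Poisson mean coverage per arm.
#' @param noise a `telomap_noise`.
#' @return an object of class `telomap_profile`.
#' @export
cell_line_profile <- function(name, frac_endtel, frac_tfe, frac_its_plus,
                              frac_its_minus, endtel_len, its_plus_len = NULL,
                              ectr_len = length_distribution(11, 9),
                              ectr_per_100_molecules = 0,
                              mean_molecules_per_arm = 30,
                              noise = noise_model()) {
  fr <- c(frac_endtel, frac_tfe, frac_its_plus, frac_its_minus)
  if (any(fr < 0) || abs(sum(fr) - 1) > 1e-9)
    stop("category fractions must be non-negative and sum to 1", call. = FALSE)
  if (frac_its_plus > 0 && is.null(its_plus_len))
    stop("its_plus_len required when frac_its_plus > 0", call. = FALSE)
  if (ectr_per_100_molecules < 0 || mean_molecules_per_arm <= 0)
    stop("rates must be positive", call. = FALSE)
  structure(
    list(name = name, frac_endtel = frac_endtel, frac_tfe = frac_tfe,
         frac_its_plus = frac_its_plus, frac_its_minus = frac_its_minus,
         endtel_len = endtel_len, its_plus_len = its_plus_len,
         ectr_len = ectr_len,
         ectr_per_100_molecules = ectr_per_100_molecules,
         mean_molecules_per_arm = mean_molecules_per_arm, noise = noise),
    class = "telomap_profile")
}

# published readouts the packaged profiles transcribe: category percentages,
# end-telomere and fusion/ITS+ length moments (kb), and the fraction of
# measured telomeres exceeding 15 kb
TABLE1 <- list(
  "U2OS"     = list(its_plus_pct = 23.1, its_minus_pct = 12.2, tfe_pct = 6.4,
                    endtel_mean = 5.0, endtel_sd = 2.2,
                    its_mean = 1.8, its_sd = 3.3, pct_gt_15kb = 4.1,
                    alt = TRUE),
  "Saos-2"   = list(its_plus_pct = 17.6, its_minus_pct = 0.5, tfe_pct = 6.3,
                    endtel_mean = 4.5, endtel_sd = 5.6,
                    its_mean = 2.7, its_sd = 3.6, pct_gt_15kb = 4.3,
                    alt = TRUE),
  "SK-MEL-2" = list(its_plus_pct = 8.6, its_minus_pct = 0.5, tfe_pct = 7.6,
                    endtel_mean = 3.5, endtel_sd = 3.9,
                    its_mean = 3.7, its_sd = 3.4, pct_gt_15kb = 1.0,
                    alt = TRUE),
  "UMUC3"    = list(its_plus_pct = 0, its_minus_pct = 0, tfe_pct = 0,
                    endtel_mean = 3.1, endtel_sd = 2.8,
                    its_mean = NA, its_sd = NA, pct_gt_15kb = 0,
                    max_kb = 15, alt = FALSE),
  "LNCaP"    = list(its_plus_pct = 0, its_minus_pct = 0, tfe_pct = 0,
                    endtel_mean = 3.2, endtel_sd = 2.1,
                    its_mean = NA, its_sd = NA, pct_gt_15kb = 0.4,
                    max_kb = 23.5, alt = FALSE),
  "IMR90-S"  = list(its_plus_pct = 0, its_minus_pct = 0, tfe_pct = 0,
                    endtel_mean = 4.0, endtel_sd = 2.6,
                    its_mean = NA, its_sd = NA, pct_gt_15kb = 0.3,
                    max_kb = 16.4, alt = FALSE))

#' Names of the packaged cell-line profiles
#' @return character vector of profile names.
#' @export
packaged_profiles <- function() names(TABLE1)

#' Build a packaged cell-line profile from the published summary readouts
#'
#' Category fractions are transcribed from the published percentages
#' (`frac_endtel` absorbs the remainder). The end-telomere length
#' distribution preserves the published mean exactly, and its super-long
#' tail weight is calibrated so that the *measured-telomere mixture*
#' (end telomeres plus fusion/ITS+ junction telomeres, weighted by their
#' category fractions) carries the published >15 kb mass; see
#' [calibrate_tail()]. ECTRs are abundant in the ALT+ profiles
#' (20 per 100 arm-anchored molecules, mean length 11 kb) and absent in the
#' telomerase-positive and senescent profiles.
#'
#' @param cell_line_name one of `packaged_profiles()` (case-insensitive).
#' @return a `telomap_profile`.
#' @export
profile_from_table1 <- function(cell_line_name) {
  idx <- match(tolower(cell_line_name), tolower(names(TABLE1)))
  if (is.na(idx))
    stop("unknown profile: ", cell_line_name, " (known: ",
         paste(names(TABLE1), collapse = ", "), ")", call. = FALSE)
  name <- names(TABLE1)[idx]
  tb <- TABLE1[[idx]]
  fp <- tb$its_plus_pct / 100
  fm <- tb$its_minus_pct / 100
  ft <- tb$tfe_pct / 100
  fe <- 1 - fp - fm - ft

  its_len <- NULL
  p_its <- 0
  if (fp > 0) {
    its_len <- length_distribution(tb$its_mean, tb$its_sd)
    p_its <- dist_p_exceed(its_len, 15)
  }
  # share of measured telomeres that are end telomeres vs ITS+ junctions
  se <- fe / (fe + fp)
  target_end <- (tb$pct_gt_15kb / 100 - (1 - se) * p_its) / se
  # telomerase-positive and senescent samples are bounded by their
  # published longest telomere; ALT tails are unbounded
  max_kb <- if (is.null(tb$max_kb)) Inf else tb$max_kb
  end_len <- length_distribution(tb$endtel_mean, tb$endtel_sd,
                                 max_kb = max_kb)
  if (target_end > 0) end_len <- calibrate_tail(end_len, target_end)

  cell_line_profile(
    name = name,
    frac_endtel = fe, frac_tfe = ft,
    frac_its_plus = fp, frac_its_minus = fm,
    endtel_len = end_len, its_plus_len = its_len,
    ectr_len = length_distribution(11, 9),
    ectr_per_100_molecules = if (tb$alt) 20 else 0,
    mean_molecules_per_arm = 30,
    noise = noise_model())
}

#' @export
print.telomap_profile <- function(x, ...) {
  cat(sprintf(
    "<telomap_profile %s: EndTel %.1f%% | TFE %.1f%% | ITS+ %.1f%% | ITS- %.1f%% | ECTR %.0f/100>\n",
    x$name, 100 * x$frac_endtel, 100 * x$frac_tfe, 100 * x$frac_its_plus,
    100 * x$frac_its_minus, x$ectr_per_100_molecules))
  invisible(x)
}

#' Serialize / restore a profile as YAML
#'
#' @param profile a `telomap_profile`.
#' @param path file path.
#' @return `read_profile_yaml` returns a `telomap_profile`.
#' @export
write_profile_yaml <- function(profile, path) {
  dist_as_list <- function(d) if (is.null(d)) NULL else unclass(d)
  x <- list(name = profile$name,
            fractions = list(endtel = profile$frac_endtel,
                             tfe = profile$frac_tfe,
                             its_plus = profile$frac_its_plus,
                             its_minus = profile$frac_its_minus),
            endtel_len = dist_as_list(profile$endtel_len),
            its_plus_len = dist_as_list(profile$its_plus_len),
            ectr_len = dist_as_list(profile$ectr_len),
            ectr_per_100_molecules = profile$ectr_per_100_molecules,
            mean_molecules_per_arm = profile$mean_molecules_per_arm,
            noise = unclass(profile$noise))
  yaml::write_yaml(x, path, precision = 12)
  invisible(path)
}

#' @rdname write_profile_yaml
#' @export
read_profile_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  as_dist <- function(l) if (is.null(l)) NULL else do.call(length_distribution, l)
  cell_line_profile(
    name = x$name,
    frac_endtel = x$fractions$endtel, frac_tfe = x$fractions$tfe,
    frac_its_plus = x$fractions$its_plus,
    frac_its_minus = x$fractions$its_minus,
    endtel_len = as_dist(x$endtel_len), its_plus_len = as_dist(x$its_plus_len),
    ectr_len = as_dist(x$ectr_len),
    ectr_per_100_molecules = x$ectr_per_100_molecules,
    mean_molecules_per_arm = x$mean_molecules_per_arm,
    noise = do.call(noise_model, x$noise))
}
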