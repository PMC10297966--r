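#' Intensity-to-length calibration model
#'
#' Telomere-label fluorescence intensity is proportional to telomere length;
#' dividing by the calibration constant recovers kb. Lengths below the
#' detection floor report 0 (undetected); lengths above the ceiling clamp.
#'
#' @param k_units_per_kb intensity per kb of telomere (> 0).
#' @param detection_floor_kb minimum detectable length (default 0.1 kb).
#' @param detection_ceiling_kb maximum reportable length (default 110 kb).
#' @return an object of class `telomap_calibration`.
#' @export
calibration_model <- function(k_units_per_kb = K_UNITS_PER_KB_DEFAULT,
                              detection_floor_kb = 0.1,
                              detection_ceiling_kb = 110) {
  if (k_units_per_kb <= 0) stop("k must be > 0", call. = FALSE)
  if (detection_floor_kb >= detection_ceiling_kb)
    stop("detection floor must be below the ceiling", call. = FALSE)
  structure(list(k_units_per_kb = k_units_per_kb,
                 detection_floor_kb = detection_floor_kb,
                 detection_ceiling_kb = detection_ceiling_kb),
            class = "telomap_calibration")
}

#' Convert a telomere cluster intensity to a length in kb
#'
#' @param cluster_intensity fluorescence units (vectorized, >= 0).
#' @param cal a `telomap_calibration`.
#' @return lengths in kb; 0 for undetected (below-floor) signal.
#' @export
estimate_telomere_length <- function(cluster_intensity,
                                     cal = calibration_model()) {
  if (any(cluster_intensity < 0))
    stop("intensity must be >= 0", call. = FALSE)
  len <- cluster_intensity / cal$k_units_per_kb
  len[len < cal$detection_floor_kb] <- 0
  pmin(len, cal$detection_ceiling_kb)
}

#' Merge telomere labels into clusters
#'
#' Labels within `cluster_gap_bp` of each other merge into one cluster whose
#' intensity is the sum of its labels.
#'
#' @param telomere_labels data.frame with `position_bp`, `intensity`,
#'   position-sorted.
#' @param cluster_gap_bp maximum gap joining two labels.
#' @return data.frame with `start_bp`, `end_bp`, `intensity`, ordered by
#'   position.
#' @export
merge_telomere_clusters <- function(telomere_labels, cluster_gap_bp = 3000) {
  if (!nrow(telomere_labels))
    return(data.frame(start_bp = numeric(0), end_bp = numeric(0),
                      intensity = numeric(0)))
  pos <- telomere_labels$position_bp
  grp <- cumsum(c(1, diff(pos) > cluster_gap_bp))
  do.call(rbind, lapply(split(seq_along(pos), grp), function(ix) {
    data.frame(start_bp = pos[ix[1]], end_bp = pos[ix[length(ix)]],
               intensity = sum(telomere_labels$intensity[ix]))
  })) -> out
  rownames(out) <- NULL
  out
}

#' Classification thresholds
#'
#' @param end_window_bp maximum distance of an alignment's distal matched
#'   reference label from the chromosome terminus for end-anchored context.
#' @param tfe_min_overhang_bp minimum unlabeled molecule overhang past the
#'   distal matched label to call a telomere-free end rather than a
#'   truncated fiber.
#' @param internal_min_flank_bp minimum molecule span distal to a telomere
#'   cluster for the telomere to count as internal (a fusion junction).
#' @param cluster_gap_bp gap merging telomere labels into one cluster.
#' @param min_partner_labels minimum nick labels in the distal continuation
#'   for a fusion call (guards against isolated spurious labels).
#' @return an object of class `telomap_classifyparams`.
#' @export
classify_params <- function(end_window_bp = 20000, tfe_min_overhang_bp = 5000,
                            internal_min_flank_bp = 10000,
                            cluster_gap_bp = 3000, min_partner_labels = 2) {
  if (end_window_bp <= 0 || tfe_min_overhang_bp <= 0 ||
      internal_min_flank_bp <= 0 || cluster_gap_bp <= 0)
    stop("thresholds must be positive", call. = FALSE)
  structure(list(end_window_bp = end_window_bp,
                 tfe_min_overhang_bp = tfe_min_overhang_bp,
                 internal_min_flank_bp = internal_min_flank_bp,
                 cluster_gap_bp = cluster_gap_bp,
                 min_partner_labels = min_partner_labels),
            class = "telomap_classifyparams")
}

# per-end call for one end-anchored aligned segment: examine the molecule
# region distal of the segment's anchor (the label matched to the arm's
# terminal reference label), in the direction the chromosome end points
classify_segment <- function(aln, mol, clusters, params, cal) {
  anchor_at_max <- aln$orientation == "forward"
  # the molecule label matched to the highest reference index
  anchor <- if (anchor_at_max) max(aln$matched_mol_pos) else min(aln$matched_mol_pos)
  if (anchor_at_max) {
    d_len <- mol$length_bp - anchor
    in_d <- function(p) p > anchor
    dist_beyond <- function(p) mol$length_bp - p
  } else {
    d_len <- anchor
    in_d <- function(p) p < anchor
    dist_beyond <- function(p) p
  }
  nicks_d <- mol$nick_labels[in_d(mol$nick_labels) &
                               !(mol$nick_labels %in% aln$matched_mol_pos)]
  cl_d <- clusters[in_d((clusters$start_bp + clusters$end_bp) / 2), ,
                   drop = FALSE]
  if (nrow(cl_d)) {
    # junction cluster: nearest to the anchor
    mid <- (cl_d$start_bp + cl_d$end_bp) / 2
    jx <- which.min(abs(mid - anchor))
    jc <- cl_d[jx, ]
    far_edge <- if (anchor_at_max) jc$end_bp else jc$start_bp
    flank <- dist_beyond(far_edge)
    n_beyond <- sum(if (anchor_at_max) nicks_d > far_edge
                    else nicks_d < far_edge)
    kb <- estimate_telomere_length(jc$intensity, cal)
    if (flank >= params$internal_min_flank_bp &&
        n_beyond >= params$min_partner_labels)
      return(list(category = "FUSION_ITS_PLUS", kb = kb))
    return(list(category = "END_TEL", kb = kb))
  }
  if (length(nicks_d) >= params$min_partner_labels &&
      d_len >= params$internal_min_flank_bp)
    return(list(category = "FUSION_ITS_MINUS", kb = 0))
  if (length(nicks_d) < params$min_partner_labels) {
    # fewer nicks than a credible partner fragment: a clean (or nearly
    # clean) terminal overhang with no telomere signal is a TFE
    if (d_len >= params$tfe_min_overhang_bp)
      return(list(category = "TFE", kb = 0))
  }
  list(category = "UNCLASSIFIED", kb = NA_real_)
}

#' Classify one molecule from its alignments
#'
#' Applies the chromosome-end feature definitions: END_TEL (terminal
#' telomere on an end-anchored arm), TFE (end-anchored arm, no telomere,
#' clean overhang), FUSION_ITS_PLUS (internal telomere at a fusion
#' junction), FUSION_ITS_MINUS (fusion junction without telomere), ECTR
#' (telomere-only fiber, no alignment), else UNCLASSIFIED. TFE and
#' FUSION_ITS_MINUS report 0 kb by convention. A fusion whose two segments
#' are end-anchored on arms records one sighting per arm (the same arm
#' twice for same-arm fusions).
#'
#' @param mol a `telomap_molecule`.
#' @param alignments list of `telomap_alignment` for this molecule.
#' @param params a `telomap_classifyparams`.
#' @param cal a `telomap_calibration`.
#' @return an object of class `telomap_classified`: list(molecule_id,
#'   category, arms_of_record, telomere_length_kb).
#' @export
classify_molecule <- function(mol, alignments, params = classify_params(),
                              cal = calibration_model()) {
  clusters <- merge_telomere_clusters(mol$telomere_labels,
                                      params$cluster_gap_bp)
  # undetectable clusters are not signal
  if (nrow(clusters))
    clusters <- clusters[estimate_telomere_length(clusters$intensity, cal) > 0, ,
                         drop = FALSE]
  # end-anchored context: the segment's distal matched label lies within
  # end_window_bp of the arm terminus (a dropped terminal label does not
  # disqualify an otherwise terminal alignment)
  anchored <- Filter(function(a) {
    a$distal_ref_gap_bp <= params$end_window_bp
  }, alignments)

  if (!length(anchored)) {
    if (!length(alignments) && nrow(clusters)) {
      kb <- estimate_telomere_length(max(clusters$intensity), cal)
      return(new_classified(mol$molecule_id, "ECTR", character(0), kb))
    }
    return(new_classified(mol$molecule_id, "UNCLASSIFIED", character(0),
                          NA_real_))
  }

  calls <- lapply(anchored, classify_segment, mol = mol, clusters = clusters,
                  params = params, cal = cal)
  cats <- vapply(calls, function(x) x$category, character(1))
  arms <- vapply(anchored, function(a) a$arm_id, character(1))
  pick <- function(cat) {
    ix <- which(cats == cat)
    kb <- calls[[ix[1]]]$kb
    rec_arms <- if (cat %in% c("FUSION_ITS_PLUS", "FUSION_ITS_MINUS"))
      arms else arms[ix[1]]
    new_classified(mol$molecule_id, cat, rec_arms, kb)
  }
  for (cat in c("FUSION_ITS_PLUS", "FUSION_ITS_MINUS", "END_TEL", "TFE")) {
    if (cat %in% cats) return(pick(cat))
  }
  new_classified(mol$molecule_id, "UNCLASSIFIED", character(0), NA_real_)
}

new_classified <- function(id, category, arms, kb) {
  if (category %in% c("TFE", "FUSION_ITS_MINUS")) kb <- 0
  structure(list(molecule_id = id, category = category,
                 arms_of_record = arms, telomere_length_kb = kb),
            class = "telomap_classified")
}

#' Align and classify a whole molecule set
#'
#' @param molecules list of `telomap_molecule`.
#' @param reference a `telomap_reference`.
#' @param align_params a `telomap_alignparams`.
#' @param params a `telomap_classifyparams`.
#' @param cal a `telomap_calibration`.
#' @return list of `telomap_classified`.
#' @export
classify_molecules <- function(molecules, reference,
                               align_params = alignment_params(),
                               params = classify_params(),
                               cal = calibration_model()) {
  lapply(molecules, function(m) {
    classify_molecule(m, align_molecule(m, reference, align_params),
                      params, cal)
  })
}

#' Tabulate classified molecules
#'
#' @param classified list of `telomap_classified`.
#' @return data.frame with `molecule_id`, `category`, `arms` (list column),
#'   `telomere_length_kb`.
#' @export
classified_table <- function(classified) {
  data.frame(
    molecule_id = vapply(classified, function(x) x$molecule_id, integer(1)),
    category = vapply(classified, function(x) x$category, character(1)),
    arms = I(lapply(classified, function(x) x$arms_of_record)),
    telomere_length_kb = vapply(classified,
                                function(x) x$telomere_length_kb, numeric(1)))
}
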