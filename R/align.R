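#' Alignment scoring parameters
#'
#' Interval-agreement alignment: successive label gaps on the molecule are
#' compared with successive gaps on the reference, which is robust to the
#' unknown offset of a molecule within an arm. A consecutive matched pair is
#' allowed when `|dref - dmol| <= max(abs_tol_bp, rel_tol * dref)`; within
#' the tolerance a small graded cost (`gap_cost_per_bp` per bp of deviation)
#' prefers exact geometry on otherwise tied matchings.
#'
#' @param abs_tol_bp absolute interval tolerance in bp.
#' @param rel_tol relative interval tolerance.
#' @param miss_penalty cost per skipped reference label between matches.
#' @param extra_penalty cost per skipped molecule label between matches.
#' @param match_bonus reward per matched pair.
#' @param gap_cost_per_bp graded deviation cost within the tolerance.
#' @param min_matched_labels acceptance floor on matched pairs (>= 3).
#' @param min_score acceptance floor on the alignment score.
#' @param max_skip maximum consecutive skipped labels considered by the DP.
#' @param scan_max_skip tighter skip window used by the candidate-arm scan
#'   (the winning arm is re-aligned with the full `max_skip`).
#' @return an object of class `telomap_alignparams`.
#' @export
alignment_params <- function(abs_tol_bp = 500, rel_tol = 0.12,
                             miss_penalty = 1, extra_penalty = 1,
                             match_bonus = 3, gap_cost_per_bp = 1e-4,
                             min_matched_labels = 8, min_score = 20,
                             max_skip = 8, scan_max_skip = 2) {
  if (miss_penalty < 0 || extra_penalty < 0 || abs_tol_bp < 0 || rel_tol < 0)
    stop("penalties and tolerances must be >= 0", call. = FALSE)
  if (min_matched_labels < 3)
    stop("min_matched_labels must be >= 3", call. = FALSE)
  structure(list(abs_tol_bp = abs_tol_bp, rel_tol = rel_tol,
                 miss_penalty = miss_penalty, extra_penalty = extra_penalty,
                 match_bonus = match_bonus, gap_cost_per_bp = gap_cost_per_bp,
                 min_matched_labels = min_matched_labels,
                 min_score = min_score, max_skip = max_skip,
                 scan_max_skip = scan_max_skip),
            class = "telomap_alignparams")
}

# run the DP on an oriented position vector against one arm
dp_run <- function(positions, arm, params, want_path) {
  dp_align_cpp(positions, arm$label_positions,
               params$abs_tol_bp, params$rel_tol,
               params$miss_penalty, params$extra_penalty,
               params$match_bonus, params$gap_cost_per_bp,
               as.integer(params$max_skip), want_path)
}

# oriented view of a subset of a molecule's nick labels; reverse orientation
# mirrors through the molecule length so gaps are preserved
orient_positions <- function(positions, length_bp, orientation) {
  if (orientation == "forward") positions else rev(length_bp - positions)
}

#' Align a molecule to one reference arm in a fixed orientation
#'
#' @param mol a `telomap_molecule`.
#' @param arm a `telomap_arm`.
#' @param params a `telomap_alignparams`.
#' @param orientation "forward" or "reverse".
#' @return a `telomap_alignment`, or NULL when no alignment reaches the
#'   acceptance floors (absence of alignment is a valid outcome).
#' @export
align_to_arm <- function(mol, arm, params = alignment_params(),
                         orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  build_alignment(mol$nick_labels, mol, arm, params, orientation)
}

# core: align a subset of nick positions (original molecule coordinates)
build_alignment <- function(positions, mol, arm, params, orientation) {
  n_lab <- length(positions)
  if (n_lab < params$min_matched_labels) return(NULL)
  oriented <- orient_positions(positions, mol$length_bp, orientation)
  res <- dp_run(oriented, arm, params, want_path = TRUE)
  if (!is.finite(res$score) || res$score < params$min_score ||
      res$n_matched < params$min_matched_labels) return(NULL)
  # map oriented indices back to original molecule coordinates
  mol_pos <- if (orientation == "forward") {
    positions[res$mol_idx]
  } else {
    positions[n_lab + 1L - res$mol_idx]
  }
  nref <- length(arm$label_positions)
  ref_idx <- res$ref_idx
  ref_pos <- arm$label_positions[ref_idx]
  structure(
    list(molecule_id = mol$molecule_id,
         arm_id = arm$arm_id,
         orientation = orientation,
         matched_mol_pos = mol_pos,       # ascending in oriented coords
         matched_ref_idx = ref_idx,
         score = res$score,
         n_matched = res$n_matched,
         mol_span_bp = range(mol_pos),
         ref_span_bp = range(ref_pos),
         end_anchored = max(ref_idx) == nref,
         chrom_end_pos = arm$chrom_end_pos,
         distal_ref_gap_bp = arm$chrom_end_pos - max(ref_pos)),
    class = "telomap_alignment")
}

#' @export
print.telomap_alignment <- function(x, ...) {
  cat(sprintf(
    "<telomap_alignment mol %d ~ %s (%s): %d matched, score %.1f%s>\n",
    x$molecule_id, x$arm_id, x$orientation, x$n_matched, x$score,
    if (x$end_anchored) ", end-anchored" else ""))
  invisible(x)
}

# best accepted alignment of a position subset over all arms x orientations.
# A fast score-only scan (scan_max_skip) ranks the candidates; the winner is
# re-aligned with the full DP and must pass the acceptance floors. Ties are
# broken by higher score then lexicographic arm_id (arm order is sorted).
scan_arms <- function(positions, mol, reference, params) {
  if (length(positions) < params$min_matched_labels) return(NULL)
  ids <- names(reference$arms)
  ord <- order(ids)
  tracks <- lapply(reference$arms[ord], `[[`, "label_positions")
  sc <- dp_scan_cpp(positions, mol$length_bp, tracks,
                    params$abs_tol_bp, params$rel_tol,
                    params$miss_penalty, params$extra_penalty,
                    params$match_bonus, params$gap_cost_per_bp,
                    as.integer(params$scan_max_skip))
  score <- c(sc[, 1], sc[, 3])
  nmat <- c(sc[, 2], sc[, 4])
  ok <- is.finite(score) & nmat >= params$min_matched_labels
  if (!any(ok)) return(NULL)
  best <- which(ok)[which.max(score[ok])]   # which.max takes the first tie
  arm <- reference$arms[[ord[(best - 1L) %% nrow(sc) + 1L]]]
  ori <- if (best <= nrow(sc)) "forward" else "reverse"
  build_alignment(positions, mol, arm, params, ori)
}

#' Align a molecule against a reference set, with split alignments
#'
#' Greedy split alignment: the best-scoring accepted alignment over all arms
#' and orientations is found; its molecule span is masked; the flanking
#' label subsets are re-scanned once, so a fusion molecule can yield two
#' segments. Returns at most two alignments sorted by molecule coordinate.
#'
#' @param mol a `telomap_molecule`.
#' @param reference a `telomap_reference`.
#' @param params a `telomap_alignparams`.
#' @return list of 0, 1 or 2 `telomap_alignment`.
#' @export
align_molecule <- function(mol, reference, params = alignment_params()) {
  if (!inherits(reference, "telomap_reference") || !length(reference$arms))
    stop("reference must be a non-empty telomap_reference", call. = FALSE)
  first <- scan_arms(mol$nick_labels, mol, reference, params)
  if (is.null(first)) return(list())
  span <- first$mol_span_bp
  left <- mol$nick_labels[mol$nick_labels < span[1]]
  right <- mol$nick_labels[mol$nick_labels > span[2]]
  second <- NULL
  for (flank in list(left, right)) {
    cand <- scan_arms(flank, mol, reference, params)
    if (!is.null(cand) &&
        (is.null(second) || cand$score > second$score)) second <- cand
  }
  out <- c(list(first), if (!is.null(second)) list(second))
  out[order(vapply(out, function(a) a$mol_span_bp[1], numeric(1)))]
}
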