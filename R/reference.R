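#' Human chromosome-arm names used for reference maps
#'
#' All 46 arm labels in karyotype order (1p..22q plus the two
#' pseudoautosomal ends XpYp and XqYq). The short arms of the five
#' acrocentric chromosomes are excluded by default: too few molecules map
#' there for the assay to report on them.
#'
#' @param exclude character vector of arm ids to drop.
#' @return character vector of arm ids.
#' @export
arm_names <- function(exclude = excluded_arms_default()) {
  all <- c(paste0(rep(1:22, each = 2), c("p", "q")), "XpYp", "XqYq")
  setdiff(all, exclude)
}

#' @rdname arm_names
#' @export
excluded_arms_default <- function() c("13p", "14p", "15p", "21p", "22p")

#' Construct a reference arm map
#'
#' A reference arm map holds the nick-label coordinates of one subtelomeric
#' segment, oriented so the chromosome terminus sits at the maximal
#' coordinate (`chrom_end_pos == map_length_bp`).
#'
#' @param arm_id arm label such as "3q".
#' @param label_positions ascending bp coordinates of nick sites.
#' @param map_length_bp total mapped span in bp; also the terminus position.
#' @return an object of class `telomap_arm`.
#' @export
reference_arm <- function(arm_id, label_positions, map_length_bp) {
  label_positions <- as.numeric(label_positions)
  if (length(arm_id) != 1L || !nzchar(arm_id))
    stop("arm_id must be a single non-empty label", call. = FALSE)
  if (!is.numeric(map_length_bp) || map_length_bp <= 0)
    stop("map_length_bp must be positive", call. = FALSE)
  if (is.unsorted(label_positions, strictly = TRUE))
    stop("label_positions must be strictly ascending (arm ", arm_id, ")",
         call. = FALSE)
  if (length(label_positions) &&
      (label_positions[1] < 0 || label_positions[length(label_positions)] > map_length_bp))
    stop("label_positions must lie in [0, map_length_bp] (arm ", arm_id, ")",
         call. = FALSE)
  structure(
    list(arm_id = as.character(arm_id),
         label_positions = label_positions,
         chrom_end_pos = as.numeric(map_length_bp),
         map_length_bp = as.numeric(map_length_bp)),
    class = "telomap_arm")
}

#' Assemble a reference set
#'
#' @param arms list of `telomap_arm` objects.
#' @param excluded_arms arm ids never simulated or reported.
#' @return an object of class `telomap_reference`.
#' @export
reference_set <- function(arms, excluded_arms = excluded_arms_default()) {
  ids <- vapply(arms, function(a) a$arm_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate arm_ids in reference", call. = FALSE)
  names(arms) <- ids
  structure(list(arms = arms, excluded_arms = excluded_arms),
            class = "telomap_reference")
}

#' Generate a synthetic reference set
#'
#' Nick-label positions follow a shifted-exponential interval model:
#' consecutive labels are separated by `min_spacing_bp` plus an exponential
#' with mean `mean_label_spacing_bp - min_spacing_bp`, so the mean
#' inter-label spacing equals `mean_label_spacing_bp` while respecting the
#' minimum resolvable spacing. Each arm's distal-most label is anchored
#' 6-18 kb from the chromosome terminus so that end-anchorage and terminal
#' overhang are geometrically decidable for every arm.
#'
#' @param n_arms number of arms (at most 41 named arms).
#' @param mean_label_spacing_bp mean nick-to-nick spacing in bp.
#' @param map_length_bp mapped span of each arm in bp.
#' @param min_spacing_bp minimum resolvable spacing between labels in bp.
#' @param seed integer seed; identical inputs give identical references.
#' @return a `telomap_reference`.
#' @export
make_reference <- function(n_arms = 41L,
                           mean_label_spacing_bp = 9000,
                           map_length_bp = 300000,
                           min_spacing_bp = 1500,
                           seed = 1L) {
  if (n_arms < 1) stop("n_arms must be >= 1", call. = FALSE)
  if (mean_label_spacing_bp <= 0 || map_length_bp <= 0 || min_spacing_bp <= 0)
    stop("spacings and map length must be positive", call. = FALSE)
  if (mean_label_spacing_bp <= min_spacing_bp)
    stop("mean_label_spacing_bp must exceed min_spacing_bp", call. = FALSE)
  if (map_length_bp < 10 * mean_label_spacing_bp)
    stop("map_length_bp must be at least 10 x mean_label_spacing_bp",
         call. = FALSE)
  ids <- arm_names()
  if (n_arms > length(ids))
    stop("n_arms exceeds the ", length(ids), " available arm names",
         call. = FALSE)
  set.seed(as.integer(seed))
  arms <- lapply(ids[seq_len(n_arms)], function(id) {
    pos <- sample_label_track(map_length_bp, mean_label_spacing_bp,
                              min_spacing_bp)
    reference_arm(id, pos, map_length_bp)
  })
  reference_set(arms)
}

# one arm's label track; terminal gap forced into [6, 18] kb
sample_label_track <- function(map_length, mean_sp, min_sp,
                               end_gap = c(6000, 18000)) {
  end_hi <- map_length - end_gap[1]
  end_lo <- map_length - end_gap[2]
  n_guess <- ceiling(2 * map_length / mean_sp) + 10
  gaps <- min_sp + rexp(n_guess, rate = 1 / (mean_sp - min_sp))
  pos <- cumsum(gaps)
  while (pos[length(pos)] <= end_hi) {
    gaps <- min_sp + rexp(n_guess, rate = 1 / (mean_sp - min_sp))
    pos <- c(pos, pos[length(pos)] + cumsum(gaps))
  }
  pos <- pos[pos <= end_hi]
  if (!length(pos) || pos[length(pos)] < end_lo) {
    u <- runif(1, end_lo, end_hi)
    if (length(pos) && u - pos[length(pos)] < min_sp)
      u <- pos[length(pos)] + min_sp
    pos <- c(pos, u)
  }
  pos
}

#' @export
print.telomap_arm <- function(x, ...) {
  cat(sprintf("<telomap_arm %s: %d labels over %.0f bp, terminus at %.0f>\n",
              x$arm_id, length(x$label_positions), x$map_length_bp,
              x$chrom_end_pos))
  invisible(x)
}

#' @export
print.telomap_reference <- function(x, ...) {
  cat(sprintf("<telomap_reference: %d arms (%s ...), %d excluded>\n",
              length(x$arms), paste(utils::head(names(x$arms), 4), collapse = ", "),
              length(x$excluded_arms)))
  invisible(x)
}
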