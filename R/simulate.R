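#' Construct a single-molecule record
#'
#' One imaged DNA fiber: nick-channel label positions plus telomere-channel
#' labels with intensities, and an optional simulation truth record.
#'
#' @param molecule_id integer id.
#' @param length_bp backbone length in bp.
#' @param nick_labels ascending bp positions of nick-channel labels.
#' @param telomere_labels data.frame with columns `position_bp`, `intensity`.
#' @param truth optional list(category, arms, true_kb).
#' @return an object of class `telomap_molecule`.
#' @export
molecule <- function(molecule_id, length_bp, nick_labels = numeric(0),
                     telomere_labels = empty_telomere_labels(), truth = NULL) {
  nick_labels <- as.numeric(nick_labels)
  if (length_bp <= 0) stop("length_bp must be positive", call. = FALSE)
  if (is.unsorted(nick_labels, strictly = TRUE))
    stop("nick_labels must be strictly ascending", call. = FALSE)
  if (length(nick_labels) &&
      (nick_labels[1] < 0 || nick_labels[length(nick_labels)] > length_bp))
    stop("nick_labels must lie in [0, length_bp]", call. = FALSE)
  if (nrow(telomere_labels)) {
    if (any(telomere_labels$position_bp < 0 |
            telomere_labels$position_bp > length_bp))
      stop("telomere labels must lie in [0, length_bp]", call. = FALSE)
    if (any(telomere_labels$intensity <= 0))
      stop("telomere label intensity must be positive", call. = FALSE)
  }
  structure(list(molecule_id = as.integer(molecule_id),
                 length_bp = as.numeric(length_bp),
                 nick_labels = nick_labels,
                 telomere_labels = telomere_labels,
                 truth = truth),
            class = "telomap_molecule")
}

#' @rdname molecule
#' @export
empty_telomere_labels <- function() {
  data.frame(position_bp = numeric(0), intensity = numeric(0))
}

#' @export
print.telomap_molecule <- function(x, ...) {
  cat(sprintf("<telomap_molecule %d: %.0f bp, %d nicks, %d telomere labels%s>\n",
              x$molecule_id, x$length_bp, length(x$nick_labels),
              nrow(x$telomere_labels),
              if (is.null(x$truth)) "" else paste0(", truth=", x$truth$category)))
  invisible(x)
}

CATEGORIES <- c("END_TEL", "TFE", "FUSION_ITS_PLUS", "FUSION_ITS_MINUS",
                "ECTR", "UNCLASSIFIED")

# molecule backbone window within the mapped arm segment (bp); fibers below
# the loading threshold (~150 kb) are not imaged, ECTRs excepted
BACKBONE_MIN_BP <- 150000
BACKBONE_MAX_BP <- 400000

#' Simulate a cell line's molecule set
#'
#' For each reference arm, Poisson(`mean_molecules_per_arm`) molecules are
#' drawn; each gets a category from the profile's mixture and is constructed
#' from the arm's subtelomeric label pattern:
#' \describe{
#'   \item{END_TEL}{subtelomere window ending at the terminus plus a terminal
#'     telomere label of intensity `k * length`.}
#'   \item{TFE}{subtelomere window truncated at the terminus, no telomere
#'     label.}
#'   \item{FUSION_ITS_PLUS}{subtelomere window, an internal telomere label at
#'     the junction, then a partner fragment (another arm's reversed
#'     subtelomere with probability 0.5, else a short uncharacterized label
#'     pattern) carrying nick labels distal to the telomere.}
#'   \item{FUSION_ITS_MINUS}{subtelomere window joined directly to a partner
#'     fragment at the terminus, no junction telomere.}
#' }
#' ECTR molecules (telomere-only fibers) are emitted additionally at the
#' profile's rate. Noise (sizing jitter, dropout, false labels, intensity
#' noise) is applied last; telomeres below the detection floor emit no
#' label. Truth records are retained on every molecule.
#'
#' @param profile a `telomap_profile`.
#' @param reference a `telomap_reference`.
#' @param seed integer seed; identical inputs give identical molecule sets.
#' @param noise noise model; defaults to the profile's. Use [noise_off()]
#'   for noiseless simulations.
#' @param k_units_per_kb intensity calibration constant.
#' @return list of `telomap_molecule`.
#' @export
simulate_cell_line <- function(profile, reference, seed,
                               noise = profile$noise,
                               k_units_per_kb = K_UNITS_PER_KB_DEFAULT) {
  if (!inherits(reference, "telomap_reference") || !length(reference$arms))
    stop("reference must be a non-empty telomap_reference", call. = FALSE)
  set.seed(as.integer(seed))
  floor_kb <- noise$detection_floor_kb
  arms <- reference$arms
  arm_ids <- names(arms)
  mols <- list()
  next_id <- 1L
  n_anchored <- 0L

  for (aid in arm_ids) {
    n <- rpois(1, profile$mean_molecules_per_arm)
    if (n == 0) next
    n_anchored <- n_anchored + n
    cats <- sample(CATEGORIES[1:4], n, replace = TRUE,
                   prob = c(profile$frac_endtel, profile$frac_tfe,
                            profile$frac_its_plus, profile$frac_its_minus))
    for (cat in cats) {
      m <- build_arm_molecule(cat, aid, arms, profile, next_id,
                              floor_kb, k_units_per_kb)
      mols[[length(mols) + 1L]] <- m
      next_id <- next_id + 1L
    }
  }
  n_ectr <- rpois(1, n_anchored * profile$ectr_per_100_molecules / 100)
  for (i in seq_len(n_ectr)) {
    t_kb <- sample_lengths(profile$ectr_len, 1, min_kb = max(floor_kb, 0.5))
    m <- molecule(next_id, t_kb * 1000,
                  telomere_labels = data.frame(position_bp = t_kb * 500,
                                               intensity = k_units_per_kb * t_kb),
                  truth = list(category = "ECTR", arms = character(0),
                               true_kb = t_kb))
    mols[[length(mols) + 1L]] <- m
    next_id <- next_id + 1L
  }
  lapply(mols, function(m) apply_noise(maybe_flip(m), noise))
}

# subtelomere window of an arm mapped to molecule coordinates [0, W]
arm_window <- function(arm, w) {
  lo <- arm$chrom_end_pos - w
  arm$label_positions[arm$label_positions > lo] - lo
}

build_arm_molecule <- function(cat, aid, arms, profile, id, floor_kb, k) {
  arm <- arms[[aid]]
  map_len <- arm$map_length_bp
  w <- runif(1, BACKBONE_MIN_BP, min(BACKBONE_MAX_BP, map_len))
  nick <- arm_window(arm, w)
  truth_arms <- aid

  if (cat == "END_TEL") {
    t_kb <- sample_lengths(profile$endtel_len, 1, min_kb = floor_kb)
    len <- w + t_kb * 1000
    telo <- data.frame(position_bp = w + t_kb * 500, intensity = k * t_kb)
  } else if (cat == "TFE") {
    t_kb <- 0
    len <- w
    telo <- empty_telomere_labels()
  } else {  # fusion: attach a partner fragment beyond the terminus
    partner <- sample_partner(arms, profile, map_len)
    if (length(partner$arm_id)) truth_arms <- c(aid, partner$arm_id)
    if (cat == "FUSION_ITS_PLUS") {
      t_kb <- sample_lengths(profile$its_plus_len, 1, min_kb = floor_kb)
      junction <- w + t_kb * 1000
      telo <- data.frame(position_bp = w + t_kb * 500, intensity = k * t_kb)
    } else {
      t_kb <- 0
      junction <- w
      telo <- empty_telomere_labels()
    }
    nick <- c(nick, junction + partner$labels)
    len <- junction + partner$length_bp
  }
  molecule(id, len, nick, telo,
           truth = list(category = cat, arms = truth_arms, true_kb = t_kb))
}

# fusion partner: with prob 0.5 another arm's reversed subtelomere (its own
# terminus faces the junction), else a short uncharacterized fragment whose
# few labels cannot reach the aligner's acceptance floor
sample_partner <- function(arms, profile, map_len) {
  if (runif(1) < 0.5) {
    pid <- sample(names(arms), 1)
    parm <- arms[[pid]]
    w2 <- runif(1, 100000, min(250000, parm$map_length_bp))
    win <- arm_window(parm, w2)
    # reversed: the partner's terminus (at local coordinate w2) faces the
    # junction, so a label at p maps to w2 - p from the junction
    list(arm_id = pid, labels = sort(w2 - win), length_bp = w2)
  } else {
    len <- runif(1, 40000, 80000)
    gaps <- 1500 + rexp(12, 1 / 7500)
    pos <- 4000 + cumsum(gaps)
    pos <- pos[pos < len - 2000]
    if (length(pos) > 7) pos <- pos[1:7]
    if (length(pos) < 2) pos <- c(len / 3, 2 * len / 3)
    list(arm_id = character(0), labels = pos, length_bp = len)
  }
}

# half the fibers are imaged in the opposite orientation
maybe_flip <- function(m) {
  if (runif(1) < 0.5) flip_molecule(m) else m
}

#' Reverse a molecule end-to-end
#' @param m a `telomap_molecule`.
#' @return the reversed molecule.
#' @export
flip_molecule <- function(m) {
  m$nick_labels <- rev(m$length_bp - m$nick_labels)
  if (nrow(m$telomere_labels)) {
    m$telomere_labels$position_bp <- m$length_bp - m$telomere_labels$position_bp
    m$telomere_labels <- m$telomere_labels[order(m$telomere_labels$position_bp), ,
                                           drop = FALSE]
    rownames(m$telomere_labels) <- NULL
  }
  m
}

# sizing jitter, dropout, false labels, intensity noise
apply_noise <- function(m, noise) {
  nick <- m$nick_labels
  if (length(nick) && noise$dropout_prob > 0)
    nick <- nick[runif(length(nick)) > noise$dropout_prob]
  if (length(nick) && noise$sizing_sd_bp > 0)
    nick <- nick + rnorm(length(nick), 0, noise$sizing_sd_bp)
  if (noise$false_label_rate_per_100kb > 0) {
    nf <- rpois(1, m$length_bp / 1e5 * noise$false_label_rate_per_100kb)
    if (nf > 0) nick <- c(nick, runif(nf, 0, m$length_bp))
  }
  nick <- sort(pmin(pmax(nick, 0), m$length_bp))
  nick <- nick[!duplicated(round(nick, 1))]
  m$nick_labels <- nick
  if (nrow(m$telomere_labels)) {
    tl <- m$telomere_labels
    if (noise$sizing_sd_bp > 0) {
      tl$position_bp <- pmin(pmax(
        tl$position_bp + rnorm(nrow(tl), 0, noise$sizing_sd_bp), 0),
        m$length_bp)
    }
    if (noise$intensity_cv > 0)
      tl$intensity <- pmax(tl$intensity *
                             (1 + rnorm(nrow(tl), 0, noise$intensity_cv)),
                           1e-6)
    m$telomere_labels <- tl[order(tl$position_bp), , drop = FALSE]
    rownames(m$telomere_labels) <- NULL
  }
  m
}

#' Build a noiseless worked-example molecule set for one arm
#'
#' Constructs raw molecules whose downstream classification is guaranteed by
#' geometry: each molecule carries the arm's full label track, and fusion
#' partners are short deterministic label patterns (7 labels, below the
#' aligner's acceptance floor) so per-arm statistics involve only the named
#' arm.
#'
#' @param arm_id arm to build on.
#' @param composition data.frame with columns `category` (END_TEL, TFE,
#'   FUSION_ITS_PLUS, FUSION_ITS_MINUS), `count`, `telomere_kb`.
#' @param reference a `telomap_reference` containing `arm_id`.
#' @param k_units_per_kb intensity calibration constant.
#' @return list of `telomap_molecule` (noiseless, deterministic).
#' @export
build_worked_fixture <- function(arm_id, composition, reference,
                                 k_units_per_kb = K_UNITS_PER_KB_DEFAULT) {
  if (!arm_id %in% names(reference$arms))
    stop("unknown arm: ", arm_id, call. = FALSE)
  if (nrow(composition) && any(composition$count < 0))
    stop("counts must be >= 0", call. = FALSE)
  bad <- setdiff(composition$category, CATEGORIES[1:4])
  if (length(bad))
    stop("unsupported category in composition: ", paste(bad, collapse = ", "),
         call. = FALSE)
  arm <- reference$arms[[arm_id]]
  end <- arm$chrom_end_pos
  partner_offsets <- 8000 + 9000 * (0:6)   # 7 labels over 62 kb
  partner_len <- 70000
  mols <- list()
  id <- 1L
  for (r in seq_len(nrow(composition))) {
    cat <- composition$category[r]
    t_kb <- composition$telomere_kb[r]
    for (i in seq_len(composition$count[r])) {
      nick <- arm$label_positions
      telo <- empty_telomere_labels()
      if (cat == "END_TEL") {
        len <- end + t_kb * 1000
        telo <- data.frame(position_bp = end + t_kb * 500,
                           intensity = k_units_per_kb * t_kb)
      } else if (cat == "TFE") {
        len <- end
      } else if (cat == "FUSION_ITS_PLUS") {
        junction <- end + t_kb * 1000
        telo <- data.frame(position_bp = end + t_kb * 500,
                           intensity = k_units_per_kb * t_kb)
        nick <- c(nick, junction + partner_offsets)
        len <- junction + partner_len
      } else {  # FUSION_ITS_MINUS
        t_kb <- 0
        nick <- c(nick, end + partner_offsets)
        len <- end + partner_len
      }
      mols[[length(mols) + 1L]] <-
        molecule(id, len, nick, telo,
                 truth = list(category = cat, arms = arm_id, true_kb = t_kb))
      id <- id + 1L
    }
  }
  mols
}
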