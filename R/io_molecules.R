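BNX_VERSION <- "# telomap-bnx 1.0"
CMAP_VERSION <- "# telomap-cmap 1.0"

#' Write / read molecules in the simplified BNX dialect
#'
#' Four lines per molecule: a `0` backbone row (id, length), a `1` row with
#' channel-1 nick positions, a `2` row with channel-2 telomere positions,
#' and a `QX21` row with the matching telomere intensities. Positions are
#' written to 0.1 bp and intensities to 6 significant digits; header lines
#' are `#`-prefixed. Writers are deterministic.
#'
#' @param molecules list of `telomap_molecule`.
#' @param path file path.
#' @param header_extra optional named character vector written as
#'   `# key: value` comments.
#' @return `read_bnx` returns a list of `telomap_molecule` (without truth).
#' @export
write_bnx <- function(molecules, path, header_extra = NULL) {
  fmt_pos <- function(x) sprintf("%.1f", x)
  fmt_int <- function(x) sprintf("%.6g", x)
  lines <- c(BNX_VERSION,
             if (length(header_extra))
               sprintf("# %s: %s", names(header_extra), header_extra))
  body <- vapply(molecules, function(m) {
    paste(c(paste(c("0", m$molecule_id, fmt_pos(m$length_bp)),
                  collapse = "\t"),
            paste(c("1", fmt_pos(m$nick_labels)), collapse = "\t"),
            paste(c("2", fmt_pos(m$telomere_labels$position_bp)),
                  collapse = "\t"),
            paste(c("QX21", fmt_int(m$telomere_labels$intensity)),
                  collapse = "\t")),
          collapse = "\n")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

bnx_parse_error <- function(line_no, msg) {
  stop(sprintf("BNX parse error at line %d: %s", line_no, msg),
       call. = FALSE)
}

#' @rdname write_bnx
#' @export
read_bnx <- function(path) {
  lines <- readLines(path)
  is_comment <- startsWith(lines, "#")
  body_idx <- which(!is_comment & nzchar(lines))
  if (!length(body_idx)) return(list())
  if (length(body_idx) %% 4 != 0)
    bnx_parse_error(body_idx[length(body_idx)],
                    "molecule records must be 4 lines (0, 1, 2, QX21)")
  nums <- function(fields, line_no) {
    out <- suppressWarnings(as.numeric(fields))
    if (anyNA(out)) bnx_parse_error(line_no, "non-numeric field")
    out
  }
  mols <- vector("list", length(body_idx) / 4)
  for (k in seq_along(mols)) {
    ix <- body_idx[(4 * k - 3):(4 * k)]
    f <- strsplit(lines[ix], "\t", fixed = TRUE)
    tags <- vapply(f, `[[`, character(1), 1)
    if (!identical(tags, c("0", "1", "2", "QX21")))
      bnx_parse_error(ix[1], paste0("expected rows 0/1/2/QX21, got ",
                                    paste(tags, collapse = "/")))
    if (length(f[[1]]) != 3)
      bnx_parse_error(ix[1], "backbone row must be: 0 <id> <length>")
    id <- nums(f[[1]][2], ix[1])
    len <- nums(f[[1]][3], ix[1])
    nick <- nums(f[[2]][-1], ix[2])
    tpos <- nums(f[[3]][-1], ix[3])
    tint <- nums(f[[4]][-1], ix[4])
    if (length(tpos) != length(tint))
      bnx_parse_error(ix[4], "intensity row arity differs from position row")
    if (is.unsorted(nick, strictly = TRUE))
      bnx_parse_error(ix[2], "nick positions must be strictly ascending")
    if (length(nick) && (nick[1] < 0 || nick[length(nick)] > len))
      bnx_parse_error(ix[2], "nick position outside [0, length]")
    if (length(tpos) && (min(tpos) < 0 || max(tpos) > len))
      bnx_parse_error(ix[3], "telomere position outside [0, length]")
    if (any(tint <= 0))
      bnx_parse_error(ix[4], "intensity must be positive")
    mols[[k]] <- molecule(id, len, nick,
                          data.frame(position_bp = tpos, intensity = tint))
  }
  mols
}

#' Write / read a reference set in the simplified CMAP dialect
#'
#' One row per label: `map_id`, `map_length`, `label_index`, `position`
#' (tab-separated). The arm_id to map_id mapping is carried in header
#' comments. The round trip is lossless.
#'
#' @param reference a `telomap_reference`.
#' @param path file path.
#' @return `read_cmap` returns a `telomap_reference`.
#' @export
write_cmap <- function(reference, path) {
  arms <- reference$arms
  lines <- c(CMAP_VERSION,
             sprintf("# arm\t%d\t%s", seq_along(arms), names(arms)),
             sprintf("# excluded\t%s",
                     paste(reference$excluded_arms, collapse = ",")))
  rows <- unlist(lapply(seq_along(arms), function(i) {
    a <- arms[[i]]
    sprintf("%d\t%.1f\t%d\t%.1f", i, a$map_length_bp,
            seq_along(a$label_positions), a$label_positions)
  }))
  writeLines(c(lines, rows), path)
  invisible(path)
}

cmap_parse_error <- function(line_no, msg) {
  stop(sprintf("CMAP parse error at line %d: %s", line_no, msg),
       call. = FALSE)
}

#' @rdname write_cmap
#' @export
read_cmap <- function(path) {
  lines <- readLines(path)
  arm_hdr <- grep("^# arm\t", lines)
  ids <- character(0)
  for (i in arm_hdr) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 3) cmap_parse_error(i, "malformed arm header")
    ids[as.integer(f[2])] <- f[3]
  }
  excl <- excluded_arms_default()
  ex_hdr <- grep("^# excluded\t", lines)
  if (length(ex_hdr))
    excl <- strsplit(strsplit(lines[ex_hdr[1]], "\t")[[1]][2], ",")[[1]]
  body_idx <- which(!startsWith(lines, "#") & nzchar(lines))
  if (!length(body_idx))
    stop("empty CMAP: no label rows", call. = FALSE)
  recs <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  bad <- which(lengths(recs) != 4)
  if (length(bad)) cmap_parse_error(body_idx[bad[1]], "expected 4 fields")
  df <- data.frame(
    map_id = as.integer(vapply(recs, `[[`, character(1), 1)),
    map_len = as.numeric(vapply(recs, `[[`, character(1), 2)),
    label_index = as.integer(vapply(recs, `[[`, character(1), 3)),
    position = as.numeric(vapply(recs, `[[`, character(1), 4)))
  if (anyNA(df)) cmap_parse_error(body_idx[which(!stats::complete.cases(df))[1]],
                                  "non-numeric field")
  if (anyDuplicated(df[c("map_id", "label_index")])) {
    d <- which(duplicated(df[c("map_id", "label_index")]))[1]
    cmap_parse_error(body_idx[d], "duplicate map_id + label_index")
  }
  arms <- lapply(sort(unique(df$map_id)), function(mid) {
    sub <- df[df$map_id == mid, ]
    sub <- sub[order(sub$label_index), ]
    aid <- if (mid <= length(ids) && !is.na(ids[mid])) ids[mid]
    else as.character(mid)
    reference_arm(aid, sub$position, sub$map_len[1])
  })
  reference_set(arms, excluded_arms = excl)
}

#' Write / read the simulation truth sidecar
#'
#' @param molecules list of `telomap_molecule` carrying truth records.
#' @param path file path.
#' @return `read_truth` returns a data.frame (molecule_id, category, arms,
#'   true_kb); `arms` is a comma-joined string.
#' @export
write_truth <- function(molecules, path) {
  df <- data.frame(
    molecule_id = vapply(molecules, function(m) m$molecule_id, integer(1)),
    category = vapply(molecules, function(m)
      if (is.null(m$truth)) NA_character_ else m$truth$category, character(1)),
    arms = vapply(molecules, function(m)
      if (is.null(m$truth)) "" else paste(m$truth$arms, collapse = ","),
      character(1)),
    true_kb = vapply(molecules, function(m)
      if (is.null(m$truth)) NA_real_ else m$truth$true_kb, numeric(1)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
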