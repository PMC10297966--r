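# Independent oracles and small fixture builders shared across tests.

# Exhaustive enumeration of all monotone matchings between two ascending
# label tracks, scored exactly as the aligner scores them: match_bonus per
# pair, graded deviation cost within the interval tolerance gate (pairs
# outside the gate are disallowed), miss/extra penalties for labels skipped
# between consecutive matches, free ends. Returns the optimum score.
brute_force_align_score <- function(mol, ref, p) {
  best <- -Inf
  m <- length(mol); r <- length(ref)
  rec <- function(last_m, last_r, score) {
    a0 <- if (last_m == 0) 1 else last_m + 1
    b0 <- if (last_r == 0) 1 else last_r + 1
    if (a0 > m || b0 > r) return(invisible())
    for (a in a0:m) {
      for (b in b0:r) {
        if (last_m > 0) {
          dm <- mol[a] - mol[last_m]
          dr <- ref[b] - ref[last_r]
          dev <- abs(dr - dm)
          if (dev > max(p$abs_tol_bp, p$rel_tol * dr)) next
          s2 <- score + p$match_bonus - p$gap_cost_per_bp * dev -
            p$miss_penalty * (b - last_r - 1) -
            p$extra_penalty * (a - last_m - 1)
        } else {
          s2 <- p$match_bonus
        }
        if (s2 > best) best <<- s2
        rec(a, b, s2)
      }
    }
  }
  rec(0, 0, 0)
  best
}

# DP score for the same raw instance (no acceptance floors applied)
dp_raw_score <- function(mol, ref, p) {
  res <- telomap:::dp_align_cpp(mol, ref, p$abs_tol_bp, p$rel_tol,
                                p$miss_penalty, p$extra_penalty,
                                p$match_bonus, p$gap_cost_per_bp,
                                as.integer(p$max_skip), FALSE)
  res$score
}

# Textbook Welch statistic, Welch-Satterthwaite df, two-tailed p
welch_formula_oracle <- function(a, b) {
  m <- length(a); n <- length(b)
  va <- sum((a - mean(a))^2) / (m - 1)
  vb <- sum((b - mean(b))^2) / (n - 1)
  se2 <- va / m + vb / n
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / m)^2 / (m - 1) + (vb / n)^2 / (n - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# small deterministic reference shared by unit tests (built once per run)
test_reference <- local({
  ref <- NULL
  function() {
    if (is.null(ref)) ref <<- make_reference(seed = 1)
    ref
  }
})

# composition rows for build_worked_fixture
comp_rows <- function(...) {
  do.call(rbind, lapply(list(...), function(x) {
    data.frame(category = x[[1]], count = as.numeric(x[[2]]),
               telomere_kb = as.numeric(x[[3]]))
  }))
}

truth_categories <- function(mols) {
  vapply(mols, function(m) m$truth$category, character(1))
}

# run the analysis chain in memory (no files)
classify_set <- function(mols, ref, ...) {
  classified_table(classify_molecules(mols, ref, ...))
}
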