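test_that("a verbatim copy of an arm aligns with every label matched", {
  ref <- test_reference()
  arm <- ref$arms[["2q"]]
  m <- molecule(1, arm$map_length_bp, arm$label_positions)
  al <- align_to_arm(m, arm, orientation = "forward")
  expect_false(is.null(al))
  expect_equal(al$n_matched, length(arm$label_positions))
  expect_true(al$end_anchored)
  # zero deviation: score is exactly bonus * n
  expect_equal(al$score, 3 * al$n_matched, tolerance = 1e-9)
})

test_that("DP optimum equals brute-force enumeration on small instances", {
  p <- alignment_params(min_matched_labels = 3, min_score = -Inf)
  set.seed(99)
  for (case in 1:60) {
    m <- sample(3:8, 1); r <- sample(3:8, 1)
    mol <- sort(runif(m, 0, 60000))
    ref <- sort(runif(r, 0, 60000))
    # ensure some structure half the time: embed a shared gap pattern
    if (case %% 2 == 0 && m >= 4 && r >= 4) {
      shared <- cumsum(runif(3, 2000, 9000))
      mol[2:4] <- mol[1] + shared
      ref[2:4] <- ref[1] + shared * (1 + rnorm(3, 0, 0.02))
      mol <- sort(mol); ref <- sort(ref)
    }
    expect_equal(dp_raw_score(mol, ref, p),
                 brute_force_align_score(mol, ref, p),
                 tolerance = 1e-9,
                 info = sprintf("case %d", case))
  }
})

test_that("score is invariant under joint reversal of molecule and reference", {
  p <- alignment_params(min_matched_labels = 3, min_score = -Inf)
  set.seed(5)
  for (i in 1:20) {
    mol <- sort(runif(6, 0, 50000))
    ref <- sort(runif(7, 0, 50000))
    s1 <- dp_raw_score(mol, ref, p)
    s2 <- dp_raw_score(sort(50000 - mol), sort(50000 - ref), p)
    expect_equal(s1, s2, tolerance = 1e-9)
  }
})

test_that("a reversed molecule aligns to the same arm with the same score", {
  ref <- test_reference()
  arm <- ref$arms[["7p"]]
  m <- molecule(1, arm$map_length_bp, arm$label_positions)
  fwd <- align_to_arm(m, arm, orientation = "forward")
  rev_m <- flip_molecule(m)
  rev_al <- align_to_arm(rev_m, arm, orientation = "reverse")
  expect_false(is.null(rev_al))
  expect_equal(rev_al$score, fwd$score, tolerance = 1e-9)
  expect_identical(rev_al$orientation, "reverse")
  expect_true(rev_al$end_anchored)
})

test_that("split alignment resolves a same-arm fusion into two segments", {
  ref <- test_reference()
  arm <- ref$arms[["21q"]]
  end <- arm$chrom_end_pos
  # two 21q subtelomeres fused end-to-end (terminus to terminus)
  nick <- c(arm$label_positions, end + sort(end - arm$label_positions))
  m <- molecule(1, 2 * end, nick)
  als <- align_molecule(m, ref)
  expect_length(als, 2L)
  expect_setequal(vapply(als, function(a) a$arm_id, character(1)),
                  c("21q", "21q"))
  expect_true(all(vapply(als, function(a) a$end_anchored, logical(1))))
  # masked second-pass segments never overlap the first segment's span
  expect_lt(als[[1]]$mol_span_bp[2], als[[2]]$mol_span_bp[1])
})

test_that("a telomere-only molecule yields no alignment", {
  ref <- test_reference()
  m <- molecule(1, 11000,
                telomere_labels = data.frame(position_bp = 5500,
                                             intensity = 11000))
  expect_length(align_molecule(m, ref), 0L)
})

test_that("arm assignment is perfect on noiseless simulated molecules", {
  ref <- test_reference()
  prof <- profile_from_table1("U2OS")
  mols <- simulate_cell_line(prof, ref, seed = 21, noise = noise_off())
  mols <- mols[truth_categories(mols) != "ECTR"][1:200]
  hits <- vapply(mols, function(m) {
    als <- align_molecule(m, ref)
    m$truth$arms[1] %in% vapply(als, function(a) a$arm_id, character(1))
  }, logical(1))
  expect_equal(mean(hits), 1)
})

test_that("arm assignment accuracy under default noise is at least 95%", {
  ref <- test_reference()
  prof <- profile_from_table1("LNCaP")   # pure END_TEL
  mols <- simulate_cell_line(prof, ref, seed = 22)
  mols <- mols[truth_categories(mols) == "END_TEL"]
  assigned <- lapply(mols, function(m) {
    als <- align_molecule(m, ref)
    vapply(als, function(a) a$arm_id, character(1))
  })
  has_call <- lengths(assigned) > 0
  correct <- mapply(function(m, a) m$truth$arms[1] %in% a,
                    mols[has_call], assigned[has_call])
  # accuracy among aligned molecules, and alignment itself must mostly work
  expect_gte(mean(correct), 0.95)
  expect_gte(mean(has_call), 0.9)
})
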