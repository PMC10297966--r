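test_that("reference generation respects counts, ordering and spacing", {
  ref1 <- make_reference(n_arms = 1, seed = 7)
  expect_length(ref1$arms, 1L)
  a <- ref1$arms[[1]]
  expect_false(is.unsorted(a$label_positions, strictly = TRUE))
  expect_true(all(a$label_positions >= 0 &
                    a$label_positions <= a$chrom_end_pos))
  expect_identical(a$chrom_end_pos, a$map_length_bp)

  # seeded reproducibility
  ref_a <- make_reference(seed = 11)
  ref_b <- make_reference(seed = 11)
  expect_identical(ref_a, ref_b)

  # parameter validation
  expect_error(make_reference(mean_label_spacing_bp = -1), "positive")
  expect_error(make_reference(map_length_bp = 50000), "10 x")
  expect_error(make_reference(n_arms = 99), "available arm names")
})

test_that("empirical mean label spacing recovers the configured mean", {
  ref <- make_reference(n_arms = 41, mean_label_spacing_bp = 9000,
                        map_length_bp = 300000, seed = 1)
  gaps <- unlist(lapply(ref$arms, function(a) diff(a$label_positions)))
  se <- sd(gaps) / sqrt(length(gaps))
  expect_lt(abs(mean(gaps) - 9000), 3 * se)
  expect_true(all(gaps >= 1500 - 1e-9))
})

test_that("reference arms anchor a label 6-18 kb from the terminus", {
  ref <- make_reference(seed = 3)
  term_gap <- vapply(ref$arms, function(a)
    a$chrom_end_pos - max(a$label_positions), numeric(1))
  expect_true(all(term_gap >= 6000 - 1e-9 & term_gap <= 18000 + 1e-9))
})

test_that("length distribution preserves its mean and calibrated tail mass", {
  set.seed(42)
  d0 <- length_distribution(5.0, 2.2)
  # moment-matched lognormal body
  x <- sample_lengths(d0, 1e5)
  expect_lt(abs(mean(x) - 5.0) / 5.0, 0.01)
  expect_lt(abs(sd(x) - 2.2) / 2.2, 0.03)

  # calibration: Monte-Carlo exceedance agrees with the analytic target
  d <- calibrate_tail(length_distribution(4.5, 5.6), 0.043)
  expect_lt(abs(dist_p_exceed(d, 15) - 0.043), 1e-3)
  y <- sample_lengths(d, 1e5)
  expect_lt(abs(mean(y > 15) - 0.043), 0.003)
  expect_lt(abs(mean(y) - 4.5) / 4.5, 0.02)   # mean preserved under the tail

  # trivial and monotone behaviour
  expect_identical(calibrate_tail(d0, 0)$tail_weight, 0)
  targets <- c(0.01, 0.03, 0.06, 0.10)
  ws <- vapply(targets, function(t)
    calibrate_tail(length_distribution(5, 2.2), t)$tail_weight, numeric(1))
  expect_true(all(diff(ws) > 0))
  expect_error(calibrate_tail(length_distribution(5, 2.2), 0.7), "0.5")
  expect_error(
    calibrate_tail(length_distribution(2, 1, tail_median_kb = 16,
                                       tail_sigma = 0.1), 0.5),
    "calibration failure")
})

test_that("packaged profiles transcribe the published category mixture", {
  u <- profile_from_table1("U2OS")
  expect_equal(u$frac_its_plus, 0.231)
  expect_equal(u$frac_its_minus, 0.122)
  expect_equal(u$frac_tfe, 0.064)
  expect_equal(u$frac_endtel, 1 - 0.231 - 0.122 - 0.064)

  l <- profile_from_table1("LNCaP")
  expect_equal(l$frac_its_plus, 0)
  expect_equal(l$frac_its_minus, 0)
  expect_equal(l$frac_tfe, 0)
  expect_equal(l$frac_endtel, 1)

  expect_error(profile_from_table1("nosuch"), "unknown profile")

  # end-telomere mixture mean reproduces the published mean at n = 1e5
  set.seed(7)
  x <- sample_lengths(u$endtel_len, 1e5)
  expect_lt(abs(mean(x) - 5.0) / 5.0, 0.01)

  # and the measured-telomere mixture carries the published >15 kb mass
  p_end <- dist_p_exceed(u$endtel_len, 15)
  p_its <- dist_p_exceed(u$its_plus_len, 15)
  fe <- u$frac_endtel; fp <- u$frac_its_plus
  expect_lt(abs((fe * p_end + fp * p_its) / (fe + fp) - 0.041), 2e-3)
})

test_that("simulation is seed-deterministic and matches the profile mixture", {
  ref <- test_reference()
  prof <- profile_from_table1("U2OS")
  a <- simulate_cell_line(prof, ref, seed = 42, noise = noise_off())
  b <- simulate_cell_line(prof, ref, seed = 42, noise = noise_off())
  expect_identical(a, b)

  tr <- truth_categories(a)
  n <- sum(tr != "ECTR")
  for (pair in list(c("FUSION_ITS_PLUS", prof$frac_its_plus),
                    c("FUSION_ITS_MINUS", prof$frac_its_minus),
                    c("TFE", prof$frac_tfe),
                    c("END_TEL", prof$frac_endtel))) {
    p <- as.numeric(pair[2])
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(tr[tr != "ECTR"] == pair[1]) - p), 3 * se)
  }
})

test_that("a pure end-telomere profile yields only terminal telomeres", {
  ref <- test_reference()
  prof <- profile_from_table1("LNCaP")
  mols <- simulate_cell_line(prof, ref, seed = 5, noise = noise_off())
  non_ectr <- mols[truth_categories(mols) != "ECTR"]
  expect_true(all(vapply(non_ectr, function(m)
    nrow(m$telomere_labels) == 1, logical(1))))
  expect_true(all(truth_categories(non_ectr) == "END_TEL"))
})

test_that("ECTR molecules emulate the published length scale", {
  d <- profile_from_table1("U2OS")$ectr_len
  set.seed(9)
  x <- sample_lengths(d, 1e4)
  expect_lt(abs(mean(x) - 11) / 11, 0.05)
})

test_that("telomere-label intensity is proportional to true length", {
  ref <- test_reference()
  prof <- profile_from_table1("U2OS")
  mols <- simulate_cell_line(prof, ref, seed = 8, noise = noise_off())
  et <- mols[truth_categories(mols) == "END_TEL"]
  intensity <- vapply(et, function(m) sum(m$telomere_labels$intensity),
                      numeric(1))
  truth_kb <- vapply(et, function(m) m$truth$true_kb, numeric(1))
  k_hat <- sum(intensity * truth_kb) / sum(truth_kb^2)  # through the origin
  expect_lt(abs(k_hat - 1000) / 1000, 0.02)
})

test_that("worked fixtures honour composition counts and reject bad input", {
  ref <- test_reference()
  f <- build_worked_fixture("3q", comp_rows(list("FUSION_ITS_PLUS", 3, 2.0),
                                            list("FUSION_ITS_MINUS", 3, 0)),
                            ref)
  expect_length(f, 6L)
  f2 <- build_worked_fixture("19q", comp_rows(list("FUSION_ITS_PLUS", 25, 1.8),
                                              list("END_TEL", 1, 5.0)), ref)
  expect_length(f2, 26L)
  empty <- data.frame(category = character(0), count = numeric(0),
                      telomere_kb = numeric(0))
  expect_length(build_worked_fixture("3q", empty, ref), 0L)
  expect_error(build_worked_fixture("99z", comp_rows(list("TFE", 1, 0)), ref),
               "unknown arm")
  expect_error(build_worked_fixture("3q", comp_rows(list("ECTR", 1, 5)), ref),
               "unsupported category")
})
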