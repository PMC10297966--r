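mk_classified <- function(categories, lengths, arm = "1p") {
  classified_table(lapply(seq_along(categories), function(i) {
    telomap:::new_classified(i, categories[i],
                             if (categories[i] %in% c("ECTR", "UNCLASSIFIED"))
                               character(0) else arm,
                             lengths[i])
  }))
}

test_that("per-arm statistics reproduce hand-computed values", {
  # 16 fusion/ITS- and 7 TFE: the all-fusion arm with zero overall mean
  df <- mk_classified(c(rep("FUSION_ITS_MINUS", 16), rep("TFE", 7)),
                      rep(0, 23), arm = "3q")
  st <- arm_stats(df, "3q")
  expect_equal(round(st$its_minus_pct, 1), 69.6)
  expect_equal(round(st$tfe_pct, 1), 30.4)
  expect_equal(st$overall_mean_kb, 0)
  expect_true(is.na(st$cv))   # undefined when the mean is 0

  # constant sample
  df2 <- mk_classified(rep("END_TEL", 4), rep(5, 4))
  st2 <- arm_stats(df2, "1p")
  expect_equal(st2$overall_mean_kb, 5)
  expect_equal(st2$overall_sd_kb, 0)
  expect_equal(st2$endtel_pct, 100)
  expect_equal(st2$its_pct + st2$tfe_pct, 0)
  expect_equal(st2$cv, 0)

  # arithmetic oracle: lengths {0, 0, 5, 10}
  df3 <- mk_classified(c("TFE", "TFE", "END_TEL", "END_TEL"), c(0, 0, 5, 10))
  st3 <- arm_stats(df3, "1p")
  expect_equal(st3$overall_mean_kb, 3.75)
  expect_equal(st3$overall_sd_kb, sd(c(0, 0, 5, 10)))
  expect_equal(round(st3$overall_sd_kb, 3), 4.787)
  expect_equal(st3$overall_max_kb, 10)

  # empty arm drops from the report
  expect_null(arm_stats(df3, "9q"))
})

test_that("per-arm percentage partition sums to 100 on simulated data", {
  ref <- test_reference()
  mols <- simulate_cell_line(profile_from_table1("U2OS"), ref, seed = 14)
  tab <- arm_stats_table(classify_set(mols, ref))
  expect_gt(nrow(tab), 30)
  part <- tab$endtel_pct + tab$tfe_pct + tab$its_plus_pct + tab$its_minus_pct
  expect_true(all(abs(part - 100) < 0.05))
  expect_true(all(tab$overall_count == tab$endtel_count + tab$tfe_count +
                    tab$its_plus_count + tab$its_minus_count))
})

test_that("genome summary obeys scale invariance and pooling identities", {
  cats <- c(rep("END_TEL", 6), rep("FUSION_ITS_PLUS", 2), "TFE",
            "FUSION_ITS_MINUS")
  lens <- c(4, 5, 6, 7, 8, 9, 1.5, 2.5, 0, 0)
  s1 <- genome_summary(mk_classified(cats, lens))
  # zeros only lower the mean
  expect_lte(s1$overall_mean_kb, mean(lens[lens > 0]))
  # pooled mean identity
  expect_equal(s1$overall_mean_kb,
               (6 * s1$endtel_mean_kb + 2 * s1$its_plus_mean_kb) / 10)
  # scale invariance of CV
  s3 <- genome_summary(mk_classified(cats, lens * 3))
  expect_equal(s3$cv, s1$cv, tolerance = 1e-12)
  # constant nonzero sample has zero dispersion
  s0 <- genome_summary(mk_classified(rep("END_TEL", 5), rep(7, 5)))
  expect_equal(s0$cv, 0)
  # degenerate input
  expect_error(genome_summary(mk_classified("ECTR", 11)), "no arm-anchored")
})

test_that("pooled category weights reproduce the published overall mean", {
  # weighted-mean consistency on the published U2OS rows:
  # 0.583 * 5.0 + 0.231 * 1.8 = 3.33, printed overall 3.4
  cats <- c(rep("END_TEL", 583), rep("FUSION_ITS_PLUS", 231),
            rep("TFE", 64), rep("FUSION_ITS_MINUS", 122))
  lens <- c(rep(5.0, 583), rep(1.8, 231), rep(0, 186))
  s <- genome_summary(mk_classified(cats, lens))
  expect_equal(s$overall_mean_kb, 0.583 * 5.0 + 0.231 * 1.8, tolerance = 1e-9)
  expect_lt(abs(s$overall_mean_kb - 3.4), 0.1)
})

test_that("welch test matches its formula oracle and handles degeneracy", {
  # worked example: a = {1,2,3}, b = {2,3,4}
  r <- welch_t_test(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r$t_statistic, -1.2247, tolerance = 1e-4)
  expect_equal(r$degrees_of_freedom, 4, tolerance = 1e-9)
  expect_equal(r$p_value_two_tailed, 0.2878, tolerance = 1e-3)

  # identical non-degenerate samples
  r0 <- welch_t_test(c(1, 5, 9), c(1, 5, 9))
  expect_equal(r0$t_statistic, 0)
  expect_equal(r0$p_value_two_tailed, 1)

  # antisymmetry
  a <- rnorm(10); b <- rnorm(12, 1)
  r1 <- welch_t_test(a, b); r2 <- welch_t_test(b, a)
  expect_equal(r1$t_statistic, -r2$t_statistic)
  expect_equal(r1$p_value_two_tailed, r2$p_value_two_tailed)

  # degenerate zero-variance rules
  rz <- welch_t_test(c(2, 2, 2), c(2, 2))
  expect_equal(rz$t_statistic, 0); expect_equal(rz$p_value_two_tailed, 1)
  ri <- welch_t_test(c(3, 3), c(2, 2))
  expect_identical(ri$t_statistic, Inf)
  expect_equal(ri$p_value_two_tailed, 0)
  expect_error(welch_t_test(1, c(1, 2)), "insufficient")

  # formula oracle to 1e-10 over 1000 random pairs
  set.seed(123)
  for (i in 1:1000) {
    a <- rnorm(sample(3:20, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(3:20, 1), mean = runif(1, -1, 1))
    got <- welch_t_test(a, b)
    want <- welch_formula_oracle(a, b)
    expect_equal(got$t_statistic, want$t, tolerance = 1e-10)
    expect_equal(got$degrees_of_freedom, want$df, tolerance = 1e-10)
    expect_equal(got$p_value_two_tailed, want$p, tolerance = 1e-10)
  }
})

test_that("cell-line comparison is symmetric with unit diagonal", {
  ref <- test_reference()
  t1 <- arm_stats_table(classify_set(
    simulate_cell_line(profile_from_table1("U2OS"), ref, seed = 1), ref))
  t2 <- arm_stats_table(classify_set(
    simulate_cell_line(profile_from_table1("LNCaP"), ref, seed = 2), ref))
  t3 <- arm_stats_table(classify_set(
    simulate_cell_line(profile_from_table1("LNCaP"), ref, seed = 3), ref))
  cmp <- compare_cell_lines(list(U2OS = t1, LNCaP_a = t2, LNCaP_b = t3),
                            "its_plus_pct_by_arm")
  expect_equal(dim(cmp$p), c(3L, 3L))
  expect_equal(unname(diag(cmp$p)), rep(1, 3))
  expect_equal(cmp$p, t(cmp$p), tolerance = 1e-9)
  # ALT vs TEL+ separates; TEL+ replicates do not (both all-zero -> p = 1)
  expect_lt(cmp$p["U2OS", "LNCaP_a"], 0.05)
  expect_equal(cmp$p["LNCaP_a", "LNCaP_b"], 1)
  cmp_tfe <- compare_cell_lines(list(a = t2, b = t3), "tfe_pct_by_arm")
  expect_gt(cmp_tfe$p["a", "b"], 0.05)
  expect_error(compare_cell_lines(list(t1)), "at least 2")
})

test_that("the five-readout vote reproduces the published calls", {
  mk_sum <- function(its_p, its_m, tfe, cv, gt15) {
    structure(list(its_plus_pct = its_p, its_minus_pct = its_m,
                   tfe_pct = tfe, cv = cv, pct_gt_15kb = gt15),
              class = "telomap_summary")
  }
  u2os <- call_alt(mk_sum(23.1, 12.2, 6.4, 1.4, 4.1))
  expect_identical(u2os$call, "ALT_positive")
  expect_equal(u2os$n_positive, 5L)
  lncap <- call_alt(mk_sum(0, 0, 0, 0.5, 0.4))
  expect_identical(lncap$call, "ALT_negative")
  expect_equal(lncap$n_positive, 0L)
  zero <- call_alt(mk_sum(0, 0, 0, 0, 0))
  expect_identical(zero$call, "ALT_negative")
  # borderline: exactly 3 flags trips the vote
  three <- call_alt(mk_sum(8.6, 0.5, 6.3, 0.9, 0.4))
  expect_identical(three$call, "ALT_positive")
  expect_equal(three$n_positive, 3L)
})
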