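test_that("localization calls follow set semantics and are symmetric", {
  expect_equal(classify_localization_pair("cw", "cy"), "complete_change")
  expect_equal(classify_localization_pair(c("mt", "cp"), "mt"), "partial_change")
  expect_equal(classify_localization_pair("nu", "nu"), "same")
  # case-insensitive, order-insensitive
  expect_equal(classify_localization_pair(c("Va", "PM"), c("pm", "va")), "same")
  expect_error(classify_localization_pair(character(0), "cy"), "empty")
  set.seed(2)
  vocab <- compartment_vocabulary()
  for (i in 1:50) {
    a <- sample(vocab, sample(1:3, 1))
    b <- sample(vocab, sample(1:3, 1))
    expect_equal(classify_localization_pair(a, b), classify_localization_pair(b, a))
  }
})

test_that("the curated 19-pair table classifies as 14 complete + 5 partial", {
  loc <- read_localization_table(extdata("gfp_localizations.tsv"))
  pairs <- read_roster(extdata("relocalized_pairs.tsv"))
  calls <- classify_pair_localizations(pairs, loc)$call
  expect_equal(sum(calls == "complete_change"), 14)
  expect_equal(sum(calls == "partial_change"), 5)
  expect_equal(sum(grepl("excluded", calls)), 0)
})

test_that("the contingency builder reproduces the observed cohort counts", {
  roster <- simulate_cohort(cohort_spec(128, 19, 8 / 19, 13 / 109,
                                        deterministic_counts = TRUE))
  calls <- ifelse(roster$reloc_flag, "complete_change", "same")
  tab <- build_contingency(calls, roster$asym_flag)
  expect_equal(unname(tab), matrix(c(8, 11, 13, 96), 2, 2, byrow = TRUE))
  # degenerate inputs
  all_same <- build_contingency(rep("same", 5), c(TRUE, rep(FALSE, 4)))
  expect_equal(sum(all_same[1, ]), 0)
  expect_error(build_contingency(character(0), logical(0)), "non-empty")
  # excluded pairs are dropped from the table
  tab2 <- build_contingency(c("same", "excluded(missing_record)"), c(TRUE, TRUE))
  expect_equal(sum(tab2), 1)
})

test_that("one-tailed Fisher handles degenerate margins and rejects bad input", {
  expect_equal(fisher_one_tailed(matrix(c(0, 0, 3, 5), 2, 2, byrow = TRUE)), 1)
  expect_error(fisher_one_tailed(matrix(c(1.5, 1, 1, 1), 2, 2)), "integers")
  expect_error(fisher_one_tailed(matrix(c(-1, 1, 1, 1), 2, 2)), "non-negative")
})

test_that("Fisher matches brute-force hypergeometric enumeration (N <= 30)", {
  # random tables; the exhaustive sweep over every margin lives in the
  # acceptance suite
  set.seed(11)
  for (i in 1:60) {
    n1 <- sample(1:15, 1); n2 <- sample(1:15, 1)
    a <- sample(0:n1, 1); c <- sample(0:n2, 1)
    tab <- matrix(c(a, n1 - a, c, n2 - c), 2, 2, byrow = TRUE)
    k <- a + c
    support <- max(0, k - n2):min(n1, k)
    brute <- sum(dhyper(support[support >= a], n1, n2, k))
    expect_equal(fisher_one_tailed(tab), brute, tolerance = 1e-12)
  }
})

test_that("DIF statistic and Monte Carlo p behave on the observed cohort", {
  d <- dif_randomization(c(19, 109), c(8, 13), n_sim = 10000, seed = 1)
  expect_equal(d$dif_obs, abs(8 / 19 - 13 / 109), tolerance = 1e-12)
  expect_lt(d$mc_p, 0.01) # strong association
  expect_gt(d$mc_p, 0)
  # bit-reproducible under a fixed seed
  d2 <- dif_randomization(c(19, 109), c(8, 13), n_sim = 10000, seed = 1)
  expect_identical(d$dif_sim, d2$dif_sim)
  expect_identical(d$mc_p, d2$mc_p)
  # permute scheme agrees in order of magnitude with the Fisher tail here
  dp <- dif_randomization(c(19, 109), c(8, 13), n_sim = 10000, seed = 1,
                          scheme = "permute")
  expect_lt(dp$mc_p, 0.02)
})

test_that("equal observed group frequencies give mc_p = 1", {
  d <- dif_randomization(c(20, 100), c(4, 20), n_sim = 2000, seed = 3)
  expect_equal(d$dif_obs, 0)
  expect_equal(d$mc_p, 1)
})

test_that("DIF randomization is calibrated under exchangeable groups", {
  # 200 null cohorts at the pooled frequency; mc_p < 0.05 should occur at
  # about the nominal rate
  hits <- 0L
  for (i in 1:200) {
    r <- simulate_cohort(cohort_spec(60, 20, 0.2, 0.2, seed = 7000 + i))
    a <- sum(r$asym_flag[r$reloc_flag]); c <- sum(r$asym_flag[!r$reloc_flag])
    d <- dif_randomization(c(20, 40), c(a, c), n_sim = 1000, seed = i)
    if (d$mc_p < 0.05) hits <- hits + 1L
  }
  expect_lt(abs(hits / 200 - 0.05), 0.05) # discrete statistic: generous band
})

test_that("invalid DIF inputs are rejected", {
  expect_error(dif_randomization(c(10, 10), c(11, 2)), "fit in their groups")
  expect_error(dif_randomization(c(10, 10), c(2, 2), n_sim = 0), "n_sim")
})

test_that("isoelectric point: exact diamino case, monotonicity, acid dominance", {
  expect_equal(isoelectric_point("GG"), 6.10, tolerance = 1e-3)
  base <- isoelectric_point("ACDEFGHIKLMNPQRSTVWY")
  expect_gt(isoelectric_point("ACDEFGHIKLMNPQRSTVWYK"), base)
  expect_lt(isoelectric_point(strrep("D", 10)), 7)
  expect_error(isoelectric_point(""), "empty")
})

test_that("bisection pI matches the fine-grid scan oracle", {
  seqs <- random_protein(25, 60, seed = 44)
  for (s in seqs) {
    expect_equal(isoelectric_point(s), pi_grid_oracle(s), tolerance = 1e-3)
  }
})

test_that("delta-pI Welch test: degenerate equality and hand-computed case", {
  expect_equal(delta_pi_ttest(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_equal(delta_pi_ttest(c(1, 2, 3), c(1, 2, 3))$t, 0)
  x <- c(1.0, 1.2, 0.8); y <- c(2.0, 2.2, 1.8)
  got <- delta_pi_ttest(x, y)
  # Welch formula by hand
  se <- sqrt(var(x) / 3 + var(y) / 3)
  t_hand <- (mean(x) - mean(y)) / se
  df_hand <- se^4 / ((var(x) / 3)^2 / 2 + (var(y) / 3)^2 / 2)
  p_hand <- 2 * pt(abs(t_hand), df_hand, lower.tail = FALSE)
  expect_equal(got$t, t_hand, tolerance = 1e-10)
  expect_equal(got$p_value, p_hand, tolerance = 1e-10)
  expect_error(delta_pi_ttest(1, c(1, 2)), "at least 2")
})
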