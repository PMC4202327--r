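test_that("zero branch lengths force three identical sequences", {
  aln <- simulate_aa_triplet(triplet_tree(0, 0, 0), n_sites = 200, seed = 1)
  expect_equal(aln$seqs[["d1"]], aln$seqs[["d2"]])
  expect_equal(aln$seqs[["d1"]], aln$seqs[["o"]])
})

test_that("simulation is deterministic in the seed and leaves global RNG alone", {
  tr <- triplet_tree(0.1, 0.2, 0.3)
  set.seed(99); before <- runif(1)
  a <- simulate_aa_triplet(tr, n_sites = 500, seed = 7)
  b <- simulate_aa_triplet(tr, n_sites = 500, seed = 7)
  expect_identical(a$seqs, b$seqs)
  c <- simulate_aa_triplet(tr, n_sites = 500, seed = 8)
  expect_false(identical(a$seqs, c$seqs))
  set.seed(99)
  expect_identical(runif(1), before)

  x <- simulate_codon_triplet(tr, 2, list(list(prop = 1, omega = 0.5)),
                              n_codons = 100, seed = 5)
  y <- simulate_codon_triplet(tr, 2, list(list(prop = 1, omega = 0.5)),
                              n_codons = 100, seed = 5)
  expect_identical(x$seqs, y$seqs)
})

test_that("pairwise divergence matches the transition-matrix expectation", {
  m <- aa_model_jtt()
  tr <- triplet_tree(0.1, 0.1, 0.2)
  n <- 10000
  aln <- simulate_aa_triplet(tr, m, n_sites = n, seed = 13)
  s1 <- strsplit(aln$seqs[["d1"]], "")[[1]]
  s2 <- strsplit(aln$seqs[["d2"]], "")[[1]]
  p_obs <- mean(s1 != s2)
  # closed form at total distance 0.2 between the duplicates
  P <- transition_matrix(m, 0.2)
  p_exp <- sum(m$freqs * (1 - diag(P)))
  se <- sqrt(p_exp * (1 - p_exp) / n)
  expect_lt(abs(p_obs - p_exp), 3 * se)
})

test_that("simulated site patterns converge to the stationary distribution", {
  m <- aa_model_jtt()
  aln <- simulate_aa_triplet(triplet_tree(0.05, 0.05, 0.1), m,
                             n_sites = 10000, seed = 21)
  # leaf composition must follow the equilibrium frequencies
  counts <- table(factor(strsplit(aln$seqs[["o"]], "")[[1]], m$alphabet))
  gof <- suppressWarnings(chisq.test(as.vector(counts), p = m$freqs))
  expect_gt(gof$p.value, 0.01)
})

test_that("free-rate branch-length errors shrink as sites grow", {
  tr <- triplet_tree(0.25, 0.15, 0.3)
  err_at <- function(n_sites) {
    errs <- vapply(1:6, function(i) {
      aln <- simulate_aa_triplet(tr, n_sites = n_sites, seed = 400 + i)
      fit <- fit_triplet_aa(aln, "free")
      mean(abs(fit$b[1:2] - c(0.25, 0.15)))
    }, 0)
    mean(errs)
  }
  expect_lt(err_at(5000), err_at(500))
})

test_that("omega = 0 everywhere yields only synonymous differences", {
  aln <- simulate_codon_triplet(triplet_tree(0.4, 0.4, 0.4), kappa = 2,
                                site_classes = list(list(prop = 1, omega = 0)),
                                n_codons = 400, seed = 2)
  gc_tab <- Biostrings::GENETIC_CODE
  to_aa <- function(s) {
    starts <- seq(1, nchar(s), 3)
    paste(gc_tab[substring(s, starts, starts + 2)], collapse = "")
  }
  aas <- vapply(aln$seqs, to_aa, "")
  expect_equal(aas[["d1"]], aas[["d2"]])
  expect_equal(aas[["d1"]], aas[["o"]])
  expect_false(any(grepl("\\*", aas)))
})

test_that("codon simulation validates proportions and produces no stops", {
  tr <- triplet_tree(0.2, 0.2, 0.2)
  expect_error(simulate_codon_triplet(tr, 2, list(list(prop = 0.7, omega = 1)),
                                      n_codons = 10, seed = 1),
               "proportions must sum to 1")
  aln <- simulate_codon_triplet(tr, 2, list(list(prop = 1, omega = 5)),
                                n_codons = 500, seed = 3)
  gc_tab <- Biostrings::GENETIC_CODE
  for (s in aln$seqs) {
    starts <- seq(1, nchar(s), 3)
    expect_false(any(gc_tab[substring(s, starts, starts + 2)] == "*"))
  }
})

test_that("deterministic cohort reproduces the observed 2x2 exactly", {
  spec <- cohort_spec(128, 19, 8 / 19, 13 / 109, deterministic_counts = TRUE)
  roster <- simulate_cohort(spec)
  expect_equal(nrow(roster), 128)
  tab <- table(reloc = roster$reloc_flag, asym = roster$asym_flag)
  expect_equal(unname(tab["TRUE", "TRUE"]), 8)
  expect_equal(unname(tab["TRUE", "FALSE"]), 11)
  expect_equal(unname(tab["FALSE", "TRUE"]), 13)
  expect_equal(unname(tab["FALSE", "FALSE"]), 96)
})

test_that("cohort generator marginals match the spec probabilities", {
  # 1000 replicates of a small cohort; group asymmetry frequencies must sit
  # within 3 binomial SEs of their target probabilities
  n_rep <- 1000
  k_reloc <- 0; k_same <- 0
  for (i in seq_len(n_rep)) {
    r <- simulate_cohort(cohort_spec(30, 10, 0.4, 0.1, seed = i))
    k_reloc <- k_reloc + sum(r$asym_flag[r$reloc_flag])
    k_same <- k_same + sum(r$asym_flag[!r$reloc_flag])
  }
  p_reloc <- k_reloc / (10 * n_rep)
  p_same <- k_same / (20 * n_rep)
  expect_lt(abs(p_reloc - 0.4), 3 * sqrt(0.4 * 0.6 / (10 * n_rep)))
  expect_lt(abs(p_same - 0.1), 3 * sqrt(0.1 * 0.9 / (20 * n_rep)))
})

test_that("equal group probabilities give DIF centred at zero", {
  difs <- vapply(1:300, function(i) {
    r <- simulate_cohort(cohort_spec(40, 15, 0.25, 0.25, seed = 5000 + i))
    sum(r$asym_flag[r$reloc_flag]) / 15 - sum(r$asym_flag[!r$reloc_flag]) / 25
  }, 0)
  expect_lt(abs(mean(difs)), 3 * sd(difs) / sqrt(length(difs)))
})

test_that("cohort draws do not depend on roster order (counter substreams)", {
  r1 <- simulate_cohort(cohort_spec(50, 20, 0.5, 0.5, seed = 4))
  r2 <- simulate_cohort(cohort_spec(50, 20, 0.5, 0.5, seed = 4))
  expect_identical(r1, r2)
  expect_error(cohort_spec(10, 11, 0.5, 0.5), "n_relocalized <= n_pairs")
})

test_that("rosters round trip through TSV", {
  roster <- simulate_cohort(cohort_spec(12, 4, 0.5, 0.2, seed = 6))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_roster(roster, path)
  back <- read_roster(path)
  expect_equal(back, roster)
})
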