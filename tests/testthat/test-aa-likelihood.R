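test_that("the JTT rate matrix is a normalized reversible generator", {
  m <- aa_model_jtt()
  expect_equal(rowSums(m$Q), rep(0, 20), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(sum(m$freqs), 1, tolerance = 1e-12)
  expect_equal(-sum(m$freqs * diag(m$Q)), 1, tolerance = 1e-12)
  # detailed balance: pi_i Q_ij = pi_j Q_ji
  F <- m$freqs * m$Q
  expect_equal(F, t(F), tolerance = 1e-12)
  # agreement with an independent JTT source when available
  skip_if_not_installed("phangorn")
  ref <- get(".JTT", envir = asNamespace("phangorn"))
  S <- matrix(0, 20, 20); S[lower.tri(S)] <- ref$Q; S <- S + t(S)
  theirs <- aa_model(S, unname(ref$bf))
  expect_equal(m$Q, theirs$Q, tolerance = 1e-4)
})

test_that("transition matrices are stochastic across time scales", {
  m <- aa_model_jtt()
  for (t in c(0.01, 0.1, 1, 10)) {
    P <- transition_matrix(m, t)
    expect_equal(rowSums(P), rep(1, 20), tolerance = 1e-12, ignore_attr = TRUE)
    expect_true(all(P >= 0))
  }
  expect_equal(transition_matrix(m, 0), diag(20), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(transition_matrix(m, -0.1), "branch length")
})

test_that("pruning equals exhaustive state enumeration and phangorn", {
  m <- aa_model_jtt()
  tr <- triplet_tree(0.13, 0.41, 0.27)
  P1 <- transition_matrix(m, tr$b1)
  P2 <- transition_matrix(m, tr$b2)
  P3 <- transition_matrix(m, tr$b3)
  # random sample of 1-site patterns against the brute-force sum over the
  # internal state (full 20^3 sweep lives in the acceptance suite)
  set.seed(5)
  for (i in 1:50) {
    x <- sample.int(20, 3, replace = TRUE)
    aln <- setNames(m$alphabet[x], c("d1", "d2", "o"))
    brute <- log(sum(m$freqs * P1[, x[1]] * P2[, x[2]] * P3[, x[3]]))
    expect_equal(aa_log_likelihood(aln, tr, m), brute, tolerance = 1e-12)
  }
  skip_if_not_installed("phangorn")
  sim <- simulate_aa_triplet(tr, m, 300, seed = 31)
  dat <- phangorn::phyDat(t(vapply(strsplit(sim$seqs, ""), identity,
                                   character(300))), type = "AA")
  ptr <- ape::read.tree(text = sprintf("(d1:%f,d2:%f,o:%f);", tr$b1, tr$b2, tr$b3))
  expect_equal(aa_log_likelihood(sim, tr, m),
               phangorn::pml(ptr, dat, model = "JTT")$logLik, tolerance = 1e-6)
})

test_that("degenerate limits behave: zero branches and stationarity", {
  m <- aa_model_jtt()
  # one site, all branches zero, same residue everywhere -> ln pi
  aln <- c(d1 = "A", d2 = "A", o = "A")
  expect_equal(aa_log_likelihood(aln, triplet_tree(0, 0, 0), m),
               log(m$freqs[["A"]]))
  # very long branches -> independence: product of frequencies
  aln2 <- c(d1 = "A", d2 = "R", o = "C")
  expect_equal(aa_log_likelihood(aln2, triplet_tree(40, 40, 40), m),
               log(m$freqs[["A"]] * m$freqs[["R"]] * m$freqs[["C"]]),
               tolerance = 1e-6)
})

test_that("log-likelihood is invariant under leaf relabeling", {
  m <- aa_model_jtt()
  sim <- simulate_aa_triplet(triplet_tree(0.1, 0.3, 0.2), m, 200, seed = 17)
  base <- aa_log_likelihood(sim, triplet_tree(0.1, 0.3, 0.2), m)
  swapped <- sim$seqs[c("d2", "d1", "o")]
  names(swapped) <- c("d1", "d2", "o")
  expect_equal(aa_log_likelihood(swapped, triplet_tree(0.3, 0.1, 0.2), m), base)
})

test_that("identical sequences fit to zero branch lengths with equal lnL", {
  seqs <- c(d1 = strrep("ARNDC", 40), d2 = strrep("ARNDC", 40),
            o = strrep("ARNDC", 40))
  free <- fit_triplet_aa(seqs, "free")
  clock <- fit_triplet_aa(seqs, "clock", free_lnl = free$lnL)
  expect_true(all(free$b < 1e-6))
  expect_equal(free$lnL, clock$lnL, tolerance = 1e-6)
})

test_that("the free fit always dominates the clock fit (nesting)", {
  for (i in 1:8) {
    aln <- simulate_aa_triplet(triplet_tree(0.1 + 0.05 * i, 0.1, 0.2),
                               n_sites = 300, seed = 600 + i)
    free <- fit_triplet_aa(aln, "free")
    clock <- fit_triplet_aa(aln, "clock", free_lnl = free$lnL)
    expect_gte(free$lnL, clock$lnL - 1e-4)
    expect_equal(clock$b[1], clock$b[2])
  }
})

test_that("the LRT handles boundaries and matches chi-square arithmetic", {
  flat <- lrt(-100, -100)
  expect_equal(flat$two_delta_L, 0)
  expect_equal(flat$p_value, 1)
  expect_equal(lrt(-100, -101.9205, df = 1)$two_delta_L, 3.841,
               tolerance = 1e-9)
  expect_equal(lrt(-100, -101.9205, df = 1)$p_value, 0.05, tolerance = 1e-3)
  expect_error(lrt(-100, -99, df = 1), "below null")
  expect_error(lrt(-100, -100, df = 0), "df")
})

test_that("BH adjustment matches the hand-worked cases and is monotone", {
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(rep(0.2, 5)), rep(0.2, 5))
  # monotone in p rank; a fully tied (step-up-flattened) vector is stable
  set.seed(8)
  p <- runif(50)
  q <- fdr_adjust(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_equal(fdr_adjust(rep(0.04, 4)), rep(0.04, 4))
  expect_error(fdr_adjust(c(0.5, 1.2)), "p-values")
})

test_that("rate_asymmetry_test calls the accelerated copy only under Q < 0.05", {
  alns <- list(
    fast1 = simulate_aa_triplet(triplet_tree(0.45, 0.1, 0.3), n_sites = 1500, seed = 71),
    equal = simulate_aa_triplet(triplet_tree(0.2, 0.2, 0.3), n_sites = 300, seed = 72),
    fast2 = simulate_aa_triplet(triplet_tree(0.1, 0.45, 0.3), n_sites = 1500, seed = 73))
  res <- rate_asymmetry_test(alns)
  expect_equal(res$pair_id, names(alns))
  expect_equal(res$accelerated_copy[res$pair_id == "fast1"], "gene1")
  expect_equal(res$accelerated_copy[res$pair_id == "fast2"], "gene2")
  expect_true(all(res$accelerated_copy[res$q_value >= 0.05] == "none"))
  expect_true(all(res$two_delta_L >= 0))
})
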