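make_hits <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(query = r[[1]], subject = r[[2]], pident = 90, length = as.numeric(r[[3]]),
               mismatch = 0L, gapopen = 0L, qstart = 1L, qend = 1L, sstart = 1L,
               send = 1L, evalue = as.numeric(r[[4]]), bitscore = as.numeric(r[[5]]),
               stringsAsFactors = FALSE)
  }))
  df
}

test_that("hit filtering enforces the e-value and 60% coverage thresholds", {
  lens <- c(a = 100, x = 120)
  hits <- make_hits(
    list("a", "x", 80, 1e-4, 200),  # e-value too large
    list("a", "x", 59, 1e-9, 200),  # 59/100 < 0.60
    list("a", "x", 80, 1e-6, 200),  # passes both
    list("a", "x", 60, 1e-5, 200))  # both thresholds exactly at the boundary
  kept <- filter_hits(hits, lens, lens)
  expect_equal(nrow(kept), 2)
  expect_equal(kept$length, c(80, 60))
  expect_error(filter_hits(make_hits(list("a", "zz", 80, 1e-9, 10)), lens, lens),
               "missing subject length for id: zz")
  # idempotence
  expect_equal(filter_hits(kept, lens, lens), kept)
})

test_that("reciprocal best hits require mutual best and fall back one-way", {
  ab <- make_hits(list("a", "x", 80, 1e-9, 300), list("a", "y", 80, 1e-9, 100))
  ba_recip <- make_hits(list("x", "a", 80, 1e-9, 300))
  got <- reciprocal_best_hits(ab, ba_recip)
  expect_equal(got$subject, "x")
  expect_equal(got$provenance, "reciprocal")

  ba_other <- make_hits(list("x", "aprime", 80, 1e-9, 300))
  expect_equal(nrow(reciprocal_best_hits(ab, ba_other)), 0)
  fallback <- reciprocal_best_hits(ab, ba_other, allow_one_way = TRUE)
  expect_equal(fallback$subject, "x")
  expect_equal(fallback$provenance, "one-way")
})

test_that("best-hit ties break by e-value then lexicographic subject id", {
  ab <- make_hits(list("a", "zz", 80, 1e-9, 300), list("a", "bb", 80, 1e-9, 300))
  got <- reciprocal_best_hits(ab, make_hits(list("bb", "a", 80, 1e-9, 300)))
  expect_equal(got$subject, "bb")
  # lower e-value wins over lexicographic order
  ab2 <- make_hits(list("a", "zz", 80, 1e-12, 300), list("a", "bb", 80, 1e-9, 300))
  got2 <- reciprocal_best_hits(ab2, make_hits(list("zz", "a", 80, 1e-9, 300)))
  expect_equal(got2$subject, "zz")
})

test_that("RBH membership is symmetric under table swap", {
  ab <- make_hits(list("a", "x", 80, 1e-9, 300), list("b", "x", 80, 1e-9, 250))
  ba <- make_hits(list("x", "a", 80, 1e-9, 300))
  fwd <- reciprocal_best_hits(ab, ba)
  swapped <- reciprocal_best_hits(ba, ab)
  expect_equal(nrow(fwd), nrow(swapped))
  expect_setequal(paste(fwd$query, fwd$subject), paste(swapped$subject, swapped$query))
})

test_that("dS triangulation accepts strictly, rejects boundaries and NaN", {
  expect_true(triangulation_filter(0.5, 0.8, 0.9)$accept)
  expect_false(triangulation_filter(0.5, 0.4, 0.9)$accept)
  strict <- triangulation_filter(0.5, 0.5, 0.9)
  expect_false(strict$accept)
  sat <- triangulation_filter(0.5, NaN, 0.9)
  expect_false(sat$accept)
  expect_equal(sat$reason, "unestimable")
})

test_that("ortholog assignment respects species priority and flags provenance", {
  pairs <- data.frame(gene1 = "d1", gene2 = "d2")
  sp1 <- data.frame(query = "d1", subject = "o1", provenance = "reciprocal")
  sp2 <- data.frame(query = c("d1", "d2"), subject = c("o2", "o2"),
                    provenance = c("reciprocal", "one-way"))
  got <- assign_orthologs(pairs, list(papaya = sp1, vitis = sp2))
  # papaya lacks a shared candidate -> falls through to vitis
  expect_equal(got$ortholog, "o2")
  expect_equal(got$ortholog_species, "vitis")
  expect_equal(got$provenance, "one-way")
})

test_that("triangulation accepts simulated triplets with young duplications", {
  # duplication well inside the speciation: dS1 ~ 0.2, dS2/dS3 ~ 0.8
  accepted <- 0L
  n <- 12L
  for (i in seq_len(n)) {
    aln <- simulate_codon_triplet(triplet_tree(0.15, 0.15, 0.9), kappa = 2,
                                  site_classes = list(list(prop = 1, omega = 0.2)),
                                  n_codons = 800, seed = 3000 + i)
    ds1 <- pairwise_dnds_ml(aln$seqs["d1"], aln$seqs["d2"])$dS
    ds2 <- pairwise_dnds_ml(aln$seqs["d1"], aln$seqs["o"])$dS
    ds3 <- pairwise_dnds_ml(aln$seqs["d2"], aln$seqs["o"])$dS
    if (triangulation_filter(ds1, ds2, ds3)$accept) accepted <- accepted + 1L
  }
  expect_gte(accepted, n - 1L)
})
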