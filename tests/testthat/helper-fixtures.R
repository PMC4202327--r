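# Shared fixture builders; everything is generated in code.

# Random ungapped protein sequences (for IO round trips and pI checks).
random_protein <- function(n, len, seed = 1) {
  aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    paste(sample(aa, len, replace = TRUE), collapse = "")
  }, "")
}

# Random bifurcating trees on a fixed leaf set.
random_trees <- function(n_trees, leaves, seed = 1) {
  set.seed(seed)
  trees <- lapply(seq_len(n_trees), function(i) {
    ape::rtree(length(leaves), tip.label = sample(leaves))
  })
  class(trees) <- "multiPhylo"
  trees
}

# Vectorized net-charge scan: independent fine-grid oracle for the
# isoelectric point (bisection is the implementation path).
pi_grid_oracle <- function(sequence, step = 1e-5) {
  pk <- c(Nterm = 8.6, Cterm = 3.6, C = 8.5, D = 3.9, E = 4.1,
          H = 6.5, K = 10.8, R = 12.5, Y = 10.1)
  chars <- strsplit(toupper(sequence), "")[[1]]
  cnt <- vapply(c("C", "D", "E", "H", "K", "R", "Y"), function(a) sum(chars == a), 0)
  pH <- seq(0, 14, by = step)
  pos <- 1 / (1 + 10^(pH - pk["Nterm"])) +
    cnt["H"] / (1 + 10^(pH - pk["H"])) +
    cnt["K"] / (1 + 10^(pH - pk["K"])) +
    cnt["R"] / (1 + 10^(pH - pk["R"]))
  neg <- 1 / (1 + 10^(pk["Cterm"] - pH)) +
    cnt["C"] / (1 + 10^(pk["C"] - pH)) +
    cnt["D"] / (1 + 10^(pk["D"] - pH)) +
    cnt["E"] / (1 + 10^(pk["E"] - pH)) +
    cnt["Y"] / (1 + 10^(pk["Y"] - pH))
  charge <- pos - neg
  pH[which.min(abs(charge))]
}

# A small codon triplet fixture reused by codon-model tests.
small_codon_triplet <- function(n_codons = 300, seed = 42,
                                b = c(0.2, 0.2, 0.4), omega = 0.3, kappa = 2) {
  simulate_codon_triplet(triplet_tree(b[1], b[2], b[3]), kappa = kappa,
                         site_classes = list(list(prop = 1, omega = omega)),
                         n_codons = n_codons, seed = seed)
}

extdata <- function(name) system.file("extdata", name, package = "dupreloc")

# Topology equality irrespective of rooting and rotation.
topo_equal <- function(t1, t2) {
  u1 <- ape::unroot(t1); u2 <- ape::unroot(t2)
  isTRUE(all.equal(ape::dist.topo(u1, u2)[1], 0))
}
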