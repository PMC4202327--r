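# Simulators for the two kinds of objects the pipeline consumes: 3-taxon
# sequence triplets (duplicate 1, duplicate 2, outgroup) under amino-acid or
# codon models, and duplicate-pair cohorts with configurable relocalization
# and asymmetry structure.

#' Unrooted triplet tree
#'
#' The three-taxon star joining duplicate 1, duplicate 2, and the outgroup at
#' a single internal node. The clock (rate-symmetry) null constrains
#' `b1 == b2`.
#'
#' @param b1,b2 Branch lengths (expected substitutions per site) to the two
#'   duplicates.
#' @param b3 Branch length to the outgroup.
#' @return Object of class `triplet_tree`.
#' @export
triplet_tree <- function(b1, b2, b3) {
  b <- c(b1 = b1, b2 = b2, b3 = b3)
  assert_that(all(is.finite(b)), "non-finite branch length")
  assert_that(all(b >= 0), "branch lengths must be >= 0")
  structure(list(b1 = b1, b2 = b2, b3 = b3), class = "triplet_tree")
}

new_triplet_alignment <- function(seqs, type, n_sites, classes = NULL) {
  structure(list(seqs = seqs, type = type, n_sites = n_sites, classes = classes),
            class = "triplet_alignment")
}

# Evolve state indices one branch down: for each site, draw the child state
# from the parent's transition-matrix row. Vectorized by parent state.
evolve_states <- function(parent, P) {
  child <- integer(length(parent))
  n <- ncol(P)
  for (s in unique(parent)) {
    idx <- which(parent == s)
    child[idx] <- sample.int(n, length(idx), replace = TRUE, prob = P[s, ])
  }
  child
}

#' Simulate an amino-acid triplet alignment
#'
#' Draws root states from the model's equilibrium frequencies and evolves
#' them independently down the three branches of a [triplet_tree()].
#'
#' @param tree A [triplet_tree()].
#' @param model An [aa_model()]; JTT by default.
#' @param n_sites Number of alignment columns (>= 1).
#' @param seed Integer seed; every call with the same arguments returns the
#'   identical alignment.
#' @return A `triplet_alignment` with ungapped sequences named `d1`, `d2`, `o`.
#' @export
simulate_aa_triplet <- function(tree, model = aa_model_jtt(), n_sites, seed = 0) {
  assert_that(inherits(tree, "triplet_tree"), "tree must be a triplet_tree")
  assert_that(is.finite(n_sites) && n_sites >= 1, "n_sites must be >= 1")
  n_sites <- as.integer(n_sites)
  with_seed(seed, {
    root <- sample.int(20L, n_sites, replace = TRUE, prob = model$freqs)
    leaves <- lapply(c(tree$b1, tree$b2, tree$b3), function(b) {
      evolve_states(root, transition_matrix(model, b))
    })
    seqs <- vapply(leaves, function(x) paste(model$alphabet[x], collapse = ""), "")
    names(seqs) <- c("d1", "d2", "o")
    new_triplet_alignment(seqs, "aa", n_sites)
  })
}

#' Simulate a codon triplet alignment with site classes
#'
#' Sites are assigned i.i.d. to classes by `proportion`; each class carries
#' its own dN/dS ratio per branch, so both uniform-omega data and branch-site
#' (foreground-only positive selection) data can be generated. Branch lengths
#' are expected substitutions per codon under the class mixture on that
#' branch.
#'
#' @param tree A [triplet_tree()] (branch lengths in substitutions/codon).
#' @param kappa Transition/transversion ratio.
#' @param site_classes List of classes, each `list(prop =, omega =)` where
#'   `omega` is a single ratio or a length-3 vector (branches b1, b2, b3);
#'   proportions must sum to 1.
#' @param codon_freqs 61-vector of sense-codon frequencies (uniform default).
#' @param n_codons Number of codon columns (>= 1).
#' @param seed Integer seed.
#' @return A `triplet_alignment` (type `"codon"`, nucleotide strings of
#'   length `3 * n_codons`, no stop codons) whose `classes` field records the
#'   simulated class of each site.
#' @export
simulate_codon_triplet <- function(tree, kappa, site_classes, codon_freqs = NULL,
                                   n_codons, seed = 0) {
  assert_that(inherits(tree, "triplet_tree"), "tree must be a triplet_tree")
  assert_that(is.finite(n_codons) && n_codons >= 1, "n_codons must be >= 1")
  props <- vapply(site_classes, function(cl) cl$prop, 0)
  assert_that(abs(sum(props) - 1) < 1e-8, "class proportions must sum to 1")
  omegas <- lapply(site_classes, function(cl) {
    w <- cl$omega
    if (length(w) == 1L) w <- rep(w, 3L)
    assert_that(length(w) == 3L && all(w >= 0), "omega must be length 1 or 3, >= 0")
    w
  })
  n_codons <- as.integer(n_codons)
  sp <- codon_space()
  blen <- c(tree$b1, tree$b2, tree$b3)

  # Per-branch time scale: mixture-weighted expected flux across classes.
  models <- vector("list", 3L)
  for (br in 1:3) {
    raw <- lapply(omegas, function(w) codon_model(kappa, w[br], codon_freqs))
    scale_br <- sum(props * vapply(raw, function(m) m$flux, 0))
    models[[br]] <- lapply(omegas, function(w) {
      codon_model(kappa, w[br], codon_freqs, scale = scale_br)
    })
  }

  with_seed(seed, {
    cls <- sample.int(length(props), n_codons, replace = TRUE, prob = props)
    pi <- models[[1]][[1]]$freqs
    root <- sample.int(sp$n, n_codons, replace = TRUE, prob = pi)
    seqs <- character(3L)
    for (br in 1:3) {
      child <- integer(n_codons)
      for (k in seq_along(props)) {
        idx <- which(cls == k)
        if (!length(idx)) next
        P <- transition_matrix(models[[br]][[k]], blen[br])
        child[idx] <- evolve_states(root[idx], P)
      }
      seqs[br] <- paste(sp$codons[child], collapse = "")
    }
    names(seqs) <- c("d1", "d2", "o")
    new_triplet_alignment(seqs, "codon", n_codons, classes = cls)
  })
}

#' Cohort specification
#'
#' Describes a cohort of duplicate pairs: how many, how many relocalized, and
#' the per-group probability of asymmetric sequence evolution. The observed
#' study cohort corresponds to
#' `cohort_spec(128, 19, 8/19, 13/109, deterministic_counts = TRUE)`.
#'
#' @param n_pairs Number of duplicate pairs.
#' @param n_relocalized Number of pairs with divergent localization
#'   (0..n_pairs; always exact).
#' @param p_asym_reloc,p_asym_same Probability of asymmetric evolution in the
#'   relocalized / non-relocalized group.
#' @param seed Integer seed (default 0).
#' @param deterministic_counts If `TRUE`, assign exactly `round(p * n)`
#'   asymmetric pairs per group instead of Bernoulli draws.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_pairs, n_relocalized, p_asym_reloc, p_asym_same,
                        seed = 0, deterministic_counts = FALSE) {
  assert_that(n_pairs >= 0 && n_relocalized >= 0 && n_relocalized <= n_pairs,
              "need 0 <= n_relocalized <= n_pairs")
  assert_that(p_asym_reloc >= 0 && p_asym_reloc <= 1 &&
              p_asym_same >= 0 && p_asym_same <= 1,
              "probabilities must be in [0, 1]")
  structure(list(n_pairs = as.integer(n_pairs),
                 n_relocalized = as.integer(n_relocalized),
                 p_asym_reloc = p_asym_reloc, p_asym_same = p_asym_same,
                 seed = seed, deterministic_counts = deterministic_counts),
            class = "cohort_spec")
}

#' Simulate a duplicate-pair cohort
#'
#' Produces a pair roster with relocalization and asymmetry flags. Asymmetry
#' draws use a per-pair sub-seed derived by counter, so a pair's flag does not
#' depend on cohort order.
#'
#' @param spec A [cohort_spec()].
#' @return `data.frame` with columns `pair_id`, `gene1`, `gene2`,
#'   `reloc_flag`, `asym_flag`.
#' @export
simulate_cohort <- function(spec) {
  assert_that(inherits(spec, "cohort_spec"), "spec must be a cohort_spec")
  n <- spec$n_pairs
  reloc <- seq_len(n) <= spec$n_relocalized
  if (spec$deterministic_counts) {
    k_reloc <- round(spec$p_asym_reloc * spec$n_relocalized)
    k_same <- round(spec$p_asym_same * (n - spec$n_relocalized))
    asym <- logical(n)
    asym[which(reloc)[seq_len(k_reloc)]] <- TRUE
    asym[which(!reloc)[seq_len(k_same)]] <- TRUE
  } else {
    p <- ifelse(reloc, spec$p_asym_reloc, spec$p_asym_same)
    asym <- vapply(seq_len(n), function(i) {
      with_seed(derive_seed(spec$seed, i), runif(1) < p[i])
    }, logical(1))
  }
  data.frame(
    pair_id = sprintf("pair%04d", seq_len(n)),
    gene1 = sprintf("g%04da", seq_len(n)),
    gene2 = sprintf("g%04db", seq_len(n)),
    reloc_flag = reloc,
    asym_flag = asym,
    stringsAsFactors = FALSE
  )
}

#' Write / read a pair roster
#'
#' Tab-separated roster with header `pair_id gene1 gene2 reloc_flag asym_flag`.
#'
#' @param roster Data frame as returned by [simulate_cohort()].
#' @param path File path.
#' @return `read_roster` returns the roster data frame.
#' @export
write_roster <- function(roster, path) {
  write.table(roster, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_roster
#' @export
read_roster <- function(path) {
  assert_that(file.exists(path), paste0("no such file: ", path))
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("pair_id", "gene1", "gene2")
  assert_that(all(need %in% names(df)),
              paste("roster must have columns:", paste(need, collapse = ", ")))
  for (col in c("reloc_flag", "asym_flag")) {
    if (col %in% names(df)) df[[col]] <- as.logical(df[[col]])
  }
  df
}
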