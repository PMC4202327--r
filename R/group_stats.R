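# Localization-set comparison, 2x2 enrichment statistics (one-tailed Fisher
# exact, Monte Carlo DIF randomization), and isoelectric-point analysis.

#' Classify localization divergence of a duplicate pair
#'
#' Compares the two compartment-token sets (case-insensitively): `same` when
#' equal, `complete_change` when disjoint, `partial_change` otherwise
#' (expansion, contraction, or partial overlap). Symmetric in its arguments.
#'
#' @param setA,setB Non-empty character vectors of compartment tokens.
#' @return `"same"`, `"complete_change"`, or `"partial_change"`.
#' @export
classify_localization_pair <- function(setA, setB) {
  assert_that(length(setA) > 0 && length(setB) > 0, "empty compartment set")
  a <- unique(tolower(trimws(setA)))
  b <- unique(tolower(trimws(setB)))
  if (setequal(a, b)) return("same")
  if (length(intersect(a, b)) == 0L) return("complete_change")
  "partial_change"
}

#' Classify localization for a table of pairs
#'
#' Joins per-gene localization records onto a pair roster and classifies each
#' pair. With `strict_same_study`, pairs whose two records come from
#' different studies or different conditions are excluded (call
#' `excluded(different_study_or_condition)`), as are pairs with a missing
#' record (`excluded(missing_record)`).
#'
#' @param pairs `data.frame` with `gene1`, `gene2`.
#' @param localizations Localization table from [read_localization_table()]
#'   (or equivalent, with `gene_id`, list-column `compartments`, `study_id`,
#'   `condition`).
#' @param strict_same_study Apply the same-study/same-condition exclusion
#'   (default `TRUE`).
#' @return `pairs` with a `call` column.
#' @export
classify_pair_localizations <- function(pairs, localizations,
                                        strict_same_study = TRUE) {
  loc_at <- function(g) {
    i <- match(g, localizations$gene_id)
    if (is.na(i)) NULL else localizations[i, , drop = FALSE]
  }
  pairs$call <- vapply(seq_len(nrow(pairs)), function(i) {
    r1 <- loc_at(pairs$gene1[i]); r2 <- loc_at(pairs$gene2[i])
    if (is.null(r1) || is.null(r2)) return("excluded(missing_record)")
    if (strict_same_study &&
        (r1$study_id != r2$study_id || r1$condition != r2$condition)) {
      return("excluded(different_study_or_condition)")
    }
    classify_localization_pair(r1$compartments[[1]], r2$compartments[[1]])
  }, "")
  pairs
}

#' Build the relocalization-by-asymmetry 2x2 table
#'
#' Relocalized means `complete_change` or `partial_change`; excluded pairs
#' are dropped. Counts are `[a, b; c, d]` = relocalized & asymmetric,
#' relocalized & not, same & asymmetric, same & not.
#'
#' @param calls Character vector of pair calls (values from
#'   [classify_localization_pair()] or `excluded(...)`).
#' @param asym_flags Logical vector, same length: asymmetric sequence
#'   evolution per pair.
#' @return 2x2 integer matrix with dimnames.
#' @export
build_contingency <- function(calls, asym_flags) {
  assert_that(length(calls) == length(asym_flags) && length(calls) > 0,
              "calls and asym_flags must be non-empty and the same length")
  assert_that(!anyNA(asym_flags), "pair missing asymmetry flag")
  keep <- !grepl("^excluded", calls)
  calls <- calls[keep]; asym_flags <- asym_flags[keep]
  assert_that(all(calls %in% c("same", "complete_change", "partial_change")),
              "invalid localization call")
  reloc <- calls != "same"
  tab <- matrix(c(sum(reloc & asym_flags), sum(reloc & !asym_flags),
                  sum(!reloc & asym_flags), sum(!reloc & !asym_flags)),
                2, 2, byrow = TRUE,
                dimnames = list(c("relocalized", "same"),
                                c("asymmetric", "symmetric")))
  tab
}

#' One-tailed Fisher exact test for asymmetry enrichment
#'
#' Upper-tail hypergeometric probability of observing at least `a` asymmetric
#' pairs in the relocalized group, with all margins fixed (enrichment
#' direction).
#'
#' @param table 2x2 matrix `[a, b; c, d]` as from [build_contingency()].
#' @return One-tailed p-value.
#' @export
fisher_one_tailed <- function(table) {
  assert_that(all(dim(table) == c(2, 2)), "need a 2x2 table")
  assert_that(all(table >= 0) && all(table == round(table)),
              "counts must be non-negative integers")
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  if (a + b == 0L || a + c == 0L) return(1)
  phyper(a - 1, m = a + b, n = c + d, k = a + c, lower.tail = FALSE)
}

#' Monte Carlo DIF randomization test
#'
#' The DIF statistic is the absolute difference in the frequency of
#' asymmetric sequence evolution between the relocalized and non-relocalized
#' groups: `DIF_obs = |a/n_reloc - c/n_same|`. The null distribution is
#' built from `n_sim` randomized cohorts; `mc_p` is the fraction of
#' replicates with `DIF_sim >= DIF_obs` (the two-tailed interpretation of an
#' absolute-valued statistic).
#'
#' Two randomization schemes are available because published descriptions of
#' "randomized data" are often under-specified: `resample` (default) redraws
#' every pair's asymmetry flag independently at the pooled frequency with
#' group sizes fixed; `permute` shuffles the observed flags across pairs
#' (equivalent to drawing the group-1 count from the hypergeometric).
#'
#' @param group_sizes Integer vector `(n_reloc, n_same)`.
#' @param asym_counts Integer vector `(a, c)`: asymmetric pairs per group.
#' @param n_sim Number of randomized replicates (default 10000).
#' @param seed Integer seed (default 0); fixed seed gives bit-reproducible p.
#' @param scheme `"resample"` or `"permute"`.
#' @param add_one Use `(k + 1) / (n_sim + 1)` instead of `k / n_sim`.
#' @return List with `dif_obs`, `mc_p`, `n_sim`, `seed`, `scheme`, and the
#'   simulated statistics `dif_sim`.
#' @export
dif_randomization <- function(group_sizes, asym_counts, n_sim = 10000,
                              seed = 0, scheme = c("resample", "permute"),
                              add_one = FALSE) {
  scheme <- match.arg(scheme)
  n1 <- group_sizes[1]; n2 <- group_sizes[2]
  a <- asym_counts[1]; c <- asym_counts[2]
  assert_that(n_sim >= 1, "n_sim must be >= 1")
  assert_that(a >= 0 && c >= 0 && a <= n1 && c <= n2,
              "asymmetric counts must fit in their groups")
  dif_obs <- abs(a / n1 - c / n2)
  k_tot <- a + c
  dif_sim <- with_seed(seed, {
    if (scheme == "resample") {
      p_pool <- k_tot / (n1 + n2)
      abs(rbinom(n_sim, n1, p_pool) / n1 - rbinom(n_sim, n2, p_pool) / n2)
    } else {
      k1 <- rhyper(n_sim, m = k_tot, n = n1 + n2 - k_tot, k = n1)
      abs(k1 / n1 - (k_tot - k1) / n2)
    }
  })
  k <- sum(dif_sim >= dif_obs - 1e-12)
  mc_p <- if (add_one) (k + 1) / (n_sim + 1) else k / n_sim
  list(dif_obs = dif_obs, mc_p = mc_p, n_sim = n_sim, seed = seed,
       scheme = scheme, dif_sim = dif_sim)
}

#' Group enrichment summary
#'
#' Convenience wrapper: builds the 2x2 table from calls and flags and runs
#' both the one-tailed Fisher exact test and the DIF randomization.
#'
#' @inheritParams build_contingency
#' @inheritParams dif_randomization
#' @return List with `table`, `fisher_p`, `dif_obs`, `mc_p`, `n_sim`,
#'   `seed`, `scheme`.
#' @export
group_enrichment <- function(calls, asym_flags, n_sim = 10000, seed = 0,
                             scheme = c("resample", "permute")) {
  scheme <- match.arg(scheme)
  tab <- build_contingency(calls, asym_flags)
  dif <- dif_randomization(c(sum(tab[1, ]), sum(tab[2, ])),
                           c(tab[1, 1], tab[2, 1]),
                           n_sim = n_sim, seed = seed, scheme = scheme)
  list(table = tab, fisher_p = fisher_one_tailed(tab),
       dif_obs = dif$dif_obs, mc_p = dif$mc_p, n_sim = n_sim, seed = seed,
       scheme = scheme)
}

# EMBOSS pK set: terminal and side-chain dissociation constants.
.EMBOSS_PK <- c(Nterm = 8.6, Cterm = 3.6, C = 8.5, D = 3.9, E = 4.1,
                H = 6.5, K = 10.8, R = 12.5, Y = 10.1)

# Net charge of a protein at a given pH under Henderson-Hasselbalch.
protein_net_charge <- function(counts, pH, pk = .EMBOSS_PK) {
  pos <- c(Nterm = 1, H = unname(counts["H"]), K = unname(counts["K"]),
           R = unname(counts["R"]))
  neg <- c(Cterm = 1, C = unname(counts["C"]), D = unname(counts["D"]),
           E = unname(counts["E"]), Y = unname(counts["Y"]))
  sum(pos * 1 / (1 + 10^(pH - pk[names(pos)]))) -
    sum(neg * 1 / (1 + 10^(pk[names(neg)] - pH)))
}

#' Protein isoelectric point
#'
#' pH at which the net charge of the protein is zero, from the
#' Henderson-Hasselbalch titration of the N- and C-termini and the C, D, E,
#' H, K, R, Y side chains with the EMBOSS pK set, solved by bisection on
#' \[0, 14\].
#'
#' @param sequence Amino-acid sequence (one-letter codes; characters outside
#'   the 20-letter alphabet are ignored for charge).
#' @param tol Bisection tolerance in pH units (default 1e-4).
#' @return The pI in pH units.
#' @export
isoelectric_point <- function(sequence, tol = 1e-4) {
  chars <- strsplit(toupper(gsub("[-*\\s]", "", sequence)), "")[[1]]
  chars <- chars[chars %in% AA_ALPHABET]
  assert_that(length(chars) > 0, "empty sequence")
  counts <- vapply(c("C", "D", "E", "H", "K", "R", "Y"),
                   function(a) sum(chars == a), 0)
  lo <- 0; hi <- 14
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (protein_net_charge(counts, mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Welch t-test on within-pair pI differences
#'
#' Two-sample two-tailed Welch test of the absolute pI difference (delta-pI)
#' between duplicate pairs with and without subcellular relocalization.
#'
#' @param dpi_relocalized,dpi_same Numeric vectors of per-pair `|pI1 - pI2|`
#'   values; each group needs at least 2 values.
#' @return List with group means, `t`, `df`, `p_value`.
#' @export
delta_pi_ttest <- function(dpi_relocalized, dpi_same) {
  assert_that(length(dpi_relocalized) >= 2 && length(dpi_same) >= 2,
              "each group needs at least 2 values")
  if (identical(sort(dpi_relocalized), sort(dpi_same)) ||
      (var(dpi_relocalized) == 0 && var(dpi_same) == 0 &&
       mean(dpi_relocalized) == mean(dpi_same))) {
    return(list(mean_relocalized = mean(dpi_relocalized),
                mean_same = mean(dpi_same), t = 0, df = NA_real_, p_value = 1))
  }
  tt <- t.test(dpi_relocalized, dpi_same, var.equal = FALSE)
  list(mean_relocalized = mean(dpi_relocalized), mean_same = mean(dpi_same),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}
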