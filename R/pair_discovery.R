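# Duplicate-pair discovery: majority-rule consensus of bootstrap gene-family
# trees, extraction of two-member monophyletic clades, dS age filtering, and
# duplication-type labeling against WGD/tandem rosters.

#' Strict-majority consensus tree
#'
#' Consensus of a set of trees on the same leaves: exactly those non-trivial
#' bipartitions present in strictly more than `threshold` of the input trees
#' are retained (a clade in exactly 50% of trees is excluded at the default
#' threshold). Retained clades carry their support fraction as node labels.
#'
#' @param trees A list of `phylo` trees or an `ape::multiPhylo`.
#' @param threshold Support fraction that must be exceeded; default 0.5
#'   (majority rule).
#' @return A `phylo` tree with support fractions in `node.label`.
#' @export
majority_consensus <- function(trees, threshold = 0.5) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- lapply(trees, function(tr) {
    assert_that(inherits(tr, "phylo"), "every element must be a phylo tree")
    tr
  })
  class(trees) <- "multiPhylo"
  leafsets <- lapply(trees, function(tr) sort(tr$tip.label))
  for (ls in leafsets) {
    assert_that(identical(ls, leafsets[[1]]), "trees have mismatched leaf sets")
  }
  cons <- ape::consensus(trees, p = threshold, check.labels = TRUE)
  # ape records support as proportions in node labels; keep them numeric.
  if (!is.null(cons$node.label)) {
    cons$node.label <- as.character(suppressWarnings(as.numeric(cons$node.label)))
  }
  cons
}

#' Extract two-member monophyletic clades (cherries)
#'
#' Returns every internal node with exactly two leaf children as an unordered
#' id pair, ordered lexicographically within and across pairs.
#'
#' @param tree A `phylo` tree.
#' @return `data.frame` with columns `gene1`, `gene2` (gene1 < gene2).
#' @export
extract_two_member_clades <- function(tree) {
  assert_that(inherits(tree, "phylo"), "tree must be a phylo object")
  ntip <- length(tree$tip.label)
  out <- list()
  for (node in unique(tree$edge[, 1])) {
    children <- tree$edge[tree$edge[, 1] == node, 2]
    if (length(children) == 2L && all(children <= ntip)) {
      pr <- sort(tree$tip.label[children])
      out[[length(out) + 1L]] <- pr
    }
  }
  if (!length(out)) {
    return(data.frame(gene1 = character(), gene2 = character(),
                      stringsAsFactors = FALSE))
  }
  df <- data.frame(gene1 = vapply(out, `[[`, "", 1),
                   gene2 = vapply(out, `[[`, "", 2),
                   stringsAsFactors = FALSE)
  df <- df[order(df$gene1, df$gene2), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Filter duplicate pairs by synonymous-distance age
#'
#' Pairwise dS between duplicates proxies the age of the duplication; pairs
#' older than the cutoff are dropped. The cutoff (default dS = 1, about the
#' mean age of alpha-WGD duplicates) is inclusive: `dS <= cutoff` is kept.
#'
#' @param pairs `data.frame` with a numeric `dS` column.
#' @param cutoff Maximum dS retained (default 1.0).
#' @param verbose Log how many pairs were dropped.
#' @return The retained rows of `pairs`.
#' @export
filter_by_age <- function(pairs, cutoff = 1.0, verbose = FALSE) {
  assert_that("dS" %in% names(pairs), "pairs must have a dS column")
  assert_that(all(is.finite(pairs$dS)), "missing or non-finite dS")
  keep <- pairs$dS <= cutoff
  stage_log("filter_by_age", nrow(pairs), sum(keep),
            rep("dS_above_cutoff", sum(!keep)), verbose)
  pairs[keep, , drop = FALSE]
}

#' Label duplication type against WGD and tandem rosters
#'
#' A pair found in the whole-genome-duplication roster is `alpha-WGD`, else
#' in the tandem roster `tandem`, else `other`. Membership is
#' order-insensitive; a pair present in both rosters is an error.
#'
#' @param pairs `data.frame` with `gene1`, `gene2`.
#' @param wgd_roster,tandem_roster Data frames with `gene1`, `gene2` columns
#'   (unordered pairs).
#' @return `pairs` with a `duplication_type` column.
#' @export
label_duplication_type <- function(pairs, wgd_roster, tandem_roster) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  roster_keys <- function(r) {
    if (is.null(r) || nrow(r) == 0L) return(character(0))
    key(r$gene1, r$gene2)
  }
  wk <- roster_keys(wgd_roster)
  tk <- roster_keys(tandem_roster)
  pk <- key(pairs$gene1, pairs$gene2)
  both <- pk %in% wk & pk %in% tk
  assert_that(!any(both),
              paste0("pair in both WGD and tandem rosters: ",
                     pairs$gene1[both][1], "/", pairs$gene2[both][1]))
  pairs$duplication_type <- ifelse(pk %in% wk, "alpha-WGD",
                            ifelse(pk %in% tk, "tandem", "other"))
  pairs
}

#' Discover duplicate pairs from bootstrap tree sets
#'
#' Convenience composition for one gene family: strict-majority consensus of
#' the bootstrap trees, then cherry extraction.
#'
#' @param trees Bootstrap trees (list or `multiPhylo`) on one leaf set.
#' @param threshold Consensus threshold (see [majority_consensus()]).
#' @return `data.frame` of candidate pairs (`gene1`, `gene2`).
#' @export
discover_pairs <- function(trees, threshold = 0.5) {
  extract_two_member_clades(majority_consensus(trees, threshold))
}
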