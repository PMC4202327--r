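# Outgroup-ortholog assignment: e-value/coverage filtering of similarity
# hits, reciprocal best hit with one-way fallback, and dS triangulation.

#' Filter similarity hits by e-value and coverage
#'
#' Retains hits with e-value <= `max_evalue` and alignment length covering at
#' least `min_coverage` of the shorter of the two proteins. Coverage uses the
#' hit's reported alignment length (aligned columns, gaps included) against
#' full protein lengths.
#'
#' @param hits Hit table from [read_hit_table()].
#' @param query_len,subject_len Named numeric vectors of protein lengths; an
#'   id appearing in `hits` but missing here is an error.
#' @param max_evalue E-value threshold (default 1e-5).
#' @param min_coverage Minimum fraction of the shorter protein (default 0.60).
#' @return The retained rows of `hits`.
#' @export
filter_hits <- function(hits, query_len, subject_len,
                        max_evalue = 1e-5, min_coverage = 0.60) {
  if (nrow(hits) == 0L) return(hits)
  missing_q <- setdiff(hits$query, names(query_len))
  assert_that(length(missing_q) == 0L,
              paste0("missing query length for id: ", missing_q[1]))
  missing_s <- setdiff(hits$subject, names(subject_len))
  assert_that(length(missing_s) == 0L,
              paste0("missing subject length for id: ", missing_s[1]))
  shorter <- pmin(query_len[hits$query], subject_len[hits$subject])
  keep <- hits$evalue <= max_evalue & hits$length / shorter >= min_coverage
  hits[keep, , drop = FALSE]
}

# Best hit per query: highest bit score, ties broken by lowest e-value then
# lexicographically smallest subject id.
best_hits <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  ord <- order(hits$query, -hits$bitscore, hits$evalue, hits$subject)
  h <- hits[ord, , drop = FALSE]
  h[!duplicated(h$query), , drop = FALSE]
}

#' Reciprocal best hits with one-way fallback
#'
#' A pair (a, b) is reciprocal iff b is a's best hit in the forward table and
#' a is b's best hit in the reverse table. With `allow_one_way`, queries with
#' no reciprocal partner fall back to their one-way best hit. Both tables
#' should already be filtered by [filter_hits()].
#'
#' @param hits_ab Forward hit table (queries in A, subjects in B).
#' @param hits_ba Reverse hit table (queries in B, subjects in A).
#' @param allow_one_way Emit one-way best hits when reciprocity fails.
#' @return `data.frame` with `query`, `subject`, `bitscore`, `evalue`,
#'   `provenance` (`"reciprocal"` or `"one-way"`).
#' @export
reciprocal_best_hits <- function(hits_ab, hits_ba, allow_one_way = FALSE) {
  fwd <- best_hits(hits_ab)
  rev <- best_hits(hits_ba)
  if (nrow(fwd) == 0L) {
    return(data.frame(query = character(), subject = character(),
                      bitscore = numeric(), evalue = numeric(),
                      provenance = character(), stringsAsFactors = FALSE))
  }
  back <- setNames(rev$subject, rev$query)
  recip <- !is.na(back[fwd$subject]) & back[fwd$subject] == fwd$query
  out <- fwd[, c("query", "subject", "bitscore", "evalue")]
  out$provenance <- ifelse(recip, "reciprocal", "one-way")
  if (!allow_one_way) out <- out[recip, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' dS triangulation filter
#'
#' A triplet (duplicate 1, duplicate 2, ortholog) is accepted only when both
#' duplicate-to-ortholog synonymous distances strictly exceed the
#' duplicate-to-duplicate distance (`dS2 > dS1` and `dS3 > dS1`), confirming
#' that the duplication postdates the speciation. Non-finite (saturated)
#' estimates are rejected as unestimable.
#'
#' @param dS1 dS between the two duplicates.
#' @param dS2,dS3 dS between each duplicate and the ortholog.
#' @return List with `accept` (logical) and `reason` (`NA` when accepted).
#' @export
triangulation_filter <- function(dS1, dS2, dS3) {
  ds <- c(dS1, dS2, dS3)
  if (!all(is.finite(ds))) {
    return(list(accept = FALSE, reason = "unestimable"))
  }
  assert_that(all(ds >= 0), "dS must be >= 0")
  if (dS2 > dS1 && dS3 > dS1) list(accept = TRUE, reason = NA_character_)
  else list(accept = FALSE, reason = "dS_triangulation_failed")
}

#' Assign one outgroup ortholog per duplicate pair
#'
#' For each pair, candidate orthologs (one per outgroup species, from
#' [reciprocal_best_hits()] tables) are considered in species-priority order;
#' the first candidate hit shared by both duplicates is taken. The chosen
#' species and hit provenance are flagged in the output.
#'
#' @param pairs `data.frame` with `gene1`, `gene2`.
#' @param candidates_by_species Named list (by species, in priority order) of
#'   RBH tables (`query`, `subject`, `provenance`).
#' @return `pairs` with `ortholog`, `ortholog_species`, `provenance` columns
#'   (`NA` when no species yields a shared candidate).
#' @export
assign_orthologs <- function(pairs, candidates_by_species) {
  pairs$ortholog <- NA_character_
  pairs$ortholog_species <- NA_character_
  pairs$provenance <- NA_character_
  for (i in seq_len(nrow(pairs))) {
    for (spc in names(candidates_by_species)) {
      tab <- candidates_by_species[[spc]]
      h1 <- tab[tab$query == pairs$gene1[i], , drop = FALSE]
      h2 <- tab[tab$query == pairs$gene2[i], , drop = FALSE]
      shared <- intersect(h1$subject, h2$subject)
      if (length(shared)) {
        ort <- sort(shared)[1]
        prov <- c(h1$provenance[h1$subject == ort][1],
                  h2$provenance[h2$subject == ort][1])
        pairs$ortholog[i] <- ort
        pairs$ortholog_species[i] <- spc
        pairs$provenance[i] <- if (all(prov == "reciprocal")) "reciprocal" else "one-way"
        break
      }
    }
  }
  pairs
}
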