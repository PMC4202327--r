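# Codon alignment by back-translation: map protein alignment columns onto
# the underlying coding sequences.

#' Back-translate a protein alignment to a codon alignment
#'
#' Each aligned protein residue is replaced by its source codon; protein gaps
#' become `---`. Every CDS must translate exactly to its ungapped protein
#' under the standard genetic code (a terminal stop codon is stripped);
#' mismatches are reported with sequence id and residue position.
#'
#' @param protein_alignment Named character vector of aligned protein
#'   sequences (equal lengths, gaps as `-`).
#' @param cds_by_id Named character vector of unaligned coding sequences; a
#'   CDS must exist for every protein id.
#' @return Named character vector of aligned nucleotide sequences (length
#'   `3 *` alignment width).
#' @export
back_translate_alignment <- function(protein_alignment, cds_by_id) {
  widths <- unique(nchar(protein_alignment))
  assert_that(length(widths) == 1L, "protein sequences must be aligned (equal length)")
  missing <- setdiff(names(protein_alignment), names(cds_by_id))
  assert_that(length(missing) == 0L, paste0("no CDS for id: ", missing[1]))
  gc_tab <- Biostrings::GENETIC_CODE
  out <- protein_alignment
  for (id in names(protein_alignment)) {
    prot <- strsplit(toupper(protein_alignment[[id]]), "")[[1]]
    cds <- toupper(gsub("\\s", "", cds_by_id[[id]]))
    assert_that(nchar(cds) %% 3 == 0,
                sprintf("CDS of '%s' has length %d, not a multiple of 3", id, nchar(cds)))
    codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    aas <- unname(gc_tab[codons])
    assert_that(!anyNA(aas),
                sprintf("CDS of '%s' contains an ambiguous/invalid codon", id))
    if (length(aas) && aas[length(aas)] == "*") {
      codons <- codons[-length(codons)]
      aas <- aas[-length(aas)]
    }
    assert_that(!any(aas == "*"),
                sprintf("internal stop codon in CDS of '%s' (codon %d)",
                        id, which(aas == "*")[1]))
    ungapped <- prot[prot != "-"]
    assert_that(length(ungapped) == length(codons),
                sprintf("CDS of '%s' codes for %d residues but protein has %d",
                        id, length(codons), length(ungapped)))
    mism <- which(aas != ungapped)
    assert_that(length(mism) == 0L,
                sprintf("translation mismatch in '%s' at residue %d: CDS gives '%s', protein has '%s'",
                        id, mism[1], aas[mism[1]], ungapped[mism[1]]))
    filled <- character(length(prot))
    filled[prot == "-"] <- "---"
    filled[prot != "-"] <- codons
    out[[id]] <- paste(filled, collapse = "")
  }
  out
}
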