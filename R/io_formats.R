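# Readers/writers for the standard formats the pipeline touches. All errors
# carry file/line context; nothing is skipped silently.

#' Read and write FASTA
#'
#' Thin, validating wrappers around Biostrings. `read_fasta` enforces unique
#' record ids and (optionally) a residue alphabet; `write_fasta` normalizes
#' line wrapping. Write-then-read round trips preserve ids and sequences
#' exactly.
#'
#' @param path File path.
#' @param alphabet Optional character vector of allowed residue letters
#'   (checked case-insensitively, `-` always allowed); `NULL` disables the
#'   check.
#' @return Named character vector of sequences (names are record ids).
#' @export
read_fasta <- function(path, alphabet = NULL) {
  assert_that(file.exists(path), paste0("no such file: ", path))
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) {
    warning("empty FASTA file: ", path)
    return(setNames(character(0), character(0)))
  }
  ids <- sub("\\s.*$", "", names(ss))
  dup <- ids[duplicated(ids)]
  assert_that(length(dup) == 0L,
              paste0("duplicate FASTA id in ", path, ": ", dup[1]))
  seqs <- setNames(as.character(ss), ids)
  if (!is.null(alphabet)) {
    ok <- c(toupper(alphabet), tolower(alphabet), "-")
    for (i in seq_along(seqs)) {
      bad <- setdiff(unique(strsplit(seqs[[i]], "")[[1]]), ok)
      assert_that(length(bad) == 0L,
                  sprintf("illegal residue '%s' in record '%s' of %s",
                          bad[1], ids[i], path))
    }
  }
  seqs
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 60) {
  assert_that(!is.null(names(seqs)) && all(nzchar(names(seqs))),
              "all sequences must be named")
  dup <- names(seqs)[duplicated(names(seqs))]
  assert_that(length(dup) == 0L, paste0("duplicate FASTA id: ", dup[1]))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1, max(nchar(s), 1), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Parse and write Newick trees
#'
#' Backed by ape. Internal node labels are read as bootstrap supports
#' (integer counts or fractions, as emitted by common ML software). Round
#' trips preserve leaves, topology, branch lengths, and supports up to
#' rotation.
#'
#' @param text A Newick string (one tree).
#' @return `parse_newick` returns an `ape::phylo`; `write_newick` a string.
#' @export
parse_newick <- function(text) {
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL, warning = function(w) NULL)
  assert_that(!is.null(tr) && inherits(tr, "phylo"),
              paste0("malformed Newick string: ", substr(text, 1, 60)))
  dup <- tr$tip.label[duplicated(tr$tip.label)]
  assert_that(length(dup) == 0L, paste0("duplicate leaf label: ", dup[1]))
  tr
}

#' @rdname parse_newick
#' @param tree An `ape::phylo` object.
#' @export
write_newick <- function(tree) {
  assert_that(inherits(tree, "phylo"), "tree must be a phylo object")
  ape::write.tree(tree)
}

#' Read a tabular similarity-hit file
#'
#' Parses the 12-column BLAST tabular (outfmt 6) dialect: query id, subject
#' id, percent identity, alignment length, mismatches, gap opens, query
#' start/end, subject start/end, e-value, bit score. Extra columns are passed
#' through.
#'
#' @param path File path (tab-separated, no header).
#' @param strict If `TRUE` (default), rows with fewer than 12 columns or
#'   non-numeric e-values are an error reported with the line number.
#' @return `data.frame` with typed columns `query`, `subject`, `pident`,
#'   `length`, `evalue`, `bitscore` (plus passthrough columns).
#' @export
read_hit_table <- function(path, strict = TRUE) {
  assert_that(file.exists(path), paste0("no such file: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty hit table: ", path)
    return(data.frame(query = character(), subject = character(),
                      pident = numeric(), length = integer(),
                      evalue = numeric(), bitscore = numeric()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (strict) {
    bad <- which(ncols < 12L)
    assert_that(length(bad) == 0L,
                sprintf("%s line %d: expected >= 12 tab-separated columns, got %d",
                        path, bad[1], ncols[bad[1]]))
  } else {
    keep <- ncols >= 12L
    fields <- fields[keep]
    if (!all(keep)) warning(sum(!keep), " malformed rows dropped from ", path)
  }
  get_col <- function(i) vapply(fields, `[[`, "", i)
  num_col <- function(i, what) {
    x <- suppressWarnings(as.numeric(get_col(i)))
    bad <- which(!is.finite(x))
    assert_that(length(bad) == 0L,
                sprintf("%s line %d: non-numeric %s '%s'",
                        path, bad[1], what, get_col(i)[bad[1]]))
    x
  }
  df <- data.frame(
    query = get_col(1), subject = get_col(2),
    pident = num_col(3, "percent identity"),
    length = as.integer(num_col(4, "alignment length")),
    mismatch = as.integer(num_col(5, "mismatches")),
    gapopen = as.integer(num_col(6, "gap opens")),
    qstart = as.integer(num_col(7, "qstart")), qend = as.integer(num_col(8, "qend")),
    sstart = as.integer(num_col(9, "sstart")), send = as.integer(num_col(10, "send")),
    evalue = num_col(11, "e-value"), bitscore = num_col(12, "bit score"),
    stringsAsFactors = FALSE
  )
  assert_that(all(df$evalue >= 0), "negative e-value")
  assert_that(all(df$length >= 1), "alignment length < 1")
  df
}

#' Controlled vocabulary of subcellular compartment tokens
#'
#' GFP localization compartments: cp (chloroplast), cpl (cell plate), cw
#' (cell wall), cy (cytosol), cyb (cytosolic body; distinct from cy), ck
#' (cytoskeleton), en (endosome), ER (endoplasmic reticulum), lb (lipid
#' bodies), mt (mitochondrion), nu (nucleus), per (peroxisome), pm (plasma
#' membrane), TGN/PVC (trans-Golgi network / prevacuolar compartment), va
#' (vacuole). Tokens are case-preserved but compared case-insensitively.
#'
#' @return Character vector of tokens.
#' @export
compartment_vocabulary <- function() {
  c("cp", "cpl", "cw", "cy", "cyb", "ck", "en", "ER", "lb",
    "mt", "nu", "per", "pm", "TGN/PVC", "va")
}

#' Read a per-gene localization table
#'
#' TSV with header columns `gene_id`, `compartments` (semicolon-separated
#' tokens), `study_id`, `condition`, and optional `evidence`. The
#' same-study/same-condition exclusion used when assembling pairs is applied
#' downstream (see [classify_pair_localizations()]); this reader just
#' validates records.
#'
#' @param path File path.
#' @param unknown_token `"error"` (default) or `"warn"`: what to do with a
#'   compartment token outside [compartment_vocabulary()].
#' @return `data.frame` with a list-column `compartments` of token sets.
#' @export
read_localization_table <- function(path, unknown_token = c("error", "warn")) {
  unknown_token <- match.arg(unknown_token)
  assert_that(file.exists(path), paste0("no such file: ", path))
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("gene_id", "compartments", "study_id", "condition")
  assert_that(all(need %in% names(df)),
              paste("localization table must have columns:",
                    paste(need, collapse = ", ")))
  vocab <- compartment_vocabulary()
  sets <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    toks <- trimws(strsplit(df$compartments[i], ";", fixed = TRUE)[[1]])
    toks <- toks[nzchar(toks)]
    assert_that(length(toks) > 0L,
                sprintf("%s row %d (%s): empty compartment set", path, i, df$gene_id[i]))
    hit <- match(tolower(toks), tolower(vocab))
    if (anyNA(hit)) {
      msg <- sprintf("%s row %d (%s): unknown compartment token '%s'",
                     path, i, df$gene_id[i], toks[which(is.na(hit))[1]])
      if (unknown_token == "error") stop(msg, call. = FALSE) else warning(msg)
      toks <- ifelse(is.na(hit), toks, vocab[hit])
    } else {
      toks <- vocab[hit] # canonical casing
    }
    sets[[i]] <- unique(toks)
  }
  df$compartments <- sets
  if (!"evidence" %in% names(df)) df$evidence <- "GFP"
  df
}
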