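# Pairwise dN/dS: maximum likelihood under the codon model, and the
# Nei-Gojobori (1986) counting method as an independent cross-check.

# Split a pair of aligned nucleotide strings into gap-free, unambiguous
# codon-column index pairs over the 61 sense codons (complete deletion).
codon_pair_columns <- function(seq1, seq2, forbid_stop = FALSE) {
  sp <- codon_space()
  assert_that(nchar(seq1) == nchar(seq2), "sequences must be aligned")
  assert_that(nchar(seq1) %% 3 == 0, "alignment length not a multiple of 3")
  s1 <- toupper(seq1); s2 <- toupper(seq2)
  starts <- seq(1, nchar(s1), 3)
  c1 <- substring(s1, starts, starts + 2)
  c2 <- substring(s2, starts, starts + 2)
  if (forbid_stop) {
    gc_tab <- Biostrings::GENETIC_CODE
    stops <- c(c1, c2)[!is.na(gc_tab[c(c1, c2)]) & gc_tab[c(c1, c2)] == "*"]
    assert_that(length(stops) == 0L,
                paste0("stop codon in alignment: ", stops[1]))
  }
  i1 <- match(c1, sp$codons)
  i2 <- match(c2, sp$codons)
  keep <- !is.na(i1) & !is.na(i2)
  list(i1 = i1[keep], i2 = i2[keep], n_used = sum(keep), n_total = length(c1))
}

#' Pairwise dN and dS by maximum likelihood
#'
#' Fits the codon model to two aligned coding sequences, maximizing over
#' total divergence `t`, transition/transversion ratio `kappa`, and `omega`
#' with F3x4 codon frequencies estimated from the data. `dN` and `dS` are
#' derived from the fitted flux decomposition (sites counted at omega = 1),
#' under which `omega = dN/dS` exactly. Gap- or ambiguity-containing codon
#' columns are excluded (complete deletion).
#'
#' @param seq1,seq2 Aligned in-frame nucleotide sequences.
#' @param codon_freqs Optional 61-vector overriding the F3x4 estimate.
#' @return List with `dN`, `dS`, `omega`, `t`, `kappa`, `lnL`, `n_codons`,
#'   and `saturated` (TRUE when dS is effectively unestimable).
#' @export
pairwise_dnds_ml <- function(seq1, seq2, codon_freqs = NULL) {
  cols <- codon_pair_columns(seq1, seq2)
  assert_that(cols$n_used >= 1, "no usable gap-free codon columns")
  if (is.null(codon_freqs)) {
    codon_freqs <- f3x4_freqs(c(gsub("-", "", seq1), gsub("-", "", seq2)))
  }
  # Pattern compression over ordered codon pairs.
  key <- paste(cols$i1, cols$i2)
  tab <- table(key)
  first <- match(names(tab), key)
  p1 <- cols$i1[first]; p2 <- cols$i2[first]; w <- as.numeric(tab)

  nll <- function(par) {
    t <- exp(par[1]); kappa <- exp(par[2]); omega <- exp(par[3])
    m <- codon_model(kappa, omega, codon_freqs)
    P <- transition_matrix(m, t)
    lik <- m$freqs[p1] * P[cbind(p1, p2)]
    -sum(w * log(pmax(lik, 1e-300)))
  }
  ident <- all(p1 == p2)
  if (ident) {
    return(list(dN = 0, dS = 0, omega = NA_real_, t = 0, kappa = NA_real_,
                lnL = NA_real_, n_codons = cols$n_used, saturated = FALSE))
  }
  pdiff <- sum(w * (p1 != p2)) / sum(w)
  t0 <- max(-log(1 - min(pdiff, 0.95)), 0.01)
  fit <- optim(log(c(t0, 2, 0.3)), nll, method = "L-BFGS-B",
               lower = log(c(1e-6, 0.01, 1e-6)), upper = log(c(50, 100, 50)),
               control = list(factr = 1e4, maxit = 500))
  t_hat <- exp(fit$par[1]); kappa_hat <- exp(fit$par[2]); omega_hat <- exp(fit$par[3])
  dec <- dnds_decompose(t_hat, kappa_hat, omega_hat, codon_freqs)
  saturated <- t_hat >= 49 || !is.finite(dec$dS)
  list(dN = dec$dN, dS = dec$dS, omega = omega_hat, t = t_hat,
       kappa = kappa_hat, lnL = -fit$value, n_codons = cols$n_used,
       saturated = saturated)
}

# Synonymous/nonsynonymous site counts per codon, and path-averaged
# substitution counts per codon pair, after Nei & Gojobori (1986).
.ng86_env <- new.env(parent = emptyenv())

ng86_tables <- function() {
  if (!is.null(.ng86_env$tab)) return(.ng86_env$tab)
  sp <- codon_space()
  gc_tab <- Biostrings::GENETIC_CODE
  nucs <- c("A", "C", "G", "T")
  mat <- do.call(rbind, strsplit(sp$codons, ""))
  # Per-codon synonymous site count: for each position, fraction of the
  # three possible changes (excluding to-stop) that are synonymous.
  syn_sites <- numeric(sp$n)
  for (i in seq_len(sp$n)) {
    s <- 0
    for (pos in 1:3) {
      for (nt in setdiff(nucs, mat[i, pos])) {
        mut <- mat[i, ]; mut[pos] <- nt
        mutc <- paste(mut, collapse = "")
        if (gc_tab[mutc] == "*") next # stops excluded from site counting
        if (gc_tab[mutc] == sp$aa[i]) s <- s + 1 / 3
      }
    }
    syn_sites[i] <- s
  }
  # Path-averaged (sd, nd) for every codon pair, averaging over all orders
  # of the differing positions; paths through stop codons are discarded.
  pair_counts <- function(i, j) {
    dpos <- which(mat[i, ] != mat[j, ])
    if (!length(dpos)) return(c(0, 0))
    perms <- if (length(dpos) == 1L) list(dpos) else {
      if (length(dpos) == 2L) list(dpos, rev(dpos)) else {
        idx <- c(1L, 2L, 3L)
        lapply(list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1)),
               function(o) dpos[o])
      }
    }
    acc <- c(0, 0); nok <- 0L
    for (ord in perms) {
      cur <- mat[i, ]; sd <- 0; nd <- 0; ok <- TRUE
      for (pos in ord) {
        nxt <- cur; nxt[pos] <- mat[j, pos]
        a1 <- gc_tab[paste(cur, collapse = "")]
        a2 <- gc_tab[paste(nxt, collapse = "")]
        if (a2 == "*") { ok <- FALSE; break }
        if (a1 == a2) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      if (ok) { acc <- acc + c(sd, nd); nok <- nok + 1L }
    }
    if (nok == 0L) c(0, length(dpos)) else acc / nok
  }
  SD <- matrix(0, sp$n, sp$n); ND <- matrix(0, sp$n, sp$n)
  for (i in seq_len(sp$n)) {
    for (j in seq_len(sp$n)) {
      if (i == j) next
      cnt <- pair_counts(i, j)
      SD[i, j] <- cnt[1]; ND[i, j] <- cnt[2]
    }
  }
  .ng86_env$tab <- list(syn_sites = syn_sites, SD = SD, ND = ND)
  .ng86_env$tab
}

#' Pairwise dN and dS by the Nei-Gojobori (1986) counting method
#'
#' Counts synonymous/nonsynonymous sites and substitutions (equal-weight
#' averaging over substitution paths; paths through stop codons discarded)
#' and applies the Jukes-Cantor correction. Gap-containing codon columns are
#' removed; a stop codon in the alignment is an error.
#'
#' @param seq1,seq2 Aligned in-frame nucleotide sequences.
#' @return List with `dN`, `dS`, `omega`, `S`, `N`, `Sd`, `Nd`, `n_codons`.
#' @export
ng86_dnds <- function(seq1, seq2) {
  cols <- codon_pair_columns(seq1, seq2, forbid_stop = TRUE)
  assert_that(cols$n_used >= 1, "no usable gap-free codon columns")
  tab <- ng86_tables()
  S <- mean(c(sum(tab$syn_sites[cols$i1]), sum(tab$syn_sites[cols$i2])))
  N <- 3 * cols$n_used - S
  Sd <- sum(tab$SD[cbind(cols$i1, cols$i2)])
  Nd <- sum(tab$ND[cbind(cols$i1, cols$i2)])
  jc <- function(p) {
    if (p >= 0.75) return(Inf)
    -3 / 4 * log(1 - 4 * p / 3)
  }
  dS <- if (S > 0) jc(Sd / S) else NA_real_
  dN <- if (N > 0) jc(Nd / N) else NA_real_
  omega <- if (is.finite(dS) && dS > 0) dN / dS else NA_real_
  list(dN = dN, dS = dS, omega = omega, S = S, N = N, Sd = Sd, Nd = Nd,
       n_codons = cols$n_used)
}
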