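# Goldman-Yang style codon model on the 61 sense codons of the standard
# genetic code: single-nucleotide changes at rate pi_j * kappa^{ts} *
# omega^{nonsyn}; stop codons excluded from the state space.

.codon_env <- new.env(parent = emptyenv())
.codon_model_memo <- new.env(parent = emptyenv())

# Memoized codon_model for repeated builds with identical parameters (the
# optimizer re-visits omega = 1 and BEB grids revisit omega values). Keyed on
# kappa, omega, scale, and a fingerprint of the frequency vector.
codon_model_memo <- function(kappa, omega, codon_freqs = NULL, scale = NULL) {
  key <- paste(format(kappa, digits = 15), format(omega, digits = 15),
               if (is.null(scale)) "." else format(scale, digits = 15),
               if (is.null(codon_freqs)) "." else
                 paste(format(sum(codon_freqs * seq_along(codon_freqs)),
                              digits = 15),
                       format(codon_freqs[1], digits = 15)),
               sep = "|")
  hit <- .codon_model_memo[[key]]
  if (!is.null(hit)) return(hit)
  if (length(ls(.codon_model_memo)) > 400) {
    rm(list = ls(.codon_model_memo), envir = .codon_model_memo)
  }
  m <- codon_model(kappa, omega, codon_freqs, scale)
  .codon_model_memo[[key]] <- m
  m
}

# Static structure of the codon state space: codon strings, encoded amino
# acids, and for every single-nucleotide codon pair whether the change is a
# transition and whether it is synonymous. Computed once.
codon_space <- function() {
  if (!is.null(.codon_env$space)) return(.codon_env$space)
  gc_tab <- Biostrings::GENETIC_CODE
  codons <- names(gc_tab)[gc_tab != "*"]
  aa <- unname(gc_tab[codons])
  n <- length(codons) # 61
  mat <- do.call(rbind, strsplit(codons, ""))
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  ndiff <- matrix(0L, n, n)
  for (k in 1:3) ndiff <- ndiff + outer(mat[, k], mat[, k], "!=")
  single <- ndiff == 1L
  is_ts <- matrix(FALSE, n, n)
  for (k in 1:3) {
    d <- outer(mat[, k], mat[, k], "!=")
    same_class <- outer(purine[mat[, k]], purine[mat[, k]], "==")
    is_ts <- is_ts | (d & same_class)
  }
  is_ts <- is_ts & single
  is_syn <- single & outer(aa, aa, "==")
  space <- list(codons = codons, aa = aa, n = n,
                single = single, is_ts = is_ts, is_syn = is_syn)
  .codon_env$space <- space
  space
}

#' Codon substitution model
#'
#' Builds a reversible codon rate matrix over the 61 sense codons with
#' transition/transversion ratio `kappa`, nonsynonymous/synonymous ratio
#' `omega`, and codon equilibrium frequencies. The matrix is scaled to one
#' expected substitution per codon per unit branch length unless a shared
#' `scale` (from a site-class mixture) is supplied.
#'
#' @param kappa Transition/transversion rate ratio, > 0.
#' @param omega dN/dS ratio, >= 0.
#' @param codon_freqs Equilibrium frequencies of the 61 sense codons (in
#'   `codon_space()$codons` order); normalized internally. Uniform by default.
#' @param scale Optional positive scaling divisor overriding the model's own
#'   expected rate (used by site-class mixtures that share one time scale).
#' @return Object of class `codon_model` with the rate matrix `Q`, cached
#'   eigendecomposition, `freqs`, and the synonymous/nonsynonymous flux
#'   proportions `rho_s`/`rho_n` (of the unscaled matrix).
#' @export
codon_model <- function(kappa, omega, codon_freqs = NULL, scale = NULL) {
  assert_that(is.finite(kappa) && kappa > 0, "kappa must be > 0")
  assert_that(is.finite(omega) && omega >= 0, "omega must be >= 0")
  sp <- codon_space()
  if (is.null(codon_freqs)) codon_freqs <- rep(1 / sp$n, sp$n)
  assert_that(length(codon_freqs) == sp$n, "need 61 sense-codon frequencies")
  assert_that(all(codon_freqs > 0), "codon frequencies must be positive")
  if (!is.null(names(codon_freqs))) {
    assert_that(all(names(codon_freqs) %in% sp$codons),
                "stop codon in frequency support")
    codon_freqs <- codon_freqs[sp$codons]
  }
  pi <- codon_freqs / sum(codon_freqs)

  R <- matrix(0, sp$n, sp$n)
  R[sp$single] <- 1
  R[sp$is_ts] <- kappa
  R[sp$single & !sp$is_syn] <- R[sp$single & !sp$is_syn] * omega
  Q <- R * rep(pi, each = sp$n) # Q_ij = R_ij * pi_j
  diag(Q) <- -rowSums(Q)
  flux <- -sum(pi * diag(Q))

  syn_flux <- sum(pi * rowSums(Q * sp$is_syn))
  rho_s <- if (flux > 0) syn_flux / flux else 0

  div <- if (is.null(scale)) flux else scale
  assert_that(div > 0, "degenerate codon model: zero expected rate")
  Q <- Q / div

  spi <- sqrt(pi)
  B <- diag(spi) %*% Q %*% diag(1 / spi)
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  out <- list(
    Q = Q, freqs = pi, kappa = kappa, omega = omega,
    flux = flux, rho_s = rho_s, rho_n = 1 - rho_s,
    alphabet = sp$codons,
    values = eig$values,
    left = diag(1 / spi) %*% eig$vectors,
    right = t(eig$vectors) %*% diag(spi)
  )
  dimnames(out$Q) <- list(sp$codons, sp$codons)
  names(out$freqs) <- sp$codons
  class(out) <- c("codon_model", "aa_model")
  out
}

# Proportion of substitutions that are synonymous under (kappa, freqs) at
# omega = 1: defines synonymous "sites" in the ML dN/dS decomposition.
neutral_rho_s <- function(kappa, codon_freqs = NULL) {
  codon_model(kappa, 1, codon_freqs)$rho_s
}

# Decompose (t, omega) into dN and dS per site using flux proportions:
# dS = t * rho_s(omega) / (3 * rho_s(1)), dN analogous. With GY rates this
# makes dN/dS equal omega exactly.
dnds_decompose <- function(t, kappa, omega, codon_freqs = NULL) {
  m <- codon_model(kappa, omega, codon_freqs)
  r1 <- neutral_rho_s(kappa, codon_freqs)
  list(dS = t * m$rho_s / (3 * r1), dN = t * m$rho_n / (3 * (1 - r1)))
}

# Inverse map: branch length (subs/codon) giving the requested dN and dS
# under (kappa, freqs); omega = dN/dS.
dnds_compose <- function(dN, dS, kappa, codon_freqs = NULL) {
  r1 <- neutral_rho_s(kappa, codon_freqs)
  t <- 3 * (dS * r1 + dN * (1 - r1))
  omega <- if (dS > 0) dN / dS else Inf
  list(t = t, omega = omega)
}

#' Empirical F3x4 codon frequencies
#'
#' Estimates sense-codon equilibrium frequencies as the product of the
#' position-specific nucleotide frequencies observed in a codon alignment,
#' renormalized over the 61 sense codons.
#'
#' @param codon_seqs Character vector of in-frame coding sequences (may be a
#'   codon alignment; gaps and ambiguous codons are skipped for counting).
#' @param pseudocount Added to every position-specific nucleotide count so no
#'   codon gets zero frequency. Default 0.5.
#' @return Named 61-vector of codon frequencies summing to one.
#' @export
f3x4_freqs <- function(codon_seqs, pseudocount = 0.5) {
  sp <- codon_space()
  counts <- matrix(pseudocount, 3, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  for (s in codon_seqs) {
    s <- toupper(s)
    assert_that(nchar(s) %% 3 == 0, "coding sequence length not a multiple of 3")
    chars <- strsplit(s, "")[[1]]
    pos <- rep(1:3, length.out = length(chars))
    keep <- chars %in% c("A", "C", "G", "T")
    tab <- table(factor(pos[keep], 1:3), factor(chars[keep], c("A", "C", "G", "T")))
    counts <- counts + as.matrix(tab)
  }
  nf <- counts / rowSums(counts)
  mat <- do.call(rbind, strsplit(sp$codons, ""))
  pi <- nf[1, mat[, 1]] * nf[2, mat[, 2]] * nf[3, mat[, 3]]
  pi <- pi / sum(pi)
  names(pi) <- sp$codons
  pi
}
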