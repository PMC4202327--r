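# Amino-acid substitution model: reversible rate matrix from an
# exchangeability matrix and equilibrium frequencies, JTT by default.

AA_ALPHABET <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

# JTT exchangeabilities, lower triangle in ARNDCQEGHILKMFPSTWYV order
# (Jones, Taylor & Thornton's matrix as distributed with standard
# phylogenetics software), and the matching equilibrium frequencies.
.JTT_EXCH <- c(
  58, 54, 81, 56, 57, 105, 179, 27, 36, 30, 35, 54, 15, 194,
  378, 475, 9, 11, 298, 45, 16, 113, 310, 29, 137, 328, 22, 38,
  646, 44, 5, 74, 101, 64, 126, 20, 17, 528, 34, 86, 58, 81, 391,
  47, 12, 263, 30, 10, 15, 503, 232, 8, 70, 16, 10, 49, 767, 130,
  112, 11, 7, 26, 15, 4, 15, 59, 38, 4, 46, 31, 9, 5, 59, 69, 17,
  23, 7, 31, 78, 14, 223, 42, 115, 209, 62, 323, 26, 597, 9, 72,
  292, 43, 4, 164, 53, 51, 18, 24, 20, 119, 26, 12, 9, 181, 18,
  5, 18, 30, 32, 10, 7, 45, 23, 6, 6, 27, 14, 5, 24, 201, 33, 55,
  8, 47, 16, 56, 45, 33, 40, 115, 73, 46, 8, 573, 11, 229, 21,
  479, 89, 10, 40, 245, 9, 32, 961, 14, 388, 248, 102, 59, 25,
  52, 24, 180, 65, 4, 21, 47, 103, 10, 8, 14, 43, 16, 29, 226,
  24, 18, 323, 17, 92, 12, 53, 536, 62, 285, 118, 6, 10, 23, 477,
  35, 63, 38, 12, 21, 112, 71, 25, 16)

.JTT_FREQS <- c(
  0.076748, 0.051691, 0.042645, 0.051544, 0.019803, 0.040752, 0.061830,
  0.073152, 0.022944, 0.053761, 0.091904, 0.058676, 0.023826, 0.040126,
  0.050901, 0.068765, 0.058565, 0.014261, 0.032102, 0.066005)

#' Amino-acid substitution model
#'
#' Builds a time-reversible amino-acid model from a symmetric exchangeability
#' matrix and equilibrium frequencies. The rate matrix is normalized to one
#' expected substitution per site per unit branch length, and its symmetric
#' similarity transform is eigendecomposed once so that transition matrices
#' for arbitrary branch lengths are cheap.
#'
#' @param exchangeabilities Lower-triangle vector (length 190) or full 20x20
#'   symmetric matrix of exchangeabilities, rows/columns in the order
#'   `ARNDCQEGHILKMFPSTWYV`. Default: the JTT matrix.
#' @param freqs Equilibrium frequencies (length 20, same residue order);
#'   normalized to sum to one. Default: the JTT frequencies.
#' @return An object of class `aa_model` with elements `Q` (rate matrix),
#'   `freqs`, and the cached eigendecomposition.
#' @examples
#' m <- aa_model_jtt()
#' rowSums(m$Q) # ~0
#' @export
aa_model <- function(exchangeabilities = .JTT_EXCH, freqs = .JTT_FREQS) {
  if (is.matrix(exchangeabilities)) {
    S <- exchangeabilities
    assert_that(all(dim(S) == c(20L, 20L)), "exchangeability matrix must be 20x20")
    assert_that(isTRUE(all.equal(S, t(S))), "exchangeability matrix must be symmetric")
  } else {
    assert_that(length(exchangeabilities) == 190L,
                "exchangeability vector must have length 190 (lower triangle)")
    S <- matrix(0, 20, 20)
    S[lower.tri(S)] <- exchangeabilities
    S <- S + t(S)
  }
  assert_that(length(freqs) == 20L && all(freqs > 0), "need 20 positive frequencies")
  assert_that(all(S[lower.tri(S)] >= 0), "exchangeabilities must be non-negative")
  pi <- freqs / sum(freqs)

  Q <- S %*% diag(pi)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  Q <- Q / scale

  # Reversibility makes D^{1/2} Q D^{-1/2} symmetric; eigendecompose once.
  sp <- sqrt(pi)
  B <- diag(sp) %*% Q %*% diag(1 / sp)
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  out <- list(
    Q = Q, freqs = pi, alphabet = AA_ALPHABET,
    values = eig$values,
    left = diag(1 / sp) %*% eig$vectors,    # P(t) = left diag(e^{vt}) right
    right = t(eig$vectors) %*% diag(sp)
  )
  dimnames(out$Q) <- list(AA_ALPHABET, AA_ALPHABET)
  names(out$freqs) <- AA_ALPHABET
  class(out) <- "aa_model"
  out
}

#' @rdname aa_model
#' @export
aa_model_jtt <- function() aa_model()

#' Transition probability matrix at a branch length
#'
#' @param model An [aa_model()] (or codon model) object with a cached
#'   eigendecomposition.
#' @param t Branch length in expected substitutions per site; must be finite
#'   and non-negative.
#' @return Stochastic matrix of transition probabilities.
#' @export
transition_matrix <- function(model, t) {
  assert_that(is.finite(t) && t >= 0, "branch length must be finite and >= 0")
  P <- model$left %*% (exp(model$values * t) * model$right)
  # Clamp tiny negative round-off and renormalize rows.
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- dimnames(model$Q)
  P
}
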