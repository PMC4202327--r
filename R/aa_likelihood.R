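# Likelihood machinery for the rate-symmetry (clock) test on triplets:
# pruning likelihood on the 3-taxon star, constrained/free ML fits, the
# likelihood ratio test, and FDR adjustment.

# Convert a triplet alignment (triplet_alignment or named character vector of
# 3 equal-length sequences) into a compressed pattern representation:
# index matrix (3 x n_patterns, 0 = gap/ambiguity) plus pattern weights.
aa_patterns <- function(alignment, alphabet = AA_ALPHABET) {
  seqs <- if (inherits(alignment, "triplet_alignment")) alignment$seqs else alignment
  assert_that(length(seqs) == 3L, "need exactly 3 sequences")
  n <- unique(nchar(seqs))
  assert_that(length(n) == 1L, "sequences must be aligned (equal length)")
  assert_that(n >= 1L, "empty alignment")
  idx <- vapply(seqs, function(s) {
    m <- match(strsplit(toupper(s), "")[[1]], alphabet)
    m[is.na(m)] <- 0L # gap / ambiguity -> marginalized
    m
  }, integer(n))
  idx <- matrix(idx, nrow = n, ncol = 3L) # vapply drops dims when n = 1
  key <- idx[, 1] * (length(alphabet) + 1L)^2 +
         idx[, 2] * (length(alphabet) + 1L) + idx[, 3]
  tab <- table(key)
  first <- match(as.numeric(names(tab)), key)
  list(idx = t(idx[first, , drop = FALSE]), w = as.numeric(tab), n_sites = n)
}

# Conditional-likelihood matrix for one branch: column j holds P(b)[, x_j]
# for pattern residue x_j, or 1s when marginalized (gap).
leaf_conditionals <- function(P, x) {
  M <- matrix(1, nrow(P), length(x))
  obs <- x > 0L
  M[, obs] <- P[, x[obs]]
  M
}

#' Pruning log-likelihood of a triplet alignment
#'
#' Sum over sites of `log( sum_s pi_s * P(b1)[s, x1] P(b2)[s, x2] P(b3)[s, x3] )`
#' on the unrooted 3-taxon star; gap and ambiguity characters are
#' marginalized as missing data.
#'
#' @param alignment A `triplet_alignment` (type `"aa"`) or named character
#'   vector of three aligned amino-acid sequences (order: duplicate 1,
#'   duplicate 2, outgroup).
#' @param tree A [triplet_tree()].
#' @param model An [aa_model()].
#' @return Log-likelihood (numeric scalar).
#' @export
aa_log_likelihood <- function(alignment, tree, model = aa_model_jtt()) {
  pat <- aa_patterns(alignment, model$alphabet)
  aa_log_likelihood_patterns(pat, c(tree$b1, tree$b2, tree$b3), model)
}

aa_log_likelihood_patterns <- function(pat, blen, model) {
  assert_that(all(is.finite(blen)) && all(blen >= 0),
              "branch lengths must be finite and >= 0")
  M <- leaf_conditionals(transition_matrix(model, blen[1]), pat$idx[1, ])
  M <- M * leaf_conditionals(transition_matrix(model, blen[2]), pat$idx[2, ])
  M <- M * leaf_conditionals(transition_matrix(model, blen[3]), pat$idx[3, ])
  site_lik <- colSums(model$freqs * M)
  sum(pat$w * log(site_lik))
}

# Rough additive branch-length initialization from pairwise distances with a
# saturating log correction (init only; the optimizer does the real work).
init_branch_lengths <- function(pat, n_states = 20) {
  pdist <- function(i, j) {
    obs <- pat$idx[i, ] > 0 & pat$idx[j, ] > 0
    if (!any(obs)) return(0.5)
    p <- sum(pat$w[obs] * (pat$idx[i, obs] != pat$idx[j, obs])) / sum(pat$w[obs])
    pmax <- (n_states - 1) / n_states
    if (p >= 0.95 * pmax) p <- 0.95 * pmax
    -pmax * log(1 - p / pmax)
  }
  d12 <- pdist(1, 2); d13 <- pdist(1, 3); d23 <- pdist(2, 3)
  b <- c((d12 + d13 - d23) / 2, (d12 + d23 - d13) / 2, (d13 + d23 - d12) / 2)
  pmin(pmax(b, 1e-6), 20)
}

#' Maximum-likelihood branch lengths for a triplet, clock or free
#'
#' Fits the three branch lengths of the star tree by bounded quasi-Newton
#' optimization (log scale, L-BFGS-B). Under the clock constraint the two
#' duplicate branches are forced equal (`b1 = b2`); the outgroup branch is
#' free in both fits. Deterministic restarts from a coarse grid are attempted
#' when the nested-likelihood ordering looks violated.
#'
#' @param alignment Triplet amino-acid alignment (see [aa_log_likelihood()]).
#' @param constraint `"free"` or `"clock"`.
#' @param model An [aa_model()].
#' @param free_lnl Optional free-fit log-likelihood used as a consistency
#'   reference when fitting the clock model (triggers restarts).
#' @return List with `b` (length-3 branch-length MLEs), `lnL`, `constraint`,
#'   and `convergence` (0 = converged).
#' @export
fit_triplet_aa <- function(alignment, constraint = c("free", "clock"),
                           model = aa_model_jtt(), free_lnl = NULL) {
  constraint <- match.arg(constraint)
  pat <- aa_patterns(alignment, model$alphabet)
  lb <- log(1e-9); ub <- log(50)
  expand <- function(theta) {
    b <- exp(theta)
    if (constraint == "clock") c(b[1], b[1], b[2]) else b
  }
  nll <- function(theta) -aa_log_likelihood_patterns(pat, expand(theta), model)
  b0 <- init_branch_lengths(pat)
  start <- if (constraint == "clock") {
    log(pmax(c(mean(b0[1:2]), b0[3]), 1e-8))
  } else log(pmax(b0, 1e-8))

  run <- function(par) {
    optim(par, nll, method = "L-BFGS-B", lower = lb, upper = ub,
          control = list(factr = 1e4, maxit = 500))
  }
  fit <- run(start)
  # Deterministic restarts if the fit looks stuck (nested ordering violated).
  ref <- if (constraint == "clock") NULL else free_lnl
  need_restart <- function(f) {
    !is.null(free_lnl) && constraint == "clock" && (-f$value) > free_lnl + 1e-4 ||
      FALSE
  }
  grid <- c(0.01, 0.1, 0.5)
  if (fit$convergence != 0 || need_restart(fit)) {
    for (g in grid) {
      alt <- run(rep(log(g), length(start)))
      if (alt$value < fit$value) fit <- alt
      if (fit$convergence == 0 && !need_restart(fit)) break
    }
  }
  list(b = expand(fit$par), lnL = -fit$value, constraint = constraint,
       convergence = fit$convergence)
}

#' Likelihood ratio test
#'
#' `2dL = -2 (lnL_null - lnL_alt)`, clamped at zero against optimizer jitter,
#' compared to the upper tail of a chi-square distribution.
#'
#' @param ln_alt,ln_null Log-likelihoods of the alternative (free) and null
#'   (constrained) fits; `ln_alt` must not be below `ln_null` beyond a small
#'   tolerance.
#' @param df Degrees of freedom (>= 1; default 1).
#' @param tol Allowed negative slack in `ln_alt - ln_null` (optimizer noise).
#' @return List with `ln_alt`, `ln_null`, `two_delta_L`, `df`, `p_value`.
#' @export
lrt <- function(ln_alt, ln_null, df = 1, tol = 1e-4) {
  assert_that(df >= 1, "df must be >= 1")
  assert_that(ln_alt >= ln_null - max(tol, 1e-12),
              sprintf("alternative lnL (%.6f) below null lnL (%.6f): fit failed",
                      ln_alt, ln_null))
  stat <- max(0, 2 * (ln_alt - ln_null))
  list(ln_alt = ln_alt, ln_null = ln_null, two_delta_L = stat, df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (q-values in the loose sense), monotone in
#' p-value rank and capped at 1.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, same length and order as the input.
#' @export
fdr_adjust <- function(p_values) {
  assert_that(all(is.finite(p_values)) && all(p_values >= 0 & p_values <= 1),
              "p-values must be in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Clock-versus-free rate-asymmetry test over a set of triplets
#'
#' For every pair: fit the free and clock models, run the df = 1 LRT, adjust
#' across pairs by FDR, and call the accelerated copy (the duplicate with the
#' longer free-fit branch) only when `q < q_cutoff`.
#'
#' @param alignments Named list of triplet amino-acid alignments (names are
#'   pair ids; unnamed lists get `pair1`, `pair2`, ...).
#' @param model An [aa_model()].
#' @param q_cutoff Significance threshold on the FDR-adjusted value
#'   (default 0.05).
#' @return `data.frame` with one row per pair: `pair_id`, `lnL_clock`,
#'   `lnL_free`, `b1`, `b2`, `b3`, `two_delta_L`, `p_value`, `q_value`,
#'   `accelerated_copy` (`"gene1"`, `"gene2"`, or `"none"`).
#' @export
rate_asymmetry_test <- function(alignments, model = aa_model_jtt(),
                                q_cutoff = 0.05) {
  if (is.null(names(alignments))) {
    names(alignments) <- paste0("pair", seq_along(alignments))
  }
  rows <- lapply(names(alignments), function(id) {
    aln <- alignments[[id]]
    free <- fit_triplet_aa(aln, "free", model)
    clock <- fit_triplet_aa(aln, "clock", model, free_lnl = free$lnL)
    test <- lrt(free$lnL, clock$lnL, df = 1)
    data.frame(pair_id = id, lnL_clock = clock$lnL, lnL_free = free$lnL,
               b1 = free$b[1], b2 = free$b[2], b3 = free$b[3],
               two_delta_L = test$two_delta_L, p_value = test$p_value,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q_value <- fdr_adjust(res$p_value)
  res$accelerated_copy <- ifelse(
    res$q_value < q_cutoff, ifelse(res$b1 >= res$b2, "gene1", "gene2"), "none")
  res
}
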