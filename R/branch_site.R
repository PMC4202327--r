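# Codon-model tests on triplets: branch-specific dN / omega asymmetry LRTs,
# branch-site Model A positive-selection test, and Bayes Empirical Bayes
# site identification.

# Compressed sense-codon patterns for a 3-sequence codon alignment; columns
# containing a gap or ambiguity in any sequence are dropped (complete
# deletion). Keeps the alignment codon position of each retained column.
codon_triplet_patterns <- function(alignment) {
  seqs <- if (inherits(alignment, "triplet_alignment")) alignment$seqs else alignment
  assert_that(length(seqs) == 3L, "need exactly 3 sequences")
  sp <- codon_space()
  n <- unique(nchar(seqs))
  assert_that(length(n) == 1L && n %% 3 == 0,
              "sequences must be aligned with length a multiple of 3")
  starts <- seq(1, n, 3)
  idx <- vapply(seqs, function(s) {
    match(substring(toupper(s), starts, starts + 2), sp$codons)
  }, integer(length(starts)))
  idx <- matrix(idx, nrow = length(starts), ncol = 3L)
  keep <- !is.na(idx[, 1]) & !is.na(idx[, 2]) & !is.na(idx[, 3])
  assert_that(any(keep), "no usable gap-free codon columns")
  idx <- idx[keep, , drop = FALSE]
  key <- paste(idx[, 1], idx[, 2], idx[, 3])
  tab <- table(key)
  first <- match(names(tab), key)
  list(idx = t(idx[first, , drop = FALSE]), w = as.numeric(tab),
       site_pattern = match(key, names(tab)), positions = which(keep),
       n_codons = sum(keep))
}

# Site likelihood vector (one entry per pattern) for a single site class:
# branch b uses transition matrix P_b; product over leaves against pi.
class_site_lik <- function(pat, Plist, pi) {
  M <- leaf_conditionals(Plist[[1]], pat$idx[1, ]) *
       leaf_conditionals(Plist[[2]], pat$idx[2, ]) *
       leaf_conditionals(Plist[[3]], pat$idx[3, ])
  colSums(pi * M)
}

# Pairwise NG86-based initialization of per-branch (dN, dS).
init_branch_dnds <- function(alignment) {
  seqs <- if (inherits(alignment, "triplet_alignment")) alignment$seqs else alignment
  d <- list(ng86_dnds(seqs[1], seqs[2]), ng86_dnds(seqs[1], seqs[3]),
            ng86_dnds(seqs[2], seqs[3]))
  branch <- function(x12, x13, x23) max((x12 + x13 - x23) / 2, 1e-4)
  g <- function(f) vapply(d, function(x) {
    v <- x[[f]]
    if (!is.finite(v)) 1.5 else v
  }, 0)
  dN <- g("dN"); dS <- g("dS")
  list(dN = c(branch(dN[1], dN[2], dN[3]), branch(dN[1], dN[3], dN[2]),
              branch(dN[2], dN[3], dN[1])),
       dS = c(branch(dS[1], dS[2], dS[3]), branch(dS[1], dS[3], dS[2]),
              branch(dS[2], dS[3], dS[1])))
}

# Shared kappa estimate for a triplet: ML pairwise fit of the two most
# informative pairs, averaged. Used as a fixed profile value by the
# branch-model fits so null and alternative condition on the same kappa.
estimate_kappa <- function(alignment, codon_freqs) {
  seqs <- if (inherits(alignment, "triplet_alignment")) alignment$seqs else alignment
  ks <- c(pairwise_dnds_ml(seqs[1], seqs[3], codon_freqs)$kappa,
          pairwise_dnds_ml(seqs[2], seqs[3], codon_freqs)$kappa)
  ks <- ks[is.finite(ks)]
  if (!length(ks)) 2 else exp(mean(log(ks)))
}

# Log-likelihood of a triplet under per-branch (t, omega), single class.
branch_model_lnl <- function(pat, t, omega, kappa, codon_freqs) {
  models <- lapply(unique(omega), function(w) codon_model_memo(kappa, w, codon_freqs))
  names(models) <- as.character(unique(omega))
  Plist <- lapply(1:3, function(b) {
    transition_matrix(models[[as.character(omega[b])]], t[b])
  })
  sum(pat$w * log(pmax(class_site_lik(pat, Plist, models[[1]]$freqs), 1e-300)))
}

#' Branch-specific dN / omega asymmetry test
#'
#' Likelihood ratio test for asymmetric nonsynonymous evolution between the
#' two duplicate branches of a codon triplet. Each branch is parameterized
#' directly by its `(dN, dS)` (bijective with branch length and omega), so
#' the null is a single linear constraint: `which = "dN"` constrains
#' `dN1 = dN2`; `which = "omega"` constrains `dN1/dS1 = dN2/dS2`. df = 1.
#'
#' @param alignment Codon triplet alignment (`triplet_alignment` of type
#'   `"codon"` or named character vector `d1`, `d2`, `o`).
#' @param which `"dN"` or `"omega"`: the quantity constrained under the null.
#' @param codon_freqs Optional 61-vector (default: F3x4 from the alignment).
#' @return List with `lrt` (see [lrt()]), per-branch alternative estimates
#'   `dN`, `dS`, `omega`, and the fixed `kappa`.
#' @export
branch_asymmetry_test <- function(alignment, which = c("dN", "omega"),
                                  codon_freqs = NULL) {
  which <- match.arg(which)
  pat <- codon_triplet_patterns(alignment)
  seqs <- if (inherits(alignment, "triplet_alignment")) alignment$seqs else alignment
  if (is.null(codon_freqs)) codon_freqs <- f3x4_freqs(gsub("-", "", seqs))
  kappa <- estimate_kappa(alignment, codon_freqs)
  init <- init_branch_dnds(alignment)

  lnl_from_dnds <- function(dN, dS) {
    t <- numeric(3); omega <- numeric(3)
    for (b in 1:3) {
      cmp <- dnds_compose(dN[b], dS[b], kappa, codon_freqs)
      t[b] <- cmp$t; omega[b] <- min(cmp$omega, 50)
    }
    branch_model_lnl(pat, t, omega, kappa, codon_freqs)
  }
  lo <- log(1e-6); hi <- log(20)
  fit_par <- function(start, expand) {
    f <- function(par) {
      v <- expand(exp(par))
      -lnl_from_dnds(v$dN, v$dS)
    }
    optim(pmin(pmax(log(start), lo), hi), f, method = "L-BFGS-B",
          lower = lo, upper = hi, control = list(factr = 1e5, maxit = 300))
  }

  # Alternative: 6 free (dN1, dN2, dN3, dS1, dS2, dS3).
  alt <- fit_par(c(init$dN, init$dS),
                 function(x) list(dN = x[1:3], dS = x[4:6]))
  # Null: shared dN (or shared omega) across the duplicate branches.
  if (which == "dN") {
    null <- fit_par(c(mean(init$dN[1:2]), init$dN[3], init$dS),
                    function(x) list(dN = c(x[1], x[1], x[2]), dS = x[3:5]))
  } else {
    w0 <- mean(init$dN[1:2] / pmax(init$dS[1:2], 1e-4))
    null <- fit_par(c(w0, init$dN[3], init$dS),
                    function(x) list(dN = c(x[1] * x[3], x[1] * x[4], x[2]),
                                     dS = x[3:5]))
  }
  alt_v <- exp(alt$par)
  test <- lrt(-alt$value, -null$value, df = 1, tol = 0.05)
  list(lrt = test, dN = alt_v[1:3], dS = alt_v[4:6],
       omega = alt_v[1:3] / alt_v[4:6], kappa = kappa, which = which)
}

# Model A internals -----------------------------------------------------

# Class structure given foreground branch fg (1 or 2): per-class omega for
# branches (b1, b2, b3) and proportions from the stick-breaking pair (u, v):
# p0 = u v, p1 = u (1 - v), p2a = (1 - u) v, p2b = (1 - u)(1 - v).
model_a_classes <- function(u, v, w0, w2, fg) {
  bg_of <- function(w_bg, w_fg) {
    w <- rep(w_bg, 3)
    w[fg] <- w_fg
    w
  }
  list(
    list(prop = u * v, omega = bg_of(w0, w0)),
    list(prop = u * (1 - v), omega = bg_of(1, 1)),
    list(prop = (1 - u) * v, omega = bg_of(w0, w2)),
    list(prop = (1 - u) * (1 - v), omega = bg_of(1, w2))
  )
}

# Mixture log-likelihood for site classes with per-branch omegas. Branch
# lengths are expected substitutions per codon under the class mixture on
# that branch (per-branch mixture-weighted flux scaling).
site_class_lnl <- function(pat, t, classes, kappa, codon_freqs,
                           return_class_liks = FALSE) {
  props <- vapply(classes, `[[`, 0, "prop")
  omegas <- lapply(classes, `[[`, "omega")
  uw <- sort(unique(unlist(omegas)))
  models <- lapply(uw, function(w) codon_model_memo(kappa, w, codon_freqs))
  names(models) <- as.character(uw)
  flux <- vapply(models, `[[`, 0, "flux")
  scale_b <- vapply(1:3, function(b) {
    sum(props * flux[as.character(vapply(omegas, `[`, 0, b))])
  }, 0)
  # Cache the per-(omega, branch) leaf-conditional matrices: only 7 distinct
  # ones exist across the four site classes.
  Mcache <- new.env(parent = emptyenv())
  getM <- function(w, b) {
    key <- paste(w, b)
    if (is.null(Mcache[[key]])) {
      P <- transition_matrix(models[[as.character(w)]], t[b] / scale_b[b])
      Mcache[[key]] <- leaf_conditionals(P, pat$idx[b, ])
    }
    Mcache[[key]]
  }
  pi <- models[[1]]$freqs
  class_liks <- lapply(seq_along(classes), function(k) {
    w <- omegas[[k]]
    colSums(pi * (getM(w[1], 1) * getM(w[2], 2) * getM(w[3], 3)))
  })
  mix <- Reduce(`+`, Map(function(p, L) p * L, props, class_liks))
  lnl <- sum(pat$w * log(pmax(mix, 1e-300)))
  if (return_class_liks) list(lnl = lnl, class_liks = class_liks, mix = mix)
  else lnl
}

#' Branch-site Model A fit and positive-selection LRT
#'
#' Fits the branch-site model with four site classes on the codon triplet:
#' class 0 (omega0 < 1 everywhere), class 1 (omega = 1 everywhere), and
#' classes 2a/2b (omega2 >= 1 on the foreground duplicate branch, omega0 or 1
#' on the background). The null fixes omega2 = 1; the alternative frees it
#' (one extra parameter, df = 1 LRT). Branch lengths and class proportions
#' are estimated in both fits; kappa is profiled once per triplet and shared
#' between the fits.
#'
#' @param alignment Codon triplet alignment.
#' @param foreground `"d1"` or `"d2"`: the duplicate branch tested for
#'   positive selection (the accelerated copy).
#' @param codon_freqs Optional 61-vector (default: F3x4 from the alignment).
#' @return Object of class `branch_site_fit`: `alt` and `null` sub-lists
#'   (each with `lnL`, `p0`, `p1`, `p2`, `omega0`, `omega2`, `t`, `n_free`),
#'   the `lrt` result, `kappa`, `foreground`, and the data needed for
#'   [beb_site_posteriors()].
#' @export
branch_site_fit <- function(alignment, foreground = c("d1", "d2"),
                            codon_freqs = NULL) {
  foreground <- match.arg(foreground)
  fg <- if (foreground == "d1") 1L else 2L
  pat <- codon_triplet_patterns(alignment)
  seqs <- if (inherits(alignment, "triplet_alignment")) alignment$seqs else alignment
  if (is.null(codon_freqs)) codon_freqs <- f3x4_freqs(gsub("-", "", seqs))
  kappa <- estimate_kappa(alignment, codon_freqs)
  init <- init_branch_dnds(alignment)
  t0 <- pmax(3 * (init$dS * 0.25 + init$dN * 0.75), 1e-3) # rough subs/codon

  sigm <- function(x) 1 / (1 + exp(-x))
  lgt <- function(p) log(p / (1 - p))

  # Parameter vector: log t1, log t2, log t3, logit u, logit v, logit w0,
  # and (alternative only) log(w2 - 1).
  nll <- function(par, w2_free) {
    t <- exp(par[1:3])
    u <- sigm(par[4]); v <- sigm(par[5]); w0 <- sigm(par[6])
    w2 <- if (w2_free) 1 + exp(par[7]) else 1
    -site_class_lnl(pat, t, model_a_classes(u, v, w0, w2, fg), kappa, codon_freqs)
  }
  fit_one <- function(w2_free, start) {
    lower <- c(rep(log(1e-7), 3), rep(-8, 3), if (w2_free) log(1e-4))
    upper <- c(rep(log(50), 3), rep(8, 3), if (w2_free) log(49))
    best <- optim(start, nll, w2_free = w2_free, method = "L-BFGS-B",
                  lower = lower, upper = upper,
                  control = list(factr = 1e7, maxit = 200))
    best
  }
  start_base <- c(log(t0), lgt(0.85), lgt(0.8), lgt(0.2))
  null_fit <- fit_one(FALSE, start_base)
  alt_fit <- fit_one(TRUE, c(null_fit$par, log(1.5 - 1)))
  # Deterministic restarts if the nested ordering is violated.
  restarts <- list(c(start_base, log(3 - 1)),
                   c(log(t0), lgt(0.5), lgt(0.5), lgt(0.05), log(5 - 1)),
                   c(log(t0), lgt(0.95), lgt(0.9), lgt(0.5), log(1.2 - 1)))
  for (st in restarts) {
    if (-alt_fit$value >= -null_fit$value - 1e-3) break
    cand <- fit_one(TRUE, st)
    if (cand$value < alt_fit$value) alt_fit <- cand
  }

  unpack <- function(f, w2_free) {
    u <- sigm(f$par[4]); v <- sigm(f$par[5])
    list(lnL = -f$value, t = exp(f$par[1:3]),
         p0 = u * v, p1 = u * (1 - v), p2 = 1 - u,
         omega0 = sigm(f$par[6]),
         omega2 = if (w2_free) 1 + exp(f$par[7]) else 1,
         n_free = length(f$par), convergence = f$convergence)
  }
  alt <- unpack(alt_fit, TRUE)
  null <- unpack(null_fit, FALSE)
  test <- lrt(alt$lnL, null$lnL, df = 1, tol = 0.05)
  structure(list(alt = alt, null = null, lrt = test, kappa = kappa,
                 foreground = foreground, fg_index = fg,
                 codon_freqs = codon_freqs, pat = pat, seqs = seqs),
            class = "branch_site_fit")
}

#' Bayes Empirical Bayes posteriors for positively selected sites
#'
#' Empirical-Bayes posterior probability, per codon site, of membership in
#' the positively selected classes (2a/2b) of the alternative Model A fit,
#' averaging over a discrete prior grid on the class-proportion simplex
#' (10 divisions), omega0 in (0, 1) (10 midpoints), and omega2 in (1, 11)
#' (10 midpoints). Branch lengths, kappa, and the time scaling are held at
#' the alternative-model MLEs. Sites are reported when their posterior
#' exceeds the cutoff (strict inequality).
#'
#' @param fit A [branch_site_fit()] result (the alternative fit is used; an
#'   error if called on a fit whose alternative did not free omega2).
#' @param cutoff Posterior probability threshold (default 0.95, strict `>`).
#' @param grid_div Grid density per dimension (default 10).
#' @return `data.frame` with `position` (codon position in the alignment),
#'   `residue` (foreground amino acid), `posterior`, and a `label` like
#'   `"166E (0.998)"`, sorted by position. Attribute `posterior_all` holds
#'   the per-site posterior for every usable site.
#' @export
beb_site_posteriors <- function(fit, cutoff = 0.95, grid_div = 10) {
  assert_that(inherits(fit, "branch_site_fit"), "fit must be a branch_site_fit")
  assert_that(!is.null(fit$alt$omega2) && fit$alt$n_free == fit$null$n_free + 1,
              "BEB requires the alternative (omega2 free) fit")
  pat <- fit$pat
  fg <- fit$fg_index
  d <- grid_div

  # Fixed at the alternative MLEs: branch lengths, kappa, per-branch scale.
  alt <- fit$alt
  classes_mle <- model_a_classes(alt$p0 + alt$p1,
                                 alt$p0 / max(alt$p0 + alt$p1, 1e-12),
                                 alt$omega0, alt$omega2, fg)
  props_mle <- vapply(classes_mle, `[[`, 0, "prop")
  omegas_mle <- lapply(classes_mle, `[[`, "omega")
  flux_of <- function(w) codon_model(fit$kappa, w, fit$codon_freqs)$flux
  uw_mle <- unique(unlist(omegas_mle))
  flux_mle <- vapply(uw_mle, flux_of, 0)
  names(flux_mle) <- as.character(uw_mle)
  scale_b <- vapply(1:3, function(b) {
    sum(props_mle * flux_mle[as.character(vapply(omegas_mle, `[`, 0, b))])
  }, 0)
  tb <- alt$t / scale_b

  w0_grid <- (seq_len(d) - 0.5) / d          # omega0 in (0, 1)
  w2_grid <- 1 + 10 * (seq_len(d) - 0.5) / d # omega2 in (1, 11)
  # Midpoint grid on the (p0, p1) triangle.
  pp <- expand.grid(i = seq_len(d), j = seq_len(d))
  pp$p0 <- (pp$i - 0.5) / d
  pp$p1 <- (pp$j - 0.5) / d
  pp <- pp[pp$p0 + pp$p1 < 1, , drop = FALSE]

  # Per-branch conditional-likelihood caches by omega value.
  pi <- codon_model(fit$kappa, 1, fit$codon_freqs)$freqs
  M_of <- function(w, b) {
    P <- transition_matrix(codon_model_memo(fit$kappa, w, fit$codon_freqs), tb[b])
    leaf_conditionals(P, pat$idx[b, ])
  }
  bg <- setdiff(1:3, fg)
  M1_w <- lapply(w0_grid, function(w) M_of(w, fg))     # class 0 on fg
  M2_w <- lapply(w0_grid, function(w) M_of(w, bg[1]))
  M3_w <- lapply(w0_grid, function(w) M_of(w, bg[2]))
  M1_2 <- lapply(w2_grid, function(w) M_of(w, fg))     # classes 2a/2b on fg
  Mn <- lapply(1:3, function(b) M_of(1, b))            # neutral

  L0 <- vapply(seq_len(d), function(a) {
    colSums(pi * (M1_w[[a]] * M2_w[[a]] * M3_w[[a]]))
  }, numeric(length(pat$w)))
  L1 <- colSums(pi * (Mn[[fg]] * Mn[[bg[1]]] * Mn[[bg[2]]]))
  L2b <- vapply(seq_len(d), function(c2) {
    colSums(pi * (M1_2[[c2]] * Mn[[bg[1]]] * Mn[[bg[2]]]))
  }, numeric(length(pat$w)))
  L2a <- array(0, c(length(pat$w), d, d)) # [pattern, w0, w2]
  for (a in seq_len(d)) {
    B <- M2_w[[a]] * M3_w[[a]]
    for (c2 in seq_len(d)) L2a[, a, c2] <- colSums(pi * (M1_2[[c2]] * B))
  }

  grid_lnl <- numeric(0)
  grid_post <- list()
  for (r in seq_len(nrow(pp))) {
    p0 <- pp$p0[r]; p1 <- pp$p1[r]
    u <- p0 + p1; v <- p0 / u
    p2a <- (1 - u) * v; p2b <- (1 - u) * (1 - v)
    for (a in seq_len(d)) {
      for (c2 in seq_len(d)) {
        mix <- p0 * L0[, a] + p1 * L1 + p2a * L2a[, a, c2] + p2b * L2b[, c2]
        mix <- pmax(mix, 1e-300)
        grid_lnl <- c(grid_lnl, sum(pat$w * log(mix)))
        grid_post[[length(grid_post) + 1L]] <-
          (p2a * L2a[, a, c2] + p2b * L2b[, c2]) / mix
      }
    }
  }
  wgt <- exp(grid_lnl - max(grid_lnl))
  wgt <- wgt / sum(wgt)
  post_pat <- Reduce(`+`, Map(`*`, wgt, grid_post))

  post_site <- post_pat[pat$site_pattern]
  positions <- pat$positions
  sp <- codon_space()
  fg_res <- sp$aa[pat$idx[fg, pat$site_pattern]]
  sel <- which(post_site > cutoff)
  out <- data.frame(position = positions[sel], residue = fg_res[sel],
                    posterior = post_site[sel], stringsAsFactors = FALSE)
  out <- out[order(out$position), , drop = FALSE]
  out$label <- sprintf("%d%s (%.3f)", out$position, out$residue, out$posterior)
  rownames(out) <- NULL
  attr(out, "posterior_all") <- data.frame(position = positions,
                                           posterior = post_site)
  out
}
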