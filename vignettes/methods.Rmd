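---
title: "Models and methods behind dupreloc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dupreloc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`dupreloc` tests whether duplicated genes whose protein products have been
retargeted to a new subcellular compartment also show distinctive sequence
evolution. This vignette documents the models, the tunable parameters, the
numerical choices, and the limits of what the package's own simulations can
establish.

## The rate-symmetry (clock) test on triplets

Each duplicate pair is analyzed with one outgroup ortholog on the unrooted
three-taxon star: branches `b1` and `b2` lead to the two duplicates, `b3` to
the outgroup, all in expected substitutions per site. Under equal-rates
evolution the two duplicate lineages have accumulated the same expected
divergence since the duplication node, so the null model constrains
`b1 = b2` (the outgroup branch stays free). The alternative frees all three
branches. Amino-acid likelihoods use the JTT replacement model: the
exchangeability matrix is combined with its published equilibrium
frequencies, scaled to one expected substitution per site per unit branch
length, and site likelihoods are computed by the pruning sum over the
internal state; gap and ambiguity characters are marginalized as missing
data rather than the columns being deleted (both conventions exist in
practice; marginalization uses more of the alignment).

The test statistic is `2δL = 2(lnL_free − lnL_clock)`, clamped at zero and
referred to χ² with one degree of freedom. Across a cohort of pairs the
p-values are adjusted by the Benjamini–Hochberg step-up procedure; a pair is
called asymmetric when the adjusted value is below `q_cutoff` (default
0.05), and the accelerated copy is the duplicate with the longer free-fit
branch. No accelerated copy is reported for non-significant pairs.

Branch lengths are optimized on the log scale with L-BFGS-B inside
`[1e-9, 50]`. Starting values come from pairwise distances with a saturating
log correction. Restarts from a deterministic grid are attempted only when a
fit fails to converge or the nested-likelihood ordering
(`lnL_free ≥ lnL_clock`) is violated; unconditional multi-start added
nothing on simulated data while multiplying the cost of calibration studies
several-fold, so it is reserved for the failure path (up to five starts).

## Codon models

Pairwise and branch-specific analyses use a Goldman–Yang style model on the
61 sense codons of the standard code: single-nucleotide changes occur at
rate `π_j · κ^[transition] · ω^[nonsynonymous]`, with κ the
transition/transversion ratio and ω = dN/dS. Codon frequencies are F3x4
(products of position-specific nucleotide frequencies estimated from the
data, with a 0.5 pseudocount); columns containing a gap or ambiguous codon
are excluded from codon fits (complete deletion). The rate matrix is scaled
to one expected substitution per codon per unit branch length.

`dN` and `dS` are derived from the fitted `(t, κ, ω)` by flux
decomposition: the proportion of substitutions that are synonymous, divided
by the proportion of *sites* that are synonymous, where sites are counted
from the same model at ω = 1. Under this decomposition `dN/dS` equals the
model's ω exactly, which the tests assert. The Nei–Gojobori (1986) counting
estimator (equal-weight path averaging, Jukes–Cantor correction) is
implemented independently and serves as a cross-check: the two estimators
must agree within 20% at moderate divergence (t ≤ 0.3) and converge as
t → 0.

For the branch-specific asymmetry test each branch is parameterized directly
by its `(dN, dS)` pair — a bijective reparameterization of `(t, ω)` — so the
null hypotheses `dN1 = dN2` and `ω1 = ω2` are single equality constraints
and the LRT has one degree of freedom. κ is profiled once per triplet from
pairwise ML fits to the outgroup and held fixed in both the null and
alternative fits; both models therefore condition on the same κ and the test
remains properly nested. This profiling choice costs little (κ is well
determined and nearly orthogonal to the branch parameters) and roughly
halves the optimization dimension.

## Branch-site positive selection and BEB

The branch-site model (Model A) assigns sites to four classes: class 0
(0 < ω₀ < 1 on all branches, proportion p0), class 1 (ω = 1 everywhere,
p1), and classes 2a/2b (ω₂ ≥ 1 on the designated foreground branch — the
accelerated duplicate — with ω₀ or 1 on the background; proportions
`(1−p0−p1)·p0/(p0+p1)` and `(1−p0−p1)·p1/(p0+p1)`). The proportions are
optimized through a stick-breaking transform that maps exactly onto this
structure. The null fixes ω₂ = 1; the alternative frees it, giving exactly
one extra parameter and a df = 1 χ² reference, the convention used
throughout (not the 50:50 boundary-mixture refinement, which would only make
the test more conservative). The calibration tests confirm the χ²(1) version
rejects at well below the nominal level under null simulations.

Because site classes mix branches with different ω, a time-scale convention
is needed: each branch's rate matrix set is divided by the mixture-weighted
expected flux *on that branch*, so a branch length is the expected number of
substitutions per codon on that branch under the class mixture. The
simulator uses the identical convention, making simulated branch lengths and
fitted branch lengths directly comparable.

Site identification uses Bayes Empirical Bayes: the posterior probability
that a site belongs to class 2a/2b, averaged over a discrete prior grid —
55 midpoints on the (p0, p1) simplex triangle (10 divisions), 10 midpoints
for ω₀ in (0, 1), 10 for ω₂ in (1, 11) — with each grid point weighted by
its data likelihood. Branch lengths, κ, and the per-branch time scaling are
held at the alternative-model MLEs. Sites are reported only above a strict
0.95 posterior. With only three sequences the per-site information is
limited: the BEB list has high precision (on simulated data ≥80% of flagged
sites are truly selected, and null simulations almost never flag any site)
but low recall, which is the intended trade-off of the >0.95 rule.

## Group statistics

Localization calls compare the two compartment-token sets
case-insensitively: equal sets are `same`, disjoint sets `complete_change`,
any other overlap `partial_change` (expansion, contraction, or partial
overlap). Tokens are atomic: in particular `cyb` (cytosolic body) and `cy`
(cytosol) are distinct compartments — treating them as related would change
the 14/5 complete/partial split of the curated pair table. Pairs whose two GFP
records come from different studies or different experimental conditions are
excluded when `strict_same_study` is set, since localization can genuinely
differ across conditions.

Relocalized (complete ∪ partial) versus same pairs are crossed with the
asymmetry calls into a 2×2 table. Enrichment is tested two ways:

* a one-tailed Fisher exact test (upper hypergeometric tail — the
  enrichment direction), checked in the test suite against brute-force
  enumeration over all tables with N ≤ 30;
* a Monte Carlo test on `DIF = |a/n_reloc − c/n_same|`, the absolute
  difference in asymmetry frequency. The default null (`resample`) redraws
  every pair's flag at the pooled frequency with group sizes fixed;
  `permute` shuffles the observed flags (hypergeometric). Published
  descriptions of randomization nulls rarely pin this down, so both schemes
  are implemented and recorded in the output; the Monte Carlo p is the
  fraction of replicates with `DIF_sim ≥ DIF_obs` (the natural two-tailed
  reading for an absolute-valued statistic), computed as `k/n_sim` with a
  `(k+1)/(n+1)` option. With a fixed seed the p-value is bit-reproducible.

Isoelectric points solve the Henderson–Hasselbalch net-charge equation by
bisection on [0, 14] to 1e-4 pH, with the EMBOSS pK set (N-terminus 8.6,
C-terminus 3.6, C 8.5, D 3.9, E 4.1, H 6.5, K 10.8, R 12.5, Y 10.1). The
within-pair |ΔpI| values of the two groups are compared by a Welch
(unequal-variance) two-tailed t-test — the safer default when group sizes
and spreads differ.

## The simulators and what they do (not) show

`simulate_aa_triplet` and `simulate_codon_triplet` draw a root state from
the model's equilibrium and evolve it independently down the three branches
with exact transition probabilities; codon site classes are i.i.d. across
sites. `simulate_cohort` generates pair rosters with a fixed number of
relocalized pairs and Bernoulli (or exact-count) asymmetry flags; per-pair
flags use counter-derived sub-seeds so a pair's draw is independent of
cohort order. The deterministic mode reproduces the observed cohort
structure (128 pairs; 19 relocalized, 8 asymmetric; 109 non-relocalized,
13 asymmetric) exactly.

The simulators deliberately omit indels, rate autocorrelation along the
sequence, selection on synonymous sites, and alignment error. Passing
calibration and recovery tests on simulated data therefore demonstrates the
statistical machinery is correct under the stated models, not that real
alignments satisfy those models; gap handling is exercised with explicit
fixtures instead.

## Numerical choices and problem sizes

* Optimizers: L-BFGS-B on transformed (log / logit) parameters; bounds
  `b ∈ [1e-9, 50]` substitutions per site, `κ ∈ [0.01, 100]`,
  `ω ∈ [1e-6, 50]`; relative convergence `factr = 1e4–1e7` by model size.
* Degenerate inputs: identical sequences fit to zero branch lengths with
  equal clock/free likelihoods; saturated pairwise dS is flagged rather than
  propagated; `2δL` is clamped at zero; empty compartment sets and margin-
  degenerate 2×2 tables are rejected or short-circuited (`p = 1`).
* Ties in best-hit selection break by bit score, then e-value, then
  lexicographic subject id, making ortholog assignment deterministic.
* The dS age cutoff is inclusive (`dS ≤ 1` kept): the duplicate-age rule is
  a cutoff value, and the boundary pair is evidence-equivalent to the mean
  alpha-WGD age; the cutoff is configurable.
* Strict-majority consensus: a clade in exactly half the trees is excluded;
  supports are recorded as fractions.
* Calibration studies in the test suite run at desk scale, chosen to keep
  the full suite in minutes while leaving the binomial error bands
  informative: 500 replicates × 1,000 sites for the clock-test type-I error,
  60 × 2,000 sites for accelerated-copy identification, 40 × 200 codons for
  branch-site null calibration, 4 × 600 codons for BEB precision. The same
  properties hold at larger sizes; the sizes are stated here so they can be
  scaled up deliberately.

## Interfaces

All stages read and write standard formats: FASTA (Biostrings), Newick
(ape; internal labels read as bootstrap supports), 12-column tabular
similarity hits, and TSV tables for localization records, rosters, and
results. `pipeline_config()` carries every threshold (e ≤ 1e-5, coverage
≥ 0.60, dS ≤ 1, α = 0.05, Q < 0.05, BEB > 0.95, 10,000 randomization
replicates) and is serialized into every report for provenance. The package
is function-first: `run_pipeline()` composes the stages on in-memory inputs,
and `scripts/acceptance.R` is the runnable entry point that recomputes the
headline numbers from scratch.

## Known limitations

* Three-taxon branch-site analyses have modest power; the LRT detects
  pervasive foreground selection but single-site recall of BEB is low (by
  design of the strict cutoff).
* κ profiling (rather than joint estimation) in branch-model fits is an
  approximation; on simulated data it does not measurably shift the LRT
  null distribution, but extremely short alignments may see a small effect.
* The one-ortholog-per-pair rule resolves multi-species candidates by a
  configurable species-priority list; synteny-aware orthology is out of
  scope.
* The pipeline consumes similarity hits and trees; it does not run BLAST,
  aligners, or tree builders.
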