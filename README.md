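# dupreloc

Subcellular relocalization and asymmetric sequence evolution of duplicated
genes.

## What it is for

After a gene duplication, one protein product can acquire a new subcellular
localization (neolocalization) or the two copies can partition ancestral
localizations (sublocalization). `dupreloc` implements a reusable pipeline
for asking whether such relocalized duplicate pairs also evolve differently
at the sequence level, as studied in recently duplicated *Arabidopsis*
(Brassicaceae) gene pairs with GFP localization data. It is aimed at
molecular-evolution researchers who have duplicate-pair rosters, gene-family
trees, similarity-hit tables, and per-gene localization annotations, and
want the full statistical chain from raw inputs to enrichment tests.

The pipeline stages, each usable on its own:

1. **Pair discovery** — strict-majority (>50%) consensus of bootstrap
   gene-family trees, extraction of two-member monophyletic clades,
   synonymous-distance age filtering (dS ≤ 1 by default), and duplication-type
   labeling (alpha-WGD / tandem / other) against rosters.
2. **Ortholog assignment** — reciprocal-best-hit filtering of BLAST-style
   tabular hits (e ≤ 10⁻⁵, alignment covering ≥60% of the shorter protein),
   one-way fallback, and dS triangulation (`dS2 > dS1` and `dS3 > dS1`)
   to confirm the duplication postdates the speciation.
3. **Rate asymmetry** — for each (duplicate 1, duplicate 2, outgroup)
   triplet, a likelihood ratio test of clock-like (`b1 = b2`) versus free
   branch lengths under the JTT amino-acid model (`2δL` against χ², df = 1),
   with Benjamini–Hochberg FDR across pairs (Q < 0.05) and identification of
   the accelerated copy.
4. **Positive selection** — pairwise and branch-specific dN/dS under a
   Goldman–Yang codon model (F3x4 frequencies), the Nei–Gojobori counting
   estimator as a cross-check, branch-site Model A with the accelerated copy
   as foreground (ω₂ free ≥ 1 vs ω₂ = 1, df = 1), and Bayes Empirical Bayes
   posteriors for positively selected sites (reported above 0.95).
5. **Group statistics** — localization-set comparison (`same`,
   `complete_change`, `partial_change`), a one-tailed Fisher exact test for
   asymmetry enrichment in relocalized pairs, a Monte Carlo randomization
   test on the DIF statistic (absolute difference in asymmetry frequency
   between groups; 10,000 replicates), and a Welch t-test on within-pair
   isoelectric-point differences (EMBOSS pK set).
6. **Simulation** — amino-acid and codon triplet simulators (including
   branch-site selection on a site fraction) and a cohort generator, so every
   stage is testable without external data.

## Worked example

A cohort with the observed structure — 128 duplicate pairs, 19 relocalized
of which 8 evolve asymmetrically, 109 non-relocalized of which 13 do:

```r
library(dupreloc)

roster <- simulate_cohort(cohort_spec(128, 19, 8/19, 13/109,
                                      deterministic_counts = TRUE))
calls <- ifelse(roster$reloc_flag, "complete_change", "same")
tab <- build_contingency(calls, roster$asym_flag)
tab
#>             asymmetric symmetric
#> relocalized          8        11
#> same                13        96

fisher_one_tailed(tab)
#> [1] 0.003405388

dif <- dif_randomization(c(19, 109), c(8, 13), n_sim = 10000, seed = 1)
dif$dif_obs
#> [1] 0.3017866
dif$mc_p
#> [1] 0.0013
```

So relocalized pairs are asymmetric at 42% versus 12% for non-relocalized
pairs; the enrichment is significant by the exact test (P ≈ 3.4 × 10⁻³) and
by randomization (DIF_obs ≈ 0.302, Monte Carlo P ≈ 10⁻³ at 10,000
replicates).

Classifying the curated 19-pair GFP localization table shipped with the
package:

```r
loc   <- read_localization_table(system.file("extdata",
           "gfp_localizations.tsv", package = "dupreloc"))
pairs <- read_roster(system.file("extdata",
           "relocalized_pairs.tsv", package = "dupreloc"))
table(classify_pair_localizations(pairs, loc)$call)
#> complete_change  partial_change
#>              14               5
```

And a rate test on a simulated asymmetric triplet:

```r
aln   <- simulate_aa_triplet(triplet_tree(0.3, 0.1, 0.3), n_sites = 2000, seed = 1)
free  <- fit_triplet_aa(aln, "free")
clock <- fit_triplet_aa(aln, "clock", free_lnl = free$lnL)
lrt(free$lnL, clock$lnL)$two_delta_L
#> [1] 113.5019
```

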