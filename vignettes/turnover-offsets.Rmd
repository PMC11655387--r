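---
title: "Methods: turnover functions, genomic offsets and scenario planning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: turnover functions, genomic offsets and scenario planning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical methods behind `archoffset`, the
conventions the implementation follows, and the places where a reasonable
reader could have made a different choice. It is a methods reference, not a
tutorial; the README walks through a complete example.

## The problem

Conservation programmes for long-lived island plants increasingly ask a
quantitative question: if the climate a population is adapted to moves out
from under it, *which seed sources should be planted where*? The package
answers this with the genomic-offset framework: learn how allelic
composition turns over along climate gradients, map every climate into that
"genomic-scaled" space, and measure the mismatch between a seed source's
climate of origin and a candidate planting site's expected future climate.

The pipeline is: variant filtering → population structure checks →
genotype–environment association (RDA) → spatial eigenvectors (PCNM) →
gradient-forest turnover functions → offsets, scenarios, and suitability
maps. A self-contained archipelago simulator provides end-to-end validation
fixtures with known truth.

## Variant filtering and LD pruning

`read_vcf()` keeps biallelic records only and masks genotypes below a depth
threshold (default 5 reads). `filter_sites()` then applies, in order: site
mean depth < 5 removed; minor allele frequency < 1% removed; missingness >
10% removed. The report object carries a conservation identity (input =
output + all removals) enforced by an internal assertion.

`ld_prune()` implements windowed `r^2` pruning (window 50 SNPs, step 10,
threshold 0.1 by default). Within a window the *worst* correlated pair is
resolved first, dropping the lower-MAF member; exact MAF ties drop the SNP
at the later position (`dialect = "keep-first"` gives the alternative
convention of always dropping the later SNP). Pruning dialects differ
between mainstream tools; ours is deterministic, idempotent, and verified
against an exhaustive brute-force oracle in the tests.

`impute_mode()` fills missing dosages with the per-SNP modal genotype,
breaking ties toward the lower dosage (so imputation never inflates the
minor allele on ambiguous evidence).

## Population structure

`wc_fst()` is the Weir–Cockerham variance-components estimator, generalised
to any number of groups; multi-locus estimates are ratios of summed
components (the "ratio of averages" form, which is less biased than
averaging per-locus ratios). The spread reported is the SD of per-locus
estimates; the 1-SD band may dip below zero, which carries no meaning
beyond "indistinguishable from zero". Loci with fewer than two genotyped
individuals in any group, or monomorphic overall, are excluded and counted.

`fit_ibd()` fits a four-parameter logistic to pairwise genetic versus
geographic distance. Because distance pairs are not independent, the
p-value is a Mantel-style permutation of individuals, not a regression
test. When the sigmoid fails to converge the function falls back to
isotonic regression and flags it.

## Redundancy analysis

`fit_rda()` centres the response matrix, standardises predictors, projects
via the QR decomposition, and decomposes the fitted values by SVD;
eigenvalues are `d^2 / (n - 1)` and the adjusted R² is Ezekiel's formula.
Partial models residualise both sides on the conditioning set. The
permutation test permutes rows of the (conditioned) response — the
Freedman–Lane scheme for partial models — and reports
`p = (1 + #{F >= F_obs}) / (1 + n_perm)`, so 99 permutations floor the
p-value at 0.01.

`variance_partition()` uses the classic adjusted-R² decomposition
(climate alone, geography alone, joint). The identity
`full = climate + geography + joint` holds to numerical precision *by
construction*; the joint fraction is confounded and deliberately untested.

Candidate SNPs are loadings more than 4 SD from the mean on any of the
first 3 constrained axes. Under a Gaussian null this flags about
`2 * pnorm(-4)` of SNPs per axis (~1.9 expected in 10,000 × 3), which the
tests verify with a Poisson envelope. A caution that matters in practice:
island climate gradients are strongly collinear, so the "most correlated
predictor" attribution (`assign_predictor()`) is only identifiable up to a
cluster of tightly correlated variables.

## PCNM spatial eigenvectors

`pcnm()` truncates the site distance matrix at `t` (distances beyond `t`
are set to `4t`), applies Gower double-centring to `-0.5 D'^2`, and keeps
positive-eigenvalue axes scaled by the square root of their eigenvalue.
The leading half of the positive axes (broad-scale structure) is retained
as the geography proxy; with an odd count we take the floor
(`retain_half_positive(..., halving = "ceiling")` gives the other
convention). The equilateral-triangle closed form (both eigenvalues
`d^2/2`) and a brute-force double-centring oracle pin the implementation
down in the tests.

## Gradient-forest turnover functions

This is the package's core and is implemented from scratch on a compiled
regression-forest backend:

* one regression forest per SNP (dosage on the predictor table), with
  bootstrap resampling, `mtry = floor(p/3)`, minimum node size 5, and
  depth capped at `max(1, round(log2(0.368 n / 2)))` — the depth that
  matches the expected number of distinct observations in a bootstrap
  sample (about `0.368 n` left out). `max_level_rule()` exposes the
  arithmetic; a `floor` variant is available.
* split quality is variance impurity; every split's improvement is
  recorded against its predictor and threshold.
* a SNP contributes only if its out-of-bag R² is positive; its split
  improvements are rescaled so they total exactly that R².
* improvements are accumulated into 50 equal-frequency bins per predictor,
  averaged over contributing SNPs, and cumulated. The result is one
  non-decreasing step function `f_v` per predictor with `f_v(min) = 0` and
  `f_v(max)` equal to the predictor's overall importance; total importance
  equals the mean out-of-bag R² of contributing SNPs (mass conservation,
  tested to 1e-8).

One deliberate deviation from some reference implementations: we bin raw
cumulative split importance without per-bin density standardisation. The
binned curve is simpler, exactly mass-conserving, and sufficient for
offsets, but its *shape* within a predictor's range can differ from
density-standardised curves where sampling of the gradient is very uneven.

Determinism: forests are seeded per SNP via `child_seed(seed, snp_index)`,
and the C++ backend uses its own fixed random-draw algorithm rather than
`std::uniform_int_distribution` (whose output is implementation-defined),
so results are bit-identical across platforms and refits.

Evaluation is a right-continuous step lookup,
`c(0, cum)[findInterval(x, upper) + 1]`, clamped to the training range —
extrapolation beyond observed climates is deliberately flat.

## Offsets, scenarios, suitability

`genomic_offset()` is the Euclidean distance between turnover-transformed
climates. PCNM axes are excluded from offsets by default because unsampled
grid cells have no meaningful PCNM coordinates; `include_spatial = TRUE`
overrides this for sampled-site comparisons.

Three planting scenarios, all derived from one sources-by-sites offset
table:

* **status quo** — each population against its own future climate;
* **ecosystem preservation** — per site, the seed source with minimal
  offset (exact ties are counted and the first source designated);
* **species preservation** — per population, the planting site with
  minimal offset, over the sampled sites or over every grid cell.

Because staying put is one admissible choice, both relocation scenarios
are bounded above by the status quo, and widening the site pool can only
help; the tests assert these dominance relations end-to-end.

Suitability is `S = 1 - O / max(O)`: 1 means a transformed climate
identical to the climate of origin, 0 the worst pairing in the table. The
orientation (dividing by the maximum and *subtracting from one*) is chosen
so those endpoints hold exactly; when sub-tables are compared, pass the
global maximum explicitly via `max_offset` so values stay commensurable.
`best_pairs()` ranks sources per site (and sites per population) and
orders sites by mean suitability for heat-map-style layouts.

## The archipelago simulator

`make_archipelago()` lays out islands on a line with Gaussian cell scatter
and builds historic climates from linear latitudinal/longitudinal
gradients plus noise; the future slice adds a named displacement per
predictor (exact by default, optionally with cell-level noise).
`simulate_genotypes()` draws island allele frequencies from the
Balding–Nichols model (`Beta(p0 (1-F)/F, (1-p0)(1-F)/F)`), so the
realised multi-locus F_ST recovers the target `F` (verified: `F = 0.05`
lands in [0.035, 0.065] at 4 × 25 × 2,000). Adaptive loci get logistic
clines along a named climate driver with slope `effect_b`. Optional
uniform missingness writes synthetic depths so a VCF round-trip through
the depth mask reproduces the pattern exactly.

Realism limits, stated plainly: gradients are linear, islands are
one-dimensional in layout, linkage is absent (loci are independent), and
adaptation is single-driver logistic. The simulator is a validation
instrument — it produces known truth for recovery tests — not an
ecological model. Problem sizes used in the tests (6 islands × 10 cells,
120 individuals, 2,000 SNPs, 200-SNP forest fits) are the package's own
desk-scale choices, selected so the full suite runs in minutes.

## Numerical conventions worth knowing

* Ties: mode imputation breaks toward the lower dosage; LD pruning toward
  the later position (under equal MAF); predictor assignment toward the
  earlier column (flagged).
* `p`-values from permutation tests never reach zero; the floor is
  `1 / (1 + n_perm)`.
* All RNG fan-out uses `child_seed()`, so adding or removing one SNP does
  not shift every downstream stream.
* Step functions are exact: no interpolation anywhere in the offset path.

## Limitations

Offsets assume space-for-time substitution and ignore demography,
dispersal, biotic interactions, and plasticity. Impurity-based importances
are inflated for correlated predictors (the fit emits a message above a
0.5 correlation). Binned turnover curves are resolution-limited by the 50
equal-frequency bins. None of these caveats is unique to this
implementation, but all of them matter when ranking real seed sources.
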