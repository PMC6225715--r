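---
title: "Methods: cross-host FMT microbiome analysis with fmtpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-host FMT microbiome analysis with fmtpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmtpipe)
```

`fmtpipe` analyzes paired donor/recipient microbiome studies built around
cross-species fecal microbiota transplantation: stool communities from
healthy (H) and diseased (M) donors, transplanted into germ-free recipients,
with an optional probiotic-intervention arm (P) in the recipient host. This
vignette is the package's own account of the models it implements, the
parameters that matter, and what its synthetic-data tests do and do not
demonstrate.

## The phylogeny-weighted community distance

Community distances for OTU tables weight shared abundance by where on the
phylogeny it is shared. Both profiles are relative-normalized. In a
post-order pass over the rooted tree, abundance matched at a leaf scores
with weight 1; unmatched residuals propagate upward, and residual mass
matched at an internal node `v` scores with weight `w(v)`. The default
weight is linear in node height, `w(v) = max(0, 1 - h_v / H)`, where `h_v`
is the longest path from `v` down to one of its leaves and `H` is the tree
height; an exponential mode `w(v) = exp(-lambda * h_v)` is available. The
similarity is the total weighted matched mass and the distance is its
complement.

This concrete weighting is this package's own definition. It was chosen
because it (i) is a proper similarity in [0, 1]; (ii) reduces *exactly* to
1 − Bray–Curtis on star trees, because every leaf has weight 1 and the root
has weight 0 — which supplies an independent oracle used throughout the test
suite; and (iii) discounts matches at deep ancestors, which is the point of
phylogeny-aware beta diversity. Published phylogeny-weighted tools do not
print their weighting scheme in a form we could replicate, so no fidelity to
any external binary is claimed; both decay modes are labeled as this
package's definitions. KO (functional) profiles use the cosine distance,
for which no phylogeny exists.

Numerical notes: profiles must sum to 1 within 1e-6; tiny negative cosine
values from floating point are clipped to 0; a tree of zero total height is
rejected rather than silently weighting all nodes equally.

## Ordination, PERMANOVA, Procrustes

PCoA is classical metric scaling (Gower centering of −d²/2, via
`ape::pcoa()`). Negative eigenvalues — expected for semi-metric community
distances — are reported but excluded from both the coordinates and the
proportion-explained denominator; this is the common convention and keeps
reported percentages interpretable. PCA of KO tables is centered, unscaled
`prcomp()` on relative abundances; whether to log-transform first is left to
the caller (`log10_transform`, pseudocount 1e-6) because the choice is not
decidable from the downstream quantities we report, and untransformed
relative abundance is the more conservative default.

PERMANOVA is the one-way pseudo-F on squared distances, with
`SS_total = sum(d²)/N` over all pairs and within-group sums scaled by group
size. The p-value uses label shuffling with the add-one convention
`p = (b + 1)/(m + 1)`, so `p >= 1/(m + 1)`; with two groups an exhaustive
mode enumerates all label splits instead, and the test suite proves the two
routes agree on every instance small enough to enumerate. The default 999
permutations makes p-values of 0.001 attainable, matching the granularity
of the headline tests this pipeline is built for. Only the one-way design
is implemented because every comparison in scope is a single group factor.

Procrustes concordance scales both configurations (first two axes by
default) to unit trace, so the statistic `M² = 1 − (Σ singular values)²` is
symmetric in its arguments; significance is Monte-Carlo by row permutation.
When the compared ordinations collapse (all points equal) the statistic is
undefined and the function errors rather than returning 0/0.

## Marker discovery

Each feature is tested between two groups with the Wilcoxon rank-sum test:
exact enumeration when the pooled sample size is at most 12 and tie-free,
otherwise the mid-rank normal approximation with tie-corrected variance and
continuity correction (both routes delegated to `stats::wilcox.test`, whose
behavior matches this contract; the test suite verifies the exact route
against direct enumeration of rank-sum splits). Two-sided p-values drive
selection; both one-sided p-values are carried along because the enrichment
stage needs per-KO direction calls. BH adjustment is the step-up rule via
`stats::p.adjust`, verified against a brute-force implementation of the
definition.

The source analyses use different thresholds for different feature kinds,
so the threshold is configuration, not code: profiles `paper-otu`
(q < 0.01), `paper-ko` (p < 0.05, unadjusted) and `paper-network`
(q < 0.01) name the three published choices, and the package default is
q < 0.1. Features must occur in at least `min_occurrence = 6` samples
("more than five") before testing. Effects are differences in group mean
relative abundance, with a log2 ratio computed at pseudocount 1e-6; tests
default to relative abundances because raw library sizes are nuisance
variation here. A feature with exactly zero effect difference takes its
direction from the smaller one-sided p-value, so that label swapping flips
every reported direction.

## Reporter-score pathway enrichment

Per tested KO, `z = qnorm(1 - p)` from the two-sided p-value; per pathway
with `k` tested members, `Z_raw = sum(z)/sqrt(k)`; the corrected score
standardizes `Z_raw` against the mean and standard deviation of the same
statistic over `n_draws = 1000` random size-`k` subsets of all tested KO z
scores. Detection uses `Z_adj > 1.6`, the one-decimal rounding of the 90%
standard-normal quantile (1.645). Direction is called from the counts of
KOs individually significant in the one-sided tests at alpha = 0.05: a
pathway is "up" only when `n_up >= 1.1 * n_down` (exact real comparison, no
rounding) and symmetrically "down", otherwise "mixed". The cited
reporter-feature literature does not print its equations, so the z
transform, the sqrt(k) normalization and the subset-sampling background are
this package's concrete instantiation, stated here as such. Using two-sided
p-values for `Z_raw` and one-sided tests only for direction counts is a
deliberate split: it keeps the score sensitive to coherent perturbation of
either sign while the direction call stays interpretable.

A property worth knowing: because the background is the pool of *tested*
KOs, the correction measures enrichment relative to the experiment-wide
signal. Under a global null the false-positive rate at 1.6 is the normal
tail (~5.5%), which the acceptance suite verifies; conversely, when nearly
every KO is strongly differential (as in the amplified recipient host at
default settings), pathways no longer stand out against the saturated
background and few or none are flagged. That is the intended behavior of a
background-corrected score, not a power failure; planted-pathway recovery
is therefore assessed in the donor host.

## Co-occurrence networks

Differential OTUs and KOs are correlated with Spearman's rho (mid-ranks,
two-sided p from the t-approximation). Edges require `|rho| > 0.8` *and* BH
q < 0.01 over all tested pairs; the magnitude rule reflects that negative
edges are meaningful (they are drawn dashed in the field's figures).
OTU–KO pairs are tested by default; same-kind edges are an option. The
published analysis used a resampling-based correlation package for this
step; this package implements plain Spearman + BH as its defined contract,
honoring the explicitly printed rho and q thresholds. Constant features are
skipped with a warning because rank correlation is undefined for them.

## Cross-host comparison

"Averaged distance" between groups is the mean of `d(i, j)` over all
between-group pairs, within-group pairs excluded — the only reading that
yields a single scalar per host. The amplification factor is the ratio of
the recipient's mean between-group distance to the donor's;
`fold_label()` provides the round-half-up integer presentation (22.88 →
"23-fold"). Rank-level sharing maps features through the taxonomy; the
reported fraction is abundance-weighted by default with a count-based
companion, since a printed percentage does not reveal its basis. Missing
taxonomy ranks become per-OTU `unclassified_` tokens that never match each
other, so unclassifiable taxa can never inflate sharing. Concordant markers
must be significant in both hosts with the same direction; at genus or
family rank a taxon only counts when all its significant markers within a
host agree.

## The synthetic study generator

`generate_paired_study()` emulates the study design the pipeline targets:
12 samples per group (H, M) in the donor host, 12 per group (H, M, P) in
the recipient, ~10,000 reads per sample, and planted structure with known
truth.

- **Counts**: Dirichlet-multinomial. The baseline composition is a
  lognormal rank-abundance profile (sdlog = 1) over `n_otus = 150` taxa.
  `base_concentration = 50` is the per-feature concentration: the Dirichlet
  parameter is `50 * n_otus * p_g`. This calibration makes replicate
  communities vary at the scale real paired-study data shows — mean
  between-group distances of ~0.1 in the donor host, as printed in the
  study this design emulates — while leaving enough overdispersion that
  tests are exercised against noise.
- **Planted markers**: 30 OTUs (half enriched in M, half depleted), shifted
  by `log2_effect = 1.5` on the log2 scale in the donor and by
  `log2_effect * amplification` (default amplification 3) in the recipient.
  Planted OTUs are drawn from the non-rare 75% of the baseline because the
  markers this pipeline is meant to find are taxa a 10,000-read survey can
  actually quantify; planting in the rarest quartile would test the
  sequencing depth, not the statistics.
- **Engraftment**: recipients are seeded from the pooled donor composition
  (donor stools are pooled into one inoculum in the emulated protocol);
  each recipient group independently loses each non-planted OTU with
  probability 0.1, mimicking incomplete transfer. Planted OTUs are exempt
  so that the planted truth remains the interpretable ground truth for
  recovery tests.
- **Function**: KO abundances are the relative OTU abundances times a
  nonnegative gene-content matrix, with multiplicative lognormal noise
  (CV = 0.2). Member KOs of the four planted pathways load on planted OTUs
  of one sign, so KO-level differences aggregate into pathway-level
  enrichment. Group P keeps group M's OTU composition but pulls the
  planted-pathway KO effects 60% of the way back toward H — "structurally
  similar to the diseased state, functionally shifted toward health".
- **Reproducibility**: all stage seeds derive from the single config seed;
  bundles are bit-identical across runs.

What passing tests on this generator do *not* show: real 16S/metagenome
data has compositional artifacts, taxonomy errors, depth variation across
samples, phylogenetic signal in which taxa respond, and between-subject
variance structure none of which is modeled. The generator demonstrates
that the statistics recover what was planted under honest noise, not that
the pipeline's biological conclusions on any real dataset are correct.

## Problem sizes and determinism

The shipped tests run the generator at its default design (150 OTUs, 300
KOs, 12 samples per group) with 20-seed averages for recovery properties
and 50 seeds for null calibration, and smaller bundles for stage-level unit
tests; these sizes were chosen as the smallest at which the distributional
claims are stable across reruns. The full pipeline (`run_full()`) derives
every stage seed from one global seed and writes all intermediates as text,
so a rerun with the same inputs and seed is byte-identical — verified by
hashing all outputs.

## Known limitations

- The phylogeny-weighted distance is this package's definition; numbers are
  comparable within analyses run by this package, not with external tools.
- PERMANOVA is one-way only; no covariates, strata or interactions.
- Exhaustive permutation enumeration supports two groups.
- The reporter score saturates when most KOs are differential (see above).
- Rank-level sharing treats taxonomy as given; no placement of
  recipient-only OTUs is attempted.
- KO relative abundances are not renormalized after occurrence filtering
  unless requested, since the correct basis is not decidable downstream.
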