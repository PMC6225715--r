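# fmtpipe

Cross-host microbiome analysis for fecal microbiota transplantation (FMT)
studies.

`fmtpipe` is a tidyverse-style R package for paired donor/recipient
microbiome studies in which stool from diseased and healthy donors of one
species (e.g. dairy cows with and without mastitis) is transplanted into
germ-free recipients of another (e.g. mice), and the question is how much of
the disease-associated community structure and function transfers, and
whether the disease-health distinction is *amplified* by the transplant.
Every user-facing function takes a data frame and returns a tibble, so whole
analyses chain with the pipe; fitted results have `tidy()`, `glance()` and
`autoplot()` methods.

## What it computes

Starting from OTU and KO (KEGG Orthology) abundance tables, sample metadata
(groups H = healthy, M = diseased, P = diseased + probiotic; hosts cow and
mouse), a rooted phylogeny and a KO-to-pathway map:

- **Alpha diversity** per sample: observed richness, Shannon H = −Σ pᵢ ln pᵢ,
  Gini–Simpson 1 − Σ pᵢ², bias-corrected Chao1 S_obs + F₁(F₁−1)/(2(F₂+1)).
- **Beta diversity**: a phylogeny-weighted similarity for OTU profiles — mass
  matched at leaves scores fully, mass matched at an ancestor of height *h*
  scores with weight w = max(0, 1 − h/H); on a star tree the distance reduces
  exactly to Bray–Curtis 1 − Σ min(aᵢ, bᵢ) — and cosine distance
  1 − a·b/(‖a‖‖b‖) for KO profiles.
- **Ordination and tests**: PCoA and PCA, one-way PERMANOVA
  (pseudo-F = [SS_B/(a−1)]/[SS_W/(N−a)] with permutation or exhaustive
  p-values), and Procrustes concordance of taxon- and function-based
  ordinations with a Monte-Carlo test.
- **Marker discovery**: per-feature Wilcoxon rank-sum tests (exact when
  n ≤ 12 without ties) with Benjamini–Hochberg control, direction and effect
  annotation, and named threshold profiles for OTU (q < 0.01), KO (p < 0.05)
  and network (q < 0.01) analyses.
- **Pathway enrichment**: reporter scores — per-KO z = Φ⁻¹(1 − p), pathway
  Z = Σz/√k, background-corrected against random same-size KO sets, detected
  at Z_adj > 1.6 — with the 10%-majority rule for calling a pathway up- or
  downregulated.
- **Taxon–function networks**: Spearman co-occurrence between differential
  OTUs and KOs (|ρ| > 0.8, BH q < 0.01), exported as edge TSV or GraphML.
- **Cross-host statistics**: donor-attributable fractions of the recipient
  community at OTU/genus/family rank, direction-concordant markers across
  hosts, and the amplification factor = mean between-group distance in the
  recipient divided by the same quantity in the donor.

A Dirichlet-multinomial study generator (`sim_config()`,
`generate_paired_study()`) plants differential OTUs, induced KO effects and
enriched pathways with known truth, so every stage is testable end to end.

## Worked example

```r
library(fmtpipe)

bundle <- generate_paired_study(sim_config(seed = 42))
bundle
#> # study_bundle: 150 OTUs, 300 KOs, 24 donor + 36 recipient samples,
#> #   30 planted OTUs, amplification 3

report <- run_full(bundle, "demo_out", seed = 42)
report
#> fmtpipe run report (version 0.1.0, seed 42)
#> PERMANOVA H vs M (donor):     OTU F = 68.054 (p = 0.001), KO F = 290.065 (p = 0.001)
#> PERMANOVA H vs M (recipient): OTU F = 1057.635 (p = 0.001), KO F = 2423.853 (p = 0.001)
#> markers: donor 38 OTU / 117 KO; recipient 147 OTU / 300 KO
#> enriched pathways: donor 4, recipient 0
#> network: 100 nodes, 394 edges
#> amplification fold: OTU 3.294 (0.0873 -> 0.2877), KO 2.702 (0.1933 -> 0.5224)
```

Reading the report: within the donor host the healthy and diseased
communities separate (PERMANOVA F = 68 on the phylogeny-weighted distances,
p at the permutation floor), and the separation is far stronger in the
recipients (F = 1058) — the planted 3-fold amplification is estimated at
3.29 for OTUs: the mean between-group distance grows from 0.087 (donor) to
0.288 (recipient). Marker discovery finds 38 donor OTU markers (30 planted),
and the four planted pathways are recovered in the donor comparison. Per
stage, the same numbers come from `pairwise_distances()`, `permanova()`,
`find_markers()`, `enrich()`, `build_network()` and
`amplification_factor()`, all of which return tibbles (or tidy-able
objects):

```r
alpha_diversity(bundle$donor_otu)
#> # A tibble: 24 × 5
#>   sample_id observed shannon simpson chao1
#>   <chr>        <int>   <dbl>   <dbl> <dbl>
#> 1 cow_H_1        150    4.56   0.985   150
#> 2 cow_H_2        149    4.60   0.986   149
#> 3 cow_H_3        150    4.58   0.986   150
#> # ...
```

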