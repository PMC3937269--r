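---
title: "pclnet: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pclnet: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`pclnet` chains five analyses that together connect transcriptional
responses of atherosclerotic lesions to plasma cholesterol lowering (PCL)
with inherited disease risk and with regulatory network structure. This
vignette documents the statistical models, the tunable parameters and their
defaults, what the synthetic-data generators do and do not emulate, and the
numerical decisions taken where the methodology left the design open.

## 1. Stage-specific gene sets

Two contrasts define the gene sets at each lesion stage (weeks 30, 40, 50 of
lesion progression): *PCL-responsive* (high-cholesterol controls vs mice
sacrificed immediately, about one week, after PCL — before any morphological
change, so expression shifts are primary responses, not composition
artefacts) and *regression-reactive* (immediately-after vs 10 weeks after
PCL, where composition change dominates).

Per gene we use the Welch unequal-variance statistic. The methodology we
follow does not name its test; Welch is the robust default for small,
possibly heteroscedastic groups (4–10 replicates per cell). Genes with zero
variance in both groups are tested against a variance floor (`1e-12` on the
squared standard error) and flagged; a zero difference with zero variance
reports statistic 0 and p 1.

Two FDR routes:

* **`bh`** — Benjamini–Hochberg over all genes (used for the knockdown
  screen, threshold 0.1, and 0.05 for the advanced-lesion screen, both
  config-exposed).
* **`efron_local`** (default for the lesion contrasts, threshold 0.30) — an
  empirical-null local fdr. Statistics are mapped to probit scores
  `z = qnorm(pt(t, df))`; the null is `N(δ̂, σ̂²)` with δ̂ the median and
  σ̂ = IQR/1.349 (central matching, valid while non-null genes stay below
  roughly a third of the genome and live in the tails); the mixture density
  f̂ comes from Lindsey's method — a Poisson GLM of counts in ~90 bins on a
  7-df natural spline; π̂₀ = min(1, f̂(δ̂)/f₀(δ̂)); membership where
  π̂₀ f₀(z)/f̂(z) < threshold.

**Numerical stabilisation of the local fdr.** In near-empty tail bins the
raw spline fit can overshoot on one or two stray null scores and produce
spuriously small fdr values. The density entering the ratio is therefore
penalised by its sampling uncertainty — the lower 2-SE bound of the GLM
prediction on the link scale. Genuine signal bumps carry tens of counts, so
the penalty is negligible there; on pure-null data it removes essentially
all false members. This is the package's own choice, made so that null
studies behave as a null should.

The FDR threshold of 0.30 is deliberately permissive: the gene sets feed
downstream enrichment and network analyses that average over many genes, so
sensitivity matters more than per-gene precision. Outlier samples are never
excluded automatically; a config list of excluded sample ids is honoured and
recorded on the result, because no automatic criterion was defensible.

## 2. Ortholog mapping and risk enrichment

Mouse gene sets map to human orthologs through a user-supplied two-column
table; 1:many and many:1 rows are honoured as-is and the output is
deduplicated, with unmapped genes counted.

Risk enrichment of a (human) gene set proceeds in four steps:

1. **cis-eSNPs** — additive dosage regression of expression on genotype for
   every SNP within ±1 Mb of the gene's TSS (inclusive, strand ignored),
   keeping pairs at BH FDR < 0.05 across all tested cis pairs. The FDR rule
   is config-exposed; the source methodology defers to an external eQTL
   study without stating a threshold, so we chose the field-standard 0.05.
2. **LD expansion** — add SNPs with dosage r² > 0.9 within 200 kb of a seed
   eSNP. r² is the squared Pearson correlation of dosages (composite LD):
   phase is not required and in-sample genotypes stand in for a reference
   panel. Expansion is idempotent.
3. **Matched null** — 5000 random SNP sets with exactly the observed per-
   chromosome counts, drawn without replacement from universe SNPs with
   MAF > 5%, excluding the observed SNPs themselves (so the null cannot
   contain the signal; the methodology is silent on this point). No finer
   position or MAF binning is applied because none is specified.
4. **Fold enrichment** — observed fraction of SNPs with GWAS P < 0.05 over
   the mean fraction across random sets. The empirical P uses the
   (r+1)/(n+1) estimator and can never be exactly 0; since 5000 resamples
   cannot reach P-values like 10⁻¹⁴, an optional Normal approximation to the
   null fraction distribution (`p_normal`) is reported alongside, clearly
   labelled approximate.

## 3. CLR TF-regulatory networks

Similarity is the absolute Pearson correlation — negative regulation is
still evidence of interaction, and CLR is built on undirected evidence. For
each pair (i, j), the similarity is standardised against each gene's own
similarity background (mean and SD of its matrix row, diagonal excluded),
clipped at zero, and combined as `z_ij = sqrt(z_i^2 + z_j^2)` — the
canonical CLR joint score. Rows with zero background SD contribute z = 0 and
are flagged; constant genes get similarity 0 to all partners.

Edge significance has two modes. The **analytic** default,
`edge_p = exp(-z²/2)`, is the Rayleigh tail of the joint of two standard
scores — parameter-free, monotone in z, and of the right order of magnitude
when inverted against the network-size thresholds the methodology prints.
The **permutation** mode pools joint scores across all gene pairs of
expression matrices whose samples are shuffled independently per gene, and
is the calibration ground truth in the test suite (the analytic mode is
checked to be monotone-consistent with it).

Candidate interactions are restricted to TF × gene pairs (TF list supplied
as an annotation file; TF–TF pairs counted once). The network retains
exactly `floor(0.5 × candidates)` edges with the smallest edge p — the 50%
most probable interactions — with boundary ties resolved deterministically
by (edge p, tf, partner) order. A keep-all-ties rule was rejected: clipping
at zero gives a majority of pairs an identical edge p of 1, so keeping ties
would degenerate to retaining everything. The largest retained p is reported
as the network's threshold. Hubs (candidate master regulators) are TFs
ranked by degree, ties broken lexicographically.

## 4. Perturbation validation

Affected genes after silencing a hub: Welch + BH over the fixed 673-gene
screen panel. Network specificity is the hypergeometric upper tail — when X
of M panel genes are affected, the probability that x or more fall in the
size-K stage network. We read the sampling population as the 673 panel
genes; the ambiguous "n" in the source description is not exposed — the
test is fully determined by (M, K, X, x). Percentages are reported as
`round(100·x/K)` with half-away-from-zero rounding, matching the printed
+12/−17 style (base R's banker's rounding would differ at .5 boundaries).

Cholesterol-ester accumulation: per replicate CE = (total − free
cholesterol)/protein; both arms scaled so the control mean is 100; percent
change = knockdown mean − 100, with a two-sided Welch p. Negative CE after
background subtraction is flagged but retained. Replicate counts in the
source assays are unstated; fixtures default to 6 per arm (config-exposed).
RT-PCR normalisation uses the comparative Ct closed form `2^(−ΔΔCt)`.

## 5. Phenotype metrics

Plaque stability = (SM22α + collagen)/(CD68 + Oil-Red-O) stained-area
percentages, divided by each mouse's lesion burden so stability is assessed
per mouse rather than per plaque. A zero denominator (no CD68, no
Oil-Red-O staining) leaves the score undefined: the mouse is flagged and
excluded from group summaries with a log message, rather than inventing a
value. Missing histology cells are imputed by the group mean of observed
values — this deliberately replaces the original multiple-imputation
procedure, whose settings are unrecoverable; group-mean imputation is
transparent, leaves group means unchanged, and every imputed cell is
logged. A seeded stochastic mode (draws from the group's fitted Normal) is
available where imputation variance matters. Group comparisons are
two-sided Welch t tests. `percent_change` returns full precision with a
one-decimal reporting default; fold changes should always be computed from
unrounded values (ratios of rounded endpoints are visibly inconsistent).

## 6. What the generators emulate — and what they do not

The synthetic-data module generates every input with known planted truth:

* **Timecourse arrays** — 21,000 genes (the gene-level content of the array
  platform), Gaussian log2 noise, defaults of 6/6/10 replicates per
  control/immediately-after/10-weeks cell and planted set sizes
  238/1306/2231 (PCL-responsive) and 42/1556/6273 (regression-reactive) per
  stage — the study's reported gene counts. Planted PCL shifts persist at 10
  weeks so the two contrasts carry disjoint truth. Planted effects default
  to |log2 fc| = 2 against replicate noise SD 0.25 — strong, clearly
  detectable responses; at substantially weaker settings the *true*
  local-fdr decision boundary itself leaves much of the planted set
  uncalled, so recovery benchmarks would measure the irreducible boundary,
  not the implementation.
* **Macrophage co-expression panel** — 38 profiles; planted TF→target edges
  with β = 1 and residual SD 0.5; non-targets independent standard
  Gaussians.
* **Genotypes/GWAS** — dosages from two Bernoulli(MAF) haplotypes; LD blocks
  copy the block seed's haplotype allele with probability √r² (else redraw
  at the seed's MAF), hitting the target r² in expectation with no external
  haplotype reference; planted cis effects are linear in dosage; GWAS
  P-values are Uniform(0,1) except planted SNPs, which fall below 0.05 with
  probability `p_hit` — the downstream fold statistic only ever sees the
  hit indicator, so planting the hit rate (0.10 vs the 0.05 background for a
  2-fold signal) is exactly sufficient.
* **Screens and histology** — knockdown reduces the target by a planted
  fraction on the linear scale; CE readouts are Normal(100(1+shift), 10);
  histology draws per-mouse stain percentages around group means (the
  pipeline's default means follow the printed stain and burden values) with
  16% of cells deleted completely at random, the study's missingness rate.

Not emulated: probe/CEL-level array structure, realistic haplotype
structure or case/control genotypes, siRNA off-target effects, image-level
histology. Passing tests therefore demonstrate that the *statistical chain*
behaves correctly under its stated model — not that it is robust to
platform-specific artefacts of real arrays or real LD.

## 7. Problem sizes and reproducibility

The test suite and the acceptance script size their simulations to run in
minutes on one CPU: null calibrations use 100 reseeded studies of 10,000
genes; recovery benchmarks use the full 21,000-gene universe at the
early-lesion planted size over a few seeds, 20 seeds for CLR edge recovery,
and 25 reseeded GWAS draws for the planted 2-fold enrichment; end-to-end
pipeline statistics average six reseeded runs with 500 matched sets each
(the pipeline default is 5000). These sizes are the package's own choice of
Monte-Carlo effort.

Every stochastic stage derives its own seed from the global seed and the
stage name (`derive_seed`), and `run_pipeline` writes a manifest (config,
stage seeds, per-file MD5 checksums, package version, no timestamps) so a
fixed configuration reproduces every output byte for byte.

## 8. Known limitations

* The analytic edge P is a convenient closed form, not a calibrated null
  probability; calibrated inference should use the permutation mode.
* The empirical-null fit assumes the non-null fraction is modest (≲ 30%)
  and tail-concentrated; at the advanced-lesion regression-reactive size
  (~30% of the genome) central matching becomes conservative.
* Fold-enrichment significance beyond the resampling resolution relies on a
  Normal tail approximation that is reported but labelled approximate.
* The matched null matches chromosome counts and filters MAF > 5% only; it
  does not match local LD structure or gene density, exactly as specified —
  enrichment estimates inherit that null's coarseness.
* Group-mean imputation understates between-imputation variance relative to
  multiple imputation; the stochastic mode recovers spread but not MI's
  proper uncertainty propagation.
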