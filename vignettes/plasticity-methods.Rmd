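---
title: "Methods: classifying adaptive and maladaptive expression plasticity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying adaptive and maladaptive expression plasticity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adaplast)
```

## The question and the design

When a population evolves under a stressor, does the *plastic* response —
the expression change any individual mounts when exposed — point in the
same direction as the *evolved* response, the expression difference that
selection produced? If it does, plasticity is read as adaptive: the
immediate physiological response anticipates the direction evolution
eventually takes. If the two point in opposite directions, plasticity is
maladaptive.

adaplast operationalizes this for a two-line (control vs
resistance-selected), two-treatment (unsprayed vs herbicide-sprayed),
two-timepoint (8 and 32 hours post-application) bulk RNA-seq design. Two
contrasts carry the inference:

* **plastic**: sprayed vs unsprayed within the *control* lines (using
  control lines avoids reading the selected lines' altered plasticity as
  the ancestral plastic response);
* **evolved**: resistant vs control lines in the *unsprayed* environment.
  Measuring the selection response in the spray environment would mix the
  evolved difference with line-specific plasticity, which is why
  `classify_genes()` refuses the sprayed evolved contrast unless
  explicitly overridden.

Genes significant in both contrasts (BH FDR < α, default α = 0.1) are
classified by sign concordance; an exact binomial test against a 50:50
split asks whether adaptive plasticity predominates. Two companion
analyses complete the picture: per-timepoint plastic contrasts are
correlated to justify pooling, and the plastic contrast is re-estimated
within the resistant lines to ask whether selection amplified plasticity
(`plasticity_amplification()`: the fraction of genes with a strictly
larger |log2 FC| in the resistant lines; ties deliberately count as "not
greater", which is conservative for any majority claim).

## The expression model

The differential-expression machinery is the familiar
normalize–transform–moderate chain for bulk counts, implemented in the
package and cross-checked in the tests against independent
implementations:

1. **Filtering.** A gene is kept if its CPM reaches `cpm_min` (default
   10) in at least k samples, k being the smallest design-cell size. The
   boundary is inclusive and the filter is idempotent; filtered matrices
   keep their pre-filter library sizes so CPM values are unchanged.
2. **TMM normalization.** Scaling factors are trimmed, precision-weighted
   means of gene-wise log-ratios against a reference sample (the one
   whose 75th-percentile CPM is closest to the mean of those
   percentiles). 30% tails of the log-ratios and 5% tails of the
   log-abundances are trimmed; weights are the reciprocal of the
   delta-method variance of each log-ratio; factors are rescaled to unit
   geometric mean. Ties in the trim ranks are broken by gene order, and a
   tie in reference selection goes to the lower sample index — both are
   arbitrary choices pinned for determinism.
3. **Precision weights.** log2-CPM is computed with a 0.5 prior count
   over effective library sizes offset by one. A per-gene OLS fit on the
   group-means design gives residual standard deviations whose square
   roots are smoothed against mean log2 count by `lowess` (span 0.5, two
   robustness iterations — one fewer than some implementations use; the
   difference is at the third decimal of the weights). Each observation's
   weight is the trend value at its fitted log2 count to the power −4,
   so weights come from the trend, never from the gene's own variance.
   The trend is extrapolated flat beyond the fitted range.
4. **Moderation.** Gene-wise weighted least squares yields a contrast
   estimate, its unscaled variance and a residual variance s². The
   variances are shrunk toward a scaled inverse-χ² prior whose
   parameters (d₀, s₀²) are estimated by moment matching on log s² —
   the trigamma inverse is solved by a monotone Newton iteration, and a
   non-positive excess variance sends d₀ to +∞ (pure shrinkage to the
   prior, normal-reference p-values). Moderated t-statistics use
   d₀ + d degrees of freedom; tests are two-sided throughout.
5. **FDR.** Benjamini–Hochberg step-up within each contrast separately,
   because the downstream counts of significant genes are reported per
   comparison.

The design matrix is parameterized by cell means (one coefficient per
occupied line × treatment × timepoint cell); "pooled" contrasts average
the two timepoint cells on each side. This is the least-assumption
reading of a pooled analysis: it needs no homogeneity assumption across
timepoints and keeps the per-timepoint contrasts consistent with the
pooled one. No family, block, or selfed/outcrossed structure is
modelled — the design sheet carries only the three crossed factors, so
any pedigree-induced correlation is absorbed into the residual.

## The binomial concordance test

`exact_binomial_two_sided(k, n, p0)` sums the probabilities of all
outcomes whose point probability does not exceed the observed one (the
minimum-likelihood convention, equal to doubling the smaller tail at
p0 = 0.5). It is evaluated in log space so that n up to ~10⁶ is safe.
With the adaptive/maladaptive splits 68/94, 44/56 and 44/71 it returns
1.7 × 10⁻⁵, 2 × 10⁻⁵ and 0.057 — the worked examples in the acceptance
script. Genes whose doubly significant log2 FC is exactly zero have no
sign and are excluded from n with a warning; with continuous estimates
this is a measure-zero event.

## What the simulator emulates — and what it does not

`simulate_experiment()` generates the full factorial design with
negative-binomial counts, mean
μ\_gi = 2^(b\_g + xᵢᵀβ\_g) · Lᵢ/10⁶ and variance μ + φμ². Its defaults
are the validation conditions of the package and were fixed once:

* **8 samples per cell** (64 total) — the study scale this design
  mirrors had 7–8 replicates per line × treatment × timepoint cell; an
  unbalanced per-cell override reproduces splits like 8/7.
* **Library sizes** log-normal around 28 million reads (typical bulk
  depth for this kind of experiment), σ = 0.25 on the natural-log scale.
* **Baselines** N(5, 2²) on the log2-CPM scale, then shifted so the
  unsprayed-control profile sums to exactly 10⁶ CPM — without that
  closure constraint "log2 CPM" would be nominal, and the stored
  baseline could not be compared to realized CPM.
* **Dispersion trend** φ\_g = 0.05 + 3/μ\_g: an asymptotic biological CV
  of ~0.22 with the usual low-count inflation.
* **Effects**: |log2 FC| ~ |N(1, 0.5)| with symmetric random signs —
  moderate, roughly two-fold responses, with enough mass near the
  detection boundary that power differences between lines are visible.
  10% of genes are plastic-only, 3% evolved-only, 5% carry both effects,
  and a doubly affected gene is sign-concordant with probability 0.72.
* **Amplification** 1.5: the plastic effect of resistant lines is 1.5×
  the control-line effect, which under these defaults puts the share of
  genes with a larger herbicide response in resistant lines near 59%.
* Plastic effects are identical at both timepoints (the two-timepoint
  correlation observed in data of this kind is high, and the
  per-timepoint contrasts exist to verify exactly that); no per-timepoint
  decorrelation is simulated.

Deliberately *not* emulated: read-level artefacts (GC/length bias,
mapping error), pedigree/block structure, correlated expression between
genes, and outlier samples. Passing the end-to-end tests therefore shows
that the estimators recover the generating model's truth — it does not
certify behaviour under violations of that model (e.g. trans-regulatory
correlation would make the binomial test's independence assumption
optimistic).

One consequence of the composition closure is worth knowing: planted
effects change the sprayed/resistant column totals, so raw CPM ratios
are biased by composition exactly as in real data. That bias is what TMM
removes, and the simulator-recovery tests use TMM-normalized CPM for
that reason.

## Numerical choices and degenerate inputs

* Counts are stored as doubles (integrality enforced on input) so
  library sizes beyond 2³¹ cannot overflow.
* `tmm_factors` errors when a sample shares no nonzero gene with the
  reference, and returns factor 1 for a sample whose log-ratios are all
  below 10⁻⁶ in magnitude.
* `voom_weights` errors when residual df ≤ 0 and when the fitted trend
  dips non-positive; a gene with zero residual variance still receives a
  finite weight through the trend.
* `ebayes_moderate` requires ≥ 10 genes with positive s²; an all-zero
  variance landscape is an explicit error.
* `concordance_test` with no doubly significant genes reports an
  undefined (NA) p-value rather than 1.0 — "no evidence" is not "perfect
  balance".
* Simulation, and hence the pipeline, is bit-reproducible for a fixed
  seed; the generator pins the RNG kind and restores the caller's RNG
  state.

## Problem sizes used in validation

The shipped tests and the acceptance script run entirely on simulated
data at desk scale: 5,000 genes × 64 samples for the end-to-end
recovery, amplification and calibration batches (20 seeds in the test
suite, 5 in the script), 2,000 genes for null calibration, 50,000
gene variances for prior recovery, and ≤ 20-gene fixtures for the
brute-force oracle comparisons. These sizes give sampling errors
comfortably inside the asserted tolerances while keeping a full run in
the order of a minute.

## Known limitations

* The moderated model has no robust option: a heavy-tailed variance
  landscape will drag d₀ down rather than down-weight outlier genes.
* FDR is controlled within contrast; nothing corrects across the family
  of contrasts.
* The enrichment helper tests one term at a time against a fixed
  background; annotation redundancy (nested terms) is not modelled.
* The classifier is a hard threshold at α on both FDRs; genes just
  outside either threshold vanish from the concordance test rather than
  contributing with reduced weight.
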