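---
title: "Methods: eRNA origins, motif displacement, and pseudo-bulk contrasts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: eRNA origins, motif displacement, and pseudo-bulk contrasts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ernamd)
```

# Scope and model

`ernamd` implements the computational core of a regulatory-genomics
analysis of bidirectionally transcribed enhancers, of the kind used to
characterize the *MUC5B* −3 kb enhancer harboring the IPF risk variant
rs35705950. Active enhancers produce short divergent enhancer RNAs
(eRNAs); the center of the divergent signature marks the RNA polymerase II
loading site ("origin"). Around these origins the package quantifies
transcription-factor motif co-localization (motif displacement, MD),
compares conditions, and complements the sequence-level analysis with
nucleosome-protection profiling and single-nucleus accessibility and
expression contrasts. Every stage can be driven by the synthetic-data
module, which plants a known truth so recovery can be measured.

Upstream steps that mature pipelines already provide — read trimming and
alignment, probabilistic transcription-unit callers, single-cell
clustering and label transfer — are out of scope; the package consumes
coverage tracks, motif models, and labeled per-nucleus count tables.

# PWM scanning with exact threshold calibration

Motifs are position weight matrices scored as log~2~ likelihood ratios
against an i.i.d. background (bits). A pseudocount mixes each row with the
background, `(p + c·bg) / (1 + c)`, so zero probabilities disappear for
`c > 0`.

The score threshold for a target p-value is obtained from the *exact*
null distribution of window scores under the background model, computed by
dynamic programming after discretizing per-position scores to bins of
**0.01 bits** (a documented constant). The threshold is the smallest score
whose null exceedance probability is at most the target (default
`1e-5`). Two numerical consequences are worth knowing:

* the threshold is resolved only to the bin width — per window the worst
  case is `L × 0.01` bits, far below the score spacing of short motifs;
  because the null tail is a step function over the finitely many
  achievable scores, any threshold between two adjacent achievable scores
  selects the same hit set;
* the smallest attainable p-value is `4^-L` under a uniform background, so
  a motif shorter than 9 bp cannot reach a `1e-5` cutoff; in that case the
  maximum score is returned with a warning.

Scanning reports every window on both strands meeting the threshold, in
forward BED coordinates (0-based, half-open). Windows containing `N` are
skipped rather than scored against the background — the usual scanner
behavior, which avoids inventing scores. Overlapping hits are all
reported; instance-level de-duplication is the MD stage's concern. The
motif "position" used downstream is the integer midpoint
`floor((start + end) / 2)`.

# Calling eRNA origins

The published mixture-model callers are deliberately replaced by a
deterministic rule, because the MD analysis needs only origin points:

1. smooth each strand with a centered moving sum of halfwidth 30 bp;
2. locate strand-local maxima with smoothed mass ≥ 20 reads (a maximal
   plateau collapses to its center; a smoothed point source is a plateau
   whose center is the source);
3. pair each minus-strand maximum with the nearest downstream plus-strand
   maximum within 300 bp, one-to-one greedily by descending total mass;
4. place the origin at the rounded mass-weighted mean of the two peaks;
5. merge origins closer than 150 bp, keeping the higher total mass, ties
   toward the smaller coordinate.

All four parameters are exposed and overridable. On synthetic divergent
coverage with ≥ 200 reads per origin and no noise the caller recovers
every planted origin within a few bp (the acceptance suite demands
± 25 bp with zero spurious calls). The integer floors used for plateau
centers and weighted means leave up to ~2 bp of rounding slack under
coordinate reflection; translation equivariance is exact.

# Motif displacement

For one motif, each instance midpoint is assigned to its nearest origin
(ties toward the smaller origin coordinate) and contributes at most once —
nearest-assignment avoids double counting when origins cluster, a policy
the original description leaves open. With signed distance `d = midpoint −
origin`, `h = #{|d| ≤ 150}`, `H = #{|d| ≤ 1500}` and `MD = h / H`. Radii
are inclusive ("within a radius") and strand is ignored, matching
position-resolved barcode plots. Under uniform placement `MD → r/R = 0.1`.
Motifs with `H = 0` have undefined MD and are excluded from testing.

Conditions are compared per motif with a two-proportion z-test on pooled
variance:

$$z = \frac{MD_a - MD_b}{\sqrt{\hat p (1-\hat p)(1/H_a + 1/H_b)}},
\qquad \hat p = \frac{h_a + h_b}{H_a + H_b},$$

two-sided normal p-value, significance at the conventional MD threshold
`alpha = 1e-4` with no further multiple-testing correction. Degenerate
pooled proportions (0 or 1) are flagged and reported as `p = 1`. Barcode
matrices histogram the signed distances over ±1500 bp into an even number
of equal bins (so 0 sits on a bin edge; bins are `[lo, hi)` with the last
closed).

# Single-nucleus pseudo-bulk contrasts

The per-nucleus table carries sample, disease group, genotype, cell type,
total counts (depth), and per-feature counts. The exact regression design
behind published per-nucleus fold changes is rarely printed; this package
fixes the minimal models consistent with "logistic regression" and
"negative binomial regression" on such data:

* **Accessibility**: response `indicator(count > 0)`, model
  `logit(P) = β0 + β1·group + β2·log(depth)`, p-value from the likelihood
  ratio test of `β1 = 0`. The headline fold change is the ratio of
  depth-normalized group mean counts (per 10^4^ total counts) — a
  logistic coefficient is an odds ratio, not a count ratio; `exp(β1)` is
  reported alongside. A pseudo-offset of 1 count per 10^4^ is applied only
  when a group mean is zero, with a degenerate flag. Complete separation
  falls back to a two-sided Fisher exact test on the 2×2 table (flagged;
  penalized-likelihood fits would also serve but the exact test needs no
  additional machinery).
* **Expression**: `count ~ group + offset(log(depth))` with NB likelihood
  and ML dispersion (`MASS::glm.nb`), LRT p-value, fold change
  `exp(β_group)`; nonconvergence falls back to Poisson with a flag.
* **Bonferroni**: `p_adj = min(1, p × n_tests)`, where `n_tests` is the
  number of contrasts the run actually performed (logged explicitly).

Group reference levels are fixed (control before IPF, GG before TT;
anything else in byte order) so the contrast direction never depends on
the session locale.

# MNase protection

Tiled qPCR Ct values are converted with the standard efficiency-2
ΔΔCt model: per replicate, `ΔCt = Ct_digested − Ct_undigested` and
`protection = 2^−(ΔCt − ΔCt_ref)` relative to a configurable reference
amplicon (the source analyses cite prior work without printing a formula;
this is the canonical choice). Protection at the reference is exactly 1;
a common additive Ct shift cancels. Replicates are summarized as mean ±
SD ordered by amplicon midpoint; amplicons missing from some replicate
are flagged, never silently dropped.

# Synthetic data: what it emulates, and what it does not

The generator encodes the statistical structure the analyses assume:

* i.i.d. genome with controlled GC; origins uniform with a minimum
  spacing; motif instances either uniform or planted within ±150 bp of an
  origin (the co-localization signal MD measures), overwriting bases so
  coordinates stay stable;
* divergent coverage with geometric origin-to-read offsets (support 1, 2,
  …; the simplest one-parameter discrete heavy tail — the empirical
  offset distribution of nascent-transcription data is not published, so
  this is a stand-in, not inferred intent) plus uniform noise reads;
* per-nucleus depth lognormal(log 5000, 0.5) — a realistic single-nucleus
  depth scale; accessibility Bernoulli with logit linear in group and
  centered log-depth (coefficient 0.5), calibrated so the rate ratio at
  mean depth equals the configured fold change; expression NB with mean
  proportional to depth and dispersion 0.5;
* tiled Ct values from the ΔΔCt model in reverse, with Gaussian noise.

Defaults mirror the study conditions the package is benchmarked against:
3000 nuclei per group, accessibility ratio 1.52 and expression ratio 1.91
(the disease contrasts reported for epithelial accessibility and
secretory-cell expression), baseline accessibility 0.2, 5 UMI baseline
expression. What passing recovery tests therefore show is that the
*estimators* are calibrated and powered under the assumed models — not
that real chromatin data meet those assumptions: real coverage has
non-geometric offset tails and position-dependent mappability, real
nuclei have batch and cell-type structure, and real motif instances
cluster with GC content. Fragment-level FASTQ simulation, aligners, and
tabix fragment files are intentionally not emulated.

# Problem sizes and determinism

Every generator draws from `config$seed` plus a fixed per-operation
offset, so a pipeline run is byte-deterministic and operations do not
share RNG streams. The test and acceptance workloads use moderate sizes
chosen to make the statistical bounds sharp: 4 × 10^5^ placements for the
MD null (H ≈ 1.2 × 10^5^), 1000 null pairs for type-I calibration, 100
seeds for MD recovery power, 20 seeds × 10 origins for caller recovery,
50 seeds × 6000 nuclei for the regression contrasts. The demo pipeline
(`run_demo()`) uses a 200 kb genome and writes a checksum manifest so two
runs from one config can be compared byte for byte.

# Known limitations

* The origin caller is a point estimator; it does not model elongation,
  pausing, or overlapping transcription units, and very asymmetric
  divergent loading shifts the mass-weighted origin toward the heavier
  strand by design.
* MD uses nearest-origin assignment; in dense origin clusters (< 3 kb
  apart) instance-to-origin attribution is ambiguous and window overlap
  makes the uniform-null value slightly geometry-dependent.
* The two-proportion z-test is asymptotic; with `H` below a few hundred
  the stated alpha is only approximate (the calibration tests quantify
  this at H = 1000).
* The logistic model's binarized response discards fragment multiplicity;
  regions with high per-nucleus fragment counts would warrant a count
  model instead.
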