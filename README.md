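# ernamd

Tools for regulatory-genomics analysis of bidirectionally transcribed
enhancers: eRNA origin detection, motif displacement (MD) scoring, and
pseudo-bulk single-nucleus contrasts, with a synthetic-data module that
makes the whole pipeline testable against known ground truth.

## The problem

Active enhancers produce short divergent enhancer RNAs (eRNAs); the center
of the divergent signature in strand-specific nascent-transcription
coverage marks the RNA polymerase II loading site — the eRNA **origin**.
Analyses of enhancers such as the *MUC5B* −3 kb region (which harbors the
idiopathic pulmonary fibrosis risk variant rs35705950) hinge on a few
recurring computations:

* **Origin calling** — find divergent minus/plus peak pairs in
  strand-specific coverage and place the origin at their mass-weighted
  center.
* **Motif scanning** — locate transcription-factor motif instances
  genome-wide with a PWM scanner whose score cutoff is calibrated to an
  exact null p-value (default `1e-5`) by dynamic programming over the
  background score distribution.
* **Motif displacement** — for each motif, the proportion of instances
  within 150 bp of the nearest origin among those within 1500 bp:

  `MD = h / H`, `h = #{|d| ≤ 150}`, `H = #{|d| ≤ 1500}`, `d = midpoint − origin`.

  Conditions are compared per motif with a two-proportion z-test on the
  pooled proportion, significance at `p ≤ 1e-4`.
* **Single-nucleus contrasts** — pseudo-bulk, per-nucleus comparisons of
  locus accessibility (logistic regression on the any-fragment indicator
  with a log-depth covariate) and gene expression (negative binomial
  regression with a log-depth offset) across disease groups or genotypes,
  with likelihood-ratio p-values and Bonferroni adjustment.
* **MNase protection** — tiled qPCR Ct tables converted to relative
  nucleosome protection via the ΔΔCt model,
  `protection = 2^−(ΔCt − ΔCt_ref)`.

The methods vignette (`vignettes/motif-displacement-methods.Rmd`)
documents every model, parameter, and numerical choice.

## Worked example

`run_demo()` exercises every stage on one seeded synthetic dataset:
a genome with planted origins and motif instances, divergent coverage,
scanning at the calibrated threshold, origin calling, MD with a matched
null comparison, single-nucleus contrasts, and an MNase profile. All
outputs land in one directory with an MD5 manifest.

```r
library(ernamd)
out <- run_demo(pipeline_config(seed = 42,
  simulation = list(genome_length = 60000, n_origins = 8,
                    n_motif_instances = 120, reads_per_origin = 200),
  nuclei = list(n_nuclei_per_group = 1000)), "demo_out")

head(out$results$origins, 3)
#>   chrom origin minus_peak plus_peak minus_mass plus_mass
#> 6  chrS   2378       2347      2412         61        57
#> 4  chrS  15282      15250     15313         65        65
#> 7  chrS  24915      24884     24950         62        55

out$results$md$md
#>     motif_id  h   H        md   r    R
#> 1 TGACGTCATC 85 120 0.7083333 150 1500

print(out$results$diff_md, digits = 3)
#>     motif_id  md_a  md_b h_a H_a h_b H_b    z        p significant degenerate
#> 1 TGACGTCATC 0.708 0.104  85 120   5  48 7.09 1.31e-12        TRUE      FALSE

print(out$results$sn[c("feature", "fold_change", "p_adj")], digits = 3)
#>              feature fold_change    p_adj
#> 1 enhancer_fragments        1.34 2.67e-04
#> 2          gene_umis        1.62 1.33e-13
```

Reading the output: the caller recovered the 8 planted origins (three
shown) with divergent peaks ~60 bp apart, as the geometric offset model
implies. Half of the 120 planted motif instances were placed within
150 bp of an origin, so the motif's MD score (0.71) towers over the
matched uniform-placement null (0.10) and the two-proportion z-test is
decisive (z = 7.1, p ≪ 1e-4). The single-nucleus contrasts estimate the
planted accessibility and expression fold changes (truth 1.52 and 1.91)
with the sampling noise expected at this demo size of 1000 nuclei per
group; both are significant after Bonferroni adjustment. The MNase stage
(not shown) returns the planted protection profile with protection 1 at
the reference amplicon.

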