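# morphoerr

Observer-error analysis for linear and outline morphometrics.

When several observers measure and photograph identical replicas of the
same artefacts — the standard design for quantifying inter-observer
error before pooling multi-site datasets — the resulting data mix
genuine variation among the objects with systematic and random
differences between the observers. `morphoerr` quantifies that mix for
archaeologists and morphometricians, on both sides of a replica study:

* **Linear measurements** (calliper data): technical error of
  measurement

  $$TEM = \sqrt{\frac{\sum_i\left(\sum_j M_{ij}^2 - (\sum_j M_{ij})^2/K\right)}{N(K-1)}},
  \qquad \%TEM = 100\,\frac{TEM}{\bar v},$$

  the pairwise coefficient of reliability
  $R = \sigma_v^2/(\sigma_v^2+\sigma_d^2)$, intraclass correlation
  coefficients from two-way ANOVA mean squares (absolute-agreement and
  consistency, single rater), Welch *t*, two-sided variance-ratio *F*
  and Tukey HSD comparisons — all usable from raw data *or* from
  published summary tables.

* **2D outline shape**: silhouette binarization and sub-pixel contour
  extraction, equidistant resampling, centroid/size/long-axis
  normalization, elliptic Fourier analysis with harmonic selection at
  99% cumulative power, PCA on the coefficients, equal-prior linear
  discriminant classification of tools vs observers, and the same
  ICC/R error statistics applied to PC scores.

* **A synthetic assemblage generator** with known ground truth:
  distinct point-like tool archetypes; observer-level scale and shear
  distortion (a parallax surrogate); smoothed outline digitization
  noise; per-observer measurement bias and 0.1 mm calliper rounding.
  Every stage of the pipeline is testable without any external data.

## Worked example

Recompute the headline error statistics of a published six-observer
replica study from its bundled cell summaries (no raw data needed):

```r
library(morphoerr)
s <- replica_summary_stats()
multi <- s[s$group == "multiple-observer", ]
tem <- tem_from_sds(multi$sd)
round(c(TEM = tem, pct_TEM = compute_percent_tem(tem, mean(multi$m))), 3)
#>     TEM pct_TEM
#>   0.368   0.909
```

A TEM of 0.368 mm, under 1% of the grand mean, says that between-observer
disagreement is far smaller than the variation among the tools.

Run the full pipeline on a simulated six-tool, six-observer assemblage
with the default error structure:

```r
cfg <- run_config(mode = "synthetic", seed = 42, n_points = 300, h_max = 16)
rep <- run_error_analysis(cfg)

rep$outlines$h_selected                       # harmonics at 99% power: 4
round(100 * rep$outlines$variance_fraction[1], 1)   # PC1 variance: 52.6 %
rep$outlines$lda_tools$accuracy               # tool LDA accuracy: 1
rep$outlines$lda_observers$accuracy           # observer LDA accuracy: 0
round(rep$outlines$pc_error$icc_pooled$estimate, 3) # shape ICC: 0.992
round(rep$measurements$tem$tem, 3)            # measurement TEM: 0.273 mm
round(rep$measurements$icc_agreement$estimate, 4)   # measurement ICC: 0.9999
```

Tools classify perfectly from outline shape while observers classify at
chance, and both ICCs are near 1: the configured observer error is
small relative to the differences between tools — the signature of an
assemblage safe to pool. `write_error_report(rep, "report.json")`
serializes the full report with provenance (config, seed, version).

The same analysis runs on real data: `mode = "images"` with a CSV
manifest (`path, image_id, tool_id, observer_id, px_per_cm`) of
silhouette photographs, or `mode = "tps"` with outline coordinates in
TPS format, plus a long-format measurement CSV
(`tool_id, observer_id, replicate_id, dimension, value_mm`).

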