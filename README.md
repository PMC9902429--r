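# regiomet

Regional differential-abundance analysis for spatial tissue metabolomics.

`regiomet` implements a complete, tested pipeline for untargeted metabolomics
studies that sample a tissue at several anatomical locations and ask which
metabolites and biochemical pathways distinguish them. Its motivating design
is a primate retina study: full-thickness punches from three eccentricities
(macula, temporal peri-macula, periphery), both eyes of a handful of
subjects, raw mass-spectrometry peak areas with substantial — partly
left-censored — missingness, and external case/control serum studies of
macular diseases to map the tissue results onto.

The pipeline covers:

1. **Preprocessing** — natural-log transform, per-(region, batch) median
   normalization (subtraction of the group median log abundance), an
   inclusive ≥ 80 % missingness filter plus a zero-variance filter, quantile
   normalization across samples after imputation, and PCA-based sample QC
   with macula-marker control metabolites (e.g. the xanthophyll pigments
   lutein/zeaxanthin).
2. **Missingness mechanism classification** — for each incomplete metabolite
   *i*, the two most correlated auxiliary metabolites (pairwise-complete
   Pearson, ≥ 3 joint observations) are tested with one-sided Welch
   *t*-tests: if either auxiliary is significantly *lower* where *i* is
   missing, *i* is labelled MNAR (left-censored), otherwise MAR; metabolites
   with ≤ 2 missing values or no usable auxiliaries are untestable and
   treated as MAR.
3. **Mechanism-aware imputation** — MAR metabolites: iterative
   random-forest (missForest-style) conditional imputation; MNAR
   metabolites: a Gibbs sampler drawing the censored cells from a
   truncated Gaussian below the metabolite's observed minimum, conditioned
   on a linear model in the two auxiliaries. Observed cells are never
   modified.
4. **Moderated differential abundance** — per metabolite, generalized least
   squares of standardized log abundance on region + age + sex + batch under
   a compound-symmetry within-subject covariance with a single *consensus*
   correlation (hyperbolic tangent of the trimmed mean of per-metabolite
   atanh correlations); residual variances are shrunk by empirical Bayes
   (scaled-inverse-chi-square prior fitted by digamma/trigamma moment
   matching), giving moderated *t*-statistics

   t̃ = ĉ'β / (s̃ · se(ĉ'β)),  s̃² = (d₀s₀² + d s²)/(d₀ + d),

   for the three contrasts macula−temporal, temporal−periphery,
   macula−periphery, with Benjamini–Hochberg FDR within each contrast.
5. **Pathway enrichment** — self-contained rotation tests on the moderated
   statistics (mean *t* for directional, mean *t*² for mixed-directionality
   enrichment; the null preserves inter-metabolite correlation), plus an
   "eigen-metabolite" summary of each pathway (first principal component of
   its members) tested through the same regional model.
6. **Spatial pattern clusters** — each metabolite's significance/direction
   signature over the three contrasts is mapped by a rule table to one of
   ten named spatial patterns (steep/shallow enrichment or depletion,
   macula/temporal/periphery enriched or depleted) or left unclassified.
7. **Disease overlap** — pathway members are stratified by their
   macula-vs-periphery status (enriched / not differentiated / depleted) and
   each stratum is tested for a coordinated shift in an external
   case/control serum summary table (rotation null when the serum model is
   available, statistic-resampling fallback for summary-only input).

Because the motivating data are not publicly deposited, the package ships a
first-class synthetic-data generator (`generate_study()`,
`apply_missingness()`, `generate_serum_study()`) that reproduces the study
design — 6 subjects (3 F / 3 M, ages ≈ 2.1 y), both eyes for all but one
subject, 3 regions × 3 preparation batches = 33 samples, 371 metabolites in
34 families, ≈ 26 % missingness rising from macula to periphery, left-censored
MNAR plus random MAR cells — together with the ground truth needed for
parameter-recovery tests.

## Worked example

```r
library(regiomet)

cfg  <- generator_config(seed = 3)
study <- apply_missingness(generate_study(cfg), cfg)
print(study$abundance)
#> abundance_matrix: 371 metabolites x 33 samples [scale=raw]
#>   missing cells: 3256 (26.6%)

run <- run_region_pipeline(study$abundance, study$samples, study$annotation,
                           config = run_config(seed = 3))
print(run$report)
#> missingness_report: 371 incomplete metabolites (MAR 297, MNAR 73, untestable 1)
print(summary(run$fit))
#> abundance_fit: 371 metabolites, 33 samples, 7 coefficients
#>   within-block correlation: 0.420 (consensus estimate)
#>   residual df: 26; prior df d0: 11.07; prior variance s0^2: 0.7179
#>   significant metabolites at FDR < 0.05:
#>     macula_vs_periphery    136
#>     macula_vs_temporal     157
#>     temporal_vs_periphery  128
head(run$patterns, 4)
#>   metabolite_id mvt tvp mvp         cluster
#> 1          M001   +   0   + macula_enriched
#> 2          M002   +   0   + macula_enriched
#> 3          M003   0   0   0    unclassified
#> 4          M004   0   0   0    unclassified
```

The consensus correlation is the estimated within-subject (between-eye)
correlation of log abundances; the per-contrast counts are metabolites whose
BH-adjusted p-value falls below 5 %; the pattern table assigns each
metabolite a spatial abundance profile (the two control metabolites, which
carry a planted macula-only enrichment, come out `macula_enriched`).

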