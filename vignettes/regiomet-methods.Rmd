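---
title: "Methods: regional metabolomics differential abundance in regiomet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regional metabolomics differential abundance in regiomet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`regiomet` analyses region-resolved tissue metabolomics: a matrix of raw
mass-spectrometry peak areas (metabolites × samples), sample metadata
(subject, eye, region, sex, age, preparation batch), a pathway annotation,
and optionally external case/control serum summary statistics. This
vignette is the package's account of its statistical machinery: the models,
their assumptions, the tunable constants and why they have the values they
have, what the synthetic-data generator does and does not emulate, and the
design decisions taken where more than one defensible choice existed.

## The data model

Raw peak areas are strictly positive, right-skewed, and incomplete. All
modelling happens on the natural-log scale; every effect size the package
reports is therefore in natural-log (after standardization, in
SD-of-log-abundance) units. Missing cells are `NA`; zeros are treated as
values, not as missing, because the acquisition platform does not produce
zero peak areas — blank cells do encode absence. A matrix carries a scale
tag (`raw`, `log`, `normalized`, `imputed`) and the stages enforce their
expected scale, so calling them out of order is an error rather than a
silent mistake.

The canonical stage order is: log transform → per-(region, batch) median
normalization → missingness/variance filter → mechanism classification →
imputation → quantile normalization → QC → standardization → model fit.
Quantile normalization needs a complete matrix, which is why it follows
imputation.

## Preprocessing

**Median normalization.** Each (region, batch) group of samples has the
median over all its observed log cells subtracted, making every group's
global median log abundance zero. Dividing raw abundances by a group-level
(geometric-median) factor is exactly this subtraction on the log scale;
subtraction is numerically exact, so that is what is implemented.

**Filtering.** Metabolites missing in ≥ 80 % of samples are dropped (the
cutoff is inclusive), as are metabolites whose observed values have zero
variance. Each dropped metabolite is recorded once with one reason.

**Quantile normalization.** Implemented by the standard tie-averaging
routine of the limma package: every sample's sorted vector is replaced by
the across-sample mean of sorted vectors, so afterwards all samples share
one value distribution (identical sorted vectors to 1e-12). The composition
"median-normalize then quantile-normalize" is idempotent: applying it twice
equals applying it once.

**PCA QC.** Samples are scored on the first two principal components of the
metabolite-standardized matrix. Standardized (rather than raw-log) PCA was
chosen so high-variance metabolites do not dominate the QC view; it is a
configuration choice, not a statistical necessity. Two flags are raised:
`pc_outlier` for samples more than 3 robust SDs (median/MAD) from their
region centroid in the PC1/PC2 plane, and `control_metabolite_mismatch`
when a sample's mean control-metabolite abundance contradicts its region
label (a macula-labelled sample below the across-region midpoint of the
control signal, or a non-macula sample above it). Control metabolites are
macula markers such as the xanthophyll pigments; the rule assumes their
regional contrast is large relative to sample noise, which for macular
pigments (orders of magnitude) it is.

## Missingness mechanism classification

For each metabolite *i* with at least one missing value, the two auxiliary
metabolites with the highest *signed* pairwise-complete Pearson correlation
to *i* (each over ≥ 3 joint observations; ties broken by larger overlap,
then lexicographic id) act as proxies for *i*'s unobserved values. A
one-sided Welch two-sample *t*-test compares each auxiliary's observed
values where *i* is missing against where *i* is present, alternative
"lower when missing". If either p-value is below α = 0.05 the metabolite is
MNAR; otherwise MAR.

Three choices deserve comment:

* *Signed, not absolute, correlation ranking.* The test logic asks whether
  the auxiliaries are **lower** when the focal metabolite is missing, which
  presumes positively co-varying auxiliaries; an anti-correlated auxiliary
  would invert the alternative.
* *One-sided Welch.* "Significantly lower" is a one-sided alternative, and
  Welch avoids an unjustified equal-variance assumption between the two
  (often very unbalanced) splits.
* *Untestable metabolites.* With fewer than 3 missing or 3 observed values
  the split test is meaningless; such metabolites (and those without two
  valid auxiliaries) are labelled `UNTESTABLE_MAR`, kept distinct for
  reporting, and routed to the MAR imputer.

Under a pure-MAR regime the MNAR false-flag rate is bounded by the union of
the two one-sided tests, 2α − α² ≈ 0.0975 at α = 0.05; the test suite
verifies ≤ 0.12 including Monte-Carlo slack. Under hard left-censoring
(bottom 30 % of each censored metabolite deleted) with strong within-family
correlation, recall exceeds 0.8.

## Imputation

**MAR: iterative random forests.** Missing cells start at their metabolite
mean; each incomplete metabolite is then regressed on all other metabolites
with a random-forest ensemble and its missing cells updated with the forest
predictions, sweeping metabolites from least to most missing until the RMS
change between sweeps drops below 1e-3 (or 10 sweeps). Forest settings are
tuned to the regime of a few dozen samples and hundreds of mutually
correlated predictors: all predictors available at every split
(`mtry = p`, i.e. bagged trees — random predictor subsets mostly inject
noise when only a handful of predictors carry signal), terminal nodes of 2,
100 trees. Regression forests cannot extrapolate beyond the training range,
so reconstruction error concentrates on cells whose true values lie outside
the observed span — an accepted property of the method, shared with the
missForest family.

**MNAR: left-censored Gibbs sampling.** Missing cells of an MNAR metabolite
are modelled as left-censored below that metabolite's observed minimum —
the natural detection-limit proxy when no explicit limit is recorded. The
sampler alternates between (a) drawing censored cells from the Gaussian
conditional on a linear model in the metabolite's two auxiliaries,
truncated above at the bound, and (b) redrawing the regression coefficients
and residual variance from their flat-prior posterior given the completed
data. 100 burn-in plus 400 kept sweeps; the imputed value is the posterior
mean of the kept draws, which by construction never exceeds the bound.
Cells whose auxiliaries are themselves missing fall back to a marginal
truncated-Gaussian draw. A single completed matrix is produced (no multiple
imputation), matching the downstream single-fit design.

Both imputers leave observed cells bit-identical — this is asserted, not
assumed.

## The moderated regional model

Let $y_m$ be the standardized log abundance of metabolite $m$ across the
$n$ samples, $X$ the design (intercept, region with macula as reference,
centred age, sex, batch), and blocks the subjects. The model is GLS under a
compound-symmetry within-subject covariance,
$\Sigma_b = (1-\rho)I + \rho J$, with one correlation $\rho$ shared by all
metabolites.

**Consensus correlation.** $\rho$ is estimated per metabolite by method of
moments on residual cross-products within subjects, then pooled as
$\tanh(\mathrm{trimmed\ mean}_{10\%}(\mathrm{atanh}\,\rho_m))$, clipped to
(−0.99, 0.99). Two details matter at this sample size:

* Only design columns that vary within at least one subject are used for
  the residualization. With six subjects, the subject-level covariates
  (age, sex, batch) are confounded with the subject effect itself;
  projecting them out would absorb precisely the covariance being measured
  (the estimate collapses towards zero if they are included).
* OLS residualization on $p$ columns biases within-block cross-products
  downward by roughly $p/n$; a first-order correction
  $\rho \mapsto \rho + (p/n)(1-\rho)$ is applied per metabolite. On null
  data the uncorrected estimator sits near $-p/n$ rather than 0.

A single consensus (rather than per-metabolite mixed models) is a stability
decision: with ~30 samples, per-metabolite REML correlation estimates are
far too noisy to use individually.

**Empirical-Bayes moderation.** Residual variances $s_m^2$ (shared residual
df $d$) receive a scaled-inverse-chi-square prior $(d_0, s_0^2)$ fitted by
matching the first two moments of $\log s_m^2$; the trigamma equation for
$d_0$ is solved by Newton inversion, and when it has no positive solution
the prior is degenerate ($d_0 = \infty$, all posterior variances equal
$s_0^2$). Posterior variances
$\tilde s_m^2 = (d_0 s_0^2 + d s_m^2)/(d_0 + d)$ scale the contrast
standard errors; moderated $t$ is referred to a $t$ distribution on
$d_0 + d$ df. The implementation is cross-checked in the tests against the
reference empirical-Bayes implementation in limma (prior df within 25 %,
posterior variances within 10 %, $t$ correlation > 0.999) but is computed
independently.

**Contrasts and FDR.** Three contrasts — macula−temporal,
temporal−periphery, macula−periphery — are tested for every metabolite, and
Benjamini–Hochberg adjustment is applied *within each contrast* (the
alternative, pooling across contrasts, is noted as a sensitivity concern;
per-contrast adjustment matches reporting counts per comparison).
Sex, age, batch and optional age×region / sex×region interaction
coefficients are reported per metabolite through the same moderated test.

## Pathway enrichment by rotation

For a contrast $c$, each metabolite's whitened data reduce to a
$(d{+}1)$-vector $z_m$: the component along the contrast direction plus an
orthonormal basis of residual space. Under the null all components are iid
$N(0, \sigma_m^2)$, so a random unit vector $r$ (shared across metabolites,
which preserves their correlation) yields a null replicate of every
moderated $t$ at once: $t^*_m = r'z_m / \tilde s^*_m$. Set statistics are
the mean moderated $t$ over members (directional) and the mean squared
moderated $t$ (mixed directionality — pathways shifted in both directions
at once); p-values are $(1 + \#\{t^*\ \mathrm{beats\ observed}\})/(B+1)$
with $B$ = 9999 rotations by default. Explicit rotation sampling was chosen
over the analytic shortcut for transparency and testability; the tests
verify calibration against a sample-permutation oracle and a null rate of
$P(p \le 0.05) \in [0.03, 0.07]$.

Direction calls apply BH across pathways within each statistic type:
`enriched` (up significant, down not), `depleted` (converse), `mixed` (only
the mean-square test significant), `none`. Sets smaller than 3 members are
skipped — a mean over fewer than three statistics is not meaningful.

**Pathway scores.** Each pathway is also summarized by the first principal
component of its standardized members ("eigen-metabolite"), sign-fixed so
most loadings are positive (ties: the alphabetically first member's loading
sign), and pushed through the same regional GLS. No cross-pathway variance
moderation is applied there: with ~34 pathways the prior is not estimable
with useful precision.

## Spatial pattern clusters

The three contrast results of a metabolite reduce to a signature in
$\{+,-,0\}^3$ (sign if significant at the FDR cutoff, else 0). A rule table
maps signatures to ten named clusters — steep/shallow enrichment and
depletion, macula/periphery/temporal enriched or depleted — with internally
contradictory signatures (e.g. significant in opposite directions along the
gradient) deliberately left `unclassified` rather than forced to a nearest
cluster. The table is exposed as data (and overridable from YAML) so an
alternative mapping can be swapped in without code changes. Exhaustive
enumeration of all 27 signatures reaches exactly the ten named clusters,
and negating all log-fold changes maps each cluster to its mirror.

## Disease overlap

Each pathway's metabolites are stratified by their macula-vs-periphery
result (`macula_enriched` / `not_differentiated` / `macula_depleted`;
strata partition the pathway), intersected with the serum study's
metabolites by exact case-folded id match — fuzzy chemical-name matching is
deliberately avoided, dropped rows are counted instead. Each stratum with
≥ 3 members is tested for a coordinated shift of its serum statistics. When
the serum model itself is available (always true for the synthetic serum
studies, fitted by the same moderated machinery with a case/control
design), the null comes from rotations of the serum residual space; when
only summary statistics exist, the null resamples member-sized subsets from
the study's full statistic vector — a documented fallback that ignores
inter-metabolite correlation and is labelled as such in the output.
Significance is by BH FDR (< 0.05) or, for studies with weak signal, a
nominal p < 0.05 mode.

## The synthetic-data generator

The generator is the package's test bed and emulates the motivating study
design: 6 subjects (3 F / 3 M; ages drawn Normal(2.1, 0.94²) truncated at
0.5 years), both eyes for all but one subject, three regions per eye (33
samples), three preparation batches assigned by subject, 371 metabolites in
34 families. Log abundance is built additively: baseline N(10, 1); region
offsets drawn *per family* (so enrichment signal exists at family level)
and jittered per metabolite, with half the families affected by default
(SD 1 log unit); a subject random effect carrying 50 % of unit residual
variance (within-subject correlation 0.5 — the study design does not pin
this value, so it is a free simulation parameter); a family-shared residual
component (within-family correlation 0.5 by default, representing
co-regulation; the auxiliary-metabolite machinery depends on it); batch
offsets (SD 0.3); per-metabolite sex and age coefficients (SD 0.2); and
Gaussian noise. Two control metabolites receive a fixed macula-only
enrichment of 6 natural-log units, mirroring the drastic macular
concentration of the xanthophyll pigments.

Missingness: a configurable fraction of metabolites (20 % by default) is
left-censored below its 26th percentile (MNAR); the remainder lose cells
uniformly at random at per-region rates solved analytically so that
realized overall missingness ≈ 26 % with the macula < temporal < periphery
gradient (24 % / 25.7 % / 28.4 % targets). Calibration is by rate solving
plus one verification pass, not rejection sampling — deterministic and
fast.

What the generator does **not** emulate: mass-spectrometry peak shapes, ion
suppression, batch-by-metabolite interactions, heavy-tailed or multimodal
abundance distributions, annotation errors, or correlated missingness
between metabolites. Passing tests therefore demonstrate statistical
correctness of the pipeline under its stated model, not robustness to every
artefact of real spectrometry data.

A companion two-group generator builds case/control serum studies
(log-normal, family-level case shifts) so the disease-overlap stage can be
exercised end to end against a serum model fitted by the same code path.

## Problem sizes and numerical choices

The simulation-based checks in the test suite and the acceptance script use
these sizes, chosen to give stable Monte-Carlo estimates at interactive run
times: 200 all-null studies for the false-discovery check; 1000 metabolites
for the pure-MAR false-flag rate; 20 studies × 100 random sets (999
rotations each) for rotation calibration, with 9999 rotations for single
planted-set power; 3 replicate studies for parameter recovery; 10 null
serum studies for the overlap flag rate. Tolerances follow the binomial /
Monte-Carlo error of those sizes.

Numerical details: compound-symmetry whitening uses the eigendecomposition
of $(1-\rho)I + \rho J$ per block (exact, no iteration); the trigamma
inversion is Newton with analytic derivative; truncated-Gaussian draws use
the inverse-CDF method with probability floors at 1e-12; rotation p-values
use the add-one estimator $(1+k)/(B+1)$, which never returns 0; BH is
`stats::p.adjust`. All randomized stages take explicit seeds, and two runs
with the same seeds are bit-identical (asserted for the generator and both
imputers).

## Known limitations

* The consensus-correlation bias correction is first order; at very small
  block counts the estimate can still be off by a few hundredths.
* The MNAR censoring bound (observed minimum) is a proxy; per-batch
  detection limits are not modelled.
* The resampling fallback in the overlap stage understates the null spread
  when serum metabolites are strongly correlated; rotation mode is
  preferred whenever sample-level serum data are available.
* Pattern-cluster rules encode one specific reading of the
  signature-to-cluster mapping; contradictory signatures are never forced
  into a cluster, so cluster counts are conservative.
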