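---
title: "Quantifying white matter hyperintensities and modelling their biomarker cascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying white matter hyperintensities and modelling their biomarker cascade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dswmh)
```

## The problem

Adults with Down syndrome develop Alzheimer's disease pathology nearly
universally by mid-life, yet they also show substantial small-vessel
cerebrovascular disease — visible as white matter hyperintensities (WMH) on
T2-FLAIR MRI — despite low systemic vascular risk. A central scientific
question is whether WMH sit *upstream* of Alzheimer-related
pathophysiology: does cerebrovascular injury promote astrocytosis (plasma
GFAP), tau pathology (plasma p-tau217) and ultimately neurodegeneration
(plasma NfL)?

`dswmh` implements the full quantitative chain needed to study that
question: WMH segmentation and volumetry from FLAIR-like volumes, cohort
frequency mapping, biomarker association tables, causal mediation, and
recursive path analysis — together with synthetic generators for both
images and cohorts, because the clinical cohort data this class of study
uses are restricted-access. Every stage is therefore exercisable, and
testable against known ground truth, from code alone.

## WMH segmentation

The segmentation operates on a FLAIR volume and a white-matter mask (the
mask is an *input*; tissue segmentation tools that produce it are out of
scope). The pipeline is:

1. **Optional resampling** to a uniform grid (e.g. 256³ at 1 mm): trilinear
   for intensities, nearest-neighbour for masks. Heterogeneous acquisitions
   are thereby brought onto one grid; phantoms generated on a uniform grid
   skip this step (`target_shape = NULL`, the default).
2. **Histogram thresholds.** Two percentiles of the WM-interior intensity
   histogram mark the dark-to-bright and bright-to-brightest transitions.
   The percentiles default to 95 and 99.5: WMH occupy the far right tail of
   the WM FLAIR histogram, typically a few percent of WM voxels. Both are
   configurable; the percentile convention is linear interpolation between
   closest ranks (`quantile(type = 7)`), chosen for reproducibility.
3. **IPR relaxation.** The inter-percentile range `ipr = t_brightest -
   t_bright` measures the spread of the bright tail. To tolerate
   scan-quality variation the working threshold is relaxed *below* the
   bright threshold by a multiplicative fraction of the IPR:
   `t_relaxed = t_bright - ipr * relaxation_factor / 100`, with
   `relaxation_factor = 10` by default. The relaxation number is
   interpreted as a percentage of the IPR; it is exposed as configuration
   so other interpretations can be dialled in.
4. **Two-component Gaussian mixture, EM.** WM-interior intensities are
   modelled as a mixture of a non-hyperintense and a hyperintense Gaussian.
   The EM is initialised from the data partition at `t_relaxed` (component
   means, variances and weights from the two sides), with a documented
   fallback to a median split when one side is empty — e.g. on noise-free
   synthetic data where the threshold coincides with the WM point mass.
   Variances are floored at `1e-6` times the overall WM variance so
   perfectly separated clusters remain well-defined. Iteration stops when
   the log-likelihood improves by less than `tol = 1e-6` (or at
   `max_iter = 200`); EM guarantees the log-likelihood never decreases,
   which the tests assert on every run. The component with the larger mean
   is the hyperintense one, and each WM voxel receives its posterior
   probability of membership in it.
5. **Labelling.** A voxel is WMH iff it is in the WM mask and its posterior
   is at least `prob_cutoff = 0.5` (ties labelled, configurable).
6. **Contour cleanup.** The Roberts cross operator is applied slice-wise
   (axially) to the posterior map — the classical operator is 2D, and
   axial application matches how FLAIR hyperintensity contours are read.
   Each 2×2 block carries one gradient magnitude; blocks above an Otsu
   threshold computed over *all* block magnitudes mark their four voxels as
   edge voxels. Labelled voxels that are both edge voxels and on the
   outermost WM shell (the one-voxel difference between the WM mask and
   its 6-connected erosion) are removed. Including the flat background in
   the Otsu population matters: posterior maps are near-binary, so their
   nonzero gradient magnitudes concentrate on {1, √2} and an Otsu
   restricted to nonzero values would split *within* the contour class and
   miss genuine contour voxels. Marking both sides of each
   above-threshold block makes the full-removal semantics exact for step
   contours. Lesions at least two voxels interior to the WM boundary are
   provably untouched.
7. **Volumetry.** `volume_cc = n_voxels × voxel volume (mm³) / 1000`,
   exactly, with full provenance (thresholds, mixture parameters,
   iteration count, config) in the result.

Two consequences worth knowing. First, the whole chain is invariant under
strictly monotone affine intensity rescaling: thresholds are percentiles,
and the EM posterior ranking is affine-equivariant — the tests assert
bitwise-identical masks. Second, on a *lesion-free, noise-free* volume the
WM histogram is constant and a two-component mixture is undefined; the
segmenter detects this and returns an empty (zero-volume) result, since a
constant histogram has no bright tail. On noisy lesion-free images a
two-class mixture will genuinely label some noise voxels — an inherent
property of this algorithm class, not of this implementation; volumes from
lesion-free scans should be interpreted with that caveat.

## Frequency maps

`build_frequency_map()` averages aligned binary WMH masks voxel-wise, so
each voxel holds the proportion of subjects in whom it was labelled.
Registration to a common space is a *precondition* — no alignment is
performed, because nonlinear registration is out of scope here.

## The synthetic generators

**Phantoms** (`make_phantom()`) are a centred white-matter ellipsoid with a
ventricle-like central cavity; the cavity and exterior take background
(CSF-suppressed) intensity. Spherical lesions default to placement against
the cavity wall, emulating the periventricular distribution typical of
Down syndrome, where WMH are confluent with the lateral ventricle walls.
Compartment intensities are Gaussian: background 30 ± 10, WM 100 ± 5,
lesion 170 ± 5 by default — a deliberately favourable ~7-SD contrast that
makes ground-truth recovery a well-posed check of the machinery. An
optional first-order multiplicative bias field and extra global noise are
available. Ground truth is exact: the rasterised lesion voxel count times
the voxel volume. Lesion spheres are clipped to the WM compartment (a
sphere tangent to the curved cavity wall necessarily rasterises a few
voxels into it); a sphere entirely outside WM is an error.

What phantoms do *not* emulate: partial-volume effects, Rician noise,
acquisition anisotropy, bias fields beyond first order, or realistic
lesion morphology. Passing the phantom suite therefore demonstrates
algorithmic correctness — exact recovery when compartments are separable,
≤10% volume error under the default noise — not clinical accuracy on real
FLAIR.

**Cohorts** (`make_cohort()`) are drawn from a linear Gaussian structural
cascade age → WMH → GFAP → p-tau217 → NfL with configurable direct edges
(WMH → p-tau217, WMH → NfL, GFAP → NfL), additive per-site shifts shared
across a subject's markers, and diagnosis strata (default proportions
137/24/16/8 of 185 — cognitively stable / MCI / Down syndrome-AD /
undetermined) with optional per-stratum coefficient overrides. Age is
N(45.2, 9.3) years. Default effect sizes were chosen once so whole-sample
correlations among cascade neighbours land in the 0.3–0.6 band typical of
this literature, giving realistic statistical power in tests without
claiming to reproduce any cohort's numbers. The amyloid ratio Aβ42/40 is
generated as an independent near-constant channel: plasma Aβ plateaus in
adults with Down syndrome, and carrying a null channel through the
analyses is itself a useful check. The generator is kept strictly linear —
no truncation at zero — so its covariance has the closed form
Σ = (I−B)⁻¹(Cov(W)+Ψ)(I−B)⁻ᵀ against which the tests verify it; scales are
chosen so negative concentrations are rare tail events.

## Biomarker statistics

NfL is **age-residualised** (OLS `nfl ~ age`) before use as the
neurodegeneration outcome: progression in Down syndrome is strongly
age-dependent, and residualising the outcome removes the shared-age
epiphenomenon without stripping age-driven variance from the predictors.
Associations are plain bivariate Pearson correlations with Fisher-z
confidence intervals (95% assumed; the level is configurable) and t-test
p-values, whole-sample and stratified by diagnosis. Subjects with an
undetermined diagnosis are included in whole-sample analyses and excluded
from every stratified one. Site adjustment applies to the regression-based
engines (mediation, path, interaction) and deliberately *not* to the
bivariate correlations. Strata with fewer than 4 complete pairs are
flagged `insufficient` rather than dropped.

The post hoc interaction probe fits `ptau217 ~ wmh * gfap + site` and
reports model-implied conditional slopes of each predictor at the
within-bin mean of the moderator, using moderator tertiles by default (the
binning is configurable; tertiles are the conventional low/mid/high read).

## Mediation

`estimate_mediation()` implements the quasi-Bayesian Monte-Carlo
decomposition for linear mediator and outcome models without
treatment–mediator interaction: fit `M ~ T + covariates` and
`Y ~ T + M + covariates` by OLS, draw `n_sims = 1000` coefficient vectors
from each model's asymptotic multivariate normal, and per draw compute
ACME = a·b, ADE = direct coefficient, total = ACME + ADE (exact per draw,
so the decomposition identity holds to machine precision for the point
estimates). Intervals are percentile intervals; p-values are doubled tail
proportions floored at `2/n_sims`; effects are per 1-unit treatment
contrast, unstandardised. Directionality is probed by exchanging the
treatment and mediator roles (`reverse_mediation()`), and
`run_mediation_suite()` runs the three hypothesised models plus their
reversals, site-adjusted, with per-model seeds. Sensitivity analysis for
sequential ignorability is out of scope: these models quantify statistical
pathways in cross-sectional data, not confirmed causal effects.

## Path analysis

The cascade is a *recursive* (acyclic) system, so each endogenous variable
is estimated by its own OLS equation on its graph parents plus covariates;
for recursive systems with uncorrelated errors this coincides with
full-information maximum likelihood, which the tests verify against an
independent joint-likelihood optimisation. Indirect effects are products
of edge coefficients along each directed path and total effects are sums
over all paths — identities that hold exactly for a single fit. Indirect
and total effects get percentile CIs from a seed-fixed nonparametric
bootstrap (`bootstrap_n = 2000` by default; the tests verify ~95%
coverage on a toy chain). Both unstandardised and standardised
coefficients are emitted, since conventions differ across reports. The
default edge set is the full upper-triangular cascade over WMH, GFAP,
p-tau217 and age-residualised NfL; the age-driver variant prepends an
age → WMH edge and uses raw NfL as the terminal node, since age is then
modelled explicitly. Stratified fits mirror the statistics layer's
handling of the undetermined group; strata too small for an equation are
returned flagged, not silently dropped. Latent variables, fit indices and
non-recursive systems are out of scope.

## Pipeline and reproducibility

`run_pipeline()` chains simulate → segment → frequency map → table
assembly → stats → mediation → path. Each cohort subject gets a phantom
whose lesion volume is a scaled version (`lesion_volume_scale = 0.12`) of
the subject's generated WMH volume — the scaling keeps lesions inside the
phantom's WM compartment without saturating the radius clamp — placed
mid-WM so contour cleanup never clips true lesion voxels; the assembled
table carries the *segmented* volumes, so downstream statistics exercise
the imaging arm end to end. In a noise-free run the segmented volume
equals the phantom ground truth exactly. Every stochastic step derives its
seed from the master seed; manifests contain config, seeds and per-file
checksums but no timestamps, so identical runs are bitwise identical.
Completed runs are never silently overwritten (`force = TRUE` to
overwrite). Stage failures abort with the stage name in the message.

Default problem sizes — 64³ phantoms, 50-phantom robustness batches,
200-replicate calibration studies, 1000 Monte-Carlo draws, 500–2000
bootstrap resamples — were chosen as the smallest sizes at which the
asymptotic properties being checked (coverage within a few percent of
nominal, recovery within sampling error) are expected to hold; they keep
any single check to seconds on one CPU.

## Known limitations

- The exact percentiles, the arithmetic of the IPR "relaxation of 10", and
  the Roberts dimensionality used by in-house clinical implementations of
  this algorithm family vary; the defaults here are declared, configurable
  choices, not inferred constants.
- EM is run on WM-interior voxels only, on the reading that the mixture is
  defined within the white-matter segment.
- Two-class mixtures over-label lesion-free noisy images (above).
- The synthetic cohort is linear-Gaussian; real biomarker distributions
  are skewed and heteroscedastic, and diagnosis is assigned independently
  of age, unlike real cohorts where dementia is age-linked.
- Mediation and path models quantify directionally-probed statistical
  pathways in cross-sectional data; they cannot confirm temporal causality.
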