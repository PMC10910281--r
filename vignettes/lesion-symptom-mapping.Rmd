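---
title: "Mapping visual extinction from lesion data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping visual extinction from lesion data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(extmap)
```

## The problem

Visual extinction is the failure to report a contralesional stimulus only
when an ipsilesional stimulus is presented at the same time; detection of
single stimuli is intact. It is typically seen after right-hemisphere
stroke and is closely linked to the limits of multi-target attention.
Mapping its neural substrate means relating, across a patient cohort, the
voxel-wise pattern of structural damage to the severity of the behavioural
deficit. `extmap` implements this analysis end to end: behavioural scoring
with covariate control, multivariate lesion-symptom mapping by support
vector regression (SVR-LSM), and voxel-wise Bayesian lesion-deficit
inference (BLDI) — plus a synthetic cohort generator with known ground
truth, so that every stage of the pipeline can be validated without access
to clinical data.

## Behavioural measures

**Extinction score.** The percentage of bilateral confrontation trials in
which the contralesional movement was missed, among trials in which the
ipsilesional movement was detected (trials with an ipsilesional miss
indicate a lapse rather than extinction and are excluded). Patients who
detect fewer than 90% of unilateral contralesional movements are flagged
*not assessable* and excluded: their bilateral misses could reflect a
primary detection deficit.

**Extinction index.** From a computerised test measuring unilateral and
bilateral hit proportions,
$I = (P_{\mathrm{hit}|uni\text{-}left} - P_{\mathrm{hit}|bil\text{-}left})
   - (P_{\mathrm{hit}|uni\text{-}right} - P_{\mathrm{hit}|bil\text{-}right}).$
Spatial biases that degrade unilateral and bilateral detection alike cancel
in the two inner differences, so the index isolates the *extra* bilateral
deficit; +1 is complete contralateral extinction, −1 complete ipsilateral
extinction.

**Center of Cancellation (CoC).** Implemented as the mean normalised
horizontal position (in [−1, 1], 0 at the sheet centre) of the cancelled
targets on a cancellation sheet. This is a deliberate simplification of the
published CoC algorithm, whose full weighting scheme is not reproduced
here; the implementation satisfies the measure's defining semantics exactly
(0 for symmetric cancellation, +1 when only the rightmost target is found),
which is what the package's validation relies on. The CoC values of a
bells-type and a letter-type sheet are averaged into one neglect score.

**Nuisance regression.** Spatial neglect inflates the extinction score
because it also degrades contralesional detection in bilateral trials. As
neglect directly influences the measured variable, it is an actual confound
and is removed by ordinary least squares: the extinction score is regressed
on the CoC and the residuals are the behavioural variable of the
multivariate mapping. The regression is fitted once on the full cohort, not
fold-wise — it is a measurement correction, not part of the predictive
model. Validity is checked by the Spearman correlation between these
residuals and the independently measured extinction index
(`validate_covariate_control()`); Spearman p-values use the exact
distribution below n = 10 and the large-sample approximation otherwise.

## SVR-based lesion-symptom mapping

All analysed voxels enter one model simultaneously. Voxels damaged in fewer
than 10 patients are excluded (too little power; the default is
configurable). Each subject's binary lesion vector is normalised to unit
Euclidean norm — *direct total lesion volume control* (dTLVC) — so that
total lesion volume cannot drive the fit. An $\varepsilon$-SVR with RBF
kernel $\exp(-\gamma\|u-v\|^2)$ is fitted to the SD-standardised scores,
and voxel weights are recovered by the linear back-projection of the dual
coefficients, $\beta_j = \sum_i \alpha_i x_{ij}$ (*pseudo-β*). For a linear
kernel this back-projection equals the primal weight vector exactly, which
anchors its correctness in the test suite; for the RBF kernel it is the
standard first-order approximation.

Numerical choices:

* $\varepsilon = 0.1$ on the SD-standardised score scale. The protocol the
  package follows does not fix $\varepsilon$; it is held constant
  everywhere and recorded in the run manifest. Scores are standardised by
  their SD (not centred — the SVR carries an intercept) so that
  $\varepsilon$ has a scale-free meaning.
* The RBF kernel matrix depends only on the lesion features, never on the
  behavioural scores. It is therefore computed once and reused across all
  permutation refits; this is exact, not an approximation.
* Hyperparameters: fivefold cross-validated grid search over
  C ∈ {1, 10, …, 80} and γ ∈ {0.1, 1, …, 10, 15, 20, 25, 30}. Each pair is
  scored by *prediction accuracy* (mean Pearson r between held-out
  predictions and scores over the five folds) and *reproducibility* (mean
  pairwise Pearson r between the five fold-models' β maps, computed over
  the analysis-mask voxels). The published criterion — high reproducibility
  at decent accuracy — is qualitative; it is formalised here as maximising
  the sum of the two criteria's ranks, with ties broken towards smaller C,
  then smaller γ (preferring the less complex model). Folds are assigned by
  shuffling subjects once under the seed and cutting into five contiguous
  blocks, identical across all pairs.
* Inference: the scores are permuted (default 10,000 times), the SVR refitted
  with the selected hyperparameters held fixed, and one-tailed add-one
  p-values computed in the damage-associated-with-worse-score direction,
  $p_j = (1 + \#\{\beta^{perm}_j \ge \beta^{obs}_j\})/(N+1)$, so p can
  never be exactly 0 and always lies in $[1/(N+1), 1]$. Re-running the grid
  search inside every permutation would be computationally prohibitive and
  is not part of the published procedure.
* Multiple comparisons: Benjamini–Hochberg step-up at q = 0.1 over the
  analysed voxels, reporting the equivalent uncorrected p threshold (the
  largest passing p).
* Reporting: 26-connected clusters of significant voxels; clusters of ≤100
  voxels and atlas-region rows of ≤15 voxels are suppressed by default.
  Probabilistic grey-matter atlases are assigned by maximum probability,
  binary (thresholded) white-matter maps by overlap. Volumes are reported
  in voxels and mm³ using the voxel volume from the affine.

## Bayesian lesion-deficit inference

BLDI is univariate and deliberately liberal: in every voxel lesioned in at
least 5 patients (a lower threshold than the SVR mask, to reach rarely
damaged territory where frequentist power is poor), a Bayesian general
linear model compares H1 "lesion status contributes to the extinction
score over and above the CoC covariate" against H0 "the covariate alone
suffices". The raw extinction score is the outcome and the CoC enters the
model as a covariate — unlike the SVR stage, which consumes pre-residualised
scores. The published description leaves the GLM orientation and prior
family open; the package makes both explicit and swappable behind
`bf_lesion_covariate()`:

* Orientation: behaviour as outcome, voxel lesion status as tested
  regressor, CoC as nuisance regressor. This follows the convention of the
  Bayesian-GLM toolkits this analysis style is built on.
* Prior: Zellner–Siow (JZS), i.e. a Cauchy prior with scale $\sqrt{2}/2$ on
  the standardised coefficients, equivalently a g-prior mixed over
  $g \sim \text{InvGamma}(1/2,\, n r^2/2)$. The Bayes factor of model
  against intercept is the one-dimensional integral over $g$; BF10 for the
  nested comparison is the ratio of the full-model and covariate-only
  Bayes factors.
* Numerics: the integral is evaluated in $t = \log g$ with adaptive
  quadrature (relative tolerance 1e−8) after shifting by the integrand's
  maximum, which keeps Bayes factors of order $10^5$ and larger stable.
  The engine is tested against an independent fine-grid trapezoid
  integration to within 2% relative error. Voxels whose lesion column is
  collinear with the covariate or intercept carry no information about the
  tested effect and are tagged not-analysed.

Bayes factors above 3 count as evidence for H1, below 1/3 as evidence for
H0, anything between as insufficient — every analysed voxel falls in
exactly one category, and unanalysed voxels form the fourth. A *peak* map
(BF > 50, strict) provides a stringency comparable to the
multiple-comparison-corrected multivariate map. Probabilistic ROI subparts
(e.g. of the intraparietal sulcus) are combined by clipped voxel-wise
summation and thresholded either at maximum extent (p > 0) or core area
(p ≥ 0.4, inclusive); `roi_bf_summary()` reports the four-way percentage
partition of ROI voxels.

## The synthetic cohort generator

The clinical cohorts this analysis style is applied to are generally not
shareable, so the package treats the generator as first-class, tested
code. It emulates the statistical structure the analysis assumes:

* **Lesion geometry.** Each lesion is grown from a random seed voxel by
  region growing, sampling frontier voxels with probability proportional to
  $\exp(-\text{decay}\cdot d)$, where $d$ is the distance from the
  territory centre. This guarantees a single 26-connected component and
  produces the strong centre-to-periphery lesion-frequency gradient of
  middle-cerebral-artery stroke. Lesion volumes are log-uniform within
  `size_range`, giving a right-skewed size distribution. The default grid
  is 20×20×20 voxels — large enough for spatial structure, small enough
  that the full pipeline runs in seconds.
* **Behaviour.** The expected bilateral miss probability is
  `clip(effect_size * load + N(0, noise_sd), 0, 1)`, where the load is the
  *maximum* lesioned fraction over the critical masks; with two or more
  disjoint masks this emulates a functional network in which complete
  damage to any one node produces the full deficit (the partial-injury
  situation). The expected CoC is the analogous clipped-linear function of
  the neglect-region load. The default `effect_size` is 2.0 — a response
  that saturates once about half the critical region is destroyed — chosen
  so that the simulated cohort's extinction-score distribution approaches
  the strongly right-skewed, high-variance distribution reported for
  clinical cohorts (many zero scores, affected patients often severe).
  Neglect additionally degrades *unilateral* contralesional detection
  (probability `0.2 * max(CoC, 0)` per trial), which is exactly the
  confound structure the nuisance regression must remove, and drives the
  assessability screen.
* **Trial level.** Confrontation testing draws 10 unilateral-left,
  10 unilateral-right and 10 bilateral trials from the per-subject
  Bernoulli rates. Cancellation sheets draw per-target cancellation with
  probabilities $p_i = \exp(\theta (x_i - x_{max}))$, with $\theta$ solved
  by root finding so that the softmax-weighted mean target position equals
  the requested CoC; at CoC 0 every target is cancelled (CoC exactly 0),
  at ±1 only the extreme target. The Monte-Carlo calibration of this link
  is itself a test. The computerised test draws the same trial counts to
  produce an extinction index.
* **Determinism.** Every generator is a pure function of one integer seed
  (`withr::with_seed`; no global RNG state is disturbed). Identical seeds
  give byte-identical cohorts.

What the generator does *not* emulate: vascular anatomy and tissue classes,
MR/CT appearance, registration error, visual field defects, and the full
CoC weighting of real cancellation sheets. Passing tests therefore show
that the statistical machinery behaves as specified under the assumed
generative model — not that clinical effect sizes or anatomical claims are
reproduced. The published clinical results (the selected hyperparameters,
suprathreshold voxel counts, the IPS evidence percentages, the extreme
Bayes factors) depend on a dataset that is not publicly available and are
documented as non-reproducible.

## Validation scenarios and problem sizes

The test suite validates the pipeline at sizes chosen to exercise the
spatial structure while keeping a full run in minutes:

* *Null calibration*: 20 cohorts of 100 subjects on the 20³ grid with
  behaviour independent of the lesions, 500 permutations each; the mean
  fraction of voxels surviving BH at q = 0.1 must not exceed 0.1. The
  uniformity of permutation p-values is checked by a Kolmogorov–Smirnov
  statistic on a 200-voxel null with independent lesion columns: with
  spatially contiguous lesions the voxel p-values within one replicate are
  strongly dependent (they share the same permutations and neighbouring
  voxels are damaged together), so the one-sample KS critical value does
  not apply to them; independent columns isolate the exchangeability
  property the check is about.
* *Ground-truth recovery*: 120 subjects, one 30-voxel critical region,
  effect 0.9, noise SD 0.1, 500 permutations, FDR q = 0.1; at least half
  of the surviving voxels must lie within one voxel of the true region and
  the survivors' centre of mass within 3 voxels of the true centre.
* *Network recovery*: two disjoint 15-voxel regions damaged by
  non-overlapping 60-patient subsets (lesions grown in two sub-territories
  centred on the regions); both regions must contain voxels at permutation
  p < 0.01. Behaviour is used on the latent scale here, isolating the
  mapping method from trial-sampling noise.
* *Covariate-control validation*: a 60-subject coupled cohort (overlapping
  critical and neglect regions); the Spearman correlation between
  residualised confrontation scores and the simulated computerised-test
  indices must exceed 0.5.
* *BF engine*: oracle agreement within 2% on random small datasets; a
  true-null voxel at n = 200 yields BF < 1/3 in at least 80% of 50
  replicates; the median BF for a fixed effect increases over
  n ∈ {20, 60, 180}.

## Known limitations

* The pseudo-β back-projection is a first-order approximation for the RBF
  kernel; only the linear-kernel case is exact.
* The permutation test fixes the hyperparameters selected on the observed
  data; selection uncertainty is not propagated.
* The CoC implementation covers the measure's endpoint semantics, not the
  full published weighting algorithm.
* BLDI assumes a Gaussian GLM for a bounded, zero-inflated score; with
  strongly non-Gaussian outcomes the Bayes factors are approximate in the
  same sense the underlying toolkits are.
* The simulator's territory model is spherically symmetric; it reproduces
  the frequency gradient, not real vascular shapes.
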