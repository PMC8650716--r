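---
title: "Latent stress and relaxation networks as predictors of quality-of-life change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent stress and relaxation networks as predictors of quality-of-life change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stressnets)
```

## The analysis problem

Persons with multiple sclerosis (MS) often experience declining
health-related quality of life (HRQoL), and neuropsychiatric symptoms that
are sensitive to psychological stress contribute to that decline. The
question this package addresses is whether individual differences in the
*neural* response to mild psychological stress — and to its cessation,
i.e. relaxation — carry prognostic information about how a patient's HRQoL
will evolve over the following years.

The measurement design is an arterial-spin-labeling (ASL) fMRI session at
baseline (T0) comprising seven stages: perceived-stress ratings on a
nine-point scale at stages I, III, V and VII, and CBF imaging plus pulse
oximetry during stage II (baseline 1, rest), stage IV (stress: mental
arithmetic under evaluative feedback) and stage VI (baseline 2, rest
again). HRQoL is assessed with the HAQUAMS questionnaire at T0 and at a
follow-up visit T1 one to three years later.

## The model

### Regional CBF, centering and latent networks

The unit of analysis is the mean CBF (ml/100 g/min) of each gray-matter
atlas region during one fMRI stage, giving a participants x regions matrix
per stage. Each participant's row is centered by subtracting their average
overall GM CBF for that stage (`gm_center()`), which removes global
perfusion differences so that the remaining variation is *regional
covariation* across participants.

Latent networks are the principal components of the centered stress-stage
matrix (`fit_networks()`): a singular-value decomposition

$$X_\text{stress} = U D V^\top,$$

where the columns of $V$ are orthonormal region loading vectors (one per
network) and $U D$ holds the per-participant network activity scores.
Deliberately, **no region-wise (column) centering** is applied: only the
stated per-participant centering. With column centering the rank would be
capped at $n-1$; without it a full-rank cohort of 28 participants with at
least 28 regions yields exactly 28 components, which is the component
count the analysis relies on (Bonferroni over 28 networks).

Two conventions make the decomposition reproducible and interpretable:

* **Sign**: each loading vector is oriented so its largest-magnitude entry
  is positive (the SVD sign is arbitrary).
* **Winner-takes-all**: each region is attributed to the network with the
  maximal *absolute* loading, ties to the lower component index. The
  absolute value is used because loadings are signed (they encode
  direction of participation, not strength of membership); a signed
  variant is available via `winner_takes_all(signed = TRUE)`.

Both baseline stages are centered the same way and projected onto the
stress-stage loadings (`project_stage()`). Differential network activity
is then

* stress exposure = score(stress) − score(baseline 1),
* stress cessation (relaxation) = score(baseline 2) − score(stress),

which telescope to score(baseline 2) − score(baseline 1). A participant
without a baseline-2 scan keeps their exposure scores and gets missing
cessation scores; they are listwise-deleted from cessation analyses only.

### Robust regression with permutation Wald inference

The change in a HAQUAMS scale (T1 − T0; positive = worsening, since
higher HAQUAMS scores mean worse HRQoL) is regressed on one differential
network activity column at a time, with nuisance covariates: intercept,
the T0 score of that scale, the follow-up interval in days, cognitive
task load, and disease type (RRMS/SPMS). The fit is a Huber M-estimate
via iteratively reweighted least squares: tuning constant $k = 1.345$
(the standard 95%-Gaussian-efficiency default; the cited robust-regression
tradition states no constant, so we expose it as an argument), residual
scale re-estimated each iteration as MAD about zero, convergence when the
maximum coefficient change falls below 1e-8 (at most 200 iterations).
With $k = \infty$ the estimator is exactly OLS, which the tests use as an
oracle.

Inference uses the squared Wald statistic
$W = \hat\beta^2 / \widehat{\mathrm{Var}}(\hat\beta)$ with a
heteroskedasticity-consistent sandwich variance built from the weighted
normal equations: bread $X^\top W X$ and meat
$X^\top \mathrm{diag}(w_i^2 r_i^2) X$, where $w_i$ are the converged IRLS
weights. The IRLS weights are strictly positive, so the bread is positive
definite whenever the design has full column rank — an important
robustness property during permutation resampling of near-degenerate
(e.g. sparse binary) predictors; in the OLS limit this is exactly HC0.
$W$ is invariant to rescaling the response or the predictor, and
asymptotically $\chi^2_1$ under the null.

The p-value is obtained by permutation: the predictor-of-interest column
is permuted across participants (the studentized-statistic construction
of the robust permutation approach; nuisance columns and the response
stay fixed), $W$ is recomputed for each permutation, and the add-one
estimator $p = (1 + \#\{W^\ast \ge W\})/(1 + B)$ guarantees validity at
any finite permutation count. A Freedman–Lane variant (permuting
nuisance-model residuals) is available via `scheme = "freedman_lane"`;
the default matches the permute-the-covariate construction. The reported
`t_equivalent` is the signed square root of $W$, negative when larger
predictor values go with smaller (improving) HRQoL changes.

Family-wise error over the 28 networks is controlled by Bonferroni within
each process-by-scale family: the overall (total-score) analysis at
$\alpha_\text{FWE} = 0.05$, i.e. a per-test threshold of
$0.05/28 = 0.0018$ (4 decimals), and the complementary subscale analyses
at $\alpha_\text{FWE} = 0.1$, per-test $0.0036$. Whether the original
families were defined per scale or across scales is not decidable from
the available material; per process-by-scale families are the stricter,
more interpretable choice and are used throughout.

The same machinery screens nine clinico-demographic/radiographic markers
(sex, age, education, disability, annualized relapse rate, T2 lesion
load, MS type, disease duration, GM fraction) one at a time against the
total-score change with T0 total and interval as nuisance
(`screen_markers()`), uncorrected at $\alpha = 0.05$ — each marker
answers its own substantive question, so no multiplicity correction is
applied there.

### Mixed models with sign-flip permutation tests

Psychophysiological stage contrasts (ratings V vs. III and pulse IV
vs. II for stress; ratings VII vs. V and pulse VI vs. IV for relaxation)
and the longitudinal HRQoL trend (time regressor: 0 at T0, the follow-up
delay in days at T1) are tested with random-intercept linear mixed
models. Fitting is by maximum likelihood — not REML — so likelihoods are
comparable across permutation refits. The fitter profiles the likelihood
over the variance ratio $\sigma^2_b/\sigma^2_e$ using the closed form of
the random-intercept covariance inverse, which makes a fit cheap enough
to refit thousands of times; it agrees with `lme4::lmer(REML = FALSE)`
to numerical precision (verified in the test suite, where lme4 is the
independent oracle).

The permutation scheme relabels the two occasions *within* each
participant independently ($2^n$ relabelings, sampled or enumerated
exhaustively). Under the null of no occasion effect the relabelings are
exchangeable, and participant-level covariates are untouched because
they are constant within participant. One-sided p-values follow the
directional claims of the design (stress increases, relaxation
decreases, worsening over time increases), with the add-one estimator;
exhaustive enumeration uses the full group (which contains the
identity). A boundary fit ($\hat\sigma^2_b = 0$) degrades gracefully to
the independence model and is flagged, not failed.

### The gray-matter group mask

For voxel-level inputs, `build_gm_mask()` reproduces the lesion-aware
GM analysis mask: (1) each voxel is assigned to the tissue (GM/WM/CSF)
with the maximal across-participant mean probability — ties resolve
GM > WM > CSF, since the analysis targets GM; (2) voxels lesioned in at
least one patient are removed together with their six face-adjacent
neighbors (Euclidean distance exactly one voxel, interpreted in *index*
space; with anisotropic voxels a millimeter interpretation would treat
the slice direction differently, which the available material does not
resolve — the index-space reading is documented here deliberately);
diagonal neighbors are retained; (3) only voxels covered by every fMRI
scan of every participant survive. Each step can only shrink the mask,
and the provenance attribute records the voxel count after each step.
NIfTI I/O (affine-preserving) is available through the RNifti package.

## The synthetic-cohort generator

No patient data ship with the package; every analysis is exercised on
synthetic cohorts from `simulate_cohort()`, whose defaults emulate the
study conditions:

| Parameter | Default | Meaning |
|---|---|---|
| `n_participants` | 28 | cohort size (23 RRMS / 5 SPMS expected; 18 women expected) |
| `n_regions` | 100 | atlas regions (>= participants) |
| `n_latent_networks` | 6 | planted networks |
| `network_score_sd`, `score_decay` | 8, 0.8 | score SD of network 1 (CBF units), geometric decay across networks |
| `stress_score_shift` | 5 | stress-stage elevation of the designated network |
| `cessation_effect_size` | 0.8 | standardized slope of the HRQoL change on the designated network's cessation score |
| `exposure_effect_size` | 0 | same for the exposure score |
| `noise_sd_cbf` | 1 | regional CBF noise (ml/100 g/min) |
| `global_offset_sd` | 5 | participant global GM CBF offset |
| `noise_sd_outcome` | 0.1 | HAQUAMS change noise |
| `followup_days_range` | 363–1169 | follow-up interval (study range) |
| `time_slope_per_day` | 2e-4 | mean worsening per day (~0.17 over a median interval, matching the observed total-score change) |
| `ms_type_effect` | 0.3 | extra worsening for SPMS |

Stage matrices follow
$X_\text{stage} = S_\text{stage} L^\top + g\,\mathbf{1}^\top +
\text{level} + E$: loading vectors $L$ are orthonormal with zero column
sums (block patterns with a +/− structure by default), so participant
centering removes the global offset $g$ and the scalar CBF level exactly
while leaving network signal untouched. Latent scores are drawn i.i.d.
Gaussian per stage with stage-mean shifts — the simplest structure
consistent with shared characteristic variation across participants. The
geometric decay of score variances is what makes individual components
identifiable; with equal variances the principal components of the noise-
free model would only be determined up to rotation, and indeed the
noise-free "recovered scores correlate perfectly" property holds exactly
only for a single planted network (the tests check the subspace via
principal angles in the multi-network case). Pulse data default to the
study's 21-of-28 availability, missing completely at random, because no
missingness mechanism is documented. The cognitive task load covariate is
drawn standard normal — its real distribution is not documented, and
nothing downstream depends on it beyond linearity. Ratings are generated
on a latent continuous scale, then rounded and clipped to the 1–9 scale.

What the generator does *not* emulate: voxel-level time series and
hemodynamics, spatial autocorrelation between atlas regions beyond the
network structure, item-level response styles (item tables are generated
around the subscale scores only for exercising the scoring path), and
informative missingness. Passing recovery tests therefore demonstrate
correctness of the statistical machinery under the assumed generative
model, not clinical validity on real cohorts.

## Numerical choices and degenerate inputs

* IRLS convergence: max coefficient change < 1e-8, <= 200 iterations;
  a vanishing MAD scale (near-exact fit) falls back to unit weights,
  whose solution interpolates anyway.
* Rank-deficient designs, constant markers and zero-variance
  differential columns raise classed errors; in the network prediction
  table a degenerate cell is reported as non-testable and the remaining
  cells are unaffected.
* Permutation draws use R's RNG, so a single `set.seed()` governs a
  whole analysis; every result records its seed and permutation count.
* Sequential early stopping (Besag–Clifford): optionally stop a
  permutation run once $h$ permutation statistics have reached the
  observed one and report $p = h/\#\text{draws}$ — a valid p-value whose
  accept/reject decisions at thresholds below $h/(B+1)$ are identical to
  the full run. The calibration studies use $h = 2$ (family-wise
  screening at 0.0018) and $h = 50$ (size studies at $\alpha = 0.05$,
  where $h = \lceil \alpha (B+1) \rceil$ makes decisions *exactly* equal
  to the full run). User-facing defaults run every permutation.
* Exhaustive enumeration is supported for $n \le 8$ (robust test,
  $n!$ permutations) and $n \le 20$ participants (sign-flip test,
  $2^n$ relabelings).

## Problem sizes used in the shipped studies

The test suite and the acceptance script calibrate the permutation test
on 1000 simulated null datasets x 999 permutations (Gaussian and
t-with-3-df noise), check end-to-end recovery of the planted
cessation-network effect over 50 cohorts, and estimate family-wise false
positives over several hundred null cohorts — sizes chosen to give
binomial confidence intervals tight enough to be informative while
keeping a full run in the minutes range on a single core. The
study-scale default of 10,000 permutations per test remains the package
default for real analyses.

## Known limitations

* The LMM permutation strategy for repeated measures is implemented as
  the within-participant occasion relabeling described above; the
  original analysis cites an unnamed repeated-measures permutation
  scheme, so ours is stated on its own terms (a participant-level
  alternative is available by configuration).
* Bonferroni families are per process x scale (see above).
* The robust loss of the original Matlab implementation is not
  documented; Huber with $k = 1.345$ is a defensible standard, and all
  conclusions in the shipped studies are insensitive to $k \in
  [1, \infty)$ at the planted effect sizes.
* `region_means()` assumes an integer-labeled parcellation on the same
  grid as the CBF image; no resampling is performed.

## A minimal run

```{r, eval = FALSE}
cfg <- pipeline_config(sim = sim_config(seed = 1), n_perm = 10000)
report <- run_pipeline(cfg)
print(report)
```

The report lists the Bonferroni thresholds actually used, the
significant process x network x scale cells with their signed
t-equivalents and family-wise p-values, the four psychophysiological
stage contrasts, and the longitudinal HRQoL tests, all reproducible from
the seeds it records.
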