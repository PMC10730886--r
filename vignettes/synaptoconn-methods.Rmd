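---
title: "Methods: linking synaptic density, connectivity and clinical severity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking synaptic density, connectivity and clinical severity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Frontotemporal lobar degeneration (FTLD) syndromes — progressive
supranuclear palsy (PSP), corticobasal syndrome (CBS) and behavioural
variant frontotemporal dementia (bvFTD) — are characterised by severe
presynaptic loss.  `synaptoconn` implements a multimodal analysis that asks
three questions of a cohort of patients and similarly aged controls:

1. Is regional synaptic density (SV2A PET binding potential, BP~ND~)
   associated with regional functional connectivity (weighted degree from
   resting-state fMRI), beyond what atrophy explains?
2. Which spatial patterns of synaptic density vary across people, and is an
   individual's functional connectivity to those patterns related to how
   strongly they express them?
3. Does functional connectivity add to — and moderate — the relationship
   between synaptic density and clinical severity (ACE-R, PSPRS)?

Because raw clinical imaging data of this kind are restricted, the package
ships a first-class synthetic study generator with recorded ground truth;
every analysis stage has a parameter-recovery test surface.

# Pipeline stages and their models

## Weighted degree

Subjects' 4-D fMRI is parcellated by an equal-volume sub-parcellation
nested in the atlas regions (volume-proportional allocation, per-region
k-means on voxel coordinates).  Node time series are correlated (Pearson),
Fisher r-to-Z transformed with r clipped to ±(1 − 10⁻¹⁵), and each node's
weighted degree is the *signed sum* of its Fisher-z edges.  Mean degree over
a region's sub-parcels gives the regional metric.  The signed, unthresholded
sum is the minimal reading of conventional weighted degree; an
absolute-value mode is available behind a flag.  Sum versus mean over
neighbours differs only by the constant node count within one analysis.

## Control-referenced z-maps and the spatial correlation test

Patient regional values are standardised to the control mean and SD (n−1)
per region.  The correlation between the mean patient z-maps of two
modalities is tested against spatial-autocorrelation-preserving surrogate
nulls: the second map's values are permuted, smoothed over k nearest
neighbours (k ∈ {3, 5, 10, 20}; inverse-distance and Gaussian kernels), and
rescaled by regressing the target's empirical semivariogram on the smoothed
map's over 15 log-spaced distance bins (γ_target ≈ αγ_smoothed + β; the
surrogate is √α·smoothed + √β·white noise, because independent noise raises
every semivariance bin by its variance).  Distance bins holding fewer than
10 region pairs are excluded from fitting and assessment: their empirical
semivariance estimates are sampling noise that no generator can or should
match.  The generator self-check statistic is the pair-count-weighted
relative deviation of the ensemble-mean variogram from the target's.  The
module surrogates the second map argument; the choice of which map is
surrogated is exposed to the caller.  p-values use the add-one permutation
convention, two-sided on |r|.

## Crossed mixed-effects models

The density–degree relationship is modelled at subject × region resolution:
standardised weighted degree on standardised binding with crossed random
intercepts for subject and region and a random binding slope by region,
estimated by maximum likelihood (fits compared by likelihood-ratio tests
must be ML, not REML).  Covariates: age, sex, mean DVARS (an in-scanner
motion summary), and a cortical/subcortical indicator; optionally regional
grey-matter volume and total intracranial volume.  The whole-cohort model
adds a patient indicator and its interactions with binding and
corticality.  Because the outcome and continuous predictors are
standardised within the estimation sample, fixed effects are standardised
betas (the standardisation convention is ours; the quantity reported by
clinical studies rarely states one).  Subject-level covariates are
standardised over subjects, not over subject × region rows, so subjects
with more regions are not over-weighted.

Singular or non-converging fits degrade deterministically: correlated
random slope → uncorrelated slope → intercepts only, with the ladder
recorded and a convergence flag consumers must respect.  Wald
normal-approximation p-values are reported; at thousands of rows per fit
the difference from Satterthwaite-type corrections is immaterial.

## Permutation GLMs and non-parametric combination

Per-region tests of degree on a modality use the Freedman–Lane scheme:
regress the outcome on the nuisance covariates, permute the residuals,
recombine with the covariate fit, refit the full model, and rank the
observed t against the permutation ts (add-one p).  One seed fixes a shared
permutation-index matrix reused across modalities and contrasts — the
synchronisation non-parametric combination (NPC) requires.  NPC combines
per-modality permutation p-values with Fisher's −2Σlog p evaluated on the
observed data and on every synchronised permutation; within-null p-values
use ranks divided by the permutation count so that a single-modality NPC
reduces *exactly* to that modality's permutation p.  Familywise adjustment
across a contrast family uses the max-statistic over synchronised
permutations.

## Source-based synaptometry (spatial ICA)

Subject binding maps are restricted to voxels positive and finite in every
participant (the voxelwise reading of the masking rule), voxelwise
demeaned, PCA-reduced to the model order (10 by default), and unmixed by
fixed-point logcosh ICA with symmetric decorrelation (tolerance 10⁻⁶, 1000
iterations, deterministic restart schedule).  When the model order exceeds
the number of non-Gaussian sources the surplus directions span a Gaussian
subspace with no logcosh fixed point and the update oscillates there
indefinitely while the signal components are settled; after the iteration
cap the best iterate is accepted if its criterion is below 0.05 (damped
updates were tried and rejected — they converge to spurious fixed points).
Maps are variance-normalised and oriented to non-negative skewness;
loadings are the least-squares projection of the subject maps onto the
maps.

Component QC mirrors standard practice: a Grubbs outlier screen on loadings
(single-outlier, applied once) with an ICA re-run excluding the outlier and
a |cor| ≥ 0.8 match requirement (0.8 is our convention); a
covariate-adjusted group-difference screen with BH-FDR across components
(retained at FDR p < 0.05); stability as the mean matched |cor| across
alternative model orders (Hungarian assignment on the absolute spatial
correlation matrix); and an optional user-supplied exclusion mask of
artefact-prone territory — a component is flagged when more than half of
its supra-97.5th-percentile voxels fall inside it ("regions known to be
sensitive to artefact" cannot be encoded generically).

## Dual regression and connectivity scores

Stage 1 regresses each fMRI volume on the component maps plus an intercept
(the intercept absorbs the global signal; no global-signal regression is
applied).  Stage 2 regresses each voxel's time series on the stage-1 time
courses plus an intercept, giving per-component beta maps and a
df-corrected residual-SD map.  The stage-1 time courses are
variance-normalised before stage 2: without normalisation the stage-2
coefficient divides by the time-course variance and the subject's network
amplitude — precisely the quantity connectivity scores are meant to
capture — cancels out of the beta map.  The normalised connectivity map is
beta ÷ residual SD (beta ÷ SE is available as an alternative reading).

Scores are means of the normalised map inside a mask: the control mask
(voxels where controls show significant positive mean connectivity with the
component by one-sample sign-flip permutation, max-statistic FWE p < 0.01)
for the primary scores, and control mask ∖ component territory (map values
beyond the 97.5th percentile) for the remote, outside-territory scores.
Voxelwise loading associations use the Freedman–Lane GLM per voxel,
one-sided, with max-statistic FWE — a deliberate substitute for
cluster-enhancement inference, which adds machinery orthogonal to the
claims tested here.

## Severity models

For each outcome (ACE-R for the whole cohort, PSPRS for patients — missing
outcomes are dropped per outcome, never imputed), loadings L_k and
connectivity scores F_k are standardised within the estimation sample and
interactions I_k = L_k × F_k formed from the standardised mains, so betas
are standardised and moderation is interpretable at ±1 SD.  A
single-predictor screen fits one covariate-adjusted model per main effect
with BH-FDR across the family.  Model selection is bidirectional stepwise
minimising BIC with age, sex and mean DVARS locked in; interactions may
enter or stay without their mains (no marginality constraint — the
scientific claim concerns moderation terms in their own right).  The
descent is run from both the full baseline model and the covariates-only
model and the lower-BIC winner kept: a single greedy descent can stall in
a local optimum, and the selection objective is BIC itself.  Ties break by
term-name order; the step trace is retained.  Simple slopes at moderator
∈ {−1, 0, +1} SD are β_L + β_I·m with delta-method intervals; coefficients
absent from the winning model contribute zero.

# The synthetic study generator

The generator emulates the study design end to end: 24/29/16/10
Control/PSP/CBS/bvFTD participants with group-matched age, sex, motion
(mean DVARS elevated in bvFTD) and intracranial volume; a Voronoi-grown
ellipsoidal atlas (30 regions, cortical/subcortical flags) with an
equal-volume sub-parcellation (90 parcels); six smooth non-negative
component maps with pairwise spatial |cor| < 0.2; subject PET maps =
baseline profile + Σ loading × component + smooth noise, with
group-specific loading deficits; 200 fMRI volumes at TR 2.5 s per subject
in which each sub-parcel mixes a weak global network and
component-specific AR(1) networks (coefficient 0.3), the subject's coupling
to the mixture scaling with local density at slope 0.2 in patients and 0 in
controls, plus idiosyncratic per-subject component-coupling factors (SD
0.3) — the variance the connectivity scores measure — and global
motion-like spikes in 2% of frames scaled by (DVARS − 5); regional ODI
linearly linked to binding (target correlation 0.55) and grey-matter
volumes linked more weakly (0.3) so binding retains explanatory power
beyond volume; and clinical scores generated on a standardised latent scale
with planted coefficients (ACE-R: +0.45·L₂ + 0.35·I₄ + 0.35·I₅; PSPRS:
−0.50·L₁ − 0.35·I₅), mapped to the instrument range and hard-clipped, with
generation rejected if clipping touches more than 5% of subjects.

Key conventions, with rationale:

* **Loading deficits** (0.55–1.8 SD, patients lower, syndrome-specific
  patterns) give between-group effects of Cohen's f ≈ 0.4–0.7, the order
  implied by published loading F-statistics for this design.
* **PET smooth noise SD 0.025** (~1% of baseline binding) reflects
  post-smoothing, partial-volume-corrected map quality and matches the
  regime in which component recovery is a meaningful contract.
* **ACE-R mapping (intercept 72, scale 9)** compresses the instrument
  scale so that ceiling clipping stays comfortably below the generator's
  own 5% rejection rule; instrument ceiling effects are deliberately not
  emulated.
* **Coupling slope in gain units.**  The configured slope (0.2) acts on
  the parcel's signal amplitude.  The standardised beta an analysis
  recovers from image-level data depends on the full variance budget and is
  considerably larger than in clinical data, where measurement noise
  dominates; the regional-level generator
  (`simulate_regional_data()`) plants the coupling directly in the
  crossed-effects model and records the *implied standardised beta* (slope
  divided by the marginal outcome SD computed from the variance
  components), making calibrated recovery tests possible.

What the generator does **not** emulate: haemodynamics and scanner physics,
registration error, spatial dependence of clinical covariates, instrument
ceiling compression, longitudinal change.  Tests passing on these synthetic
data therefore demonstrate the *statistical machinery* — calibration,
recovery, invariances — not robustness to the full messiness of clinical
imaging.

# Numerical choices and degenerate inputs

* Fisher transform clips r at ±(1 − 10⁻¹⁵); coincident series give finite
  z > 18.  Constant time series are an error naming the node.
* Regions emptied by grey-matter masking keep their unmasked voxels;
  regions with no surviving sub-parcels propagate NA, never silent zeros.
* The variogram surrogate generator excludes distance bins with < 10 pairs
  and reverts to all positive bins only if fewer than 3 survive.
* Permutation p-values always use the add-one convention.
* Grubbs uses the sample (n−1) SD; with that convention the statistic is
  bounded by (n−1)/√n.
* The stepwise tie-break is term-name order after move type; the
  convergence tolerance for a BIC improvement is 10⁻⁸.
* Mixed-model ladders and the ICA noise-subspace acceptance are described
  above; both are deterministic.

# Problem sizes used by the test-suite

Unit tests run on a reduced study (14×16×14 grid, 10 regions, 24
sub-parcels, 22 subjects, 4 components, 60 volumes).  The acceptance
checks use the default study for component recovery; 200 repeats × 500
surrogates for spatial-test calibration; 2000 simulations at n = 79 for
permutation-GLM type-I error; 100 replicates for mixed-model and
stepwise-selection recovery; and 200 repeats for familywise-error
calibration of the control masks.  These sizes make the Monte-Carlo error
of each check small relative to its acceptance band.

# Known limitations

* The surrogate family (smoothed permutations) cannot reproduce
  non-stationary autocorrelation; at very coarse parcellations (tens of
  regions) the empirical variogram itself is too noisy for tight matching,
  which is why the self-check runs at sub-parcel resolution.
* ICA identifiability requires non-Gaussian sources; model orders far above
  the true source count waste components on noise rotations (harmless but
  uninterpretable).
* Stepwise selection with BIC at n ≈ 79 and 18 candidate terms admits, by
  construction, roughly one spurious term on average under pure noise
  (P(χ²₁ > log n) ≈ 0.037 per candidate); selected models should be read
  with that base rate in mind.
* The severity models support both the whole cohort and patients only;
  the default uses all subjects with a non-missing outcome.
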