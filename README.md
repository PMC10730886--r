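# synaptoconn

Multimodal analysis of synaptic density, brain network connectivity and
clinical severity in frontotemporal lobar degeneration (FTLD) syndromes —
progressive supranuclear palsy (PSP), corticobasal syndrome (CBS) and
behavioural variant frontotemporal dementia (bvFTD).

FTLD causes severe presynaptic loss, measurable in vivo as the SV2A PET
binding potential (BP~ND~). `synaptoconn` is for imaging researchers who
want to relate that molecular signal to resting-state fMRI network function
and to cognition, with the statistical machinery validated on synthetic
data with planted ground truth:

* **Weighted degree** — equal-volume sub-parcellation nested in atlas
  regions; node-wise Pearson correlations, Fisher r-to-Z; degree of node
  *p* is the signed sum `d_p = Σ_{q≠p} z_pq`, averaged back to regions.
* **Spatial correlation with surrogate nulls** — patient regional z-maps
  (standardised to controls) are compared across modalities with a
  permutation test whose nulls preserve spatial autocorrelation by
  variogram matching.
* **Crossed mixed-effects models** — standardised weighted degree on
  standardised binding with crossed random intercepts for subject and
  region and a random binding slope by region
  (`wd ~ bp + covariates + (1|subject) + (1 + bp|region)`, ML), giving
  standardised betas for patients, controls and the group × binding
  interaction.
* **Permutation GLMs and non-parametric combination** — Freedman–Lane
  residual permutation per region with synchronised permutations across
  modalities, Fisher-combined (NPC), max-statistic familywise control.
* **Source-based synaptometry** — fixed-point logcosh spatial ICA over
  concatenated subject binding maps, with component QC (Grubbs outlier
  robustness, covariate-adjusted group screen with FDR, model-order
  stability by Hungarian matching).
* **Dual regression** — component maps → subject time courses → subject
  connectivity maps; noise-normalised connectivity scores inside
  control-defined masks and outside the component's own territory
  (97.5th-percentile mask) for remote-connectivity effects.
* **Severity moderation models** — stepwise-BIC selection over component
  loadings `L_k`, connectivity scores `F_k` and their interactions
  `L_k × F_k` with locked nuisance covariates
  (`ACE-R/PSPRS ~ L1*F1 + … + L6*F6 + age + sex + mean DVARS`), plus
  simple-slopes reporting at moderator ±1 SD.

The synthetic study generator is first-class: it produces the atlas,
per-subject PET/ODI/grey-matter maps, density-coupled 4-D fMRI and clinical
scores for a 24/29/16/10 Control/PSP/CBS/bvFTD cohort, and records every
generating quantity for parameter-recovery testing. See the methods
vignette (`vignettes/synaptoconn-methods.Rmd`) for the models, conventions
and their rationale.

## Worked example

```r
library(synaptoconn)

study <- simulate_study(sim_config(seed = 42))
study
#> Synthetic multimodal study
#>   subjects: 79 ( Control=24, PSP=29, CBS=16, bvFTD=10 )
#>   atlas: 30 regions / 90 sub-parcels on 24x28x24 grid
#>   planted PET components: 6 | fMRI volumes: 200 at TR 2.5 s

pipe <- run_pipeline(study, n_null = 500, n_perm = 300)
pipe
#> Multimodal pipeline result
#>   spatial correlation (z-maps, cortical): r = 0.616, p = 0.0040
#>   binding std beta: patients 5.639, controls -0.088, interaction 0.855
#>   random-slope LRT: chi2 = 969.6 (df 2), p = 2.9e-211
#>   components selected: 3, 5, 6, 7, 8, 10
#>   winning ace_r model: I4, I6, L1
#>   winning pspr_s model: I5, I6, L5
```

Reading the output: the patients' mean weighted-degree z-map correlates
with their mean binding z-map across cortical regions (r = 0.62), and the
surrogate test says a map with the same spatial autocorrelation rarely does
as well (p = 0.004). The mixed model finds binding associated with degree
in patients but not controls, with a positive group × binding interaction —
the planted coupling (slope 0.2 in patients, 0 in controls; the synthetic
degree measure is far less noisy than clinical fMRI, hence the large
standardised beta). Eight of ten ICA components pass QC, six of them
matching the planted sources at spatial |cor| ≥ 0.99. The winning severity
models are stated in *selected-component* indices; mapping them back
through `match_components()` shows the ACE-R model is exactly the planted
`{L2, L4×F4, L5×F5}` and the PSPRS model contains the planted
`{L1, L5×F5}`. Simple slopes for the retained ACE-R moderation:

```r
simple_slopes(pipe$severity$ace_r$inside, 4)   # design index 4 = planted component 4
#>   moderator  slope    se  ci_lo  ci_hi
#> 1        -1 -0.169 0.082 -0.330 -0.008
#> 2         0  0.000 0.000  0.000  0.000
#> 3         1  0.169 0.082  0.008  0.330
```

— the binding–cognition relationship is present only at high connectivity,
the moderation signature the pipeline is designed to detect.

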