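# Synthetic multimodal study generator.  Emulates a four-group FTLD-spectrum
# cohort: component-structured SV2A PET binding maps with group-dependent
# loadings, fMRI whose parcel connectivity is coupled to local synaptic
# density in patients but not controls, ODI and grey-matter maps correlated
# with the PET signal, and clinical scores with planted main-effect and
# density-by-connectivity interaction terms.  Every stochastic quantity is
# recorded as ground truth so downstream stages have a parameter-recovery
# test surface.

#' Simulation configuration
#'
#' Defaults mirror the study design being emulated: 24/29/16/10
#' Control/PSP/CBS/bvFTD participants, 200 fMRI volumes at TR 2.5 s, a
#' patient-only density-to-coupling slope of 0.2 and a control slope of 0.
#' Effect sizes without a published magnitude (loading deficits, clinical
#' coefficients, noise SDs) are fixed conventions documented in the methods
#' vignette.
#'
#' @param grid_shape 3-vector of voxel counts
#' @param n_regions number of atlas regions
#' @param n_subparcels target total sub-parcels
#' @param group_sizes named counts for Control, PSP, CBS, bvFTD
#' @param n_components_true number of planted PET spatial components
#' @param n_timepoints fMRI volumes per subject
#' @param tr repetition time in seconds
#' @param coupling_slope named per-group density-to-coupling slope
#' @param loading_shift groups x components matrix of loading mean shifts in
#'   SD units (patients negative); `NULL` for the built-in default pattern
#' @param loading_sd within-group loading SD
#' @param component_amplitude PET map units per unit loading at component peak
#' @param pet_baseline named baseline binding (cortical, subcortical)
#' @param pet_noise_sd SD of smooth per-subject PET noise
#' @param fmri_parcel_noise_sd,fmri_voxel_noise_sd fMRI noise SDs at the
#'   sub-parcel and voxel level
#' @param fmri_global_affinity,fmri_comp_affinity amplitude of the shared
#'   global network and peak amplitude of the component-specific networks in
#'   every sub-parcel's signal mixture
#' @param fmri_subject_coupling_sd SD of the per-subject, per-component
#'   coupling factors (idiosyncratic network strength beyond what density
#'   predicts; this is the variance the connectivity scores measure)
#' @param ar_coef AR(1) coefficient of latent network time courses
#' @param spike_frac,spike_scale fraction of frames receiving global
#'   motion-like spikes and their amplitude per unit of (DVARS - 5)
#' @param odi_intercept,odi_slope,odi_cor regional ODI linear link to binding
#'   and its target correlation (1 = noise-free)
#' @param gm_rel_sd,gm_cor relative SD of regional grey-matter volumes and
#'   their target correlation with binding
#' @param f_cor correlation of latent connectivity scores with loadings
#' @param clinical list of per-outcome generating models (see
#'   [simulate_clinical()])
#' @param seed integer master seed
#' @return a validated `sim_config` list
#' @export
sim_config <- function(grid_shape = c(24L, 28L, 24L),
                       n_regions = 30L,
                       n_subparcels = 90L,
                       group_sizes = c(Control = 24L, PSP = 29L, CBS = 16L,
                                       bvFTD = 10L),
                       n_components_true = 6L,
                       n_timepoints = 200L,
                       tr = 2.5,
                       coupling_slope = c(Control = 0, PSP = 0.2, CBS = 0.2,
                                          bvFTD = 0.2),
                       loading_shift = NULL,
                       loading_sd = 1,
                       component_amplitude = 0.25,
                       pet_baseline = c(cortical = 3.0, subcortical = 2.6),
                       pet_noise_sd = 0.025,
                       fmri_parcel_noise_sd = 1.0,
                       fmri_voxel_noise_sd = 0.5,
                       fmri_global_affinity = 0.5,
                       fmri_comp_affinity = 1.2,
                       fmri_subject_coupling_sd = 0.3,
                       ar_coef = 0.3,
                       spike_frac = 0.02,
                       spike_scale = 1.0,
                       odi_intercept = 0.2,
                       odi_slope = 0.05,
                       odi_cor = 0.55,
                       gm_rel_sd = 0.1,
                       gm_cor = 0.3,
                       f_cor = 0.4,
                       clinical = NULL,
                       seed = 1L) {
  if (is.null(loading_shift))
    loading_shift <- default_loading_shift(n_components_true)
  if (is.null(clinical)) clinical <- default_clinical_models()
  cfg <- list(grid_shape = as.integer(grid_shape), n_regions = as.integer(n_regions),
              n_subparcels = as.integer(n_subparcels),
              group_sizes = group_sizes, n_components_true = as.integer(n_components_true),
              n_timepoints = as.integer(n_timepoints), tr = tr,
              coupling_slope = coupling_slope, loading_shift = loading_shift,
              loading_sd = loading_sd, component_amplitude = component_amplitude,
              pet_baseline = pet_baseline, pet_noise_sd = pet_noise_sd,
              fmri_parcel_noise_sd = fmri_parcel_noise_sd,
              fmri_voxel_noise_sd = fmri_voxel_noise_sd,
              fmri_global_affinity = fmri_global_affinity,
              fmri_comp_affinity = fmri_comp_affinity,
              fmri_subject_coupling_sd = fmri_subject_coupling_sd,
              ar_coef = ar_coef, spike_frac = spike_frac, spike_scale = spike_scale,
              odi_intercept = odi_intercept, odi_slope = odi_slope, odi_cor = odi_cor,
              gm_rel_sd = gm_rel_sd, gm_cor = gm_cor, f_cor = f_cor,
              clinical = clinical, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  counts <- c(cfg$n_regions, cfg$n_subparcels, cfg$n_components_true,
              cfg$n_timepoints, cfg$group_sizes, cfg$grid_shape)
  if (any(counts <= 0)) stop("all counts must be positive")
  if (length(cfg$group_sizes) != 4L) stop("need 4 group sizes")
  if (cfg$n_subparcels < cfg$n_regions)
    stop("n_subparcels must be >= n_regions")
  if (!setequal(names(cfg$group_sizes), c("Control", "PSP", "CBS", "bvFTD")))
    stop("group_sizes must be named Control, PSP, CBS, bvFTD")
  if (!identical(dim(cfg$loading_shift),
                 c(4L, cfg$n_components_true)))
    stop("loading_shift must be a 4 x n_components_true matrix")
  num <- c(cfg$coupling_slope, cfg$loading_shift, cfg$loading_sd,
           cfg$component_amplitude, cfg$pet_baseline, cfg$pet_noise_sd,
           cfg$fmri_parcel_noise_sd, cfg$fmri_voxel_noise_sd, cfg$ar_coef,
           unlist(lapply(cfg$clinical, function(m) c(m$coefs, m$intercept,
                                                     m$scale, m$noise_sd))))
  if (any(!is.finite(num))) stop("all configured coefficients must be finite")
  if (cfg$pet_noise_sd < 0 || cfg$fmri_parcel_noise_sd < 0 ||
      cfg$fmri_voxel_noise_sd < 0)
    stop("noise SDs must be non-negative")
  if (abs(cfg$ar_coef) >= 1) stop("ar_coef must lie in (-1, 1)")
  invisible(cfg)
}

# Group-by-component loading deficits (SD units, patients lower), loosely
# following the anatomical pattern of FTLD syndromes: striatal deficit worst
# in PSP, cingulate/insular and frontal deficits worst in bvFTD.  Magnitudes
# give between-group effects (Cohen's f ~ 0.4-0.7) of the order reported for
# loading group differences in SV2A component analyses.
default_loading_shift <- function(K) {
  base <- rbind(Control = rep(0, 6),
                PSP   = c(-1.3, -0.55, -0.8, -0.9, -0.9, -1.1),
                CBS   = c(-0.9, -1.15, -0.5, -1.1, -0.8, -0.7),
                bvFTD = c(-1.1, -1.5, -1.5, -1.8, -1.4, -1.5))
  if (K <= 6) return(base[, seq_len(K), drop = FALSE])
  cbind(base, matrix(rep(c(0, -0.8, -0.8, -1.1), K - 6), nrow = 4))
}

# Planted severity models: cognition (ACE-R analogue) loads on the
# parietal/frontal component 2 plus density-by-connectivity interactions for
# components 4 and 5; the motor scale (PSPRS analogue) loads negatively on
# the striatal component 1 with a negative interaction for component 5.
default_clinical_models <- function() {
  list(
    ace_r = list(intercept = 72, scale = 9,
                 coefs = c(L2 = 0.45, I4 = 0.35, I5 = 0.35),
                 beta_age = -0.10, noise_sd = 0.6, range = c(0, 100)),
    pspr_s = list(intercept = 27, scale = 11,
                  coefs = c(L1 = -0.50, I5 = -0.35),
                  beta_age = 0.05, noise_sd = 0.6, range = c(0, 100),
                  patients_only = TRUE))
}

#' Simulate the participant table
#'
#' One row per subject with group, age, sex, mean DVARS (elevated in bvFTD)
#' and total intracranial volume, drawn from group-specific distributions
#' matched to the emulated cohort.
#'
#' @param config a [sim_config()]
#' @return data.frame with columns `subject_id`, `group`, `age`, `sex`,
#'   `mean_dvars`, `tiv`
#' @export
simulate_subjects <- function(config) {
  gs <- config$group_sizes
  groups <- factor(rep(names(gs), gs), levels = names(gs))
  n <- length(groups)
  pars <- list(  # age mean/sd, male fraction, dvars mean/sd per group
    Control = list(age = c(70.0, 8.4), male = 16 / 24, dvars = c(5.0, 0.4)),
    PSP     = list(age = c(70.8, 8.4), male = 15 / 29, dvars = c(5.2, 0.6)),
    CBS     = list(age = c(67.1, 5.7), male = 7 / 16,  dvars = c(4.9, 0.4)),
    bvFTD   = list(age = c(65.0, 9.1), male = 8 / 10,  dvars = c(5.9, 0.8)))
  with_seed(derive_seed(config$seed, 31L), {
    age <- dvars <- numeric(n); sex <- character(n)
    for (g in names(gs)) {
      i <- which(groups == g); p <- pars[[g]]
      age[i] <- stats::rnorm(length(i), p$age[1], p$age[2])
      sex[i] <- ifelse(stats::runif(length(i)) < p$male, "M", "F")
      dvars[i] <- stats::rnorm(length(i), p$dvars[1], p$dvars[2])
    }
    tiv <- stats::rnorm(n, 1400, 110) + ifelse(sex == "M", 110, 0)
    data.frame(subject_id = sprintf("sub-%03d", seq_len(n)), group = groups,
               age = age, sex = factor(sex, levels = c("F", "M")),
               mean_dvars = dvars, tiv = tiv)
  })
}

#' Planted spatial components
#'
#' Draws `n_components_true` smooth, spatially localised, non-negative
#' Gaussian-blob maps inside the atlas mask with low pairwise spatial
#' correlation (< 0.2), redrawing centres until separation is achieved.
#'
#' @param atlas a `labelled_atlas`
#' @param config a [sim_config()]
#' @return voxels-in-grid x K matrix stored as a list: `maps` (3-D array per
#'   component stacked in a 4-D array), `max_abs_corr`
#' @export
make_true_components <- function(atlas, config) {
  K <- config$n_components_true
  dim3 <- dim(atlas$labels)
  mask <- atlas$labels > 0L
  coords <- which(mask, arr.ind = TRUE)
  sigma <- max(1.2, min(dim3) / 10)  # blob width scales with the grid
  with_seed(derive_seed(config$seed, 41L), {
    for (try in 1:100) {
      ctr <- coords[sample.int(nrow(coords), K), , drop = FALSE]
      maps <- array(0, dim = c(dim3, K))
      vals <- matrix(0, sum(mask), K)
      for (k in seq_len(K)) {
        d2 <- rowSums((t(t(coords) - ctr[k, ]))^2)
        v <- exp(-0.5 * d2 / sigma^2)
        v <- v / max(v)
        vals[, k] <- v
        mk <- array(0, dim = dim3); mk[mask] <- v
        maps[, , , k] <- mk
      }
      cc <- stats::cor(vals)
      mac <- max(abs(cc[upper.tri(cc)]))
      if (mac < 0.2) return(list(maps = maps, max_abs_corr = mac))
    }
    stop("could not place ", K, " components with pairwise |corr| < 0.2")
  })
}

#' Simulate per-subject PET binding maps
#'
#' Each subject map is a fixed baseline profile (cortical > subcortical,
#' plus a smooth shared texture) plus the sum of loading-weighted planted
#' components plus smooth subject noise.  Loadings are drawn with
#' group-specific mean shifts implementing the configured deficits.  A
#' configuration that drives any in-mask voxel non-positive is rejected.
#'
#' @param atlas a `labelled_atlas`
#' @param subjects participant table from [simulate_subjects()]
#' @param truth_components output of [make_true_components()]
#' @param config a [sim_config()]
#' @return list: `maps` (4-D array, last dimension = subject), `loadings`
#'   (subjects x K), `baseline` (3-D array)
#' @export
simulate_pet_maps <- function(atlas, subjects, truth_components, config) {
  dim3 <- dim(atlas$labels)
  mask <- atlas$labels > 0L
  K <- config$n_components_true
  comp_flat <- matrix(truth_components$maps, ncol = K)  # voxels x K
  if (min(comp_flat) < 0) stop("truth components must be non-negative")
  n <- nrow(subjects)
  cort <- array(FALSE, dim = dim3)
  cort_ids <- atlas$region_table$region_id[atlas$region_table$is_cortical]
  cort[atlas$labels %in% cort_ids] <- TRUE
  with_seed(derive_seed(config$seed, 43L), {
    baseline <- array(0, dim = dim3)
    baseline[mask] <- ifelse(cort[mask], config$pet_baseline["cortical"],
                             config$pet_baseline["subcortical"])
    baseline <- baseline + 0.1 * smooth_field(dim3, 2) * mask
    shift <- config$loading_shift[as.integer(subjects$group), , drop = FALSE]
    loadings <- shift + matrix(stats::rnorm(n * K, sd = config$loading_sd), n, K)
    colnames(loadings) <- paste0("L", seq_len(K))
    maps <- array(0, dim = c(dim3, n))
    base_flat <- as.numeric(baseline)
    for (s in seq_len(n)) {
      noise <- config$pet_noise_sd * smooth_field(dim3, 1.5)
      v <- base_flat + comp_flat %*% (config$component_amplitude * loadings[s, ]) +
        as.numeric(noise)
      v[!mask] <- 0
      if (any(v[mask] <= 0))
        stop("configured effect sizes/noise drive PET voxels <= 0; ",
             "reduce amplitudes or noise")
      maps[, , , s] <- array(v, dim = dim3)
    }
    list(maps = maps, loadings = loadings, baseline = baseline)
  })
}

#' Simulate regional ODI and grey-matter volume tables
#'
#' Regional ODI follows a linear link to regional binding
#' (`odi = a + b * bp + noise`) with noise scaled to achieve the configured
#' correlation; grey-matter volumes use a weaker link so binding retains
#' explanatory power beyond volume.
#'
#' @param bp_regional subjects x regions matrix of regional binding
#' @param atlas a `labelled_atlas` (for nominal region volumes)
#' @param config a [sim_config()]
#' @return list of subjects x regions matrices `odi` and `gm_volume`
#' @export
simulate_secondary_modalities <- function(bp_regional, atlas, config) {
  link_noise_sd <- function(slope, target_cor, sd_x, floor_sd) {
    # a zero slope (or zero target) means pure measurement noise
    if (slope == 0 || target_cor <= 0) return(floor_sd)
    if (target_cor >= 1) return(0)
    abs(slope) * sd_x * sqrt(1 / target_cor^2 - 1)
  }
  n <- nrow(bp_regional); R <- ncol(bp_regional)
  sd_bp <- stats::sd(as.numeric(bp_regional))
  with_seed(derive_seed(config$seed, 47L), {
    s_odi <- link_noise_sd(config$odi_slope, config$odi_cor, sd_bp, 0.02)
    odi <- config$odi_intercept + config$odi_slope * bp_regional +
      matrix(stats::rnorm(n * R, sd = s_odi), n, R)
    vol_r <- atlas$region_table$voxel_count / 100  # nominal cm^3 scale
    gm_slope <- config$gm_rel_sd / sd_bp  # unit-free link on relative scale
    s_gm <- link_noise_sd(gm_slope, config$gm_cor, sd_bp, 0.05)
    rel <- gm_slope * sweep(bp_regional, 2, colMeans(bp_regional)) +
      matrix(stats::rnorm(n * R, sd = s_gm), n, R)
    gm <- sweep(1 + rel, 2, vol_r, "*")
    dimnames(odi) <- dimnames(gm) <- dimnames(bp_regional)
    list(odi = odi, gm_volume = gm)
  })
}

#' Simulate clinical severity scores
#'
#' Scores are generated on a standardised latent scale from planted
#' main-effect and interaction coefficients on component loadings `L_k` and
#' connectivity scores `F_k` (interaction columns `I_k = L_k * F_k` from
#' standardised mains), then mapped to the instrument range and hard-clipped.
#' A configuration whose clipping affects more than 5% of subjects is
#' rejected as implausible.
#'
#' @param subjects participant table
#' @param loadings subjects x K loading matrix
#' @param fscores subjects x K connectivity-score matrix
#' @param config a [sim_config()]
#' @return `subjects` with score columns appended, plus attribute
#'   `"clinical_truth"` holding the generating coefficients
#' @export
simulate_clinical <- function(subjects, loadings, fscores, config) {
  n <- nrow(subjects)
  Lz <- apply(loadings, 2, zscore)
  Fz <- apply(fscores, 2, zscore)
  K <- ncol(Lz)
  inter <- Lz * Fz
  colnames(inter) <- paste0("I", seq_len(K))
  colnames(Lz) <- paste0("L", seq_len(K))
  colnames(Fz) <- paste0("F", seq_len(K))
  X <- cbind(Lz, Fz, inter)
  age_z <- zscore(subjects$age)
  truth <- list()
  out <- subjects
  with_seed(derive_seed(config$seed, 53L), {
    for (nm in names(config$clinical)) {
      m <- config$clinical[[nm]]
      beta <- stats::setNames(rep(0, ncol(X)), colnames(X))
      use <- intersect(names(m$coefs), colnames(X))
      beta[use] <- m$coefs[use]
      latent <- as.numeric(X %*% beta) + m$beta_age * age_z +
        stats::rnorm(n, sd = m$noise_sd)
      score <- m$intercept + m$scale * latent
      clipped <- score < m$range[1] | score > m$range[2]
      if (mean(clipped) > 0.05)
        stop("clinical model '", nm, "' clips ", round(100 * mean(clipped)),
             "% of subjects; implausible configuration")
      score <- pmin(pmax(score, m$range[1]), m$range[2])
      if (isTRUE(m$patients_only)) score[subjects$group == "Control"] <- NA_real_
      out[[nm]] <- score
      truth[[nm]] <- m
    }
    # behavioural inventory: group-shift only, kept for table completeness
    cbi_mean <- c(Control = NA, PSP = 53.2, CBS = 37.7, bvFTD = 86.9)
    cbi_sd <- c(Control = NA, PSP = 34.3, CBS = 19.8, bvFTD = 34.5)
    g <- as.character(subjects$group)
    pat <- g != "Control"
    cbi <- rep(NA_real_, n)
    cbi[pat] <- stats::rnorm(sum(pat), cbi_mean[g[pat]], cbi_sd[g[pat]])
    out$cbi_r <- pmin(pmax(cbi, 0), 180)
  })
  attr(out, "clinical_truth") <- truth
  out
}

# Latent connectivity scores correlated with loadings; stands in for
# measured dual-regression scores when clinical outcomes are generated.
simulate_fscores <- function(loadings, config) {
  n <- nrow(loadings); K <- ncol(loadings)
  rho <- config$f_cor
  with_seed(derive_seed(config$seed, 59L), {
    Lz <- apply(loadings, 2, zscore)
    Fz <- rho * Lz + sqrt(1 - rho^2) * matrix(stats::rnorm(n * K), n, K)
    colnames(Fz) <- paste0("F", seq_len(K))
    Fz
  })
}

#' Simulate one subject's coupled 4-D fMRI volume
#'
#' Each sub-parcel's time course is a gain-weighted mixture of shared latent
#' AR(1) network time courses plus parcel noise; the gain increases with the
#' subject's regional synaptic density at the group's coupling slope
#' (patients > 0, controls = 0), so higher local density yields stronger
#' shared signal and hence higher weighted degree.  Global motion-like
#' spikes are injected in a fraction of frames scaled by (DVARS - 5).
#' Voxels within a sub-parcel share its time course plus voxel noise.
#'
#' @param study a `sim_study` from [simulate_study()]
#' @param s subject index
#' @param voxelwise return the full 4-D array (`TRUE`) or the sub-parcel
#'   time-course matrix before voxel expansion (`FALSE`)
#' @return 4-D array `[x, y, z, t]`, or timepoints x sub-parcels matrix
#' @export
simulate_subject_fmri <- function(study, s, voxelwise = TRUE) {
  cfg <- study$config
  if (cfg$fmri_parcel_noise_sd < 0 || cfg$fmri_voxel_noise_sd < 0)
    stop("noise SDs must be non-negative")
  sp <- study$subparcellation
  TT <- cfg$n_timepoints
  A <- study$truth$fmri$affinity            # parcels x (K + 1)
  gain <- study$truth$fmri$gain[s, ]        # per parcel
  with_seed(derive_seed(cfg$seed, 61L, s), {
    Kn <- ncol(A)
    eta <- vapply(seq_len(Kn), function(k) {
      e <- as.numeric(stats::filter(stats::rnorm(TT), cfg$ar_coef,
                                    method = "recursive"))
      e * sqrt(1 - cfg$ar_coef^2)  # unit stationary variance
    }, numeric(TT))
    # per-subject component coupling factors scale the component networks;
    # local density then scales the parcel's coupling to the mixture
    cg <- study$truth$fmri$comp_gain[s, ]
    Asub <- A
    Asub[, -1] <- sweep(Asub[, -1, drop = FALSE], 2, cg, "*")
    parcel_ts <- sweep(eta %*% t(Asub), 2, gain, "*")
    parcel_ts <- parcel_ts +
      matrix(stats::rnorm(TT * ncol(parcel_ts), sd = cfg$fmri_parcel_noise_sd),
             TT, ncol(parcel_ts))
    dv <- study$subjects$mean_dvars[s]
    spike_amp <- cfg$spike_scale * max(0, dv - 5)
    if (spike_amp > 0 && cfg$spike_frac > 0) {
      spikes <- which(stats::runif(TT) < cfg$spike_frac)
      if (length(spikes))
        parcel_ts[spikes, ] <- parcel_ts[spikes, ] +
          spike_amp * stats::rnorm(length(spikes))
    }
    if (!voxelwise) return(parcel_ts)
    dim3 <- dim(sp$labels)
    nvox <- prod(dim3)
    lab <- as.integer(sp$labels)
    out <- matrix(0, nvox, TT)
    inb <- lab > 0L
    out[inb, ] <- t(parcel_ts)[lab[inb], ]
    out <- out + matrix(stats::rnorm(nvox * TT, sd = cfg$fmri_voxel_noise_sd),
                        nvox, TT)
    array(out, dim = c(dim3, TT))
  })
}

#' Generate a complete synthetic study
#'
#' Builds the atlas and sub-parcellation, participant table, planted
#' components, per-subject PET maps, regional binding/ODI/grey-matter
#' tables, the density-coupled fMRI generative state (per-subject volumes
#' are produced on demand by [simulate_subject_fmri()]), latent connectivity
#' scores and clinical outcomes.  All generating quantities are stored
#' verbatim in `$truth` and never mutated by analysis stages.
#'
#' @param config a [sim_config()]
#' @return a `sim_study` list: `config`, `atlas`, `subparcellation`,
#'   `subjects`, `pet` (4-D map stack), `regional` (bp/odi/gm matrices),
#'   `truth`
#' @export
simulate_study <- function(config = sim_config()) {
  validate_sim_config(config)
  atlas <- make_atlas(config)
  sp <- subparcellate(atlas, config$n_subparcels,
                      seed = derive_seed(config$seed, 3L))
  subjects <- simulate_subjects(config)
  comps <- make_true_components(atlas, config)
  pet <- simulate_pet_maps(atlas, subjects, comps, config)
  n <- nrow(subjects)
  bp_regional <- t(vapply(seq_len(n), function(s)
    regional_means(pet$maps[, , , s], atlas), numeric(config$n_regions)))
  rownames(bp_regional) <- subjects$subject_id
  colnames(bp_regional) <- atlas$region_table$region_id
  sec <- simulate_secondary_modalities(bp_regional, atlas, config)

  # density -> coupling ground truth for the fMRI generator
  dens_z <- scale(bp_regional)                      # z across subjects, per region
  slope_s <- config$coupling_slope[as.character(subjects$group)]
  parc_region <- sp$table$region_id
  region_col <- match(parc_region, atlas$region_table$region_id)
  gain <- 1 + sweep(dens_z[, region_col, drop = FALSE], 1, slope_s, "*")
  gain <- pmax(gain, 0.1)
  K <- config$n_components_true
  affin <- matrix(0, nrow(sp$table), K + 1L)
  # global network shared by every parcel, kept weak relative to the
  # component-specific networks so regional degree differentiates spatially
  affin[, 1] <- config$fmri_global_affinity
  for (k in seq_len(K)) {
    pm <- vapply(sp$table$subparcel_id, function(p)
      mean(comps$maps[, , , k][sp$labels == p]), numeric(1))
    affin[, k + 1L] <- config$fmri_comp_affinity * pm / max(pm)
  }
  # idiosyncratic per-subject component coupling (network strength beyond
  # what density predicts) and the implied true connectivity scores: the
  # quantity dual regression measures is the component network's effective
  # amplitude in its own territory
  comp_gain <- with_seed(derive_seed(config$seed, 59L), {
    pmax(1 + config$fmri_subject_coupling_sd *
           matrix(stats::rnorm(n * K), n, K), 0.1)
  })
  terr_gain <- vapply(seq_len(K), function(k) {
    w <- affin[, k + 1L]
    as.numeric(gain %*% w) / sum(w)
  }, numeric(n))
  fscores <- apply(comp_gain * terr_gain, 2, zscore)
  colnames(fscores) <- paste0("F", seq_len(K))
  subjects <- simulate_clinical(subjects, pet$loadings, fscores, config)

  truth <- list(components = comps,
                loadings = pet$loadings,
                coupling_slope = config$coupling_slope,
                fmri = list(affinity = affin, gain = gain, density_z = dens_z,
                            comp_gain = comp_gain, territory_gain = terr_gain),
                fscores = fscores,
                clinical = attr(subjects, "clinical_truth"))
  structure(list(config = config, atlas = atlas, subparcellation = sp,
                 subjects = subjects, pet = pet,
                 regional = list(bp = bp_regional, odi = sec$odi,
                                 gm_volume = sec$gm_volume),
                 truth = truth),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat("Synthetic multimodal study\n")
  cat("  subjects:", nrow(x$subjects), "(",
      paste(sprintf("%s=%d", names(x$config$group_sizes), x$config$group_sizes),
            collapse = ", "), ")\n")
  cat("  atlas:", x$config$n_regions, "regions /",
      nrow(x$subparcellation$table), "sub-parcels on",
      paste(x$config$grid_shape, collapse = "x"), "grid\n")
  cat("  planted PET components:", x$config$n_components_true,
      "| fMRI volumes:", x$config$n_timepoints, "at TR", x$config$tr, "s\n")
  invisible(x)
}

#' Simulate long-format regional data from the crossed-effects generative
#' model
#'
#' Direct regional-level counterpart of the image pipeline: weighted degree
#' is generated from standardised regional binding with crossed random
#' intercepts for subject and region, a region-varying binding slope, and
#' covariate effects.  Used for parameter-recovery testing of the mixed
#' models without the cost of image synthesis.  The implied standardised
#' betas (generative slope divided by the marginal outcome SD) are recorded
#' in the `"truth"` attribute.
#'
#' @param group_sizes named group counts
#' @param n_regions number of regions
#' @param slope named per-group binding-to-degree slope (raw scale)
#' @param slope_region_sd SD of region-specific slope deviations
#' @param subject_sd,region_sd random-intercept SDs
#' @param resid_sd residual SD
#' @param beta_age,beta_dvars,beta_cortical covariate effects
#' @param frac_cortical fraction of regions flagged cortical
#' @param seed integer seed
#' @return long data.frame (one row per subject x region) with attribute
#'   `"truth"`
#' @export
simulate_regional_data <- function(group_sizes = c(Control = 24L, PSP = 29L,
                                                   CBS = 16L, bvFTD = 10L),
                                   n_regions = 30L,
                                   slope = c(Control = 0, PSP = 0.2,
                                             CBS = 0.2, bvFTD = 0.2),
                                   slope_region_sd = 0.1,
                                   subject_sd = 0.3, region_sd = 0.3,
                                   resid_sd = 0.7,
                                   beta_age = -0.05, beta_dvars = -0.1,
                                   beta_cortical = 0.3,
                                   frac_cortical = 0.7,
                                   seed = 1L) {
  groups <- factor(rep(names(group_sizes), group_sizes),
                   levels = names(group_sizes))
  n <- length(groups)
  with_seed(seed, {
    age_z <- stats::rnorm(n)
    dvars_z <- stats::rnorm(n)
    sex <- factor(sample(c("F", "M"), n, replace = TRUE), levels = c("F", "M"))
    u <- stats::rnorm(n, sd = subject_sd)
    v <- stats::rnorm(n_regions, sd = region_sd)
    delta <- stats::rnorm(n_regions, sd = slope_region_sd)
    is_cort <- seq_len(n_regions) <= round(frac_cortical * n_regions)
    rows <- expand.grid(subject = seq_len(n), region = seq_len(n_regions))
    bp_z <- stats::rnorm(nrow(rows))
    g <- groups[rows$subject]
    sl <- slope[as.character(g)] + delta[rows$region]
    wd <- u[rows$subject] + v[rows$region] + sl * bp_z +
      beta_age * age_z[rows$subject] + beta_dvars * dvars_z[rows$subject] +
      beta_cortical * is_cort[rows$region] +
      stats::rnorm(nrow(rows), sd = resid_sd)
    dat <- data.frame(subject_id = sprintf("sub-%03d", rows$subject),
                      region_id = rows$region,
                      weighted_degree = wd, bp_nd = bp_z,
                      odi = NA_real_, gm_volume = NA_real_,
                      is_cortical = is_cort[rows$region],
                      group = g, age = age_z, sex = sex[rows$subject],
                      mean_dvars = dvars_z[rows$subject], tiv = NA_real_)
    f <- mean(is_cort)
    marg_var <- function(b) subject_sd^2 + region_sd^2 +
      (b^2 + slope_region_sd^2) + beta_age^2 + beta_dvars^2 +
      beta_cortical^2 * f * (1 - f) + resid_sd^2
    pat <- names(group_sizes)[-1]
    # cohort-level implied standardised slopes (patients share one slope here)
    b_pat <- unname(slope[pat[1]])
    b_ctl <- unname(slope["Control"])
    w <- group_sizes[pat] / sum(group_sizes[pat])
    truth <- list(
      slope = slope, slope_region_sd = slope_region_sd,
      implied_std_beta = c(
        patients = b_pat / sqrt(marg_var(b_pat)),
        controls = b_ctl / sqrt(marg_var(b_ctl))))
    attr(dat, "truth") <- truth
    dat
  })
}
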