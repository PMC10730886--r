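# Dual regression of PET spatial components into individual 4-D fMRI:
# stage 1 gives per-component time courses, stage 2 gives subject-specific
# connectivity beta maps and residual-noise maps; connectivity scores are
# noise-normalised means inside control-defined or component-territory masks.

flatten_fmri <- function(fmri_4d, mask) {
  d <- dim(fmri_4d)
  if (length(d) != 4L || !identical(d[1:3], dim(mask)))
    stop("grid mismatch between fMRI volume and mask")
  matrix(fmri_4d, prod(d[1:3]), d[4])[as.logical(mask), , drop = FALSE]
}

#' Stage 1: component time courses
#'
#' For each volume, ordinary least squares of the in-mask voxel vector on
#' the K component maps plus an intercept (which absorbs the global
#' signal); row t of the result holds the K spatial-regression coefficients
#' at time t.
#'
#' @param fmri_4d 4-D array on the component grid
#' @param set a `component_set` (or K x voxels matrix with a `mask`
#'   attribute)
#' @return timepoints x K matrix
#' @export
stage1_timecourses <- function(fmri_4d, set) {
  S <- component_matrix(set)
  Y <- flatten_fmri(fmri_4d, set$mask)
  if (nrow(S) >= nrow(Y)) stop("more components than in-mask voxels")
  G <- cbind(1, t(S))
  sv <- svd(scale(t(S), center = TRUE, scale = FALSE), nu = 0, nv = 0)$d
  if (sv[1] / max(sv[length(sv)], .Machine$double.xmin) > 1e8)
    stop("collinear spatial maps (condition number > 1e8)")
  beta <- qr.coef(qr(G), Y)
  tc <- t(beta[-1, , drop = FALSE])
  colnames(tc) <- rownames(S)
  tc
}

#' Stage 2: subject connectivity maps and residual noise
#'
#' Per in-mask voxel, least squares of its time series on the stage-1 time
#' courses plus an intercept; returns the beta map per component and the
#' df-corrected residual SD per voxel.
#'
#' @param fmri_4d 4-D array
#' @param timecourses timepoints x K matrix from [stage1_timecourses()]
#' @param mask 3-D logical analysis mask
#' @return list: `beta` (K x voxels), `noise_sd` (voxels)
#' @export
stage2_maps <- function(fmri_4d, timecourses, mask) {
  Y <- flatten_fmri(fmri_4d, mask)
  TT <- ncol(Y); K <- ncol(timecourses)
  if (TT < K + 2L) stop("need at least K + 2 timepoints")
  if (any(apply(timecourses, 2, stats::sd) == 0))
    stop("constant time course")
  D <- cbind(1, timecourses)
  qd <- qr(D)
  if (qd$rank < ncol(D)) stop("collinear time courses (duplicate columns?)")
  beta <- qr.coef(qd, t(Y))
  res <- t(Y) - D %*% beta
  noise_sd <- sqrt(colSums(res^2) / (TT - K - 1L))
  list(beta = beta[-1, , drop = FALSE], noise_sd = noise_sd)
}

#' Dual regression of a component set into one subject's fMRI
#'
#' Runs both stages and forms the noise-normalised connectivity map per
#' component: beta divided by the voxel's residual SD (default) or by the
#' coefficient standard error.
#'
#' By default the stage-1 time courses are variance-normalised before the
#' stage-2 regression (`des_norm`).  Without normalisation the stage-2
#' coefficient divides by the time-course variance and the network's
#' amplitude cancels out of the beta map; with it, betas carry the
#' subject's network amplitude, which is what the connectivity scores are
#' meant to measure.
#'
#' @param fmri_4d 4-D array
#' @param set a `component_set`
#' @param normalise `"sd"` (beta / residual SD) or `"se"` (beta / SE)
#' @param des_norm variance-normalise stage-1 time courses before stage 2
#' @return a `dual_regression_result`: `timecourses`, `beta`, `noise_sd`,
#'   `normalised` (K x voxels), `mask`
#' @export
dual_regression <- function(fmri_4d, set, normalise = c("sd", "se"),
                            des_norm = TRUE) {
  normalise <- match.arg(normalise)
  tc <- stage1_timecourses(fmri_4d, set)
  tc2 <- if (des_norm) scale(tc, center = FALSE,
                             scale = apply(tc, 2, stats::sd)) else tc
  s2 <- stage2_maps(fmri_4d, tc2, set$mask)
  if (normalise == "sd") {
    nrm <- sweep(s2$beta, 2, pmax(s2$noise_sd, 1e-12), "/")
  } else {
    D <- cbind(1, tc2)
    cjj <- diag(solve(crossprod(D)))[-1]
    se <- outer(sqrt(cjj), pmax(s2$noise_sd, 1e-12))
    nrm <- s2$beta / se
  }
  structure(list(timecourses = tc, beta = s2$beta, noise_sd = s2$noise_sd,
                 normalised = nrm, mask = set$mask, normalise = normalise),
            class = "dual_regression_result")
}

#' Control-defined connectivity mask for one component
#'
#' One-sample sign-flip permutation test on the control subjects'
#' normalised connectivity maps, with familywise error control by the
#' max-statistic across voxels; the mask keeps voxels whose FWE p-value is
#' at or below `alpha` (positive, one-sided).
#'
#' @param control_maps controls x voxels matrix of normalised connectivity
#'   values (>= 5 controls)
#' @param alpha familywise significance level
#' @param n_perm sign-flip permutations
#' @param seed integer seed
#' @return logical voxel vector
#' @export
control_connectivity_mask <- function(control_maps, alpha = 0.01,
                                      n_perm = 1000L, seed = 1L) {
  n <- nrow(control_maps)
  if (n < 5L) stop("need at least 5 controls")
  ss <- colSums(control_maps^2)
  t_of <- function(m) {
    v <- (ss - n * m^2) / (n - 1)
    m / sqrt(pmax(v, 1e-300) / n)
  }
  t_obs <- t_of(colMeans(control_maps))
  mx <- with_seed(derive_seed(seed, 83L), {
    S <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), n, n_perm)
    M <- crossprod(control_maps, S) / n          # voxels x perms
    apply(t_of(M), 2, max)
  })
  p <- vapply(t_obs, function(t) (1 + sum(mx >= t)) / (n_perm + 1), numeric(1))
  p <= alpha
}

#' Component territory mask
#'
#' Voxels whose component-map value exceeds the given percentile of in-mask
#' values; invariant to monotone transforms of the map.
#'
#' @param map_values in-mask component map values
#' @param percentile percentile threshold (97.5 by default)
#' @return logical voxel vector
#' @export
component_territory_mask <- function(map_values, percentile = 97.5) {
  map_values > stats::quantile(map_values, percentile / 100, type = 7,
                               names = FALSE)
}

#' Noise-normalised connectivity score
#'
#' Mean of the normalised connectivity map over a voxel mask.  The
#' outside-territory variant uses `control_mask & !territory_mask`.
#'
#' @param normalised_map in-mask normalised connectivity values
#' @param mask logical voxel vector
#' @return scalar score
#' @export
connectivity_score <- function(normalised_map, mask) {
  if (!any(mask)) stop("empty score mask")
  mean(normalised_map[mask])
}

#' Voxelwise association of connectivity with component loadings
#'
#' Per-voxel Freedman-Lane permutation GLM of the normalised connectivity
#' maps on the loadings with nuisance covariates, one-sided (positive
#' association), with familywise error control by the max-statistic across
#' voxels.
#'
#' @param normalised_maps subjects x voxels matrix
#' @param loadings per-subject component loadings
#' @param covariates data.frame of nuisance covariates (or NULL)
#' @param n_perm permutations (>= 100)
#' @param seed integer seed
#' @return list: `t` (per voxel), `p_fwe` (per voxel), `threshold_05`
#' @export
voxelwise_loading_association <- function(normalised_maps, loadings,
                                          covariates = NULL, n_perm = 500L,
                                          seed = 1L) {
  if (n_perm < 100L) stop("need n_perm >= 100")
  n <- nrow(normalised_maps)
  perm <- make_permutations(n, n_perm, seed = seed)
  Z <- build_covariate_design(covariates, n)
  fl <- fl_engine(normalised_maps, loadings, Z, perm)
  mx <- apply(fl$t_null, 1, max)
  p_fwe <- vapply(fl$t, function(t) (1 + sum(mx >= t)) / (n_perm + 1),
                  numeric(1))
  list(t = fl$t, p_fwe = p_fwe,
       threshold_05 = stats::quantile(mx, 0.95, names = FALSE))
}
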