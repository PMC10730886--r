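# Control-referenced z-scoring, spatial correlation with
# autocorrelation-preserving surrogate nulls, FDR adjustment, Grubbs test.

#' Standardise patient regional values to control data
#'
#' `z = (x - mean_control) / sd_control` per region, with the control SD on
#' the n-1 denominator.
#'
#' @param patients patients x regions matrix
#' @param controls controls x regions matrix (>= 3 controls)
#' @return patients x regions matrix of z-scores
#' @export
control_zscores <- function(patients, controls) {
  if (ncol(patients) != ncol(controls)) stop("region sets differ")
  if (nrow(controls) < 3L) stop("need at least 3 controls per region")
  mu <- colMeans(controls)
  sdv <- apply(controls, 2, stats::sd)
  if (any(sdv == 0)) {
    bad <- colnames(controls)[sdv == 0]
    if (is.null(bad)) bad <- which(sdv == 0)
    stop("zero control SD in region(s): ", paste(bad, collapse = ", "))
  }
  sweep(sweep(patients, 2, mu), 2, sdv, "/")
}

# Empirical semivariogram over log-spaced distance bins.
# Returns bin assignment machinery so ensembles reuse it.
variogram_setup <- function(centroids, n_bins = 15L) {
  D <- as.matrix(stats::dist(centroids))
  ut <- which(upper.tri(D), arr.ind = TRUE)
  d <- D[upper.tri(D)]
  brk <- exp(seq(log(max(min(d), 1e-8) * 0.999), log(max(d) * 1.001),
                 length.out = n_bins + 1L))
  bin <- cut(d, breaks = brk, include.lowest = TRUE, labels = FALSE)
  list(i = ut[, 1], j = ut[, 2], bin = bin, n_bins = n_bins, D = D)
}

# Semivariogram of one or many maps (columns) under a precomputed setup.
variogram_eval <- function(vs, X) {
  X <- as.matrix(X)
  dif2 <- 0.5 * (X[vs$i, , drop = FALSE] - X[vs$j, , drop = FALSE])^2
  g <- rowsum(dif2, vs$bin)
  cnt <- as.vector(rowsum(rep(1, length(vs$bin)), vs$bin))
  out <- matrix(NA_real_, vs$n_bins, ncol(X))
  out[as.integer(rownames(g)), ] <- g / cnt
  out
}

# k-nearest-neighbour smoothing matrices (rows normalised), for each
# candidate k with two weight kernels: inverse distance and a Gaussian with
# bandwidth set to the k-th neighbour distance (smoother short-range
# behaviour).
knn_smoothers <- function(D, ks = c(3L, 5L, 10L, 20L)) {
  n <- nrow(D)
  ks <- ks[ks < n]
  out <- list()
  for (k in ks) {
    Wi <- Wg <- matrix(0, n, n)
    for (i in seq_len(n)) {
      ord <- order(D[i, ])
      nb <- setdiff(ord, i)[seq_len(k)]
      d <- pmax(D[i, nb], 1e-8)
      wi <- 1 / d
      Wi[i, nb] <- wi / sum(wi)
      wg <- exp(-0.5 * (d / max(d))^2)
      Wg[i, nb] <- wg / sum(wg)
    }
    out[[length(out) + 1L]] <- Wi
    out[[length(out) + 1L]] <- Wg
  }
  out
}

#' Spatial-autocorrelation-preserving surrogate ensemble
#'
#' Variogram-matching surrogates of a regional map: values are permuted,
#' smoothed by a distance-weighted average over k nearest neighbours for
#' each candidate k, then rescaled by regressing the target's empirical
#' semivariogram on the smoothed map's over log-spaced distance bins
#' (`gamma_t ~ alpha gamma_s + beta`; the surrogate is
#' `sqrt(alpha) * smoothed + sqrt(beta) * white noise`, since independent
#' noise of variance beta raises every semivariance bin by beta).  The best
#' candidate smoothing scale is kept per surrogate.
#'
#' @param map per-region values (non-constant)
#' @param centroids regions x 3 coordinate matrix
#' @param n_null number of surrogates
#' @param seed integer seed
#' @param ks candidate neighbour counts
#' @param n_bins variogram distance bins
#' @return a `surrogate_ensemble`: list with `surrogates` (n_null x regions
#'   matrix), `variogram_target`, `variogram_fit` (mean per-bin relative
#'   deviation), and generator parameters
#' @export
surrogate_maps <- function(map, centroids, n_null = 1000L, seed = 1L,
                           ks = c(3L, 5L, 10L, 20L), n_bins = 15L) {
  n <- length(map)
  if (n < 10L) stop("need at least 10 regions")
  if (stats::sd(map) == 0) stop("constant map: variogram degenerate")
  if (any(!is.finite(centroids))) stop("centroids must be finite")
  vs <- variogram_setup(centroids, n_bins)
  g_t <- variogram_eval(vs, matrix(map))[, 1]
  # sparse distance bins carry uninformative semivariance estimates and are
  # excluded from fitting and assessment (standard empirical-variogram
  # practice)
  bin_n <- tabulate(vs$bin, n_bins)
  ok_bins <- which(is.finite(g_t) & g_t > 0 & bin_n >= 10L)
  if (length(ok_bins) < 3L) ok_bins <- which(is.finite(g_t) & g_t > 0)
  wts <- bin_n[ok_bins] / sum(bin_n[ok_bins])
  Ws <- knn_smoothers(vs$D, ks)
  perm <- make_permutations(n, n_null, seed = seed)
  P <- matrix(map[perm], n, n_null)
  best <- matrix(NA_real_, n, n_null)
  best_obj <- rep(Inf, n_null)
  mu_t <- mean(map)
  noise <- with_seed(derive_seed(seed, 97L),
                     matrix(stats::rnorm(n * n_null), n, n_null))
  gt_ok <- g_t[ok_bins]
  for (W in Ws) {
    S <- W %*% P
    g_s <- variogram_eval(vs, S)[ok_bins, , drop = FALSE]
    # per surrogate, regress the target variogram on the smoothed-map
    # variogram (weighted by bin pair count): gamma_t ~ alpha * gamma_s +
    # beta.  Adding independent white noise of variance beta raises every
    # semivariance bin by beta, so the rescaled surrogate
    # sqrt(alpha) * smoothed + sqrt(beta) * z reproduces the fitted
    # variogram.
    sx <- colSums(g_s * wts); sy <- sum(gt_ok * wts)
    sxx <- colSums(g_s^2 * wts); sxy <- colSums(g_s * gt_ok * wts)
    alpha <- (sxy - sx * sy) / pmax(sxx - sx^2, 1e-300)
    alpha <- pmax(alpha, 0)
    beta <- pmax(sy - alpha * sx, 0)
    resid <- sweep(sweep(g_s, 2, alpha, "*"), 2, beta, "+") - gt_ok
    obj <- colSums(resid^2 * wts)
    take <- obj < best_obj
    if (any(take)) {
      Sr <- sweep(S[, take, drop = FALSE], 2, sqrt(alpha[take]), "*") +
        sweep(noise[, take, drop = FALSE], 2, sqrt(beta[take]), "*")
      Sr <- sweep(Sr, 2, mu_t - colMeans(Sr), "+")
      best[, take] <- Sr
      best_obj[take] <- obj[take]
    }
  }
  # generator self-check: pair-count-weighted relative deviation of the
  # ensemble-mean semivariogram from the target's, over informative bins
  g_b <- rowMeans(variogram_eval(vs, best))
  fit <- sum(wts * abs(g_b[ok_bins] - gt_ok) / gt_ok)
  structure(list(surrogates = t(best), variogram_target = g_t,
                 variogram_fit = fit,
                 params = list(n_bins = n_bins, ks = ks, seed = seed)),
            class = "surrogate_ensemble")
}

#' Spatial correlation test with surrogate nulls
#'
#' Pearson correlation between two regional maps, with a two-sided
#' permutation p-value from spatial-autocorrelation-preserving surrogates of
#' `map_b` (see [surrogate_maps()]); `p = (1 + #{|r_null| >= |r_obs|}) /
#' (n_null + 1)`.
#'
#' @param map_a,map_b per-region values
#' @param centroids regions x 3 coordinate matrix
#' @param n_null number of surrogate maps
#' @param seed integer seed
#' @return list: `r`, `p`, `ensemble`, `r_null`
#' @export
spatial_correlation_test <- function(map_a, map_b, centroids, n_null = 1000L,
                                     seed = 1L) {
  if (length(map_a) != length(map_b)) stop("maps differ in length")
  if (stats::sd(map_a) == 0 || stats::sd(map_b) == 0)
    stop("constant map: variogram degenerate")
  ens <- surrogate_maps(map_b, centroids, n_null = n_null, seed = seed)
  r <- stats::cor(map_a, map_b)
  r_null <- as.numeric(stats::cor(map_a, t(ens$surrogates)))
  p <- (1 + sum(abs(r_null) >= abs(r))) / (n_null + 1)
  list(r = r, p = p, ensemble = ens, r_null = r_null)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, monotone-enforced and capped at 1.
#'
#' @param p_values vector of p-values in `[0, 1]`
#' @return adjusted vector
#' @export
fdr_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values outside [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Grubbs test for a single outlier
#'
#' `G = max |x - mean| / sd` with the sample (n-1) SD; the two-sided
#' p-value uses the standard t-based formula `p = 2n P(T_{n-2} > t)` with
#' `t^2 = n (n-2) G^2 / ((n-1)^2 - n G^2)`, capped at 1.
#'
#' @param values numeric vector, n >= 3
#' @return list: `G`, `p`, `index` of the most extreme value
#' @export
grubbs_test <- function(values) {
  n <- length(values)
  if (n < 3L) stop("Grubbs test needs n >= 3")
  s <- stats::sd(values)
  if (s == 0) stop("zero SD: Grubbs statistic undefined")
  dev <- abs(values - mean(values))
  idx <- which.max(dev)
  G <- dev[idx] / s
  denom <- (n - 1)^2 - n * G^2
  if (denom <= 0) {
    p <- 0
  } else {
    t <- sqrt(n * (n - 2) * G^2 / denom)
    p <- min(1, 2 * n * stats::pt(t, df = n - 2, lower.tail = FALSE))
  }
  list(G = unname(G), p = p, index = idx)
}
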