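# Source-based synaptometry: spatial ICA over concatenated subject PET
# binding maps, optimal component matching, and component quality control
# (outlier robustness, group-difference screen, model-order stability).

#' Positive-everywhere analysis mask
#'
#' Voxels where every subject's value is finite and strictly positive.
#'
#' @param subject_maps 4-D array (last dimension = subject)
#' @return 3-D logical mask
#' @export
build_analysis_mask <- function(subject_maps) {
  d <- dim(subject_maps)
  X <- matrix(subject_maps, prod(d[1:3]), d[4])
  ok <- rowSums(!is.finite(X) | X <= 0) == 0L
  if (!any(ok)) stop("empty analysis mask: no voxel positive in all subjects")
  array(ok, dim = d[1:3])
}

#' Spatial ICA of subject binding maps
#'
#' Voxelwise demeaning across subjects, PCA reduction to `model_order`, then
#' fixed-point ICA with the logcosh contrast and symmetric decorrelation
#' (tolerance 1e-6, up to 1000 iterations, deterministic restart schedule
#' from `seed`, at most 5 restarts).  Component maps are variance-normalised
#' and sign-aligned to positive skewness; loadings are the least-squares
#' projection of the subject maps onto the maps.
#'
#' @param subject_maps 4-D array (last dimension = subject)
#' @param mask 3-D logical analysis mask (see [build_analysis_mask()])
#' @param model_order number of components (<= subjects)
#' @param seed integer seed
#' @return a `component_set`: `maps` (K x in-mask voxels), `loadings`
#'   (subjects x K), `mask`, `dim`, `model_order`, `seed`, `qc` (NULL until
#'   [component_qc()])
#' @export
run_sbs <- function(subject_maps, mask, model_order, seed = 1L) {
  d <- dim(subject_maps)
  n <- d[4]
  if (n < model_order) stop("need at least as many subjects as components")
  if (!any(mask)) stop("mask is empty")
  X <- matrix(subject_maps, prod(d[1:3]), n)[as.logical(mask), , drop = FALSE]
  X <- t(X)                              # subjects x voxels
  X <- sweep(X, 2, colMeans(X))          # voxelwise demean across subjects
  V <- ncol(X)
  sv <- svd(X, nu = model_order, nv = model_order)
  Z <- sqrt(V) * t(sv$v)                 # K x V, rows ~ unit variance, white
  W <- fastica_symm(Z, seed = seed)
  S <- W %*% Z                           # K x V source maps (unit 2nd moment)
  S <- S / apply(S, 1, stats::sd)        # variance-normalised maps
  # orient each map to non-negative skewness
  sk <- rowMeans(S^3)
  flip <- sk < 0
  S[flip, ] <- -S[flip, ]
  A <- X %*% t(S) %*% solve(S %*% t(S))  # loadings: least squares onto maps
  if (any(!is.finite(A))) stop("non-finite loadings")
  colnames(A) <- rownames(S) <- paste0("C", seq_len(model_order))
  structure(list(maps = S, loadings = A, mask = mask, dim = d[1:3],
                 model_order = model_order, seed = seed,
                 pca_d = sv$d[seq_len(model_order)], qc = NULL),
            class = "component_set")
}

# Symmetric fixed-point ICA (logcosh) on whitened K x V data.
#
# When the model order exceeds the number of non-Gaussian sources the extra
# directions span a Gaussian subspace with no logcosh fixed point, so the
# update can oscillate there indefinitely while the signal components are
# long settled.  After the iteration cap the best iterate is therefore
# accepted if its convergence criterion is below `loose_tol`; only a run
# that never gets that close restarts.
fastica_symm <- function(Z, seed, tol = 1e-6, max_iter = 1000L,
                         restarts = 5L, loose_tol = 0.05) {
  K <- nrow(Z); V <- ncol(Z)
  for (r in seq_len(restarts)) {
    W <- with_seed(derive_seed(seed, 71L, r), {
      M <- matrix(stats::rnorm(K * K), K, K)
      sym_decorrelate(M)
    })
    best <- Inf; best_W <- W
    for (it in seq_len(max_iter)) {
      U <- W %*% Z
      G <- tanh(U)
      Gp <- 1 - G^2
      W_new <- G %*% t(Z) / V - diag(rowMeans(Gp), K) %*% W
      W_new <- sym_decorrelate(W_new)
      delta <- max(abs(abs(diag(W_new %*% t(W))) - 1))
      W <- W_new
      if (delta < best) { best <- delta; best_W <- W }
      if (delta < tol) return(W)
    }
    if (best < loose_tol) return(best_W)
  }
  stop("ICA failed to converge after ", restarts, " restarts")
}

sym_decorrelate <- function(W) {
  e <- eigen(W %*% t(W), symmetric = TRUE)
  e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12)), nrow(W)) %*%
    t(e$vectors) %*% W
}

#' @export
print.component_set <- function(x, ...) {
  cat("Spatial component set: order", x$model_order, "|",
      nrow(x$loadings), "subjects |", sum(x$mask), "in-mask voxels\n")
  if (!is.null(x$qc)) {
    cat("  QC: ", sum(x$qc$selected), "of", nrow(x$qc),
        "components selected\n")
  }
  invisible(x)
}

#' Reconstruct a component map as a 3-D array
#'
#' @param set a `component_set`
#' @param k component index
#' @return 3-D array (zero outside the analysis mask)
#' @export
component_map_array <- function(set, k) {
  a <- array(0, dim = set$dim)
  a[set$mask] <- set$maps[k, ]
  a
}

component_matrix <- function(x) {
  if (inherits(x, "component_set")) x$maps else as.matrix(x)
}

#' Optimal one-to-one matching of two component sets
#'
#' Hungarian assignment maximising the total absolute spatial
#' cross-correlation between component maps.
#'
#' @param set_a,set_b `component_set` objects (or K x voxels matrices) on
#'   the same voxel set
#' @return data.frame: `a`, `b`, `abs_cor`; attribute `"mean_abs_cor"`
#' @export
match_components <- function(set_a, set_b) {
  A <- component_matrix(set_a); B <- component_matrix(set_b)
  if (nrow(A) == 0L || nrow(B) == 0L) stop("empty component set")
  if (ncol(A) != ncol(B)) stop("component sets live on different voxel sets")
  C <- abs(stats::cor(t(A), t(B)))
  swap <- nrow(C) > ncol(C)
  if (swap) C <- t(C)
  idx <- hungarian_assign(1 - C)
  out <- data.frame(a = if (swap) idx else seq_len(nrow(C)),
                    b = if (swap) seq_len(nrow(C)) else idx,
                    abs_cor = C[cbind(seq_len(nrow(C)), idx)])
  out <- out[order(out$a), ]
  rownames(out) <- NULL
  attr(out, "mean_abs_cor") <- mean(out$abs_cor)
  out
}

#' Component quality control
#'
#' Annotates each component with the screening rules used for source-based
#' synaptometry: (a) outlier robustness — Grubbs test on the loadings; when
#' the extreme subject is significant at `alpha` the ICA is re-run without
#' that subject and the component is flagged outlier-driven if no re-run
#' component matches at `|cor| >= match_threshold`; (b) group-difference
#' screen — covariate-adjusted one-way model on loadings with BH-FDR across
#' components, retained when FDR p < 0.05; (c) stability — mean matched
#' `|cor|` across alternative model orders; (d) artefact — more than half of
#' the component's supra-97.5th-percentile voxels fall inside a
#' user-supplied exclusion mask of artefact-prone territory.
#'
#' @param set a `component_set`
#' @param subject_maps the 4-D map stack the set was estimated from
#' @param subjects participant table (`group`, `age`, `sex`)
#' @param alt_orders integer model orders for the stability check (all >= 2),
#'   or NULL to skip
#' @param exclusion_mask optional 3-D logical mask of artefact-prone voxels
#' @param alpha Grubbs significance level
#' @param match_threshold re-run match threshold
#' @return the `component_set` with a `qc` data.frame; `selected` marks
#'   components that are not artefact, not outlier-driven, and pass the
#'   group screen
#' @export
component_qc <- function(set, subject_maps, subjects, alt_orders = NULL,
                         exclusion_mask = NULL, alpha = 0.05,
                         match_threshold = 0.8) {
  if (!is.null(alt_orders) && any(alt_orders < 2L))
    stop("alternative model orders must be >= 2")
  K <- set$model_order
  n <- nrow(set$loadings)
  g_G <- g_p <- num_stab <- rep(NA_real_, K)
  out_subj <- rep(NA_integer_, K)
  outlier_driven <- artifact <- rep(FALSE, K)
  rerun_cache <- list()
  for (k in seq_len(K)) {
    gt <- grubbs_test(set$loadings[, k])
    g_G[k] <- gt$G; g_p[k] <- gt$p
    if (gt$p < alpha) {
      out_subj[k] <- gt$index
      key <- as.character(gt$index)
      if (is.null(rerun_cache[[key]])) {
        sub_maps <- subject_maps[, , , -gt$index, drop = FALSE]
        rerun_cache[[key]] <- run_sbs(sub_maps, set$mask, set$model_order,
                                      seed = set$seed)
      }
      mm <- abs(stats::cor(set$maps[k, ], t(rerun_cache[[key]]$maps)))
      outlier_driven[k] <- max(mm) < match_threshold
    }
    if (!is.null(exclusion_mask)) {
      thr <- stats::quantile(set$maps[k, ], 0.975, type = 7)
      top <- set$maps[k, ] > thr
      excl <- exclusion_mask[set$mask]
      artifact[k] <- mean(excl[top]) > 0.5
    }
  }
  # covariate-adjusted group screen
  grp_p <- vapply(seq_len(K), function(k) {
    dat <- data.frame(y = set$loadings[, k], group = factor(subjects$group),
                      age = subjects$age, sex = subjects$sex)
    full <- stats::lm(y ~ group + age + sex, dat)
    red <- stats::lm(y ~ age + sex, dat)
    stats::anova(red, full)$`Pr(>F)`[2]
  }, numeric(1))
  grp_fdr <- fdr_adjust(grp_p)
  if (!is.null(alt_orders)) {
    stab <- matrix(NA_real_, K, length(alt_orders))
    for (j in seq_along(alt_orders)) {
      alt <- run_sbs(subject_maps, set$mask, alt_orders[j], seed = set$seed)
      C <- abs(stats::cor(t(set$maps), t(alt$maps)))
      # each reference component takes its best alternative-order match
      stab[, j] <- apply(C, 1, max)
    }
    num_stab <- rowMeans(stab)
  }
  qc <- data.frame(component = colnames(set$loadings),
                   grubbs_G = g_G, grubbs_p = g_p,
                   outlier_subject = out_subj, outlier_driven = outlier_driven,
                   group_p = grp_p, group_p_fdr = grp_fdr,
                   group_diff = grp_fdr < 0.05,
                   stability = num_stab, artifact = artifact)
  qc$selected <- !qc$artifact & !qc$outlier_driven & qc$group_diff
  set$qc <- qc
  set
}
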