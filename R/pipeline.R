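# End-to-end analysis of a (synthetic or real-structured) study: weighted
# degree, control-referenced spatial correlation, crossed mixed models,
# source-based synaptometry, dual regression with connectivity scores, and
# severity model selection.

#' Assemble long-format regional data for the mixed models
#'
#' @param study a `sim_study`
#' @param wd_regional subjects x regions weighted-degree matrix
#' @return long data.frame, one row per subject x region
#' @export
build_long_data <- function(study, wd_regional) {
  subj <- study$subjects
  rt <- study$atlas$region_table
  n <- nrow(subj); R <- nrow(rt)
  idx <- expand.grid(s = seq_len(n), r = seq_len(R))
  data.frame(subject_id = subj$subject_id[idx$s],
             region_id = rt$region_id[idx$r],
             weighted_degree = wd_regional[cbind(idx$s, idx$r)],
             bp_nd = study$regional$bp[cbind(idx$s, idx$r)],
             odi = study$regional$odi[cbind(idx$s, idx$r)],
             gm_volume = study$regional$gm_volume[cbind(idx$s, idx$r)],
             is_cortical = rt$is_cortical[idx$r],
             group = subj$group[idx$s], age = subj$age[idx$s],
             sex = subj$sex[idx$s], mean_dvars = subj$mean_dvars[idx$s],
             tiv = subj$tiv[idx$s])
}

#' Run the full multimodal pipeline on a study
#'
#' Stages: (1) per-subject fMRI synthesis, parcel time series, Fisher-z
#' connectivity, weighted degree aggregated to regions; (2) patient z-maps
#' standardised to controls and their spatial correlation with the binding
#' z-map under surrogate nulls (cortical regions); (3) crossed mixed models
#' for patients, controls and all participants, with the random-slope LRT;
#' (4) source-based synaptometry with component QC; (5) dual regression of
#' the selected components into every subject's fMRI, with control-defined
#' connectivity masks and inside/outside-territory scores; (6) stepwise-BIC
#' severity models for the cognitive and motor outcomes, inside and outside
#' scores.
#'
#' @param study a `sim_study`
#' @param model_order ICA model order
#' @param n_null surrogate maps for the spatial correlation test
#' @param n_perm permutations for the control connectivity masks
#' @param alt_orders model orders for the component stability check (NULL
#'   skips it)
#' @param territory_percentile component territory threshold
#' @param progress print stage progress
#' @return a `synaptoconn_pipeline` list; see `$scores` (per subject and
#'   component, inside/outside) and `$report` (key statistics)
#' @export
run_pipeline <- function(study, model_order = 10L, n_null = 1000L,
                         n_perm = 500L, alt_orders = NULL,
                         territory_percentile = 97.5, progress = FALSE) {
  say <- function(...) if (progress) message(...)
  cfg <- study$config
  subj <- study$subjects
  n <- nrow(subj)
  is_ctl <- subj$group == "Control"
  sp <- study$subparcellation

  say("stage 1: connectivity and weighted degree")
  reg_ids <- as.character(study$atlas$region_table$region_id)
  wd <- matrix(NA_real_, n, length(reg_ids),
               dimnames = list(subj$subject_id, reg_ids))
  say("stage 4 prep: PET analysis mask")
  mask <- build_analysis_mask(study$pet$maps)
  K <- NULL
  dr_norm <- NULL  # subjects x voxels per component, filled after ICA
  set <- NULL
  # single pass over subjects: one fMRI synthesis feeds both the degree
  # computation and (second pass) dual regression; volumes are regenerated
  # rather than stored to keep memory flat
  for (s in seq_len(n)) {
    vol <- simulate_subject_fmri(study, s, voxelwise = TRUE)
    ts <- parcel_timeseries(vol, sp)
    deg <- weighted_degree(fisher_connectivity(ts))
    rv <- degree_to_regions(deg, sp)
    wd[s, names(rv)] <- rv
  }

  say("stage 2: control z-maps and spatial correlation")
  cort <- study$atlas$region_table$is_cortical
  if (sum(cort) < 10L) cort <- rep(TRUE, length(cort))  # tiny-atlas fallback
  z_wd <- control_zscores(wd[!is_ctl, , drop = FALSE],
                          wd[is_ctl, , drop = FALSE])
  z_bp <- control_zscores(study$regional$bp[!is_ctl, , drop = FALSE],
                          study$regional$bp[is_ctl, , drop = FALSE])
  cent <- region_centroids(study$atlas)
  sct <- spatial_correlation_test(colMeans(z_bp[, cort, drop = FALSE]),
                                  colMeans(z_wd[, cort, drop = FALSE]),
                                  cent[cort, , drop = FALSE],
                                  n_null = n_null,
                                  seed = derive_seed(cfg$seed, 101L))

  say("stage 3: crossed mixed models")
  long <- build_long_data(study, wd)
  lmm_pat <- fit_density_degree_lmm(long, "patients")
  lmm_ctl <- fit_density_degree_lmm(long, "controls", random_slope = FALSE)
  lmm_all <- fit_density_degree_lmm(long, "all")
  lmm_pat_noslope <- fit_density_degree_lmm(long, "patients",
                                            random_slope = FALSE)
  lrt <- lrt_random_slope(lmm_pat_noslope, lmm_pat)

  say("stage 4: source-based synaptometry")
  set <- run_sbs(study$pet$maps, mask, model_order,
                 seed = derive_seed(cfg$seed, 103L))
  set <- component_qc(set, study$pet$maps, subj, alt_orders = alt_orders)
  sel <- which(set$qc$selected)
  if (!length(sel)) {
    warning("no component passed QC; carrying all components forward")
    sel <- seq_len(model_order)
  }
  K <- length(sel)

  say("stage 5: dual regression and connectivity scores")
  nvox <- sum(mask)
  dr_norm <- lapply(seq_len(K), function(k) matrix(NA_real_, n, nvox))
  for (s in seq_len(n)) {
    vol <- simulate_subject_fmri(study, s, voxelwise = TRUE)
    dr <- dual_regression(vol, set)
    for (j in seq_len(K)) dr_norm[[j]][s, ] <- dr$normalised[sel[j], ]
  }
  inside <- outside <- matrix(NA_real_, n, K,
                              dimnames = list(subj$subject_id,
                                              paste0("F", seq_len(K))))
  cmasks <- tmasks <- vector("list", K)
  for (j in seq_len(K)) {
    cm <- control_connectivity_mask(dr_norm[[j]][is_ctl, , drop = FALSE],
                                    alpha = 0.01, n_perm = n_perm,
                                    seed = derive_seed(cfg$seed, 107L, j))
    tm <- component_territory_mask(set$maps[sel[j], ], territory_percentile)
    cmasks[[j]] <- cm; tmasks[[j]] <- tm
    if (!any(cm)) cm <- rep(TRUE, nvox)  # degenerate mask fallback, logged
    om <- cm & !tm
    if (!any(om)) om <- !tm
    for (s in seq_len(n)) {
      inside[s, j] <- connectivity_score(dr_norm[[j]][s, ], cm)
      outside[s, j] <- connectivity_score(dr_norm[[j]][s, ], om)
    }
  }

  say("stage 6: severity models")
  L_sel <- set$loadings[, sel, drop = FALSE]
  colnames(L_sel) <- paste0("L", seq_len(K))
  sev <- list()
  for (oc in c("ace_r", "pspr_s")) {
    des_in <- severity_design(subj, L_sel, inside, outcome = oc)
    des_out <- severity_design(subj, L_sel, outside, outcome = oc)
    sev[[oc]] <- list(screen = screen_single_predictors(des_in),
                      inside = stepwise_bic(des_in),
                      outside = stepwise_bic(des_out))
  }

  scores <- data.frame(subject_id = rep(subj$subject_id, K),
                       component = rep(paste0("C", sel), each = n),
                       inside = as.numeric(inside),
                       outside = as.numeric(outside))
  report <- list(
    spatial_correlation = list(r = sct$r, p = sct$p),
    lmm = list(patients = coef_ddlmm(lmm_pat),
               controls = coef_ddlmm(lmm_ctl),
               interaction = coef_ddlmm(lmm_all, "bp_z:is_patientTRUE"),
               lrt = lrt),
    ica = list(model_order = model_order, selected = sel,
               qc = set$qc),
    severity = lapply(sev, function(x) list(
      inside_terms = x$inside$terms, inside_bic = x$inside$bic,
      outside_terms = x$outside$terms, outside_bic = x$outside$bic)))
  structure(list(weighted_degree = wd, zmaps = list(wd = z_wd, bp = z_bp),
                 spatial_test = sct, long = long,
                 lmm = list(patients = lmm_pat, controls = lmm_ctl,
                            all = lmm_all, lrt = lrt),
                 components = set, selected = sel,
                 scores = scores, score_matrices = list(inside = inside,
                                                        outside = outside),
                 masks = list(control = cmasks, territory = tmasks),
                 severity = sev, report = report),
            class = "synaptoconn_pipeline")
}

#' @export
print.synaptoconn_pipeline <- function(x, ...) {
  r <- x$report
  cat("Multimodal pipeline result\n")
  cat(sprintf("  spatial correlation (z-maps, cortical): r = %.3f, p = %.4f\n",
              r$spatial_correlation$r, r$spatial_correlation$p))
  cat(sprintf("  binding std beta: patients %.3f, controls %.3f, interaction %.3f\n",
              r$lmm$patients$estimate, r$lmm$controls$estimate,
              r$lmm$interaction$estimate))
  cat(sprintf("  random-slope LRT: chi2 = %.1f (df %d), p = %.2g\n",
              r$lmm$lrt$chisq, r$lmm$lrt$df, r$lmm$lrt$p))
  cat("  components selected:", paste(r$ica$selected, collapse = ", "), "\n")
  for (oc in names(r$severity))
    cat("  winning", oc, "model:",
        paste(r$severity[[oc]]$inside_terms, collapse = ", "), "\n")
  invisible(x)
}

#' Serialise the pipeline's score table and model report
#'
#' Canonical text serialisation (TSV scores + JSON report) used to check
#' run-to-run determinism byte for byte.
#'
#' @param pipeline a `synaptoconn_pipeline`
#' @param dir output directory
#' @return invisibly, the written file paths
#' @export
write_pipeline_report <- function(pipeline, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sc <- file.path(dir, "connectivity_scores.tsv")
  utils::write.table(format(pipeline$scores, digits = 15), sc, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  rp <- file.path(dir, "model_report.json")
  writeLines(jsonlite::toJSON(pipeline$report, auto_unbox = TRUE, digits = 12,
                              dataframe = "columns", pretty = TRUE), rp)
  invisible(c(sc, rp))
}
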