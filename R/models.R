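# Regional statistical models: covariate-adjusted group comparisons with
# Tukey post-hoc contrasts, crossed mixed-effects models of the
# density-connectivity relationship, Freedman-Lane permutation GLMs, and
# non-parametric combination across modalities.

#' Covariate-adjusted group comparison per region
#'
#' For every region, fits `value ~ group + covariates`, reports the omnibus
#' group F-test, BH-FDR adjusts across regions, and (optionally) computes
#' Tukey-adjusted pairwise contrasts on the model-adjusted group means.
#'
#' @param feature subjects x regions matrix
#' @param subjects participant table (must contain `group` and the
#'   covariates)
#' @param covariates character vector of covariate column names
#' @param pairwise also compute Tukey pairwise contrasts (via adjusted means)
#' @return list: `table` (region, F, df1, df2, p, p_fdr), `pairwise` (long
#'   data.frame of contrasts, or NULL)
#' @export
group_compare_regions <- function(feature, subjects,
                                  covariates = c("age", "sex"),
                                  pairwise = TRUE) {
  grp <- droplevels(factor(subjects$group))
  if (nlevels(grp) < 2L || any(table(grp) < 3L))
    stop("need >= 2 groups with >= 3 subjects each")
  regions <- colnames(feature)
  if (is.null(regions)) regions <- as.character(seq_len(ncol(feature)))
  covs <- subjects[, covariates, drop = FALSE]
  res <- vector("list", ncol(feature))
  pw <- list()
  for (j in seq_len(ncol(feature))) {
    dat <- data.frame(y = feature[, j], group = grp, covs)
    dat <- dat[stats::complete.cases(dat), ]
    full <- stats::lm(stats::reformulate(c("group", covariates), "y"), dat)
    if (full$rank < length(full$coefficients)) stop("rank-deficient design")
    red <- stats::lm(stats::reformulate(covariates, "y"), dat)
    an <- stats::anova(red, full)
    res[[j]] <- data.frame(region = regions[j], F = an$F[2],
                           df1 = an$Df[2], df2 = an$Res.Df[2],
                           p = an$`Pr(>F)`[2])
    if (pairwise) {
      em <- emmeans::emmeans(full, "group")
      ct <- as.data.frame(emmeans::contrast(em, method = "pairwise",
                                            adjust = "tukey"))
      ct$region <- regions[j]
      pw[[length(pw) + 1L]] <- ct
    }
  }
  tab <- do.call(rbind, res)
  tab$p_fdr <- fdr_adjust(tab$p)
  list(table = tab, pairwise = if (pairwise) do.call(rbind, pw) else NULL)
}

# Standardise the modelling frame within the estimation sample.
standardise_long <- function(data, include_volume) {
  d <- data
  d$wd_z <- zscore(d$weighted_degree)
  d$bp_z <- zscore(d$bp_nd)
  d$age_z <- zscore_by_subject(d$age, d$subject_id)
  d$dvars_z <- zscore_by_subject(d$mean_dvars, d$subject_id)
  if (include_volume) {
    d$gm_z <- zscore(d$gm_volume)
    d$tiv_z <- zscore_by_subject(d$tiv, d$subject_id)
  }
  d
}

# z-score a subject-level covariate using one value per subject (not one per
# subject-region row, which would not change the mean but shrinks the SD
# weighting towards subjects with more regions).
zscore_by_subject <- function(x, subject) {
  per <- tapply(x, subject, function(v) v[1])
  z <- (per - mean(per)) / stats::sd(per)
  as.numeric(z[as.character(subject)])
}

#' Crossed mixed-effects model of weighted degree on synaptic density
#'
#' Fits (by maximum likelihood) `weighted degree ~ binding + covariates`
#' with crossed random intercepts for subject and region and a random
#' binding slope by region.  Outcome and continuous predictors are
#' standardised within the estimation sample, so fixed-effect estimates are
#' standardised betas.  Covariates: age, sex, mean DVARS, and a
#' cortical/subcortical indicator; optionally regional grey-matter volume
#' and total intracranial volume.  For `cohort = "all"` a patient indicator
#' and its interactions with binding and corticality are added.
#'
#' On singular or non-converging fits the random structure is downgraded
#' deterministically: correlated slope, then uncorrelated slope, then
#' intercept-only; the ladder is recorded.
#'
#' @param data long regional data (see [simulate_regional_data()] for the
#'   column contract)
#' @param cohort `"patients"`, `"controls"` or `"all"`
#' @param include_volume add grey-matter volume and TIV covariates
#' @param random_slope start with a random binding slope by region
#' @return a `ddlmm` object: `fit` (merMod), `coefficients` (term,
#'   estimate, se, z, p), `converged`, `ladder`, `cohort`, `formula`
#' @export
fit_density_degree_lmm <- function(data,
                                   cohort = c("patients", "controls", "all"),
                                   include_volume = FALSE,
                                   random_slope = TRUE) {
  cohort <- match.arg(cohort)
  d <- switch(cohort,
              patients = data[data$group != "Control", ],
              controls = data[data$group == "Control", ],
              all = data)
  d <- d[stats::complete.cases(d[, c("weighted_degree", "bp_nd", "age",
                                     "mean_dvars")]), ]
  d <- standardise_long(d, include_volume)
  d$is_patient <- d$group != "Control"
  fixed <- c("bp_z", "age_z", "sex", "dvars_z", "is_cortical")
  if (include_volume) fixed <- c(fixed, "gm_z", "tiv_z")
  if (cohort == "all")
    fixed <- c(fixed, "is_patient", "is_patient:bp_z", "is_patient:is_cortical")
  rand_forms <- if (random_slope)
    c("(1 | subject_id) + (1 + bp_z | region_id)",
      "(1 | subject_id) + (1 + bp_z || region_id)",
      "(1 | subject_id) + (1 | region_id)")
  else "(1 | subject_id) + (1 | region_id)"
  ladder <- character(0)
  fit <- NULL
  for (rf in rand_forms) {
    fml <- stats::as.formula(paste("wd_z ~", paste(fixed, collapse = " + "),
                                   "+", rf))
    cand <- tryCatch(
      suppressWarnings(suppressMessages(
        lme4::lmer(fml, data = d, REML = FALSE,
                   control = lme4::lmerControl(
                     check.conv.singular = "ignore")))),
      error = function(e) NULL)
    ladder <- c(ladder, rf)
    if (!is.null(cand) && !lme4::isSingular(cand, tol = 1e-4) &&
        length(cand@optinfo$conv$lme4$messages) == 0L) {
      fit <- cand
      break
    }
    if (!is.null(cand) && is.null(fit)) fit <- cand  # keep best-effort fit
  }
  converged <- !is.null(fit) && !lme4::isSingular(fit, tol = 1e-4) &&
    length(fit@optinfo$conv$lme4$messages) == 0L
  if (is.null(fit)) stop("mixed model failed at every rung of the ladder")
  cf <- lme4_coef_table(fit)
  structure(list(fit = fit, coefficients = cf, converged = converged,
                 ladder = ladder, cohort = cohort,
                 include_volume = include_volume,
                 formula = stats::formula(fit), n = nrow(d)),
            class = "ddlmm")
}

lme4_coef_table <- function(fit) {
  cc <- summary(fit)$coefficients
  data.frame(term = rownames(cc), estimate = cc[, "Estimate"],
             se = cc[, "Std. Error"], z = cc[, "t value"],
             p = 2 * stats::pnorm(-abs(cc[, "t value"])),
             row.names = NULL)
}

#' @export
print.ddlmm <- function(x, digits = 3, ...) {
  cat("Crossed mixed-effects model of weighted degree on synaptic density\n")
  cat("  cohort:", x$cohort, "| rows:", x$n,
    "| converged:", x$converged, "\n")
  cat("  random structure:", utils::tail(x$ladder, 1), "\n")
  print(cbind(x$coefficients[1], round(x$coefficients[-1], digits)))
  invisible(x)
}

#' Coefficient of a `ddlmm`
#' @param object a `ddlmm`
#' @param term coefficient name (default: the binding standardised beta)
#' @param ... unused
#' @return named list: `estimate`, `se`, `ci` (Wald 95%), `p`
#' @export
coef_ddlmm <- function(object, term = "bp_z", ...) {
  cf <- object$coefficients
  i <- match(term, cf$term)
  if (is.na(i)) stop("no term '", term, "' in model")
  list(estimate = cf$estimate[i], se = cf$se[i],
       ci = cf$estimate[i] + c(-1, 1) * stats::qnorm(0.975) * cf$se[i],
       p = cf$p[i])
}

#' Likelihood-ratio test for the region-varying binding slope
#'
#' Compares two nested ML fits (typically with and without a random binding
#' slope by region): `chi2 = 2 * (logLik_with - logLik_without)`.
#'
#' @param fit_without,fit_with nested `ddlmm` objects on identical data
#' @return list: `chisq`, `df`, `p`
#' @export
lrt_random_slope <- function(fit_without, fit_with) {
  if (fit_without$n != fit_with$n)
    stop("models fitted to different data")
  ll0 <- stats::logLik(fit_without$fit)
  ll1 <- stats::logLik(fit_with$fit)
  df <- attr(ll1, "df") - attr(ll0, "df")
  if (df < 0) stop("models are not nested as given (larger model second)")
  chisq <- max(0, 2 * as.numeric(ll1 - ll0))
  p <- if (df == 0) 1 else stats::pchisq(chisq, df, lower.tail = FALSE)
  list(chisq = chisq, df = df, p = p)
}

# Freedman-Lane permutation engine.
# Y: n x V outcomes; x: predictor; Z: covariate design incl. intercept;
# perm: n x B permutation indices.  Returns observed t per outcome and the
# B x V matrix of permutation t statistics (full-model t for x, outcomes
# rebuilt as reduced-model fit + permuted reduced-model residuals).
fl_engine <- function(Y, x, Z, perm) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) stop("rank-deficient design")
  xt <- qr.resid(qz, x)
  xx <- sum(xt^2)
  if (xx < 1e-12) stop("predictor collinear with covariates")
  df <- n - ncol(Z) - 1L
  Yt <- qr.resid(qz, Y)
  t_of <- function(Ytil) {
    a <- as.numeric(crossprod(xt, Ytil))
    rss <- colSums(Ytil^2) - a^2 / xx
    a / (sqrt(xx) * sqrt(pmax(rss, 1e-300) / df))
  }
  t_obs <- t_of(Yt)
  B <- ncol(perm)
  t_null <- matrix(NA_real_, B, ncol(Y))
  # under Freedman-Lane the permuted outcome's covariate-residual equals
  # M_Z P (M_Z y), so only the residuals need permuting
  for (b in seq_len(B)) {
    Eb <- Yt[perm[, b], , drop = FALSE]
    t_null[b, ] <- t_of(qr.resid(qz, Eb))
  }
  list(t = t_obs, t_null = t_null, df = df)
}

build_covariate_design <- function(covariates, n) {
  if (is.null(covariates)) return(matrix(1, n, 1))
  cv <- as.data.frame(covariates)
  stats::model.matrix(~ ., data = cv)
}

#' Freedman-Lane permutation GLM for one region
#'
#' Tests a predictor against an outcome with nuisance covariates: the
#' outcome is regressed on the covariates, the residuals are permuted and
#' recombined with the covariate fit, the full model is refitted, and the
#' observed t is compared to the permutation distribution
#' (`p = (1 + #{|t*| >= |t|}) / (n_perm + 1)`, two-sided by default).
#'
#' @param outcome per-subject values
#' @param predictor per-subject values
#' @param covariates data.frame of nuisance covariates (or NULL)
#' @param n_perm number of permutations (>= 100)
#' @param perm optional precomputed permutation matrix (for synchronised
#'   permutations across modalities); overrides `n_perm`/`seed`
#' @param seed integer seed
#' @param alternative `"two.sided"` or `"greater"`
#' @return list: `t`, `p`, `t_null`, `df`
#' @export
per_region_permutation_glm <- function(outcome, predictor, covariates = NULL,
                                       n_perm = 1000L, perm = NULL, seed = 1L,
                                       alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  n <- length(outcome)
  if (is.null(perm)) {
    if (n_perm < 100L) stop("need n_perm >= 100")
    perm <- make_permutations(n, n_perm, seed = seed)
  }
  Z <- build_covariate_design(covariates, n)
  fl <- fl_engine(matrix(outcome), predictor, Z, perm)
  t_null <- fl$t_null[, 1]
  p <- perm_pvalue(fl$t[1], t_null, alternative)
  list(t = fl$t[1], p = p, t_null = t_null, df = fl$df)
}

perm_pvalue <- function(t_obs, t_null, alternative) {
  if (alternative == "greater")
    (1 + sum(t_null >= t_obs)) / (length(t_null) + 1)
  else
    (1 + sum(abs(t_null) >= abs(t_obs))) / (length(t_null) + 1)
}

#' Non-parametric combination across modalities
#'
#' Combines synchronised permutation tests with Fisher's combining function
#' `T = -2 sum log p_m`: per-modality p-values are computed for the observed
#' statistic and for every permutation against that modality's permutation
#' distribution, and the joint p is the add-one rank of the observed
#' combined statistic.  With a single modality the joint p reduces to that
#' modality's permutation p.
#'
#' @param t_obs numeric vector of observed statistics, one per modality
#' @param t_null modalities x n_perm matrix of synchronised permutation
#'   statistics
#' @param alternative `"two.sided"` or `"greater"`
#' @return list: `p`, `T_obs`, `T_null`
#' @export
npc_combine <- function(t_obs, t_null,
                        alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  t_null <- as.matrix(t_null)
  M <- length(t_obs)
  if (nrow(t_null) != M) stop("t_null must have one row per modality")
  B <- ncol(t_null)
  f <- if (alternative == "greater") identity else abs
  To <- 0; Tn <- numeric(B)
  for (m in seq_len(M)) {
    s_obs <- f(t_obs[m]); s_null <- f(t_null[m, ])
    p_obs <- (1 + sum(s_null >= s_obs)) / (B + 1)
    # p of each permutation against the same null set (itself included);
    # dividing by B (not B + 1) makes the single-modality combining
    # identity exact under the add-one convention for the observed p
    r <- rank(-s_null, ties.method = "max")
    p_null <- r / B
    To <- To - 2 * log(p_obs)
    Tn <- Tn - 2 * log(p_null)
  }
  list(p = (1 + sum(Tn >= To)) / (B + 1), T_obs = To, T_null = Tn)
}

#' Max-statistic adjustment across a family of contrasts
#'
#' Westfall-Young style familywise correction for synchronised permutation
#' statistics: each contrast's observed statistic is ranked against the
#' permutation distribution of the family maximum.
#'
#' @param stat_obs numeric vector (one per contrast)
#' @param stat_null contrasts x n_perm matrix of synchronised permutation
#'   statistics
#' @return vector of familywise-adjusted p-values
#' @export
maxstat_adjust <- function(stat_obs, stat_null) {
  stat_null <- as.matrix(stat_null)
  mx <- apply(stat_null, 2, max)
  vapply(stat_obs, function(s) (1 + sum(mx >= s)) / (ncol(stat_null) + 1),
         numeric(1))
}
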