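# Clinical severity models: single-predictor screens, stepwise-BIC model
# selection with locked covariates and free interactions, simple slopes.

#' Build a severity modelling design
#'
#' Standardises component loadings `L_k` and connectivity scores `F_k`
#' within the estimation sample (subjects with a non-missing outcome),
#' forms interaction columns `I_k = L_k * F_k` from the standardised mains,
#' and attaches the locked nuisance covariates (age, sex, mean DVARS).
#'
#' @param subjects participant table with the outcome column
#' @param loadings subjects x K loading matrix
#' @param fscores subjects x K connectivity-score matrix
#' @param outcome outcome column name (`"ace_r"` or `"pspr_s"`)
#' @param covariates locked covariate column names
#' @return a `severity_design`: list with `data` (model frame), `candidates`
#'   (steppable term names), `locked`, `outcome`, `n_dropped`
#' @export
severity_design <- function(subjects, loadings, fscores, outcome = "ace_r",
                            covariates = c("age", "sex", "mean_dvars")) {
  if (ncol(loadings) != ncol(fscores)) stop("loading/score dimension mismatch")
  keep <- !is.na(subjects[[outcome]])
  n_dropped <- sum(!keep)
  K <- ncol(loadings)
  Lz <- apply(loadings[keep, , drop = FALSE], 2, zscore)
  Fz <- apply(fscores[keep, , drop = FALSE], 2, zscore)
  colnames(Lz) <- paste0("L", seq_len(K))
  colnames(Fz) <- paste0("F", seq_len(K))
  inter <- Lz * Fz
  colnames(inter) <- paste0("I", seq_len(K))
  dat <- data.frame(y = zscore(subjects[[outcome]][keep]), Lz, Fz, inter)
  for (cv in covariates) {
    v <- subjects[[cv]][keep]
    dat[[cv]] <- if (is.numeric(v)) zscore(v) else factor(v)
  }
  structure(list(data = dat,
                 candidates = c(colnames(Lz), colnames(Fz), colnames(inter)),
                 locked = covariates, outcome = outcome, K = K,
                 n_dropped = n_dropped),
            class = "severity_design")
}

#' Single-predictor screen with FDR
#'
#' One covariate-adjusted linear model per candidate main effect (each
#' loading and each connectivity score), with BH-FDR across the predictor
#' family.
#'
#' @param design a `severity_design`
#' @return data.frame: `term`, `beta` (standardised), `se`, `t`, `p`,
#'   `p_fdr`
#' @export
screen_single_predictors <- function(design) {
  mains <- design$candidates[!startsWith(design$candidates, "I")]
  rows <- lapply(mains, function(tm) {
    f <- stats::reformulate(c(tm, design$locked), "y")
    cf <- summary(stats::lm(f, design$data))$coefficients
    data.frame(term = tm, beta = cf[tm, 1], se = cf[tm, 2], t = cf[tm, 3],
               p = cf[tm, 4])
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- fdr_adjust(out$p)
  out
}

fit_terms <- function(design, terms) {
  f <- stats::reformulate(c(if (length(terms)) terms else "1", design$locked),
                          "y")
  stats::lm(f, design$data)
}

#' Stepwise model selection by BIC with locked covariates
#'
#' Bidirectional stepwise search minimising BIC.  By default the search is
#' run twice — once from the full baseline model (every main effect and
#' every loading-by-score interaction plus the locked covariates) and once
#' from the covariates-only model — and the lower-BIC winner is kept; a
#' single greedy descent can stall in a local optimum, and the objective is
#' BIC itself.  Interactions enter and leave independently of their mains
#' (no marginality constraint).  Ties are broken deterministically by term
#' name order, and the full step trace is kept.
#'
#' @param design a `severity_design`
#' @param start `"both"` (default), `"full"` (baseline model) or `"null"`
#'   (covariates only)
#' @return a `severity_fit`: `fit` (lm), `terms`, `trace` (data.frame),
#'   `bic`, `design`
#' @export
stepwise_bic <- function(design, start = c("both", "full", "null")) {
  start <- match.arg(start)
  if (start == "both") {
    f_full <- stepwise_bic(design, "full")
    f_null <- stepwise_bic(design, "null")
    return(if (f_null$bic < f_full$bic) f_null else f_full)
  }
  n <- nrow(design$data)
  if (n <= length(design$locked) + 2L) stop("too few subjects for selection")
  current <- if (start == "full") design$candidates else character(0)
  fit <- fit_terms(design, current)
  bic <- stats::BIC(fit)
  trace <- data.frame(step = 0L, move = "start",
                      term = NA_character_, bic = bic)
  visited_bic <- bic
  step_i <- 0L
  repeat {
    drops <- sort(current)
    adds <- sort(setdiff(design$candidates, current))
    moves <- rbind(
      if (length(drops)) data.frame(move = "drop", term = drops),
      if (length(adds)) data.frame(move = "add", term = adds))
    if (is.null(moves) || nrow(moves) == 0L) break
    cand_bic <- vapply(seq_len(nrow(moves)), function(i) {
      tms <- if (moves$move[i] == "drop") setdiff(current, moves$term[i])
             else c(current, moves$term[i])
      stats::BIC(fit_terms(design, tms))
    }, numeric(1))
    best <- which.min(cand_bic)  # ties: first in (move, alphabetical) order
    if (cand_bic[best] >= bic - 1e-8) break
    current <- if (moves$move[best] == "drop") setdiff(current, moves$term[best])
               else c(current, moves$term[best])
    bic <- cand_bic[best]
    step_i <- step_i + 1L
    trace <- rbind(trace, data.frame(step = step_i, move = moves$move[best],
                                     term = moves$term[best], bic = bic))
    visited_bic <- c(visited_bic, cand_bic)
  }
  fit <- fit_terms(design, current)
  structure(list(fit = fit, terms = sort(current), trace = trace,
                 bic = stats::BIC(fit), visited_bic = visited_bic,
                 design = design),
            class = "severity_fit")
}

#' @export
print.severity_fit <- function(x, digits = 3, ...) {
  cat("Stepwise-BIC severity model for", x$design$outcome, "\n")
  cat("  retained terms:",
      if (length(x$terms)) paste(x$terms, collapse = ", ") else "(covariates only)",
      "\n")
  cat("  BIC:", round(x$bic, 2), "| steps:", max(x$trace$step), "\n")
  invisible(x)
}

#' @export
summary.severity_fit <- function(object, ...) {
  s <- summary(object$fit)
  cat("Winning model (", object$design$outcome, "):\n", sep = "")
  print(s$coefficients)
  invisible(s)
}

#' Simple slopes of a loading at levels of its connectivity moderator
#'
#' For component k, the conditional slope of the outcome on `L_k` at
#' moderator values m = -1, 0, +1 SD is `beta_L + beta_I * m` (coefficients
#' absent from the winning model contribute zero), with delta-method 95%
#' confidence intervals from the model covariance.
#'
#' @param fit a `severity_fit` (or plain lm with `L_k`/`I_k` columns)
#' @param component component index k
#' @return data.frame: `moderator` (-1, 0, 1), `slope`, `se`, `ci_lo`,
#'   `ci_hi`
#' @export
simple_slopes <- function(fit, component) {
  lmfit <- if (inherits(fit, "severity_fit")) fit$fit else fit
  cf <- stats::coef(lmfit)
  V <- stats::vcov(lmfit)
  nmL <- paste0("L", component); nmI <- paste0("I", component)
  bL <- if (nmL %in% names(cf)) cf[nmL] else 0
  bI <- if (nmI %in% names(cf)) cf[nmI] else 0
  vL <- if (nmL %in% rownames(V)) V[nmL, nmL] else 0
  vI <- if (nmI %in% rownames(V)) V[nmI, nmI] else 0
  cLI <- if (nmL %in% rownames(V) && nmI %in% rownames(V)) V[nmL, nmI] else 0
  m <- c(-1, 0, 1)
  slope <- bL + bI * m
  se <- sqrt(pmax(vL + m^2 * vI + 2 * m * cLI, 0))
  zc <- stats::qnorm(0.975)
  data.frame(moderator = m, slope = unname(slope), se = se,
             ci_lo = unname(slope) - zc * se, ci_hi = unname(slope) + zc * se)
}

#' Re-run model selection with outside-territory connectivity scores
#'
#' Identical stepwise machinery with the connectivity scores replaced by
#' the scores computed outside the component territory (remote
#' connectivity).
#'
#' @param subjects participant table
#' @param loadings subjects x K loading matrix
#' @param outside_scores subjects x K outside-territory score matrix
#' @param outcome outcome column name
#' @param ... passed to [severity_design()] / [stepwise_bic()]
#' @return a `severity_fit`
#' @export
outside_mask_refit <- function(subjects, loadings, outside_scores,
                               outcome = "ace_r", ...) {
  stepwise_bic(severity_design(subjects, loadings, outside_scores,
                               outcome = outcome, ...))
}
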