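test_that("two-group omnibus F equals the squared t from the same model", {
  set.seed(21)
  n <- 40
  subj <- data.frame(group = factor(rep(c("Control", "PSP"), each = n / 2)),
                     age = rnorm(n), sex = factor(sample(c("F", "M"), n, TRUE)))
  feat <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("r", 1:3)))
  out <- group_compare_regions(feat, subj, pairwise = FALSE)
  for (j in 1:3) {
    fit <- lm(feat[, j] ~ group + age + sex, data = subj)
    tt <- summary(fit)$coefficients["groupPSP", "t value"]
    expect_equal(out$table$F[j], tt^2, tolerance = 1e-10)
  }
})

test_that("group comparison detects planted shifts and controls the null FDR", {
  set.seed(22)
  n <- 79
  subj <- data.frame(group = factor(rep(c("Control", "PSP", "CBS", "bvFTD"),
                                        c(24, 29, 16, 10))),
                     age = rnorm(n), sex = factor(sample(c("F", "M"), n, TRUE)))
  # null: 60 regions from one distribution
  feat0 <- matrix(rnorm(n * 60), n, 60)
  out0 <- group_compare_regions(feat0, subj, pairwise = FALSE)
  expect_lte(mean(out0$table$p_fdr < 0.05), 0.05)
  # planted 1.5 SD shift in 10 of 60 regions
  feat1 <- feat0
  shift <- ifelse(subj$group == "Control", 0, 1.5)
  for (j in 1:10) feat1[, j] <- feat1[, j] + shift
  out1 <- group_compare_regions(feat1, subj, pairwise = FALSE)
  expect_gte(sum(out1$table$p_fdr[1:10] < 0.05), 8)
})

test_that("Tukey pairwise contrasts are produced on adjusted means", {
  set.seed(23)
  n <- 40
  subj <- data.frame(group = factor(rep(c("A", "B", "C", "D"), each = 10)),
                     age = rnorm(n), sex = factor(sample(c("F", "M"), n, TRUE)))
  feat <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "r1"))
  out <- group_compare_regions(feat, subj, pairwise = TRUE)
  expect_equal(nrow(out$pairwise), choose(4, 2))
  expect_true(all(out$pairwise$p.value >= 0 & out$pairwise$p.value <= 1))
})

test_that("crossed mixed model recovers the planted coupling and its absence", {
  res <- t(sapply(1:10, function(i) {
    d <- simulate_regional_data(seed = 500 + i)
    tr <- attr(d, "truth")
    fp <- fit_density_degree_lmm(d, "patients")
    fc <- fit_density_degree_lmm(d, "controls")
    cp <- coef_ddlmm(fp); cc <- coef_ddlmm(fc)
    ci <- coef_ddlmm(fit_density_degree_lmm(d, "all"), "bp_z:is_patientTRUE")
    c(tr$implied_std_beta["patients"] >= cp$ci[1] &
        tr$implied_std_beta["patients"] <= cp$ci[2],
      0 >= cc$ci[1] & 0 <= cc$ci[2],
      ci$estimate > 0)
  }))
  expect_gte(mean(res[, 1]), 0.8)
  expect_gte(mean(res[, 2]), 0.8)
  expect_gte(mean(res[, 3]), 0.9)
})

test_that("standardised betas are invariant to affine rescaling of raw predictors", {
  d <- simulate_regional_data(seed = 55)
  f1 <- fit_density_degree_lmm(d, "patients")
  d2 <- d
  d2$bp_nd <- 100 + 7 * d2$bp_nd
  d2$age <- 3 * d2$age - 2
  f2 <- fit_density_degree_lmm(d2, "patients")
  expect_equal(coef_ddlmm(f1)$estimate, coef_ddlmm(f2)$estimate,
               tolerance = 1e-6)
})

test_that("volume covariates can be added without disturbing the binding effect", {
  d <- simulate_regional_data(seed = 56)
  d$gm_volume <- rnorm(nrow(d))
  d$tiv <- rep(rnorm(79), 30)[seq_len(nrow(d))]
  f <- fit_density_degree_lmm(d, "patients", include_volume = TRUE)
  expect_true("gm_z" %in% f$coefficients$term)
  expect_gt(coef_ddlmm(f)$estimate, 0)
})

test_that("the random-slope LRT is zero for identical models and detects heterogeneity", {
  d <- simulate_regional_data(seed = 57)
  f0 <- fit_density_degree_lmm(d, "patients", random_slope = FALSE)
  expect_equal(lrt_random_slope(f0, f0)$chisq, 0)
  f1 <- fit_density_degree_lmm(d, "patients")
  lr <- lrt_random_slope(f0, f1)
  expect_gte(lr$df, 1)
  # power at generative slope heterogeneity, modest replicate count
  hits <- sapply(1:8, function(i) {
    di <- simulate_regional_data(resid_sd = 0.5, seed = 600 + i)
    g0 <- fit_density_degree_lmm(di, "patients", random_slope = FALSE)
    g1 <- fit_density_degree_lmm(di, "patients")
    lrt_random_slope(g0, g1)$p < 0.05
  })
  expect_gte(mean(hits), 0.75)
  # boundary-conservative under homogeneous slopes
  null_rej <- sapply(1:8, function(i) {
    di <- simulate_regional_data(slope_region_sd = 0, seed = 700 + i)
    g0 <- fit_density_degree_lmm(di, "patients", random_slope = FALSE)
    g1 <- fit_density_degree_lmm(di, "patients")
    lrt_random_slope(g0, g1)$p < 0.05
  })
  expect_lte(mean(null_rej), 0.25)
})

test_that("Freedman-Lane with no covariates equals plain outcome permutation", {
  set.seed(24)
  n <- 30
  for (case in 1:5) {
    y <- rnorm(n); x <- rnorm(n)
    perm <- make_permutations(n, 300, seed = case)
    fl <- per_region_permutation_glm(y, x, NULL, perm = perm)
    # direct permutation of the demeaned outcome
    yc <- y - mean(y); xc <- x - mean(x)
    t_of <- function(yy) {
      b <- sum(xc * yy) / sum(xc^2)
      res <- yy - b * xc
      b / sqrt(sum(res^2) / (n - 2) / sum(xc^2))
    }
    t_null <- apply(perm, 2, function(p) t_of(yc[p]))
    p_direct <- (1 + sum(abs(t_null) >= abs(t_of(yc)))) / 301
    expect_equal(fl$p, p_direct, tolerance = 1e-12)
  }
})

test_that("permutation p converges to the parametric p on Gaussian data", {
  set.seed(25)
  n <- 60
  covs <- data.frame(age = rnorm(n))
  for (case in 1:4) {
    x <- rnorm(n); y <- 0.25 * x + rnorm(n)
    fl <- per_region_permutation_glm(y, x, covs, n_perm = 5000, seed = case)
    p_par <- summary(lm(y ~ x + age, data = cbind(covs, x = x, y = y)))$
      coefficients["x", 4]
    expect_lt(abs(fl$p - p_par), 0.02)
  }
})

test_that("permutation GLM has power against a planted effect", {
  set.seed(26)
  hits <- replicate(40, {
    n <- 79
    covs <- data.frame(age = rnorm(n))
    x <- rnorm(n)
    y <- 0.4 * x + rnorm(n)
    per_region_permutation_glm(y, x, covs, n_perm = 300,
                               seed = sample.int(1e6, 1))$p <= 0.05
  })
  expect_gte(mean(hits), 0.8)
})

test_that("NPC reduces to the single-modality p and rejects unsynchronised input", {
  set.seed(27)
  n <- 40
  x <- rnorm(n); y <- 0.4 * x + rnorm(n)
  perm <- make_permutations(n, 400, seed = 9)
  r <- per_region_permutation_glm(y, x, NULL, perm = perm)
  expect_equal(npc_combine(r$t, matrix(r$t_null, 1))$p, r$p, tolerance = 1e-12)
  expect_error(npc_combine(c(1, 2), matrix(0, 3, 10)), "one row per modality")
})

test_that("NPC gains power over the best single modality with shared signal", {
  set.seed(28)
  res <- replicate(60, {
    n <- 79
    perm <- make_permutations(n, 200, seed = sample.int(1e6, 1))
    x <- rnorm(n)
    eff <- c(0.3, 0.3, 0)
    rs <- lapply(1:3, function(m) {
      y <- eff[m] * x + rnorm(n)
      per_region_permutation_glm(y, x, NULL, perm = perm)
    })
    joint <- npc_combine(sapply(rs, `[[`, "t"),
                         t(sapply(rs, `[[`, "t_null")))$p
    c(joint <= 0.05, rs[[1]]$p <= 0.05)
  })
  expect_gte(mean(res[1, ]), mean(res[2, ]))
})

test_that("max-statistic adjustment is monotone and bounded by the raw p", {
  set.seed(29)
  obs <- c(3, 1.2, 0.4)
  nul <- matrix(rnorm(3 * 500), 3, 500)
  adj <- maxstat_adjust(obs, nul)
  expect_true(all(diff(adj) >= 0))
  raw <- sapply(1:3, function(i) (1 + sum(nul[i, ] >= obs[i])) / 501)
  expect_true(all(adj >= raw - 1e-12))
})
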