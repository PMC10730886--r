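test_that("participant table mirrors the configured cohort", {
  subj <- simulate_subjects(sim_config(seed = 2))
  expect_equal(nrow(subj), 79)
  expect_equal(sum(subj$group == "bvFTD"), 10)
  expect_equal(as.vector(table(subj$group)), c(24, 29, 16, 10))
  cfg5 <- small_config()
  cfg5$group_sizes[] <- 5L
  expect_equal(nrow(simulate_subjects(cfg5)), 20)
  expect_identical(simulate_subjects(sim_config(seed = 2)), subj)
  expect_true(mean(subj$mean_dvars[subj$group == "bvFTD"]) >
                mean(subj$mean_dvars[subj$group == "Control"]))
})

test_that("config validation rejects inconsistent settings", {
  expect_error(sim_config(n_subparcels = 5), ">=")
  expect_error(sim_config(group_sizes = c(Control = 0, PSP = 1, CBS = 1,
                                          bvFTD = 1)), "positive")
  expect_error(sim_config(ar_coef = 1.2), "ar_coef")
  cfg <- sim_config()
  cfg$coupling_slope[1] <- NaN
  expect_error(synaptoconn:::validate_sim_config(cfg), "finite")
})

test_that("PET maps follow the linear construction exactly at zero noise", {
  cfg <- small_config(pet_noise_sd = 0)
  atlas <- make_atlas(cfg)
  comps <- make_true_components(atlas, cfg)
  subj <- simulate_subjects(cfg)
  pet <- simulate_pet_maps(atlas, subj, comps, cfg)
  mask <- atlas$labels > 0
  K <- cfg$n_components_true
  comp_flat <- matrix(comps$maps, ncol = K)
  for (s in c(1, 5)) {
    expected <- as.numeric(pet$baseline) +
      comp_flat %*% (cfg$component_amplitude * pet$loadings[s, ])
    expected[!mask] <- 0
    expect_equal(as.numeric(pet$maps[, , , s]), as.numeric(expected),
                 tolerance = 1e-12)
  }
  # identical loadings + zero noise give identical maps
  pet$loadings[2, ] <- pet$loadings[1, ]
  m1 <- as.numeric(pet$baseline) +
    comp_flat %*% (cfg$component_amplitude * pet$loadings[1, ])
  m2 <- as.numeric(pet$baseline) +
    comp_flat %*% (cfg$component_amplitude * pet$loadings[2, ])
  expect_identical(m1, m2)
})

test_that("planted components are localised with low mutual correlation", {
  study <- small_study()
  comps <- study$truth$components
  expect_lt(comps$max_abs_corr, 0.2)
  expect_true(all(comps$maps >= 0))
})

test_that("patient loadings are depressed relative to controls for every deficit component", {
  study <- simulate_study(sim_config(seed = 3))
  L <- study$truth$loadings
  ctl <- study$subjects$group == "Control"
  for (k in seq_len(ncol(L)))
    expect_lt(mean(L[!ctl, k]), mean(L[ctl, k]))
})

test_that("PET generation rejects configurations that drive voxels non-positive", {
  cfg <- small_config(component_amplitude = 5)
  atlas <- make_atlas(cfg)
  comps <- make_true_components(atlas, cfg)
  subj <- simulate_subjects(cfg)
  expect_error(simulate_pet_maps(atlas, subj, comps, cfg), "<= 0")
})

test_that("fMRI generator couples degree to density as configured", {
  study <- small_study()
  tr <- study$truth
  ctl <- study$subjects$group == "Control"
  # control gains are exactly 1 (slope 0)
  expect_true(all(tr$fmri$gain[ctl, ] == 1))
  # patient gain regression recovers the generative slope
  pat <- which(!ctl)
  g <- as.numeric(tr$fmri$gain[pat, ] - 1)
  parc_region <- study$subparcellation$table$region_id
  dz <- tr$fmri$density_z[pat, match(parc_region,
                                     study$atlas$region_table$region_id)]
  keep <- g > (0.1 - 1)  # unclipped
  fit <- lm(g[keep] ~ 0 + as.numeric(dz)[keep])
  expect_equal(unname(coef(fit)), 0.2, tolerance = 1e-6)
})

test_that("voxels within a sub-parcel share the parcel time course at zero voxel noise", {
  cfg <- small_config(fmri_voxel_noise_sd = 0)
  study <- simulate_study(cfg)
  vol <- simulate_subject_fmri(study, 1)
  sp <- study$subparcellation
  sid <- sp$table$subparcel_id[which.max(sp$table$voxel_count)]
  idx <- which(sp$labels == sid)
  mat <- matrix(vol, prod(dim(sp$labels)), cfg$n_timepoints)[idx, ]
  expect_lt(max(abs(sweep(mat, 2, mat[1, ]))), 1e-12)
})

test_that("fMRI synthesis is deterministic given the study seed", {
  study <- small_study()
  v1 <- simulate_subject_fmri(study, 3)
  v2 <- simulate_subject_fmri(study, 3)
  expect_identical(v1, v2)
})

test_that("secondary modalities honour the configured coupling", {
  study <- simulate_study(sim_config(seed = 4))
  bp <- study$regional$bp
  odi <- study$regional$odi
  expect_lt(abs(cor(as.numeric(bp), as.numeric(odi)) - 0.55), 0.1)
  # noise-free link is perfectly collinear
  cfg0 <- small_config(odi_cor = 1)
  st0 <- simulate_study(cfg0)
  expect_gt(cor(as.numeric(st0$regional$bp), as.numeric(st0$regional$odi)),
            0.999999)
  # zero slope decouples the modalities
  cfgz <- small_config(odi_slope = 0, seed = 21L)
  stz <- simulate_study(cfgz)
  ct <- cor.test(as.numeric(stz$regional$bp), as.numeric(stz$regional$odi))
  expect_gt(ct$p.value, 0.001)
  # grey matter couples more weakly than ODI
  expect_lt(abs(cor(as.numeric(bp), as.numeric(scale(study$regional$gm_volume)))),
            abs(cor(as.numeric(bp), as.numeric(odi))))
})

test_that("clinical scores obey the planted interaction algebra", {
  cfg <- sim_config(seed = 6)
  subj <- simulate_subjects(cfg)
  n <- nrow(subj)
  set.seed(1)
  L <- matrix(rnorm(n * 6), n, 6)
  Fz <- matrix(rnorm(n * 6), n, 6)

  # all coefficients zero, zero noise: constant scores
  cfg0 <- cfg
  cfg0$clinical$ace_r$coefs[] <- 0
  cfg0$clinical$ace_r$beta_age <- 0
  cfg0$clinical$ace_r$noise_sd <- 0
  out0 <- simulate_clinical(subj, L, Fz, cfg0)
  expect_equal(diff(range(out0$ace_r)), 0)

  # noiseless generation: refitting the true model recovers coefficients
  cfg1 <- cfg
  cfg1$clinical$ace_r$noise_sd <- 0
  out1 <- simulate_clinical(subj, L, Fz, cfg1)
  Lz <- apply(L, 2, zscore); Fzz <- apply(Fz, 2, zscore)
  d <- data.frame(y = out1$ace_r, L2 = Lz[, 2], I4 = Lz[, 4] * Fzz[, 4],
                  I5 = Lz[, 5] * Fzz[, 5], age = zscore(subj$age))
  ok <- d$y > 0 & d$y < 100  # unclipped rows
  cf <- coef(lm(y ~ L2 + I4 + I5 + age, d[ok, ]))
  sc <- cfg$clinical$ace_r$scale
  expect_equal(unname(cf["L2"]), 0.45 * sc, tolerance = 1e-8)
  expect_equal(unname(cf["I4"]), 0.35 * sc, tolerance = 1e-8)
  expect_equal(unname(cf["I5"]), 0.35 * sc, tolerance = 1e-8)

  # positive interaction: conditional slope increases with the moderator
  hiF <- Fzz[, 5] > 1
  loF <- Fzz[, 5] < -1
  s_hi <- coef(lm(out1$ace_r[hiF] ~ Lz[hiF, 5]))[2]
  s_lo <- coef(lm(out1$ace_r[loF] ~ Lz[loF, 5]))[2]
  expect_gt(s_hi, s_lo)

  # implausible clipping is rejected
  cfg2 <- cfg
  cfg2$clinical$ace_r$intercept <- 99
  expect_error(simulate_clinical(subj, L, Fz, cfg2), "clips")
})

test_that("whole-study generation is bit-identical across runs", {
  s1 <- simulate_study(small_config(seed = 17L))
  s2 <- simulate_study(small_config(seed = 17L))
  expect_identical(s1$pet$maps, s2$pet$maps)
  expect_identical(s1$subjects, s2$subjects)
  expect_identical(s1$truth$fscores, s2$truth$fscores)
  expect_identical(simulate_subject_fmri(s1, 2), simulate_subject_fmri(s2, 2))
})

test_that("stronger density-coupling slopes strictly increase the degree-density correlation", {
  slopes <- c(0, 0.2, 0.4)
  cors <- sapply(slopes, function(sl) {
    mean(sapply(1:4, function(r) {
      cfg <- small_config(seed = 100L + r,
                          coupling_slope = c(Control = 0, PSP = sl, CBS = sl,
                                             bvFTD = sl))
      st <- simulate_study(cfg)
      wd <- study_weighted_degree(st)$regional
      pat <- st$subjects$group != "Control"
      cor(as.numeric(wd[pat, ]), as.numeric(st$regional$bp[pat, ]),
          use = "complete.obs")
    }))
  })
  expect_true(all(diff(cors) > 0))
})

test_that("configured group deficits are ANOVA-detectable at the default cohort size", {
  hits <- sapply(1:25, function(i) {
    cfg <- sim_config(seed = 300L + i)
    subj <- simulate_subjects(cfg)
    set.seed(300L + i)
    L <- cfg$loading_shift[as.integer(subj$group), ] +
      matrix(rnorm(nrow(subj) * 6), nrow(subj), 6)
    sapply(1:6, function(k)
      anova(lm(L[, k] ~ subj$group))$`Pr(>F)`[1] < 0.05)
  })
  expect_gte(mean(hits), 0.8)
})

test_that("regional-level generator records a consistent implied standardised beta", {
  d <- simulate_regional_data(seed = 9)
  tr <- attr(d, "truth")
  pat <- d$group != "Control"
  # crude marginal check: sample SD of the outcome matches the variance
  # budget the implied beta is computed from
  expect_equal(sd(d$weighted_degree[pat]),
               0.2 / tr$implied_std_beta["patients"],
               ignore_attr = TRUE, tolerance = 0.05)
})
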