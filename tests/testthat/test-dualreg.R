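make_dr_fixture <- function(dim3 = c(8, 9, 8), K = 3, TT = 50, seed = 41) {
  set.seed(seed)
  V <- prod(dim3)
  mask <- array(TRUE, dim3)
  maps <- matrix(rnorm(K * V), K, V)
  set <- structure(list(maps = maps, mask = mask, dim = dim3,
                        model_order = K, seed = 1L, qc = NULL),
                   class = "component_set")
  tc <- matrix(rnorm(TT * K), TT, K)
  fmri <- array(t(tc %*% maps), dim = c(dim3, TT))
  list(set = set, tc = tc, fmri = fmri, maps = maps, mask = mask)
}

test_that("stage 1 and stage 2 exactly invert a maps-by-timecourses construction", {
  fx <- make_dr_fixture()
  tc <- stage1_timecourses(fx$fmri, fx$set)
  expect_lt(max(abs(tc - fx$tc)), 1e-8)
  s2 <- stage2_maps(fx$fmri, tc, fx$mask)
  expect_lt(max(abs(s2$beta - fx$maps)), 1e-8)
  expect_lt(max(s2$noise_sd), 1e-8)
})

test_that("inactive components receive near-zero time courses", {
  fx <- make_dr_fixture()
  # activity only on component 1
  act <- matrix(0, 50, 3); act[, 1] <- rnorm(50)
  fmri <- array(t(act %*% fx$maps), dim = c(dim(fx$mask), 50))
  tc <- stage1_timecourses(fmri, fx$set)
  expect_lt(max(abs(tc[, 2:3])), 1e-8)
})

test_that("stage-1 recovery degrades monotonically with added noise", {
  fx <- make_dr_fixture()
  cors <- sapply(c(0.5, 2, 8), function(sig) {
    set.seed(99)
    noisy <- fx$fmri + array(rnorm(length(fx$fmri), sd = sig), dim(fx$fmri))
    mean(diag(cor(stage1_timecourses(noisy, fx$set), fx$tc)))
  })
  expect_true(all(diff(cors) < 0))
})

test_that("stage-2 residual noise estimates the true noise level", {
  fx <- make_dr_fixture(TT = 200)
  set.seed(77)
  noisy <- fx$fmri + array(rnorm(length(fx$fmri), sd = 1.5), dim(fx$fmri))
  tc <- stage1_timecourses(noisy, fx$set)
  s2 <- stage2_maps(noisy, tc, fx$mask)
  expect_lt(abs(mean(s2$noise_sd) - 1.5) / 1.5, 0.05)
  # pure-noise voxels: betas near zero relative to map scale
  pure <- array(rnorm(length(fx$fmri), sd = 1.5), dim(fx$fmri))
  s2p <- stage2_maps(pure, tc, fx$mask)
  expect_lt(mean(abs(s2p$beta)), 0.1)
})

test_that("degenerate dual-regression inputs are rejected", {
  fx <- make_dr_fixture()
  tc <- stage1_timecourses(fx$fmri, fx$set)
  expect_error(stage2_maps(fx$fmri, cbind(tc, tc[, 1]), fx$mask), "collinear")
  expect_error(stage2_maps(fx$fmri[, , , 1:4], tc[1:4, ], fx$mask),
               "timepoints")
  # collinear spatial maps
  bad <- fx$set
  bad$maps[2, ] <- bad$maps[1, ]
  expect_error(stage1_timecourses(fx$fmri, bad), "collinear")
})

test_that("the full dual regression scales scores linearly with the data", {
  fx <- make_dr_fixture()
  set.seed(5)
  noisy <- fx$fmri + array(rnorm(length(fx$fmri)), dim(fx$fmri))
  dr1 <- dual_regression(noisy, fx$set)
  dr2 <- dual_regression(noisy * 3, fx$set)
  msk <- component_territory_mask(fx$set$maps[1, ], 90)
  # beta maps scale by 3; normalised maps are scale-free
  expect_equal(connectivity_score(dr2$beta[1, ], msk),
               3 * connectivity_score(dr1$beta[1, ], msk), tolerance = 1e-8)
  expect_equal(connectivity_score(dr2$normalised[1, ], msk),
               connectivity_score(dr1$normalised[1, ], msk), tolerance = 1e-8)
})

test_that("territory masks follow the percentile definition and rank invariance", {
  set.seed(42)
  v <- rnorm(1000)
  m <- component_territory_mask(v, 97.5)
  expect_equal(sum(m), 25)
  expect_true(all(component_territory_mask(v, 0) | v <= min(v)))
  # monotone transform leaves the mask unchanged
  expect_identical(component_territory_mask(exp(v), 97.5), m)
  # raising the percentile shrinks the inside and grows the outside
  m90 <- component_territory_mask(v, 90)
  expect_true(all(m[m90 == FALSE] == FALSE | !any(m & !m90)))
  expect_true(all(which(m) %in% which(m90)))
})

test_that("connectivity scores are mask means with disjoint inside/outside", {
  v <- rep(2.5, 100)
  msk <- rep(c(TRUE, FALSE), 50)
  expect_equal(connectivity_score(v, msk), 2.5)
  expect_error(connectivity_score(v, rep(FALSE, 100)), "empty")
  cm <- rep(TRUE, 100)
  tm <- seq_len(100) <= 10
  expect_equal(sum(tm & (cm & !tm)), 0)
})

test_that("control connectivity masks recover planted signal and respect alpha = 1", {
  set.seed(43)
  n <- 24; V <- 800
  X <- matrix(rnorm(n * V), n, V)
  blob <- 1:60
  X[, blob] <- X[, blob] + 2
  m <- control_connectivity_mask(X, alpha = 0.01, n_perm = 500, seed = 2)
  expect_gte(mean(m[blob]), 0.9)
  expect_lte(mean(m[-blob]), 0.05)
  expect_true(all(control_connectivity_mask(X, alpha = 1, n_perm = 200,
                                            seed = 3)))
  expect_error(control_connectivity_mask(X[1:3, ], 0.01), "5 controls")
})

test_that("voxelwise loading association localises a planted remote effect", {
  set.seed(44)
  n <- 30; V <- 600
  load <- rnorm(n)
  covs <- data.frame(age = rnorm(n))
  Y <- matrix(rnorm(n * V), n, V)
  blob <- 41:80
  Y[, blob] <- Y[, blob] + load %o% rep(1.2, length(blob))
  out <- voxelwise_loading_association(Y, load, covs, n_perm = 300, seed = 5)
  sig <- out$p_fwe <= 0.05
  dice <- 2 * sum(sig[blob]) / (sum(sig) + length(blob))
  expect_gte(dice, 0.5)
  # covariate-only signal produces no detections
  Y2 <- matrix(rnorm(n * V), n, V) + covs$age %o% rep(1, V)
  out2 <- voxelwise_loading_association(Y2, load, covs, n_perm = 300, seed = 6)
  expect_lte(sum(out2$p_fwe <= 0.05), 2)
  expect_error(voxelwise_loading_association(Y, load, covs, n_perm = 50), "100")
})
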