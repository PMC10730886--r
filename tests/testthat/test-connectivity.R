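test_that("parcel time series equal the voxel means, against a brute-force loop", {
  study <- small_study()
  sp <- study$subparcellation
  vol <- simulate_subject_fmri(study, 1)
  ts <- parcel_timeseries(vol, sp)
  d <- dim(vol)
  # brute force on a handful of parcels and timepoints
  for (sid in sample(sp$table$subparcel_id, 5)) {
    idx <- which(sp$labels == sid)
    for (t in c(1, 17, 60)) {
      vals <- matrix(vol, prod(d[1:3]), d[4])[idx, t]
      expect_equal(ts[t, as.character(sid)], mean(vals), tolerance = 1e-12,
                   ignore_attr = TRUE)
    }
  }
})

test_that("degenerate parcel time-series inputs behave as specified", {
  sp <- list(labels = array(c(1L, 1L, 2L, 0L, 2L, 1L, 2L, 2L),
                            dim = c(2, 2, 2)),
             table = data.frame(subparcel_id = 1:2, region_id = c(1L, 1L),
                                voxel_count = c(3L, 4L)))
  class(sp) <- "subparcellation"
  TT <- 12
  set.seed(3)
  base <- rnorm(TT)
  vol <- array(rep(base, each = 8), dim = c(2, 2, 2, TT))
  ts <- parcel_timeseries(vol, sp)
  # identical voxel series make identical parcel series
  expect_equal(ts[, 1], ts[, 2], tolerance = 1e-12)
  expect_equal(unname(ts[, 1]), base, tolerance = 1e-12)
  expect_error(parcel_timeseries(vol[, , , 1:5, drop = FALSE], sp), "10 timepoints")
  expect_error(parcel_timeseries(array(0, c(3, 3, 3, 20)), sp), "mismatch")
})

test_that("a single-voxel subparcel reproduces its voxel series", {
  labels <- array(0L, c(3, 3, 3))
  labels[1, 1, 1] <- 1L; labels[3, 3, 3] <- 2L
  sp <- structure(list(labels = labels,
                       table = data.frame(subparcel_id = 1:2,
                                          region_id = c(1L, 2L),
                                          voxel_count = c(1L, 1L))),
                  class = "subparcellation")
  set.seed(1)
  vol <- array(rnorm(27 * 15), c(3, 3, 3, 15))
  ts <- parcel_timeseries(vol, sp)
  expect_equal(unname(ts[, "1"]), vol[1, 1, 1, ], tolerance = 1e-14)
})

test_that("Fisher connectivity matches atanh with clipping at coincident series", {
  set.seed(4)
  x <- matrix(rnorm(300), 30, 10)
  z <- fisher_connectivity(x)
  expect_true(isSymmetric(unclass(z)))
  expect_true(all(diag(z) == 0))
  expect_equal(unclass(z)[1, 2], atanh(cor(x[, 1], x[, 2])), tolerance = 1e-12)
  # exact closed form: r = 0.5 -> 0.5493
  expect_equal(atanh(0.5), 0.549306144334, tolerance = 1e-10)
  # duplicate column: clipped, finite, > 18
  x2 <- cbind(x, x[, 1])
  z2 <- fisher_connectivity(x2)
  expect_true(is.finite(z2[1, 11]))
  expect_equal(z2[1, 11], atanh(1 - 1e-15), tolerance = 1e-12)
  expect_gt(z2[1, 11], 17)
  # constant column error names the node
  x3 <- x; x3[, 4] <- 2
  colnames(x3) <- paste0("p", 1:10)
  expect_error(fisher_connectivity(x3), "p4")
  expect_error(fisher_connectivity(x[1:5, ]), "10 timepoints")
})

test_that("weighted degree is the signed row sum and invariant to node order", {
  z <- matrix(0, 3, 3)
  z[1, 2] <- z[2, 1] <- 0.2
  z[1, 3] <- z[3, 1] <- 0.4
  z[2, 3] <- z[3, 2] <- -0.1
  expect_equal(unname(weighted_degree(structure(z, class = c("connectivity_matrix", "matrix")))),
               c(0.6, 0.1, 0.3), tolerance = 1e-12)
  expect_true(all(weighted_degree(structure(matrix(0, 4, 4),
    class = c("connectivity_matrix", "matrix"))) == 0))
  set.seed(5)
  ts <- matrix(rnorm(20 * 20), 20, 20)
  colnames(ts) <- paste0("n", 1:20)
  conn <- fisher_connectivity(ts)
  deg <- weighted_degree(conn)
  expect_equal(unname(deg), bf_weighted_degree(unclass(conn)), tolerance = 1e-10)
  # permutation invariance
  ord <- sample(20)
  deg_p <- weighted_degree(fisher_connectivity(ts[, ord]))
  expect_equal(deg_p[names(deg)], deg, tolerance = 1e-10)
  # absolute mode sums |z|
  expect_equal(unname(weighted_degree(conn, absolute = TRUE)),
               unname(rowSums(abs(unclass(conn)))), tolerance = 1e-12)
})

test_that("regional aggregation of degree is the unweighted subparcel mean", {
  sp <- structure(list(labels = array(0L, c(2, 2, 2)),
                       table = data.frame(subparcel_id = 1:3,
                                          region_id = c(1L, 1L, 2L),
                                          voxel_count = 1L)),
                  class = "subparcellation")
  d <- c("1" = 1.0, "2" = 3.0, "3" = 5.0)
  out <- degree_to_regions(d, sp)
  expect_equal(unname(out), c(2.0, 5.0))
  # one subparcel per region is the identity
  sp1 <- sp; sp1$table$region_id <- 1:3
  expect_equal(unname(degree_to_regions(d, sp1)), unname(d))
  # missing subparcels yield NA for their region
  out2 <- degree_to_regions(d[c("1", "2")], sp)
  expect_true(is.na(out2["2"]))
  # brute-force random instance
  set.seed(6)
  sp2 <- structure(list(labels = array(0L, c(2, 2, 2)),
                        table = data.frame(subparcel_id = 1:12,
                                           region_id = rep(1:4, each = 3),
                                           voxel_count = 1L)),
                   class = "subparcellation")
  dv <- setNames(rnorm(12), 1:12)
  got <- degree_to_regions(dv, sp2)
  expect_equal(unname(got), as.numeric(tapply(dv, rep(1:4, each = 3), mean)),
               tolerance = 1e-12)
})

test_that("patient regional degree tracks planted density under positive coupling", {
  study <- small_study()
  wd <- study_weighted_degree(study)$regional
  pat <- study$subjects$group != "Control"
  r <- cor(as.numeric(wd[pat, ]), as.numeric(study$regional$bp[pat, ]))
  expect_gt(r, 0)
})
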