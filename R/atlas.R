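# Atlas construction, grey-matter masking, equal-volume sub-parcellation and
# regional summarisation of 3-D maps.

#' Build a synthetic labelled atlas
#'
#' Constructs a brain-like labelled volume: an ellipsoidal mask inscribed in
#' the grid is partitioned into `n_regions` contiguous-ish regions by
#' nearest-seed (Voronoi) assignment over a randomly initialised seed set
#' relaxed by Lloyd iteration (k-means on voxel coordinates), which keeps
#' region volumes within a realistic range.  Regions whose centroid falls
#' inside an inner ellipsoid (40% linear scale) are flagged subcortical,
#' mimicking the cortical/subcortical split of clinical atlases.
#'
#' @param config a [sim_config()] list (uses `grid_shape`, `n_regions`,
#'   `seed`)
#' @return a `labelled_atlas`: list with `labels` (3-D integer array,
#'   0 = background) and `region_table` (data.frame: `region_id`, `name`,
#'   `is_cortical`, `voxel_count`)
#' @export
make_atlas <- function(config) {
  dim3 <- config$grid_shape
  n_regions <- config$n_regions
  mask <- ellipsoid_mask(dim3)
  n_in <- sum(mask)
  if (n_in < 8L * n_regions)
    stop("grid too small: ", n_in, " in-mask voxels cannot give every one of ",
         n_regions, " regions >= 8 voxels")
  coords <- which(mask, arr.ind = TRUE)
  atlas <- with_seed(derive_seed(config$seed, 11L), {
    repeat {
      km <- stats::kmeans(coords, centers = n_regions, iter.max = 50L,
                          nstart = 2L)
      lab <- km$cluster
      counts <- tabulate(lab, nbins = n_regions)
      if (all(counts >= 8L)) break
    }
    labels <- array(0L, dim = dim3)
    labels[mask] <- lab
    # subcortical flag: region centroid inside inner ellipsoid
    ctr <- (dim3 + 1) / 2
    semi <- dim3 / 2 * 0.4
    inner <- rowSums(((t(t(km$centers) - ctr)) /
                        rep(semi, each = n_regions))^2) <= 1
    list(labels = labels,
         region_table = data.frame(
           region_id = seq_len(n_regions),
           name = sprintf("region_%02d", seq_len(n_regions)),
           is_cortical = !inner,
           voxel_count = counts))
  })
  structure(atlas, class = "labelled_atlas")
}

ellipsoid_mask <- function(dim3) {
  ctr <- (dim3 + 1) / 2
  semi <- dim3 / 2 - 0.5
  ix <- seq_len(dim3[1]); iy <- seq_len(dim3[2]); iz <- seq_len(dim3[3])
  d2 <- outer(outer(((ix - ctr[1]) / semi[1])^2, ((iy - ctr[2]) / semi[2])^2, "+"),
              ((iz - ctr[3]) / semi[3])^2, "+")
  d2 <= 1
}

#' @export
print.labelled_atlas <- function(x, ...) {
  rt <- x$region_table
  cat("Labelled atlas:", nrow(rt), "regions on a",
      paste(dim(x$labels), collapse = "x"), "grid\n")
  cat("  in-mask voxels:", sum(rt$voxel_count),
      "| cortical regions:", sum(rt$is_cortical), "\n")
  invisible(x)
}

#' Mask an atlas by a grey-matter probability map
#'
#' Voxels whose grey-matter probability is at or below `threshold` are set to
#' background.  If masking would empty a region entirely, that region keeps
#' its unmasked voxels instead (regions must survive in every subject).
#'
#' @param atlas a `labelled_atlas`
#' @param gm_probability 3-D array of probabilities in `[0, 1]`, same grid
#' @param threshold retention threshold (default 0.5)
#' @return a `labelled_atlas` with updated labels and voxel counts
#' @export
mask_grey_matter <- function(atlas, gm_probability, threshold = 0.5) {
  if (!identical(dim(atlas$labels), dim(gm_probability)))
    stop("grid mismatch between atlas and probability map")
  if (min(gm_probability) < 0 || max(gm_probability) > 1)
    stop("probabilities must lie in [0, 1]")
  labels <- atlas$labels
  keep <- gm_probability > threshold
  masked <- labels
  masked[!keep] <- 0L
  for (r in atlas$region_table$region_id) {
    if (!any(masked == r) && any(labels == r)) {
      masked[labels == r] <- r  # retention fallback
    }
  }
  out <- atlas
  out$labels <- masked
  out$region_table$voxel_count <-
    tabulate(masked[masked > 0L], nbins = max(atlas$region_table$region_id))[
      atlas$region_table$region_id]
  out
}

#' Drop regions from an atlas
#'
#' Mirrors exclusion of regions with unreliable coverage; excluded labels
#' become background and leave the region table.
#'
#' @param atlas a `labelled_atlas`
#' @param region_ids integer region ids to exclude
#' @return a `labelled_atlas`
#' @export
exclude_regions <- function(atlas, region_ids) {
  out <- atlas
  out$labels[out$labels %in% region_ids] <- 0L
  out$region_table <- out$region_table[!out$region_table$region_id %in% region_ids, ]
  rownames(out$region_table) <- NULL
  out
}

#' Equal-volume sub-parcellation nested in atlas regions
#'
#' Allocates sub-parcels to regions in proportion to region volume
#' (`max(1, round(target_total * region_volume / total_volume))`) and splits
#' each region by k-means on voxel coordinates, so every sub-parcel lies
#' entirely inside one parent region.
#'
#' @param atlas a `labelled_atlas`
#' @param target_total desired total number of sub-parcels (>= n regions)
#' @param seed integer seed for the k-means initialisation
#' @return a `subparcellation`: list with `labels` (3-D integer array),
#'   `table` (data.frame: `subparcel_id`, `region_id`, `voxel_count`)
#' @export
subparcellate <- function(atlas, target_total, seed = 1L) {
  rt <- atlas$region_table
  n_regions <- nrow(rt)
  if (target_total < n_regions)
    stop("target_total (", target_total, ") below number of regions (",
         n_regions, ")")
  vol <- rt$voxel_count
  alloc <- allocate_largest_remainder(vol, target_total)
  sp_labels <- array(0L, dim = dim(atlas$labels))
  map <- list()
  next_id <- 1L
  for (i in seq_len(n_regions)) {
    r <- rt$region_id[i]
    idx <- which(atlas$labels == r)
    k <- min(alloc[i], length(idx))
    if (k == 1L) {
      cl <- rep(1L, length(idx))
    } else {
      coords <- which(atlas$labels == r, arr.ind = TRUE)
      cl <- with_seed(derive_seed(seed, 23L, r), {
        km <- stats::kmeans(coords, centers = k, iter.max = 100L, nstart = 5L)
        balance_clusters(coords, km$cluster, k)
      })
    }
    ids <- next_id - 1L + cl
    sp_labels[idx] <- ids
    map[[i]] <- data.frame(subparcel_id = next_id:(next_id + k - 1L),
                           region_id = r,
                           voxel_count = tabulate(cl, nbins = k))
    next_id <- next_id + k
  }
  structure(list(labels = sp_labels, table = do.call(rbind, map)),
            class = "subparcellation")
}

#' @export
print.subparcellation <- function(x, ...) {
  cat("Sub-parcellation:", nrow(x$table), "sub-parcels in",
      length(unique(x$table$region_id)), "regions\n")
  vc <- x$table$voxel_count
  cat("  voxels per sub-parcel: min", min(vc), "median", stats::median(vc),
      "max", max(vc), "\n")
  invisible(x)
}

# Volume-proportional integer allocation whose parts sum exactly to the
# target (largest-remainder method, minimum one per region).
allocate_largest_remainder <- function(vol, target_total) {
  n <- length(vol)
  raw <- target_total * vol / sum(vol)
  base <- pmax(1L, as.integer(floor(raw)))
  short <- target_total - sum(base)
  if (short > 0) {
    # distribute the shortfall by remainder, skipping regions already
    # rounded up from below one
    ord <- order(raw - floor(raw), decreasing = TRUE)
    ord <- ord[raw[ord] >= 1]
    take <- utils::head(ord, short)
    base[take] <- base[take] + 1L
  } else if (short < 0) {
    ord <- order(raw - floor(raw))
    for (i in ord) {
      if (short == 0) break
      if (base[i] > 1L) { base[i] <- base[i] - 1L; short <- short + 1L }
    }
  }
  base
}

# Even out k-means cluster sizes: repeatedly move the voxel of the largest
# cluster that lies closest to the smallest cluster's centroid.  Keeps the
# parcels compact while enforcing approximate equal volume.
balance_clusters <- function(coords, cl, k, max_ratio = 1.5) {
  for (it in seq_len(10L * nrow(coords))) {
    sizes <- tabulate(cl, k)
    if (max(sizes) <= max_ratio * min(sizes) || max(sizes) - min(sizes) <= 1L)
      break
    big <- which.max(sizes); small <- which.min(sizes)
    ctr_small <- colMeans(coords[cl == small, , drop = FALSE])
    cand <- which(cl == big)
    d2 <- rowSums((coords[cand, , drop = FALSE] -
                     matrix(ctr_small, length(cand), 3, byrow = TRUE))^2)
    cl[cand[which.min(d2)]] <- small
  }
  cl
}

#' Per-region means of a 3-D map
#'
#' @param map_3d numeric 3-D array on the atlas grid
#' @param atlas a `labelled_atlas`
#' @return named numeric vector, one mean per region (NA for regions with no
#'   in-mask voxels)
#' @export
regional_means <- function(map_3d, atlas) {
  if (!identical(dim(map_3d), dim(atlas$labels)))
    stop("grid mismatch between map and atlas")
  lab <- atlas$labels
  keep <- lab > 0L
  sums <- rowsum(as.numeric(map_3d[keep]), lab[keep])
  cnts <- rowsum(rep(1, sum(keep)), lab[keep])
  got <- as.integer(rownames(sums))
  out <- stats::setNames(rep(NA_real_, nrow(atlas$region_table)),
                         atlas$region_table$region_id)
  out[as.character(got)] <- sums[, 1] / cnts[, 1]
  out
}

#' Region centroids in voxel coordinates
#'
#' @param atlas a `labelled_atlas`
#' @return regions x 3 matrix of mean voxel coordinates
#' @export
region_centroids <- function(atlas) {
  coords <- which(atlas$labels > 0L, arr.ind = TRUE)
  lab <- atlas$labels[atlas$labels > 0L]
  ctr <- rowsum(coords, lab) / as.vector(rowsum(rep(1, length(lab)), lab))
  rownames(ctr) <- as.integer(rownames(ctr))
  ctr[as.character(atlas$region_table$region_id), , drop = FALSE]
}

#' Overlap similarity of two sub-parcellations
#'
#' For each region, sub-parcels from the two runs are matched one-to-one
#' (Hungarian assignment on pairwise Jaccard overlap) and the mean matched
#' Jaccard is returned; values near 1 indicate a stable geometry.
#'
#' @param sp_a,sp_b `subparcellation` objects of the same atlas
#' @return mean matched Jaccard overlap across sub-parcels
#' @export
subparcellation_similarity <- function(sp_a, sp_b) {
  regions <- intersect(unique(sp_a$table$region_id), unique(sp_b$table$region_id))
  jac <- c()
  for (r in regions) {
    ids_a <- sp_a$table$subparcel_id[sp_a$table$region_id == r]
    ids_b <- sp_b$table$subparcel_id[sp_b$table$region_id == r]
    vox_a <- lapply(ids_a, function(i) which(sp_a$labels == i))
    vox_b <- lapply(ids_b, function(i) which(sp_b$labels == i))
    J <- matrix(0, length(ids_a), length(ids_b))
    for (i in seq_along(ids_a)) for (j in seq_along(ids_b)) {
      inter <- length(intersect(vox_a[[i]], vox_b[[j]]))
      J[i, j] <- inter / (length(vox_a[[i]]) + length(vox_b[[j]]) - inter)
    }
    if (nrow(J) <= ncol(J)) {
      as_ <- hungarian_assign(1 - J)
      jac <- c(jac, J[cbind(seq_len(nrow(J)), as_)])
    } else {
      as_ <- hungarian_assign(1 - t(J))
      jac <- c(jac, t(J)[cbind(seq_len(ncol(J)), as_)])
    }
  }
  mean(jac)
}
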