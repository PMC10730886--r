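# Parcel-level functional connectivity and the weighted-degree metric.

#' Mean time series per sub-parcel
#'
#' @param fmri_4d 4-D array `[x, y, z, t]` aligned to the sub-parcel volume
#' @param subparcellation a `subparcellation`
#' @return timepoints x sub-parcels matrix (columns named by sub-parcel id);
#'   sub-parcels with no in-brain voxels are dropped with a warning
#' @export
parcel_timeseries <- function(fmri_4d, subparcellation) {
  d <- dim(fmri_4d)
  if (length(d) != 4L || !identical(d[1:3], dim(subparcellation$labels)))
    stop("grid mismatch between fMRI volume and sub-parcel labels")
  if (d[4] < 10L) stop("need at least 10 timepoints")
  lab <- as.integer(subparcellation$labels)
  inb <- lab > 0L
  X <- matrix(fmri_4d, prod(d[1:3]), d[4])[inb, , drop = FALSE]
  sums <- rowsum(X, lab[inb])
  cnt <- as.vector(rowsum(rep(1, sum(inb)), lab[inb]))
  ts <- t(sums / cnt)
  colnames(ts) <- rownames(sums)
  empty <- setdiff(subparcellation$table$subparcel_id,
                   as.integer(colnames(ts)))
  if (length(empty))
    warning("dropped ", length(empty), " sub-parcel(s) with no in-brain voxels: ",
            paste(empty, collapse = ", "))
  ts
}

#' Fisher-z connectivity matrix
#'
#' Pearson correlations between node time series, Fisher r-to-Z transformed
#' (`atanh`), with r clipped to +/-(1 - 1e-15) so coincident series remain
#' finite.  Diagonal is exactly zero.
#'
#' @param timeseries timepoints x nodes matrix (>= 10 timepoints)
#' @return a `connectivity_matrix`: symmetric nodes x nodes matrix of
#'   Fisher-z values with zero diagonal
#' @export
fisher_connectivity <- function(timeseries) {
  if (nrow(timeseries) < 10L) stop("need at least 10 timepoints")
  sds <- apply(timeseries, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(timeseries)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("constant time series for node(s): ", paste(bad, collapse = ", "))
  }
  r <- stats::cor(timeseries)
  clip <- 1 - 1e-15
  r <- pmin(pmax(r, -clip), clip)
  z <- atanh(r)
  diag(z) <- 0
  structure(z, class = c("connectivity_matrix", "matrix"))
}

#' Weighted degree of every node
#'
#' Signed sum of Fisher-z edge weights to all other nodes.  An optional
#' absolute-value mode sums `|z|` instead.
#'
#' @param conn a `connectivity_matrix`
#' @param absolute sum absolute edge weights instead of signed weights
#' @return named numeric vector of per-node degrees
#' @export
weighted_degree <- function(conn, absolute = FALSE) {
  if (!isSymmetric(unclass(conn), tol = 1e-8))
    stop("connectivity matrix must be symmetric")
  m <- unclass(conn)
  diag(m) <- 0
  if (absolute) m <- abs(m)
  stats::setNames(rowSums(m), colnames(m))
}

#' Aggregate sub-parcel degrees to atlas regions
#'
#' Region value = unweighted mean of the degrees of its surviving
#' sub-parcels; regions with none get `NA`.
#'
#' @param subparcel_degrees named vector from [weighted_degree()] (names =
#'   sub-parcel ids)
#' @param subparcellation a `subparcellation`
#' @return named per-region vector
#' @export
degree_to_regions <- function(subparcel_degrees, subparcellation) {
  tab <- subparcellation$table
  ids <- as.integer(names(subparcel_degrees))
  if (any(is.na(ids))) stop("subparcel degrees must be named by sub-parcel id")
  parent <- tab$region_id[match(ids, tab$subparcel_id)]
  agg <- tapply(subparcel_degrees, parent, mean)
  regions <- sort(unique(tab$region_id))
  out <- stats::setNames(rep(NA_real_, length(regions)), regions)
  out[names(agg)] <- agg
  out
}

#' Per-subject regional weighted degree for a whole study
#'
#' Convenience wrapper running fMRI synthesis (or supplied volumes), parcel
#' extraction, Fisher-z connectivity and regional degree aggregation for
#' every subject of a synthetic study.
#'
#' @param study a `sim_study`
#' @param absolute passed to [weighted_degree()]
#' @return list: `regional` (subjects x regions matrix),
#'   `subparcel` (subjects x sub-parcels matrix)
#' @export
study_weighted_degree <- function(study, absolute = FALSE) {
  n <- nrow(study$subjects)
  sp <- study$subparcellation
  reg_ids <- sort(unique(sp$table$region_id))
  reg <- matrix(NA_real_, n, length(reg_ids),
                dimnames = list(study$subjects$subject_id, reg_ids))
  spd <- matrix(NA_real_, n, nrow(sp$table),
                dimnames = list(study$subjects$subject_id,
                                sp$table$subparcel_id))
  for (s in seq_len(n)) {
    ts <- simulate_subject_fmri(study, s, voxelwise = FALSE)
    colnames(ts) <- sp$table$subparcel_id
    deg <- weighted_degree(fisher_connectivity(ts), absolute = absolute)
    spd[s, names(deg)] <- deg
    rv <- degree_to_regions(deg, sp)
    reg[s, names(rv)] <- rv
  }
  list(regional = reg, subparcel = spd)
}
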