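# Shared fixtures: a reduced study configuration keeps unit tests fast while
# exercising every stage; expensive objects are built once per test run.

small_config <- function(seed = 11L, ...) {
  sim_config(grid_shape = c(14L, 16L, 14L), n_regions = 10L,
             n_subparcels = 24L,
             group_sizes = c(Control = 6L, PSP = 6L, CBS = 5L, bvFTD = 5L),
             n_components_true = 4L, n_timepoints = 60L, seed = seed, ...)
}

.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- force(expr)
  .fixture_env[[name]]
}

small_study <- function() cached("small_study", simulate_study(small_config()))

default_atlas <- function() cached("default_atlas", make_atlas(sim_config(seed = 5L)))

# brute-force oracles, kept deliberately naive and independent of the
# implementation paths they check

bf_regional_means <- function(map, atlas) {
  ids <- atlas$region_table$region_id
  out <- setNames(rep(NA_real_, length(ids)), ids)
  for (r in ids) {
    vals <- c()
    for (i in seq_along(map)) if (atlas$labels[i] == r) vals <- c(vals, map[i])
    if (length(vals)) out[as.character(r)] <- sum(vals) / length(vals)
  }
  out
}

bf_weighted_degree <- function(z) {
  n <- nrow(z)
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (j in seq_len(n)) if (j != i) s <- s + z[i, j]
    out[i] <- s
  }
  out
}

bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  if (m > 1) for (i in (m - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

bf_grubbs_G <- function(x) {
  max(abs(x - mean(x))) / sd(x)
}
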