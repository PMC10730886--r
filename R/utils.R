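# Internal utilities: seed streams, standardisation, assignment, permutations.

#' Derive a child seed from a parent seed and integer offsets
#'
#' Deterministic LCG-style hash kept strictly below 2^31 so it is always a
#' valid R integer seed.  Used to give every stochastic stage of a simulation
#' its own reproducible stream.
#'
#' @param seed parent integer seed
#' @param ... integer offsets identifying the sub-stream
#' @return an integer seed in `[1, 2^31 - 1]`
#' @keywords internal
derive_seed <- function(seed, ...) {
  off <- c(...)
  x <- as.double(seed) %% 2147483647
  for (o in off) x <- (x * 48271 + as.double(o) + 1) %% 2147483647
  as.integer(x %% 2147483646) + 1L
}

#' Evaluate code under a temporary RNG seed
#'
#' Restores the caller's RNG state on exit, so seeded helpers do not perturb
#' the global random stream.
#'
#' @param seed integer seed
#' @param code expression to evaluate
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  code
}

#' Standardise a numeric vector to mean 0, SD 1
#'
#' @param x numeric vector
#' @param na.rm drop missing values when computing moments
#' @return standardised vector
#' @export
zscore <- function(x, na.rm = TRUE) {
  m <- mean(x, na.rm = na.rm)
  s <- stats::sd(x, na.rm = na.rm)
  if (!is.finite(s) || s == 0) stop("cannot standardise: zero or non-finite SD")
  (x - m) / s
}

#' Optimal one-to-one assignment (Hungarian algorithm)
#'
#' Minimises total cost over one-to-one assignments of rows to columns
#' (`nrow(cost) <= ncol(cost)`).  O(n^2 m) shortest-augmenting-path variant.
#'
#' @param cost numeric cost matrix
#' @return integer vector: column assigned to each row
#' @keywords internal
hungarian_assign <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  if (n > m) stop("hungarian_assign: need nrow <= ncol")
  if (any(!is.finite(cost))) stop("hungarian_assign: non-finite costs")
  # 1-based port of the classic potentials algorithm; index j+1 holds column j,
  # index 1 the virtual column 0.
  u <- numeric(n + 1); v <- numeric(m + 1)
  p <- integer(m + 1); way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, m)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- Inf; j1 <- 0L
      for (j in seq_len(m)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j]) { minv[j] <- cur; way[j + 1] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in 0:m) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(m)) if (p[j + 1] > 0L) ans[p[j + 1]] <- j
  ans
}

#' Shared permutation index matrix
#'
#' One seed produces one matrix of permutation indices reused across
#' modalities and contrasts; synchronised permutations are required for valid
#' non-parametric combination.
#'
#' @param n number of observations
#' @param n_perm number of permutations
#' @param seed integer seed
#' @return `n x n_perm` integer matrix; each column a permutation of `1:n`
#' @export
make_permutations <- function(n, n_perm, seed = 1L) {
  stopifnot(n >= 2, n_perm >= 1)
  with_seed(seed, {
    matrix(vapply(seq_len(n_perm), function(j) sample.int(n), integer(n)),
           nrow = n, ncol = n_perm)
  })
}

# Gaussian-smoothed white noise field on a 3-D grid (separable kernel).
smooth_field <- function(dim3, sigma_vox) {
  x <- array(stats::rnorm(prod(dim3)), dim = dim3)
  if (sigma_vox <= 0) return(x)
  ker <- function(s) {
    half <- max(1L, ceiling(3 * s))
    k <- exp(-0.5 * ((-half):half / s)^2)
    k / sum(k)
  }
  k <- ker(sigma_vox)
  conv1 <- function(a, k, dimn) {
    half <- (length(k) - 1L) / 2L
    out <- array(0, dim = dim(a))
    n <- dim(a)[dimn]
    for (off in (-half):half) {
      idx <- pmin(pmax(seq_len(n) + off, 1L), n)  # replicate edges
      sl <- switch(dimn, a[idx, , , drop = FALSE], a[, idx, , drop = FALSE],
                   a[, , idx, drop = FALSE])
      out <- out + k[off + half + 1L] * sl
    }
    out
  }
  x <- conv1(x, k, 1L); x <- conv1(x, k, 2L); x <- conv1(x, k, 3L)
  x / stats::sd(x)
}

# consistent missing marker for regional tables
na_real <- NA_real_
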