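#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor cov sd median rnorm runif prcomp lm.fit p.adjust
#'   pt approx spline smooth.spline predict fft convolve chol2inv
#' @importFrom utils head tail write.table read.table modifyList
NULL

# Derive a stream of child seeds from one master seed.  Streams are indexed
# by a counter so that adding a consumer never shifts the seeds of existing
# consumers.  Kept below .Machine$integer.max.
derive_seed <- function(master_seed, counter) {
  as.integer((as.double(master_seed) * 48271 + counter * 7919) %% 2147483647L)
}

vec_norm <- function(x) sqrt(sum(x^2))

# Solve the linear assignment problem (minimise total cost) for a square
# cost matrix by the Hungarian algorithm (Jonker-Volgenant style shortest
# augmenting paths).  Returns for each row the assigned column.
hungarian_assign <- function(cost) {
  stopifnot(is.matrix(cost), nrow(cost) == ncol(cost))
  n <- nrow(cost)
  INF <- sum(abs(cost)) + 1
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  p <- integer(n + 1)      # p[j]: row assigned to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L
    minv <- rep(INF, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- INF
      j1 <- 0L
      for (j in seq_len(n) + 1L) {
        if (!used[j]) {
          cur <- cost[i0, j - 1L] - u[i0 + 0L] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in seq_len(n + 1L)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  assign <- integer(n)
  for (j in seq_len(n)) if (p[j + 1L] > 0L) assign[p[j + 1L]] <- j
  assign
}

#' Match two sets of spatial maps by maximal absolute correlation
#'
#' Components estimated by ICA are defined only up to permutation and sign, so
#' comparing an estimated set of maps against a reference set requires an
#' optimal one-to-one matching.  This computes the absolute spatial
#' correlation between every reference/estimate pair and solves the
#' assignment problem maximising total |r|.
#'
#' @param reference matrix, maps in rows (maps x voxels).
#' @param estimate matrix, maps in rows, same voxel count.
#' @return a data.frame with one row per reference map: `ref`, `est`
#'   (matched estimate index) and `abs_r` (absolute spatial correlation).
#' @export
match_maps <- function(reference, estimate) {
  stopifnot(ncol(reference) == ncol(estimate))
  R <- abs(cor(t(reference), t(estimate)))
  R[is.na(R)] <- 0
  n <- max(nrow(R), ncol(R))
  # pad to square with zero-similarity dummies
  C <- matrix(1, n, n)
  C[seq_len(nrow(R)), seq_len(ncol(R))] <- 1 - R
  a <- hungarian_assign(C)
  out <- data.frame(ref = seq_len(nrow(R)), est = a[seq_len(nrow(R))])
  out$abs_r <- ifelse(out$est <= ncol(R), R[cbind(out$ref, pmin(out$est, ncol(R)))], 0)
  out$est[out$est > ncol(R)] <- NA_integer_
  out
}

# Upper-triangle vectorisation helpers shared by the FNC and state code.
# Column-major order of the strict upper triangle, i.e. (1,2), (1,3), (2,3), ...
ut_index <- function(p) which(upper.tri(diag(p)))

vec_ut <- function(m) m[upper.tri(m)]

unvec_ut <- function(v, p) {
  m <- diag(p)
  m[upper.tri(m)] <- v
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}
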