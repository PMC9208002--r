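#' Z-score each voxel time course of a dataset
#'
#' Variance normalisation applied before ICA: every voxel time course is
#' centred and scaled to unit standard deviation, so temporal coupling (not
#' amplitude) drives the decomposition.
#'
#' @param ds an `msfnc_dataset`.
#' @return the dataset with normalised `data`.
#' @export
normalize_dataset <- function(ds) {
  stopifnot(inherits(ds, "msfnc_dataset"))
  mu <- rowMeans(ds$data)
  s <- apply(ds$data, 1, sd)
  if (any(s == 0)) stop("zero-variance voxel time course in ", ds$subject_id)
  ds$data <- (ds$data - mu) / s
  ds
}

#' Subject-level spatial PCA with whitening
#'
#' Reduces a subject's voxels x time matrix to `d` whitened spatial
#' components, where `d` is the smallest dimension whose cumulative
#' explained variance reaches `var_retained`.  Rows of the output are
#' mutually uncorrelated over voxels with unit variance.
#'
#' @param ds an `msfnc_dataset`, or a plain voxels x time matrix.
#' @param var_retained fraction of variance to retain (default 0.9999,
#'   i.e. essentially lossless reduction).
#' @return list with `whitened` (d x voxels), `d`, `explained`
#'   (per-component variance fractions) and `sdev`.
#' @export
subject_pca <- function(ds, var_retained = 0.9999) {
  x <- if (inherits(ds, "msfnc_dataset")) ds$data else ds
  stopifnot(is.matrix(x), ncol(x) >= 2)
  if (all(apply(x, 2, sd) == 0)) stop("zero-variance input")
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  explained <- ev / sum(ev)
  d <- which(cumsum(explained) >= var_retained - 1e-12)[1]
  if (is.na(d)) d <- length(ev)
  scores <- pc$x[, seq_len(d), drop = FALSE]
  nv <- nrow(x)
  # unit variance over voxels (divisor nv - 1, matching cov())
  white <- t(scores) / pc$sdev[seq_len(d)]
  list(whitened = white, d = d, explained = explained,
       sdev = pc$sdev[seq_len(d)])
}

#' Group-level spatial PCA over concatenated subject components
#'
#' Subject-whitened component maps are stacked along the component (time)
#' dimension and the `N` directions of maximal spatial variance of the stack
#' are retained and whitened, giving the input to group ICA.
#'
#' @param subject_whitened list of d_s x voxels matrices from [subject_pca()].
#' @param n_components model order N.
#' @return list with `whitened` (N x voxels) and `sdev`.
#' @export
group_pca <- function(subject_whitened, n_components) {
  if (is.matrix(subject_whitened)) subject_whitened <- list(subject_whitened)
  G <- do.call(rbind, subject_whitened)
  total <- nrow(G)
  if (n_components > total)
    stop("model order ", n_components, " exceeds the ", total,
         " concatenated subject components")
  pc <- prcomp(t(G), center = TRUE, scale. = FALSE)
  if (n_components > sum(pc$sdev > 1e-10))
    stop("model order ", n_components, " exceeds the effective rank ",
         sum(pc$sdev > 1e-10), " of the concatenated data")
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  list(whitened = t(scores) / pc$sdev[seq_len(n_components)],
       sdev = pc$sdev[seq_len(n_components)])
}

#' Infomax independent component analysis
#'
#' Natural-gradient Infomax on whitened data: spatial maps are the
#' recovered sources and the algorithm maximises their independence over
#' voxels.  The default "extended" variant estimates the kurtosis sign of
#' each source every iteration and uses the matching tanh score, so both
#' super- and sub-Gaussian sources separate; `extended = FALSE` uses the
#' classical logistic score (appropriate for sparse, super-Gaussian spatial
#' maps).  Updates are full-batch, the learning rate anneals whenever the
#' update direction reverses, and convergence is declared when the relative
#' weight change drops below `tol`.  Non-convergence is flagged on the
#' result, not raised as an error.
#'
#' @param x N x voxels whitened matrix.
#' @param seed integer seed (controls the random orthogonal start).
#' @param lrate initial learning rate.
#' @param extended use the kurtosis-sign extended score (default TRUE).
#' @param tol convergence tolerance on the relative weight-change norm.
#' @param max_iter maximum number of iterations.
#' @return list with `W` (unmixing matrix), `S` (sources, rows unit
#'   variance, sign set so the peak-magnitude voxel is positive),
#'   `converged`, `iterations`, `delta`.
#' @export
infomax_ica <- function(x, seed = 1L, lrate = 0.1, extended = TRUE,
                        tol = 1e-6, max_iter = 1024L) {
  stopifnot(is.matrix(x))
  n <- nrow(x)
  nv <- ncol(x)
  set.seed(seed)
  # random orthogonal start keeps the whitening intact
  W <- qr.Q(qr(matrix(rnorm(n * n), n, n)))
  I_n <- diag(n)
  delta <- Inf
  iter <- 0L
  dW_old <- NULL
  while (iter < max_iter && delta > tol) {
    iter <- iter + 1L
    u <- W %*% x
    if (extended) {
      ksign <- sign(rowMeans(u^4) - 3 * rowMeans(u^2)^2)
      ksign[ksign == 0] <- 1
      grad <- I_n - (ksign * tanh(u)) %*% t(u) / nv - tcrossprod(u) / nv
    } else {
      y <- 1 / (1 + exp(-u))
      grad <- I_n + ((1 - 2 * y) %*% t(u)) / nv
    }
    dW <- lrate * grad %*% W
    W2 <- W + dW
    if (!all(is.finite(W2)) || max(abs(W2)) > 1e8) {
      lrate <- lrate * 0.5
      dW_old <- NULL
      next
    }
    if (!is.null(dW_old) && sum(dW * dW_old) < 0) lrate <- lrate * 0.9
    delta <- sqrt(sum(dW^2)) / sqrt(sum(W^2))
    dW_old <- dW
    W <- W2
  }
  S <- W %*% x
  sc <- apply(S, 1, sd)
  sc[sc == 0] <- 1
  S <- S / sc
  W <- W / sc
  sgn <- vapply(seq_len(n), function(i) {
    v <- S[i, ]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  sgn[sgn == 0] <- 1
  S <- S * sgn
  W <- W * sgn
  list(W = W, S = S, converged = delta <= tol, iterations = iter, delta = delta)
}

#' ICASSO-style stability analysis of repeated ICA runs
#'
#' Runs Infomax `n_runs` times from different random initial conditions
#' (optionally with bootstrap resampling of voxels), pools all estimated
#' components, clusters them by absolute spatial correlation with
#' average-linkage agglomeration into N clusters, and scores each cluster
#' with a stability (quality) index: mean within-cluster similarity minus
#' mean similarity to components outside the cluster.  The run whose
#' components are jointly closest to the N cluster centrotypes is the best
#' run; its components (with per-component stability) are returned.
#'
#' @param x N x voxels whitened matrix.
#' @param n_runs number of ICA runs (>= 2).
#' @param seed master seed; per-run seeds are derived from it.
#' @param bootstrap also resample voxels with replacement per run.
#' @param ... passed to [infomax_ica()].
#' @return list with `stability` (per returned component), `centrotypes`
#'   (N x voxels), `best_run`, `S` (best run's components, reordered to
#'   match the clusters), `W`, `runs_converged`.
#' @export
icasso <- function(x, n_runs = 10L, seed = 1L, bootstrap = FALSE, ...) {
  stopifnot(n_runs >= 2)
  n <- nrow(x)
  nv <- ncol(x)
  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    xr <- x
    if (bootstrap) {
      set.seed(derive_seed(seed, 5000L + r))
      xr <- x[, sample.int(nv, nv, replace = TRUE), drop = FALSE]
    }
    fit <- infomax_ica(xr, seed = derive_seed(seed, r), ...)
    if (bootstrap) fit$S <- fit$W %*% x    # evaluate maps on the full grid
    runs[[r]] <- fit
  }
  pool <- do.call(rbind, lapply(runs, `[[`, "S"))    # (n_runs*N) x voxels
  sim <- abs(cor(t(pool)))
  sim[is.na(sim)] <- 0
  diag(sim) <- 1
  if (min(sim) >= 1 - 1e-12) {
    cl <- rep(seq_len(n), n_runs)                    # degenerate: all identical
  } else {
    hc <- stats::hclust(stats::as.dist(1 - sim), method = "average")
    cl <- stats::cutree(hc, k = n)
  }
  stability <- numeric(n)
  centro_idx <- integer(n)
  for (k in seq_len(n)) {
    members <- which(cl == k)
    others <- which(cl != k)
    intra <- if (length(members) > 1)
      mean(sim[members, members][upper.tri(diag(length(members)))]) else 1
    extra <- if (length(others) > 0) mean(sim[members, others, drop = FALSE]) else 0
    stability[k] <- intra - extra
    centro_idx[k] <- members[which.max(colSums(sim[members, members, drop = FALSE]))]
  }
  centrotypes <- pool[centro_idx, , drop = FALSE]
  # best run: minimal summed (1 - |r|) distance of its components to the
  # centrotypes under an optimal one-to-one matching
  run_cost <- vapply(seq_len(n_runs), function(r) {
    m <- match_maps(centrotypes, runs[[r]]$S)
    sum(1 - m$abs_r)
  }, numeric(1))
  best <- which.min(run_cost)
  mb <- match_maps(centrotypes, runs[[best]]$S)
  ord <- mb$est
  list(stability = stability, centrotypes = centrotypes, best_run = best,
       S = runs[[best]]$S[ord, , drop = FALSE],
       W = runs[[best]]$W[ord, , drop = FALSE],
       cluster = cl,
       runs_converged = vapply(runs, `[[`, logical(1), "converged"))
}

#' Back-reconstruct subject component time courses by spatial regression
#'
#' At each time point the subject volume is regressed jointly on all group
#' spatial maps; the ordinary-least-squares coefficients are the subject's
#' component time courses (spatial multiple regression / dual-regression
#' first step).
#'
#' @param ds an `msfnc_dataset` (or voxels x time matrix).
#' @param group_maps components x voxels matrix.
#' @return time x components matrix.
#' @export
back_reconstruct <- function(ds, group_maps) {
  x <- if (inherits(ds, "msfnc_dataset")) ds$data else ds
  stopifnot(ncol(group_maps) == nrow(x))
  A <- t(group_maps)                   # voxels x components
  qa <- qr(A)
  if (qa$rank < ncol(A)) {
    cc <- abs(cor(A))
    diag(cc) <- 0
    bad <- which(cc > 0.999, arr.ind = TRUE)
    bad <- bad[bad[, 1] < bad[, 2], , drop = FALSE]
    stop("group maps are rank deficient; near-collinear pairs: ",
         paste(apply(bad, 1, paste, collapse = "~"), collapse = ", "))
  }
  t(qr.coef(qa, x))                    # time x components
}

# subject-specific spatial maps: second (temporal) regression step
subject_maps <- function(ds, tc) {
  x <- if (inherits(ds, "msfnc_dataset")) ds$data else ds
  stopifnot(nrow(tc) == ncol(x))
  t(qr.coef(qr(tc), t(x)))             # components x voxels -> transpose later
}

#' Run the full multiscale group-ICA chain at several model orders
#'
#' For each model order: subject PCA, group PCA, repeated Infomax with
#' ICASSO stability selection, and spatial-regression back-reconstruction of
#' every subject's component time courses and maps.  Orders are processed
#' independently; all randomness derives from one master seed.
#'
#' @param datasets list of `msfnc_dataset`.
#' @param orders integer vector of ICA model orders (default
#'   `c(25, 50, 75, 100)`).
#' @param n_runs ICA repetitions for the stability analysis.
#' @param var_retained subject-level variance retained.
#' @param seed master seed.
#' @param normalize z-score voxel time courses before decomposition.
#' @param keep_subject_maps also back-reconstruct subject spatial maps.
#' @param ... passed to [infomax_ica()].
#' @return list of `msfnc_decomposition` objects keyed `"order<N>"`.
#' @export
run_multiscale <- function(datasets, orders = c(25L, 50L, 75L, 100L),
                           n_runs = 10L, var_retained = 0.9999, seed = 1L,
                           normalize = TRUE, keep_subject_maps = FALSE, ...) {
  stopifnot(length(datasets) >= 1, !anyDuplicated(orders), all(orders >= 2))
  if (normalize) datasets <- lapply(datasets, normalize_dataset)
  subj_white <- lapply(datasets, subject_pca, var_retained = var_retained)
  out <- list()
  for (oi in seq_along(orders)) {
    N <- orders[oi]
    res <- tryCatch({
      gp <- group_pca(lapply(subj_white, `[[`, "whitened"), N)
      ic <- if (n_runs >= 2)
        icasso(gp$whitened, n_runs = n_runs, seed = derive_seed(seed, 1000L * oi), ...)
      else {
        fit <- infomax_ica(gp$whitened, seed = derive_seed(seed, 1000L * oi), ...)
        list(stability = rep(NA_real_, N), S = fit$S, W = fit$W,
             best_run = 1L, runs_converged = fit$converged)
      }
      tcs <- lapply(datasets, back_reconstruct, group_maps = ic$S)
      smaps <- if (keep_subject_maps)
        lapply(seq_along(datasets), function(i) subject_maps(datasets[[i]], tcs[[i]]))
      else NULL
      structure(list(order = N, group_maps = ic$S, stability = ic$stability,
                     best_run = ic$best_run, subject_timecourses = tcs,
                     subject_maps = smaps,
                     runs_converged = ic$runs_converged,
                     tr_seconds = datasets[[1]]$tr_seconds),
                class = "msfnc_decomposition")
    }, error = function(e)
      stop("model order ", N, ": ", conditionMessage(e), call. = FALSE))
    out[[paste0("order", N)]] <- res
  }
  out
}

#' @export
print.msfnc_decomposition <- function(x, ...) {
  cat("Group ICA decomposition, model order", x$order, "\n")
  cat("  subjects:", length(x$subject_timecourses), "\n")
  if (!all(is.na(x$stability)))
    cat("  stability index: median", round(median(x$stability), 3),
        " min", round(min(x$stability), 3), "\n")
  invisible(x)
}
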