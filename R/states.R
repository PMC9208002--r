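#' Select exemplar windows (local maxima of FNC variance)
#'
#' For each subject, the variance across pair values of every windowed-FNC
#' vector is computed and the windows at strict local maxima of that
#' variance series (both neighbours smaller; endpoints excluded) are
#' returned as exemplars for the first clustering stage.
#'
#' @param series an `msfnc_window_series` or list of them.
#' @return list with `windows` (exemplars x pairs matrix), `subject`
#'   (subject id per exemplar) and `index` (window index per exemplar).
#' @export
select_exemplars <- function(series) {
  if (inherits(series, "msfnc_window_series")) series <- list(series)
  wins <- list(); subj <- character(0); idx <- integer(0)
  for (s in series) {
    x <- s$windows[s$valid, , drop = FALSE]
    if (nrow(x) < 3) stop("need at least 3 windows per subject")
    v <- apply(x, 1, stats::var)
    n <- length(v)
    loc <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] > v[3:n]) + 1L
    if (length(loc) == 0) {
      warning("no local variance maxima for ", s$subject_id,
              "; falling back to the first window")
      loc <- 1L
    }
    wins[[length(wins) + 1L]] <- x[loc, , drop = FALSE]
    subj <- c(subj, rep(s$subject_id, length(loc)))
    idx <- c(idx, loc)
  }
  list(windows = do.call(rbind, wins), subject = subj, index = idx)
}

# pairwise distances between rows of x and rows of centers
state_dist <- function(x, centers, distance) {
  switch(distance,
    euclidean = {
      d2 <- outer(rowSums(x^2), rowSums(centers^2), "+") - 2 * tcrossprod(x, centers)
      sqrt(pmax(d2, 0))
    },
    cityblock = {
      out <- matrix(0, nrow(x), nrow(centers))
      for (k in seq_len(nrow(centers)))
        out[, k] <- rowSums(abs(sweep(x, 2, centers[k, ])))
      out
    },
    correlation = {
      r <- cor(t(x), t(centers))
      r[!is.finite(r)] <- 0
      1 - r
    },
    stop("unknown distance '", distance, "'"))
}

kmeanspp_init <- function(x, k, distance) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  if (k > 1) for (j in 2:k) {
    d <- state_dist(x, centers[seq_len(j - 1), , drop = FALSE], distance)
    dmin <- apply(d, 1, min)
    p <- dmin^2
    if (sum(p) == 0) p <- rep(1, n)
    centers[j, ] <- x[sample.int(n, 1, prob = p), ]
  }
  centers
}

#' k-means clustering with selectable distance
#'
#' k-means with k-means++ seeding and a distance-appropriate centroid
#' update: component-wise median for the city-block metric, mean for the
#' Euclidean metric, and mean of row-standardised vectors for the
#' correlation metric (1 - Pearson r).  The best of `n_rep` restarts by
#' total within-cluster distance is returned; empty clusters are re-seeded
#' at the point farthest from its centroid.
#'
#' @param x observations x features matrix.
#' @param k number of clusters (<= rows).
#' @param distance one of `"cityblock"`, `"euclidean"`, `"correlation"`.
#' @param n_rep number of restarts (default 100).
#' @param seed integer seed.
#' @param init optional k x features matrix of starting centroids; with
#'   `init` supplied, `n_rep` is ignored and a single run is polished.
#' @param max_iter iteration cap per run.
#' @return list with `centroids`, `labels`, `objective` (sum of squared
#'   Euclidean distances, summed city-block distances, or summed
#'   correlation distances, by metric), `iterations`.
#' @export
kmeans_custom <- function(x, k, distance = c("cityblock", "euclidean", "correlation"),
                          n_rep = 100L, seed = 1L, init = NULL, max_iter = 100L) {
  distance <- match.arg(distance)
  stopifnot(is.matrix(x), k >= 1, k <= nrow(x))
  set.seed(seed)
  run_once <- function(centers) {
    labels <- rep(0L, nrow(x))
    for (it in seq_len(max_iter)) {
      d <- state_dist(x, centers, distance)
      new_labels <- max.col(-d, ties.method = "first")
      for (k0 in seq_len(k)) {            # re-seed empty clusters
        if (!any(new_labels == k0)) {
          far <- which.max(d[cbind(seq_len(nrow(x)), new_labels)])
          centers[k0, ] <- x[far, ]
          new_labels[far] <- k0
        }
      }
      if (identical(new_labels, labels)) break
      labels <- new_labels
      for (k0 in seq_len(k)) {
        rows <- x[labels == k0, , drop = FALSE]
        centers[k0, ] <- switch(distance,
          cityblock = apply(rows, 2, median),
          euclidean = colMeans(rows),
          correlation = {
            rs <- t(apply(rows, 1, function(r) (r - mean(r)) / sd(r)))
            colMeans(rs)
          })
      }
    }
    d <- state_dist(x, centers, distance)
    labels <- max.col(-d, ties.method = "first")
    obj <- switch(distance,
      euclidean = sum(d[cbind(seq_len(nrow(x)), labels)]^2),
      sum(d[cbind(seq_len(nrow(x)), labels)]))
    list(centroids = centers, labels = labels, objective = obj, iterations = it)
  }
  if (!is.null(init)) {
    stopifnot(nrow(init) == k, ncol(init) == ncol(x))
    return(run_once(init))
  }
  best <- NULL
  for (r in seq_len(n_rep)) {
    res <- run_once(kmeanspp_init(x, k, distance))
    if (is.null(best) || res$objective < best$objective) best <- res
  }
  best
}

#' Choose the number of states by the elbow criterion
#'
#' Runs the clustering for `k_range` cluster counts and computes the ratio
#' of within-cluster to between-cluster sum of squared deviations about the
#' grand mean.  The optimal k is the point of maximum curvature of the
#' ratio curve, with curvature evaluated geometrically
#' (|r''| / (1 + r'^2)^(3/2) on discrete differences) so that the steep
#' initial descent of the curve does not mask the bend; k = 1 has zero
#' between-cluster variance and is recorded as an infinite sentinel,
#' excluded from the curvature scan.  A curve without a bend — one that
#' keeps declining steadily past the chosen k instead of plateauing, as a
#' single unclustered cloud does — falls back to k = 2 and is flagged
#' low-confidence.
#'
#' @param x observations x features matrix.
#' @param k_range candidate cluster counts (default 1:15).
#' @param distance clustering metric (see [kmeans_custom()]).
#' @param n_rep restarts per k.
#' @param seed integer seed.
#' @return list with `k` (chosen count), `curve` (data.frame k, ratio),
#'   `confidence` (`"ok"` or `"low"`).
#' @export
elbow_k <- function(x, k_range = 1:15, distance = "cityblock", n_rep = 10L,
                    seed = 1L) {
  stopifnot(max(k_range) <= nrow(x))
  grand <- colMeans(x)
  tot <- sum(sweep(x, 2, grand)^2)
  ratio <- numeric(length(k_range))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    if (k == 1) { ratio[i] <- Inf; next }
    fit <- kmeans_custom(x, k, distance = distance, n_rep = n_rep,
                         seed = derive_seed(seed, k))
    within <- 0
    for (k0 in seq_len(k)) {
      rows <- x[fit$labels == k0, , drop = FALSE]
      within <- within + sum(sweep(rows, 2, colMeans(rows))^2)
    }
    between <- tot - within
    ratio[i] <- if (between <= 0) Inf else within / between
  }
  finite <- is.finite(ratio)
  ks <- k_range[finite]
  rs <- ratio[finite]
  if (length(ks) < 3) stop("k_range too small for the curvature rule")
  n_r <- length(rs)
  d2 <- rs[1:(n_r - 2)] - 2 * rs[2:(n_r - 1)] + rs[3:n_r]
  d1 <- (rs[3:n_r] - rs[1:(n_r - 2)]) / 2
  curv <- d2 / (1 + d1^2)^1.5
  k_opt <- ks[which.max(curv) + 1L]
  confidence <- "ok"
  # a true elbow plateaus past the bend; steady decline means no structure
  tail_rs <- rs[ks > k_opt]
  plateau_drop <- if (length(tail_rs) >= 2)
    mean(pmax(-diff(tail_rs) / head(tail_rs, -1), 0)) else 0
  if (diff(range(rs)) < 0.1 * max(abs(rs)) || plateau_drop > 0.05) {
    k_opt <- 2L
    confidence <- "low"
  }
  list(k = as.integer(k_opt), curve = data.frame(k = k_range, ratio = ratio),
       confidence = confidence)
}

#' Fit dynamic connectivity states
#'
#' Clusters all windowed-FNC vectors into `k` states by one of three
#' strategies: `exemplar_two_stage` (cluster the per-subject variance-peak
#' exemplars, then one full pass over all windows initialised at those
#' centroids), `subject_then_group` (per-subject k-means, group k-means on
#' the concatenated subject centroids, then assign all windows), or
#' `direct` (k-means on all windows).  Per-subject state means and
#' percentage of occurrences (POC) are computed from the final assignment.
#'
#' @param all_series list of `msfnc_window_series`.
#' @param k number of states.
#' @param strategy one of `"exemplar_two_stage"`, `"subject_then_group"`,
#'   `"direct"`.
#' @param distance clustering metric (default `"cityblock"`).
#' @param n_rep restarts for the first-stage clustering.
#' @param seed integer seed.
#' @return an `msfnc_state_model`: `k`, `centroids`, `assignment`
#'   (data.frame subject, window, state), `subject_state_means` (subject x
#'   state list of mean vectors, `NULL` when unvisited), `poc` (percent of
#'   all windows per state), `strategy`, `distance`.
#' @export
fit_states <- function(all_series, k,
                       strategy = c("exemplar_two_stage", "subject_then_group", "direct"),
                       distance = "cityblock", n_rep = 100L, seed = 1L) {
  strategy <- match.arg(strategy)
  if (inherits(all_series, "msfnc_window_series")) all_series <- list(all_series)
  X <- do.call(rbind, lapply(all_series, function(s) s$windows[s$valid, , drop = FALSE]))
  subj <- unlist(lapply(all_series, function(s)
    rep(s$subject_id, sum(s$valid))))
  widx <- unlist(lapply(all_series, function(s) s$window_onsets[s$valid]))

  centroids <- switch(strategy,
    exemplar_two_stage = {
      ex <- select_exemplars(all_series)
      kmeans_custom(ex$windows, k, distance = distance, n_rep = n_rep,
                    seed = derive_seed(seed, 1L))$centroids
    },
    subject_then_group = {
      subc <- lapply(seq_along(all_series), function(i) {
        s <- all_series[[i]]
        xs <- s$windows[s$valid, , drop = FALSE]
        kk <- min(k, nrow(xs))
        kmeans_custom(xs, kk, distance = distance, n_rep = max(5L, n_rep %/% 10L),
                      seed = derive_seed(seed, 10L + i))$centroids
      })
      kmeans_custom(do.call(rbind, subc), k, distance = distance, n_rep = n_rep,
                    seed = derive_seed(seed, 2L))$centroids
    },
    direct = kmeans_custom(X, k, distance = distance,
                           n_rep = max(5L, n_rep %/% 10L),
                           seed = derive_seed(seed, 3L))$centroids)

  # final polish + assignment over all windows, initialised at the
  # first-stage centroids (for "direct" this is already the full solution)
  fit <- kmeans_custom(X, k, distance = distance, init = centroids,
                       seed = derive_seed(seed, 4L))
  assignment <- data.frame(subject = subj, window = widx, state = fit$labels,
                           stringsAsFactors = FALSE)
  poc <- 100 * tabulate(fit$labels, nbins = k) / nrow(X)
  ids <- unique(subj)
  ssm <- lapply(ids, function(id) {
    rows <- which(subj == id)
    lapply(seq_len(k), function(s) {
      sel <- rows[fit$labels[rows] == s]
      if (length(sel) == 0) NULL else colMeans(X[sel, , drop = FALSE])
    })
  })
  names(ssm) <- ids
  structure(list(k = k, centroids = fit$centroids, assignment = assignment,
                 subject_state_means = ssm, poc = poc, strategy = strategy,
                 distance = distance, objective = fit$objective,
                 n_components = all_series[[1]]$n_components),
            class = "msfnc_state_model")
}

#' @export
print.msfnc_state_model <- function(x, ...) {
  cat("Dynamic FNC state model: k =", x$k, "(", x$strategy, ",", x$distance, ")\n")
  cat("  POC:", paste(sprintf("state %d = %.2f%%", seq_len(x$k), x$poc),
                      collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.msfnc_state_model <- function(object, ...) {
  visits <- vapply(object$subject_state_means, function(s)
    sum(!vapply(s, is.null, logical(1))), integer(1))
  cat("Dynamic FNC state model\n")
  print(object)
  cat("  subjects:", length(object$subject_state_means),
      "; mean states visited per subject:", round(mean(visits), 2), "\n")
  invisible(object)
}
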