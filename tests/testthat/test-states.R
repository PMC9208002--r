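mock_series <- function(windows, id = "s1") {
  structure(list(windows = windows, window_onsets = seq_len(nrow(windows)),
                 valid = rep(TRUE, nrow(windows)),
                 n_components = NA_integer_, subject_id = id),
            class = "msfnc_window_series")
}

test_that("exemplars are strict local maxima of the variance series", {
  # rows built so the across-pair variance series is exactly 1,3,2,5,4
  row_with_var <- function(v) c(0, 0, 0, 2) * sqrt(v)   # var(c(0,0,0,2)) = 1
  base <- t(vapply(c(1, 3, 2, 5, 4), row_with_var, numeric(4)))
  ex <- select_exemplars(mock_series(base))
  expect_equal(ex$index, c(2L, 4L))
  # monotone variance: no interior maximum, fallback to the first window
  mono <- t(vapply(1:5, row_with_var, numeric(4)))
  expect_warning(exm <- select_exemplars(mock_series(mono)), "falling back")
  expect_equal(exm$index, 1L)
})

test_that("exemplar picking matches a brute-force neighbour scan", {
  set.seed(41)
  w <- matrix(rnorm(60 * 10), 60, 10)
  ex <- select_exemplars(mock_series(w))
  v <- apply(w, 1, var)
  oracle <- which(vapply(2:59, function(i)
    v[i] > v[i - 1] && v[i] > v[i + 1], logical(1))) + 1L
  expect_equal(ex$index, oracle)
})

test_that("k-means separates well-separated clouds at every metric", {
  set.seed(42)
  x <- rbind(matrix(rnorm(60, mean = 0), 30, 2),
             matrix(rnorm(60, mean = 6), 30, 2))
  truth <- rep(1:2, each = 30)
  for (d in c("cityblock", "euclidean")) {
    fit <- kmeans_custom(x, 2, distance = d, n_rep = 5, seed = 1)
    tab <- table(fit$labels, truth)
    expect_equal(max(tab[1, ]) + max(tab[2, ]), 60)
  }
  # the correlation metric separates by pattern shape, not location
  p1 <- sin(2 * pi * (1:10) / 10)
  p2 <- cos(2 * pi * (1:10) / 10)
  xs <- rbind(t(replicate(30, p1 * runif(1, 0.5, 2) + rnorm(10, sd = 0.1))),
              t(replicate(30, p2 * runif(1, 0.5, 2) + rnorm(10, sd = 0.1))))
  fit <- kmeans_custom(xs, 2, distance = "correlation", n_rep = 5, seed = 1)
  tab <- table(fit$labels, truth)
  expect_equal(max(tab[1, ]) + max(tab[2, ]), 60)
})

test_that("city-block k-means attains the exhaustive-partition optimum", {
  set.seed(43)
  for (rep in 1:5) {
    x <- matrix(runif(6 * 2, 0, 10), 6, 2)
    fit <- kmeans_custom(x, 2, distance = "cityblock", n_rep = 50, seed = rep)
    # oracle: every 2-partition, centroid = componentwise median
    parts <- Filter(function(p) length(p) == 2, all_partitions(6))
    best <- min(vapply(parts, function(p) {
      sum(vapply(p, function(m) {
        ctr <- apply(x[m, , drop = FALSE], 2, median)
        sum(abs(sweep(x[m, , drop = FALSE], 2, ctr)))
      }, numeric(1)))
    }, numeric(1)))
    expect_equal(fit$objective, best, tolerance = 1e-10)
  }
})

test_that("best-of-n restarts never do worse than a single run", {
  set.seed(44)
  x <- matrix(rnorm(40 * 8), 40, 8)
  one <- kmeans_custom(x, 4, distance = "cityblock", n_rep = 1, seed = 2)
  many <- kmeans_custom(x, 4, distance = "cityblock", n_rep = 30, seed = 2)
  expect_lte(many$objective, one$objective)
  # determinism under a fixed seed
  again <- kmeans_custom(x, 4, distance = "cityblock", n_rep = 30, seed = 2)
  expect_identical(many$labels, again$labels)
  expect_identical(many$centroids, again$centroids)
})

test_that("the elbow detects four planted clusters and flags a single cloud", {
  set.seed(45)
  ctrs <- matrix(rnorm(4 * 20, sd = 4), 4, 20)
  x <- ctrs[rep(1:4, each = 50), ] + matrix(rnorm(200 * 20, sd = 0.5), 200, 20)
  el <- elbow_k(x, 1:10, distance = "euclidean", n_rep = 5, seed = 3)
  expect_equal(el$k, 4L)
  expect_equal(el$confidence, "ok")
  expect_true(is.infinite(el$curve$ratio[1]))   # k = 1 sentinel
  cloud <- matrix(rnorm(200 * 10), 200, 10)
  el2 <- elbow_k(cloud, 1:10, distance = "euclidean", n_rep = 5, seed = 3)
  expect_equal(el2$k, 2L)
  expect_equal(el2$confidence, "low")
})

test_that("the elbow curve equals direct within/between sums", {
  set.seed(46)
  x <- matrix(rnorm(80 * 5), 80, 5)
  el <- elbow_k(x, 1:5, distance = "euclidean", n_rep = 5, seed = 4)
  grand <- colMeans(x)
  tot <- sum(sweep(x, 2, grand)^2)
  for (k in 2:5) {
    fit <- kmeans_custom(x, k, distance = "euclidean", n_rep = 5,
                         seed = msfnc:::derive_seed(4, k))
    within <- sum(vapply(seq_len(k), function(j) {
      rows <- x[fit$labels == j, , drop = FALSE]
      sum(sweep(rows, 2, colMeans(rows))^2)
    }, numeric(1)))
    expect_equal(el$curve$ratio[k], within / (tot - within), tolerance = 1e-10)
  }
})

test_that("all strategies and metrics recover the planted state centroids", {
  fx <- fix_fourstate_windows()
  truth <- vapply(fx$spec$covariances, msfnc:::vec_ut, numeric(66))
  check_fit <- function(m) {
    cc <- abs(cor(t(m$centroids), truth))
    matched <- msfnc:::hungarian_assign(1 - cc)
    r <- cc[cbind(seq_len(4), matched)]
    expect_true(all(r > 0.9))
    expect_equal(sum(m$poc), 100, tolerance = 1e-9)
  }
  ws <- fx$windows[1:25]    # strategy robustness at reduced size
  for (s in c("exemplar_two_stage", "subject_then_group", "direct"))
    check_fit(fit_states(ws, 4, strategy = s, distance = "cityblock",
                         n_rep = 20, seed = 5))
  for (d in c("euclidean", "correlation"))
    check_fit(fit_states(ws, 4, strategy = "exemplar_two_stage", distance = d,
                         n_rep = 20, seed = 5))
})

test_that("state occupancy matches the Markov stationary distribution", {
  fx <- fix_fourstate_windows()
  m <- fit_states(fx$windows, 4, strategy = "exemplar_two_stage",
                  distance = "cityblock", n_rep = 20, seed = 6)
  # stationary distribution of the symmetric transition matrix is uniform
  pi_stat <- rep(25, 4)
  truth <- vapply(fx$spec$covariances, msfnc:::vec_ut, numeric(66))
  matched <- msfnc:::hungarian_assign(1 - abs(cor(t(m$centroids), truth)))
  expect_equal(sort(m$poc), sort(pi_stat[matched]), tolerance = 0.25)
  expect_true(all(abs(m$poc - 25) < 5))       # within 5 percentage points
})

test_that("identical windows collapse to a single full-occupancy state", {
  w <- matrix(rep(c(0.5, -0.2, 0.1), each = 20), 20, 3)
  m <- fit_states(mock_series(w), 1, strategy = "direct", n_rep = 2, seed = 7)
  expect_equal(m$poc, 100)
  expect_equal(unique(m$assignment$state), 1L)
})

test_that("subject state means exist exactly for visited states", {
  fx <- fix_fourstate_windows()
  m <- fit_states(fx$windows[1:10], 4, strategy = "direct", n_rep = 5, seed = 8)
  for (id in names(m$subject_state_means)) {
    visited <- sort(unique(m$assignment$state[m$assignment$subject == id]))
    has_mean <- which(!vapply(m$subject_state_means[[id]], is.null, logical(1)))
    expect_equal(has_mean, visited)
  }
})
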