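test_that("hierarchical atlas satisfies its geometric contract", {
  atlas <- fix_atlas()
  C <- atlas$maps$coarse
  F <- atlas$maps$fine
  expect_equal(ncol(C), 4)
  expect_equal(ncol(F), 8)
  expect_equal(atlas$hierarchy, rep(1:4, each = 2))
  # unit L2 norm, nonnegative peak
  expect_equal(unname(apply(C, 2, function(v) sqrt(sum(v^2)))), rep(1, 4))
  expect_equal(unname(apply(F, 2, function(v) sqrt(sum(v^2)))), rep(1, 8))
  expect_true(all(C >= 0), all(F >= 0))
  # per-scale spatial correlation < 0.5
  expect_lt(max(cor(C)[upper.tri(diag(4))]), 0.5)
  expect_lt(max(cor(F)[upper.tri(diag(8))]), 0.5)
  for (k in 1:4) {
    kids <- which(atlas$hierarchy == k)
    # coarse source is close to, but not identical with, the child union
    r_union <- cor(C[, k], rowSums(F[, kids]))
    expect_gt(r_union, 0.5)
    expect_lt(r_union, 0.98)
    supp <- C[, k] > 0.01 * max(C[, k])
    half_max <- C[, k] >= max(C[, k]) / 2
    for (j in kids) {
      expect_gte(sum(F[supp, j]) / sum(F[, j]), 0.8)   # mass inside parent
      expect_gte(sum(F[!half_max, j]) / sum(F[, j]), 0.1)  # spills the contour
    }
  }
})

test_that("split factor one reproduces the coarse scale", {
  atlas <- make_hierarchical_sources(c(12, 12, 8), 4, 1, seed = 2)
  for (k in 1:4)
    expect_gt(cor(atlas$maps$coarse[, k], atlas$maps$fine[, k]), 0.99)
})

test_that("a grid too small for the requested sources is rejected", {
  expect_error(make_hierarchical_sources(c(4, 4, 2), 4, 2, seed = 1),
               "too small")
})

test_that("state covariances are validated", {
  bad <- matrix(c(1, 2, 2, 1), 2)          # indefinite
  expect_error(state_spec(list(bad)), "positive semi-definite")
  expect_error(state_spec(list(diag(2) * 2)), "unit diagonal")
  asym <- diag(2); asym[1, 2] <- 0.5
  expect_error(state_spec(list(asym)), "symmetric")
  tr_bad <- matrix(c(0.5, 0.2, 0.6, 0.8), 2)   # first row sums to 1.1
  expect_error(state_spec(list(diag(2), diag(2)), transition = tr_bad),
               "sum to 1")
})

test_that("single-state sampling converges to its covariance", {
  st <- state_spec(list(diag(6)))
  sim <- simulate_state_timecourses(st, 4000, 2, seed = 5)
  expect_true(all(sim$labels == 1))
  R <- cor(sim$tc)
  expect_lt(max(abs(R[upper.tri(R)])), 0.05)
})

test_that("labeled segments recover each state's correlation", {
  C1 <- diag(3); C1[1, 2] <- C1[2, 1] <- 0.8
  C2 <- diag(3); C2[1, 2] <- C2[2, 1] <- -0.8
  alternate <- matrix(c(0, 1, 1, 0), 2)
  st <- state_spec(list(C1, C2), transition = alternate)
  sim <- simulate_state_timecourses(st, 4000, 2, seed = 6)
  for (k in 1:2) {
    r <- cor(sim$tc[sim$labels == k, 1], sim$tc[sim$labels == k, 2])
    expect_equal(r, c(0.8, -0.8)[k], tolerance = 0.05)
  }
})

test_that("an identity transition keeps one state for the whole scan", {
  st <- state_spec(list(diag(2), diag(2)), transition = diag(2))
  sim <- simulate_state_timecourses(st, 200, 2, seed = 7)
  expect_length(unique(sim$labels), 1)
})

test_that("empirical state covariance converges to the specification", {
  mk <- function(r) {
    C <- diag(4)
    C[1, 2] <- C[2, 1] <- r
    C[3, 4] <- C[4, 3] <- -r
    C
  }
  st <- state_spec(list(mk(0.5), mk(-0.5)), dwell_mean = 25)
  sim <- simulate_state_timecourses(st, 4000, 2, seed = 8)
  for (k in 1:2) {
    sel <- sim$labels == k
    expect_gt(sum(sel), 1000)
    R <- cor(sim$tc[sel, ])
    expect_lt(max(abs(R - st$covariances[[k]])), 0.05)
  }
})

test_that("temporal smoothing preserves state correlation but reddens the spectrum", {
  C <- diag(2); C[1, 2] <- C[2, 1] <- 0.7
  st <- state_spec(list(C), dwell_mean = 1000)
  sm <- simulate_state_timecourses(st, 3000, 2, seed = 9, smooth_sigma_trs = 2)
  expect_equal(cor(sm$tc[, 1], sm$tc[, 2]), 0.7, tolerance = 0.08)
  f <- spectrum_features(sm$tc[, 1], 2)
  expect_gt(f$freq_ratio, 2)   # low-frequency dominated after smoothing
  raw <- simulate_state_timecourses(st, 3000, 2, seed = 9)
  f0 <- spectrum_features(raw$tc[, 1], 2)
  expect_lt(f0$freq_ratio, 2)  # white without smoothing
})

test_that("noiseless motionless rendering equals maps times time courses", {
  atlas <- fix_atlas()
  st <- state_spec(list(diag(8)))
  coh <- cohort_spec(n_per_cell = 1, noise_sd = 0, motion_amp = 0, seed = 4)
  sim <- render_cohort(atlas, st, coh, T_len = 60, tr = 2)
  for (id in names(sim$subjects)) {
    recon <- atlas$maps$fine %*% t(sim$truth$timecourses[[id]])
    expect_equal(sim$subjects[[id]]$data, recon, tolerance = 1e-12)
    # rank bounded by the number of generative sources
    expect_equal(qr(sim$subjects[[id]]$data)$rank, 8)
  }
})

test_that("rendering is deterministic under a fixed seed", {
  atlas <- fix_atlas()
  st <- state_spec(list(diag(8)), dwell_mean = 10)
  coh <- cohort_spec(n_per_cell = 1, noise_sd = 0.2, motion_amp = 0.05, seed = 4)
  a <- render_cohort(atlas, st, coh, T_len = 50, tr = 2)
  b <- render_cohort(atlas, st, coh, T_len = 50, tr = 2)
  expect_identical(a$subjects[["sub-001"]]$data, b$subjects[["sub-001"]]$data)
  expect_identical(a$subjects[["sub-003"]]$motion, b$subjects[["sub-003"]]$motion)
  expect_identical(a$truth$labels, b$truth$labels)
})

test_that("without planted effects the diagnosis groups are exchangeable", {
  st <- fourstate_spec(r = 0.5, dwell = 1e6)
  coh_pairs <- NULL
  set.seed(31)
  n_group <- 20
  # FNC features from ground-truth time courses; no diagnosis effect planted
  feats <- t(vapply(seq_len(2 * n_group), function(s) {
    sim <- simulate_state_timecourses(st, 150, 2, seed = 31000 + s)
    msfnc:::vec_ut(cor(sim$tc))
  }, numeric(66)))
  grp <- rep(c("CT", "SZ"), each = n_group)
  tstats <- apply(feats, 2, function(y)
    t.test(y[grp == "CT"], y[grp == "SZ"], var.equal = TRUE)$statistic)
  crit <- qt(0.975, df = 2 * n_group - 2)
  frac <- mean(abs(tstats) > crit)
  expect_lt(frac, 0.15)     # ~5% expected; generous bound for 66 pairs
})

test_that("cell covariance offsets shift only the targeted pairs", {
  atlas <- fix_atlas()
  st <- state_spec(list(diag(8)))
  eff <- data.frame(i = 1, j = 3, diagnosis = "SZ", sex = "*", offset = 0.4)
  coh <- cohort_spec(n_per_cell = 2, effect_pairs = eff, noise_sd = 0,
                     motion_amp = 0, seed = 5)
  sim <- render_cohort(atlas, st, coh, T_len = 3000, tr = 2,
                       smooth_sigma_trs = 0)
  ph <- sim$phenotype
  r13 <- vapply(names(sim$subjects), function(id)
    cor(sim$truth$timecourses[[id]][, 1], sim$truth$timecourses[[id]][, 3]),
    numeric(1))
  expect_gt(mean(r13[ph$diagnosis == "SZ"]) - mean(r13[ph$diagnosis == "CT"]), 0.2)
})

test_that("impossible covariance offsets are rejected", {
  atlas <- fix_atlas()
  st <- state_spec(list(diag(8)))
  eff <- data.frame(i = 1, j = 2, diagnosis = "*", sex = "*", offset = 1.5)
  coh <- cohort_spec(n_per_cell = 1, effect_pairs = eff, seed = 1)
  expect_error(render_cohort(atlas, st, coh, T_len = 20), "indefinite")
})
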