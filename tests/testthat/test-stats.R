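test_that("framewise displacement is the literal six-term sum", {
  m <- matrix(0, 5, 6)
  expect_equal(framewise_displacement(m)$fd, rep(0, 5))
  m2 <- matrix(0, 5, 6)
  m2[3:5, 1] <- 1                        # one +1 step in dx
  fd2 <- framewise_displacement(m2)
  expect_equal(fd2$fd, c(0, 0, 1, 0, 0))
  set.seed(51)
  mw <- matrix(cumsum(rnorm(60)), 10, 6)
  oracle <- c(0, rowSums(abs(apply(mw, 2, diff))))
  expect_equal(framewise_displacement(mw)$fd, oracle)
  expect_equal(framewise_displacement(mw)$mean_fd, mean(oracle))
  # optional rotation-to-arc conversion scales columns 4:6
  fd_r <- framewise_displacement(mw, rotation_radius = 50)
  mw2 <- mw; mw2[, 4:6] <- mw2[, 4:6] * 50
  expect_equal(fd_r$fd, c(0, rowSums(abs(apply(mw2, 2, diff)))))
})

test_that("the diagnosis contrast equals the two-sample t oracle", {
  set.seed(52)
  n <- 40
  ph <- data.frame(subject_id = seq_len(n),
                   diagnosis = rep(c("CT", "SZ"), each = n / 2),
                   sex = "male", age = 30, site = "s1", mean_fd = 0.1)
  y <- rnorm(n) + (ph$diagnosis == "SZ") * 0.9
  g <- glm_contrast(matrix(y, ncol = 1), ph, "male")
  tt <- t.test(y[ph$diagnosis == "SZ"], y[ph$diagnosis == "CT"],
               var.equal = TRUE)
  expect_equal(g$t, unname(tt$statistic), tolerance = 1e-8)
  expect_equal(g$p, tt$p.value, tolerance = 1e-8)
})

test_that("null t values follow the Student distribution with model df", {
  set.seed(53)
  ph <- make_phenotype(n_per_cell = 15)
  male <- ph$sex == "male"
  feats <- matrix(rnorm(nrow(ph) * 2000), nrow(ph), 2000)
  g <- glm_contrast(feats, ph, "male")
  df <- attr(g, "df")
  expect_equal(df, sum(male) - 5)   # intercept, dx, age, 1 site dummy, fd
  ks <- ks.test(g$t, function(q) pt(q, df))
  expect_gt(ks$p.value, 0.01)
})

test_that("degenerate features and cohorts are rejected", {
  ph <- make_phenotype(4)
  feats <- matrix(rnorm(nrow(ph) * 2), nrow(ph), 2)
  feats[, 2] <- 1
  expect_error(glm_contrast(feats, ph, "male"), "zero-variance")
  ph_bad <- ph[ph$diagnosis == "CT", ]
  expect_error(glm_contrast(feats[ph$diagnosis == "CT", 1, drop = FALSE],
                            ph_bad, "male"), "at least 2")
})

test_that("permutation p values are uniform when sex plays no role", {
  set.seed(54)
  ph <- make_phenotype(n_per_cell = 12)
  feats <- matrix(rnorm(nrow(ph) * 60), nrow(ph), 60)
  res <- sex_permutation_null(feats, ph, n_perm = 199, seed = 9)
  ks <- suppressWarnings(ks.test(res$p_perm, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_true(all(res$p_perm >= 1 / 200 & res$p_perm <= 1))
})

test_that("a strong sex-by-diagnosis interaction pins p at the floor", {
  set.seed(55)
  ph <- make_phenotype(n_per_cell = 12)
  feats <- matrix(rnorm(nrow(ph) * 5), nrow(ph), 5)
  bump <- 3 * (ph$diagnosis == "SZ") * ifelse(ph$sex == "male", 1, -1)
  feats[, 3] <- feats[, 3] + bump
  res <- sex_permutation_null(feats, ph, n_perm = 999, seed = 10)
  expect_equal(res$p_perm[3], 1 / 1000)
  expect_gt(min(res$p_perm[-3]), 2 / 1000)   # null features stay off the floor
  expect_error(sex_permutation_null(feats, ph, n_perm = 0), "at least 1")
})

test_that("pooled BH matches the step-up rule computed by hand", {
  r <- pooled_fdr(c(0.01, 0.02, 0.03, 0.5), q = 0.05)
  expect_equal(sum(r$significant), 3)
  expect_equal(r$q_fdr, p.adjust(c(0.01, 0.02, 0.03, 0.5), "BH"))
  expect_equal(sum(pooled_fdr(rep(1, 10))$significant), 0)
  expect_equal(nrow(pooled_fdr(numeric(0))), 0)
  # rejections monotone in q
  set.seed(56)
  p <- runif(50)^2
  n_rej <- vapply(seq(0.01, 0.2, by = 0.01),
                  function(q) sum(pooled_fdr(p, q)$significant), integer(1))
  expect_true(all(diff(n_rej) >= 0))
})

test_that("domain aggregation averages the right blocks", {
  # toy: 2 domains x 2 orders, hand-listed pairs
  icns <- data.frame(domain = c("A", "A", "B", "B"), order = c(25, 50, 25, 50))
  f <- matrix(0, 4, 4)
  f[upper.tri(f)] <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6)
  f <- f + t(f); diag(f) <- 1
  d <- domain_aggregate(f, icns)
  expect_equal(dim(d), c(4, 4))
  expect_equal(rownames(d), c("A25", "A50", "B25", "B50"))
  expect_equal(d["A25", "A50"], f[1, 2])
  expect_equal(d["A25", "B25"], f[1, 3])
  expect_equal(d["B25", "B50"], f[3, 4])
  expect_true(all(is.na(diag(d))))        # single-ICN blocks: no within pair
  expect_equal(unclass(d), t(unclass(d)), ignore_attr = TRUE)
})

test_that("seven domains by four orders give the 28 x 28 matrix", {
  set.seed(57)
  domains <- c("CC", "CR", "DM", "SB", "SM", "TP", "VS")
  orders <- c(25, 50, 75, 100)
  icns <- expand.grid(domain = domains, order = orders,
                      stringsAsFactors = FALSE)
  icns <- icns[rep(seq_len(nrow(icns)), each = 2), ]   # 2 ICNs per block
  P <- nrow(icns)
  f <- cor(matrix(rnorm((P + 5) * P), P + 5, P))
  d <- domain_aggregate(f, icns)
  expect_equal(dim(d), c(28, 28))
  expect_false(anyNA(d))
  # constant off-diagonal input: every defined entry equals the constant
  fc <- matrix(0.3, P, P); diag(fc) <- 1
  dc <- domain_aggregate(fc, icns)
  expect_true(all(dc == 0.3))
})

test_that("domain aggregation ignores ICN order within blocks", {
  set.seed(58)
  icns <- data.frame(domain = rep(c("A", "B"), each = 4),
                     order = rep(c(25, 50), 4))
  P <- nrow(icns)
  f <- cor(matrix(rnorm(20 * P), 20, P))
  d1 <- domain_aggregate(f, icns)
  # permute ICNs within identical (domain, order) blocks
  perm <- c(3, 2, 1, 4, 5, 8, 7, 6)   # swaps inside blocks only
  expect_equal(paste(icns$domain, icns$order),
               paste(icns$domain[perm], icns$order[perm]))
  d2 <- domain_aggregate(f[perm, perm], icns[perm, ])
  expect_equal(unclass(d1), unclass(d2), tolerance = 1e-12)
})

test_that("symptom correlation residualises covariates correctly", {
  set.seed(59)
  ph <- make_phenotype(n_per_cell = 50, seed = 60)   # n = 200
  # identity: feature equals score
  score <- rnorm(nrow(ph))
  r <- symptom_correlation(score, score, ph)
  expect_equal(r$r, 1, tolerance = 1e-12)
  # independence: |r| small in most replicates
  hits <- vapply(1:200, function(i) {
    f <- rnorm(nrow(ph))
    s <- rnorm(nrow(ph))
    abs(symptom_correlation(f, s, ph)$r) < 0.2
  }, logical(1))
  expect_gt(mean(hits), 0.95)
})

test_that("a planted partial correlation survives confounder adjustment", {
  set.seed(61)
  n <- 500
  ph <- make_phenotype(n_per_cell = 125, seed = 62)
  stopifnot(nrow(ph) == n)
  rr <- replicate(20, {
    common <- rnorm(n)
    age_c <- scale(ph$age)[, 1]
    feature <- sqrt(0.3) * common + sqrt(0.7) * rnorm(n) + 0.8 * age_c
    score <- sqrt(0.3) * common + sqrt(0.7) * rnorm(n) + 0.8 * age_c
    symptom_correlation(feature, score, ph)$r
  })
  expect_equal(mean(rr), 0.3, tolerance = 0.05)
  # missing scores are dropped pairwise with a message
  sc <- rnorm(n); sc[1:20] <- NA
  expect_message(symptom_correlation(rnorm(n), sc, ph), "dropped")
})

test_that("BPRS-to-PANSS conversion interpolates a monotone table", {
  ident <- data.frame(bprs = c(0, 100), panss = c(0, 100))
  expect_equal(bprs_to_panss(c(10, 55.5), ident), c(10, 55.5))
  tab <- data.frame(bprs = c(20, 40), panss = c(30, 60))
  expect_equal(bprs_to_panss(30, tab), 45)
  set.seed(63)
  mono <- data.frame(bprs = sort(runif(10, 0, 100)),
                     panss = cumsum(runif(10, 0.5, 5)))
  probes <- runif(100, min(mono$bprs), max(mono$bprs))
  expect_equal(bprs_to_panss(probes, mono),
               approx(mono$bprs, mono$panss, xout = probes)$y)
  expect_warning(bprs_to_panss(150, tab), "clamped")
  bad <- data.frame(bprs = c(40, 20), panss = c(30, 60))
  expect_error(bprs_to_panss(30, bad), "monotone")
})

test_that("the pooled pipeline keeps its type-I error below 7 percent", {
  set.seed(64)
  ph <- make_phenotype(n_per_cell = 15)
  rates <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    feats <- matrix(rnorm(nrow(ph) * 2000), nrow(ph), 2000)
    pm <- glm_contrast(feats, ph, "male")
    pf <- glm_contrast(feats, ph, "female")
    mean(pooled_fdr(c(pm$p, pf$p), q = 0.05)$significant)
  }, numeric(1))
  expect_lte(mean(rates), 0.07)
})

test_that("a d = 0.8 diagnosis effect is detected after pooled FDR", {
  hits <- vapply(1:20, function(s) {
    set.seed(2000 + s)
    n <- 120                               # 60 CT / 60 SZ
    ph <- data.frame(subject_id = seq_len(n),
                     diagnosis = rep(c("CT", "SZ"), each = 60),
                     sex = "male", age = runif(n, 20, 60),
                     site = rep(c("s1", "s2"), n / 2),
                     mean_fd = runif(n, 0, 0.3))
    feats <- matrix(rnorm(n * 20), n, 20)
    feats[, 1] <- feats[, 1] + 0.8 * (ph$diagnosis == "SZ")
    g <- glm_contrast(feats, ph, "male")
    pooled_fdr(g$p, q = 0.05)$significant[1]
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
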