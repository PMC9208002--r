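#' Framewise displacement from rigid-body motion parameters
#'
#' The per-frame sum of absolute first differences of the six rigid-body
#' parameters: fd(t) = |ddx| + |ddy| + |ddz| + |dalpha| + |dbeta| +
#' |dgamma|, with fd(1) = 0.  By default the rotations contribute in their
#' native angular units; `rotation_radius` (mm) optionally converts radians
#' to an arc displacement before summing.
#'
#' @param motion time x 6 matrix (3 translations mm, 3 rotations radians).
#' @param rotation_radius `NULL` (literal sum) or a radius in mm.
#' @return list with `fd` (per-frame series) and `mean_fd`.
#' @export
framewise_displacement <- function(motion, rotation_radius = NULL) {
  stopifnot(is.matrix(motion), ncol(motion) == 6, nrow(motion) >= 2)
  m <- motion
  if (!is.null(rotation_radius)) m[, 4:6] <- m[, 4:6] * rotation_radius
  fd <- c(0, rowSums(abs(diff(m))))
  list(fd = fd, mean_fd = mean(fd))
}

# reference-coded design matrix: intercept, diagnosis indicator (SZ = 1),
# age, site dummies (lexicographically first level as reference), mean FD
build_design <- function(pheno, with_diagnosis = TRUE) {
  X <- cbind(intercept = rep(1, nrow(pheno)))
  if (with_diagnosis) X <- cbind(X, diagnosis = as.numeric(pheno$diagnosis == "SZ"))
  X <- cbind(X, age = pheno$age)
  sites <- sort(unique(pheno$site))
  if (length(sites) > 1) {
    for (s in sites[-1]) X <- cbind(X, as.numeric(pheno$site == s))
    colnames(X)[(ncol(X) - length(sites) + 2):ncol(X)] <- paste0("site_", sites[-1])
  }
  X <- cbind(X, mean_fd = pheno$mean_fd)
  # constant covariates carry no information beyond the intercept; drop them
  const <- apply(X, 2, function(v) sd(v) == 0)
  const[colnames(X) %in% c("intercept", "diagnosis")] <- FALSE
  X[, !const, drop = FALSE]
}

#' Diagnosis contrast from a covariate-adjusted linear model, per sex cohort
#'
#' Within one sex cohort, each connectivity feature is regressed on an
#' intercept, the diagnosis indicator, age, reference-coded site dummies
#' and mean framewise displacement; the t statistic and two-sided p value
#' of the diagnosis coefficient are returned for every feature.
#'
#' @param features subjects x features matrix (rows aligned with `pheno`).
#' @param pheno phenotype data.frame with columns `subject_id`, `diagnosis`
#'   (CT/SZ), `sex`, `age`, `site`, `mean_fd`.
#' @param cohort `"male"`, `"female"`, or `NULL` for all subjects.
#' @return data.frame with `feature`, `t`, `p`, plus attributes `df` and
#'   `n`.
#' @export
glm_contrast <- function(features, pheno, cohort = NULL) {
  if (is.vector(features)) features <- matrix(features, ncol = 1)
  stopifnot(nrow(features) == nrow(pheno))
  if (!is.null(cohort)) {
    keep <- pheno$sex == cohort
    features <- features[keep, , drop = FALSE]
    pheno <- pheno[keep, , drop = FALSE]
  }
  if (min(table(factor(pheno$diagnosis, levels = c("CT", "SZ")))) < 2)
    stop("need at least 2 subjects per diagnosis in the cohort")
  if (any(!is.finite(features))) stop("non-finite feature values")
  if (any(apply(features, 2, sd) == 0))
    stop("zero-variance feature(s): column ",
         paste(which(apply(features, 2, sd) == 0), collapse = ", "))
  X <- build_design(pheno)
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop("collinear design columns: ",
         paste(colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]], collapse = ", "))
  n <- nrow(X); p <- ncol(X)
  coefs <- qr.coef(qx, features)
  resid <- features - X %*% coefs
  sigma2 <- colSums(resid^2) / (n - p)
  if (any(sigma2 <= 0)) stop("zero-variance residual for some feature")
  XtXinv <- chol2inv(qr.R(qx))
  j <- which(colnames(X) == "diagnosis")
  se <- sqrt(sigma2 * XtXinv[j, j])
  tval <- coefs[j, ] / se
  pval <- 2 * pt(-abs(tval), df = n - p)
  out <- data.frame(feature = seq_len(ncol(features)), t = as.numeric(tval),
                    p = as.numeric(pval))
  attr(out, "df") <- n - p
  attr(out, "n") <- n
  out
}

#' Permutation null for sex-specific diagnosis effects
#'
#' The observed statistic per feature is the difference of the diagnosis
#' t values from the two sex-cohort models (male minus female).  The null
#' is built by permuting sex labels *within* each diagnostic group — group
#' sizes and every covariate stay attached to their subjects — and
#' recomputing both cohort models per draw.  Two-sided add-one p values
#' are returned.
#'
#' @param features subjects x features matrix.
#' @param pheno phenotype data.frame (see [glm_contrast()]).
#' @param n_perm number of permutations (default 5000).
#' @param seed integer seed.
#' @return data.frame `feature`, `t_male`, `t_female`, `diff_t`, `p_perm`.
#' @export
sex_permutation_null <- function(features, pheno, n_perm = 5000L, seed = 1L) {
  if (n_perm < 1) stop("n_perm must be at least 1")
  if (is.vector(features)) features <- matrix(features, ncol = 1)
  for (dx in c("CT", "SZ"))
    if (length(unique(pheno$sex[pheno$diagnosis == dx])) < 2)
      stop("both sexes must be present in both diagnostic groups")
  tm <- glm_contrast(features, pheno, "male")
  tf <- glm_contrast(features, pheno, "female")
  obs <- tm$t - tf$t
  set.seed(seed)
  exceed <- rep(0L, ncol(features))
  by_dx <- split(seq_len(nrow(pheno)), pheno$diagnosis)
  draws <- 0L
  attempts <- 0L
  while (draws < n_perm) {
    attempts <- attempts + 1L
    if (attempts > 20L * n_perm + 100L)
      stop("too many degenerate permutation draws; cohort too small")
    perm <- pheno
    for (idx in by_dx) perm$sex[idx] <- sample(pheno$sex[idx])
    ok <- all(vapply(c("male", "female"), function(sx) {
      tab <- table(factor(perm$diagnosis[perm$sex == sx], levels = c("CT", "SZ")))
      min(tab) >= 2
    }, logical(1)))
    if (!ok) next                               # degenerate draw: redraw
    # permutation must preserve the sex counts inside each diagnosis
    stopifnot(identical(table(perm$sex, perm$diagnosis),
                        table(pheno$sex, pheno$diagnosis)))
    null_d <- tryCatch(
      glm_contrast(features, perm, "male")$t -
        glm_contrast(features, perm, "female")$t,
      error = function(e) NULL)                 # collinear cohort: redraw
    if (is.null(null_d)) next
    exceed <- exceed + (abs(null_d) >= abs(obs))
    draws <- draws + 1L
  }
  data.frame(feature = seq_len(ncol(features)), t_male = tm$t, t_female = tf$t,
             diff_t = obs, p_perm = (1 + exceed) / (n_perm + 1))
}

#' Pooled false-discovery-rate control
#'
#' Benjamini-Hochberg step-up over one pooled p-value vector (static and
#' dynamic features, both sex cohorts, all model orders, interaction
#' tests), with the rejection flags mapped back to their sources.
#'
#' @param p numeric vector of p values in [0, 1] (may carry names/sources).
#' @param q FDR level (default 0.05).
#' @return data.frame `p`, `q_fdr` (BH-adjusted), `significant`.
#' @export
pooled_fdr <- function(p, q = 0.05) {
  if (length(p) == 0)
    return(data.frame(p = numeric(0), q_fdr = numeric(0), significant = logical(0)))
  stopifnot(all(p >= 0 & p <= 1))
  adj <- p.adjust(p, method = "BH")
  data.frame(p = p, q_fdr = adj, significant = adj <= q)
}

#' Aggregate an FNC matrix to domain-by-order blocks
#'
#' Every ICN belongs to a (functional domain, model order) block; the
#' aggregate entry for a block pair is the mean connectivity over all ICN
#' pairs with one member in each block (within a block: the mean over
#' distinct pairs, diagonal excluded).  Seven domains by four orders gives
#' the 28 x 28 domain-level functional integration matrix.  Blocks with no
#' ICN (or, on the diagonal, a single ICN) are `NA`.
#'
#' @param fnc P x P connectivity matrix (or a vectorised upper triangle of
#'   length P(P-1)/2, e.g. a state centroid).
#' @param icns data.frame with columns `domain` and `order`, one row per
#'   ICN in matrix order.
#' @return an `msfnc_domain_matrix` with `"CC25"`-style dimnames.
#' @export
domain_aggregate <- function(fnc, icns) {
  stopifnot(all(c("domain", "order") %in% names(icns)))
  P <- nrow(icns)
  if (!is.matrix(fnc)) fnc <- unvec_ut(fnc, P)
  stopifnot(nrow(fnc) == P, ncol(fnc) == P)
  if (any(is.na(icns$domain)))
    stop("every ICN must carry a domain label")
  domains <- sort(unique(icns$domain))
  orders <- sort(unique(icns$order))
  blocks <- expand.grid(order = orders, domain = domains,
                        stringsAsFactors = FALSE)   # domain-major labels
  blocks <- blocks[order(blocks$domain, blocks$order), ]
  labels <- paste0(blocks$domain, blocks$order)
  B <- nrow(blocks)
  member <- lapply(seq_len(B), function(b)
    which(icns$domain == blocks$domain[b] & icns$order == blocks$order[b]))
  m <- matrix(NA_real_, B, B, dimnames = list(labels, labels))
  for (a in seq_len(B)) for (b in a:B) {
    ia <- member[[a]]; ib <- member[[b]]
    if (length(ia) == 0 || length(ib) == 0) next
    if (a == b) {
      if (length(ia) < 2) next
      vals <- fnc[ia, ia][upper.tri(diag(length(ia)))]
    } else {
      vals <- as.vector(fnc[ia, ib, drop = FALSE])
    }
    m[a, b] <- m[b, a] <- mean(vals)
  }
  structure(m, class = c("msfnc_domain_matrix", "matrix"))
}

#' Covariate-adjusted symptom correlation
#'
#' Residualises both the connectivity feature and the symptom score on age,
#' reference-coded site and mean framewise displacement, then reports the
#' Pearson correlation of the residuals with its t-based p value.  Subjects
#' with missing scores are dropped pairwise.
#'
#' @param feature numeric vector (one connectivity feature per subject).
#' @param scores numeric symptom totals (may contain `NA`).
#' @param pheno phenotype data.frame with `age`, `site`, `mean_fd`.
#' @return list with `r`, `p`, `n` (subjects used).
#' @export
symptom_correlation <- function(feature, scores, pheno) {
  stopifnot(length(feature) == length(scores), length(feature) == nrow(pheno))
  keep <- is.finite(feature) & is.finite(scores)
  if (sum(keep) < 10) stop("fewer than 10 subjects with scores")
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(n_dropped, " subject(s) without scores dropped")
  ph <- pheno[keep, , drop = FALSE]
  X <- build_design(ph, with_diagnosis = FALSE)
  rf <- stats::lm.fit(X, feature[keep])$residuals
  rs <- stats::lm.fit(X, scores[keep])$residuals
  ct <- stats::cor.test(rf, rs)
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(keep))
}

#' Convert BPRS totals to PANSS totals via a monotone lookup
#'
#' Linear interpolation between the rows of a published equipercentile
#' crosswalk; inputs outside the table range are clamped to the nearest
#' endpoint with a warning.
#'
#' @param bprs_total numeric vector of BPRS totals.
#' @param mapping data.frame with monotone columns `bprs` and `panss`.
#' @return numeric vector of PANSS totals.
#' @export
bprs_to_panss <- function(bprs_total, mapping) {
  stopifnot(all(c("bprs", "panss") %in% names(mapping)), nrow(mapping) >= 2)
  if (any(diff(mapping$bprs) <= 0) || any(diff(mapping$panss) < 0))
    stop("mapping table must be monotone increasing")
  rng <- range(mapping$bprs)
  out_of_range <- !is.na(bprs_total) & (bprs_total < rng[1] | bprs_total > rng[2])
  if (any(out_of_range))
    warning(sum(out_of_range), " BPRS value(s) outside the table range; clamped")
  approx(mapping$bprs, mapping$panss, xout = pmin(pmax(bprs_total, rng[1]), rng[2]),
         rule = 2)$y
}
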