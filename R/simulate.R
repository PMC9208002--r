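#' Generate a hierarchical two-scale atlas of spatial sources
#'
#' Builds synthetic functional sources on a 3D voxel grid at two spatial
#' scales: `n_coarse` large Gaussian blobs (the coarse scale) and
#' `n_coarse * split_factor` smaller blobs (the fine scale), each fine blob
#' lying mostly inside one coarse parent.  The construction deliberately
#' avoids an exact partition: a coarse source is not the plain union of its
#' children, and every child keeps part of its mass outside the parent's
#' half-maximum contour.  This mimics functional parcellations in which a
#' large-scale network subdivides into overlapping but distinct subnetworks
#' at finer granularity.
#'
#' @param grid_shape integer vector of length 3, voxel grid dimensions.
#' @param n_coarse number of coarse sources (>= 2).
#' @param split_factor children per coarse source (>= 1); `1` makes the fine
#'   scale coincide with the coarse scale.
#' @param seed integer seed; the atlas is deterministic given the seed.
#' @return an object of class `msfnc_atlas` with elements `grid_shape`,
#'   `maps` (list of two voxels x sources matrices, `coarse` and `fine`,
#'   columns unit L2 norm), and `hierarchy` (parent coarse index of each
#'   fine source).
#' @export
make_hierarchical_sources <- function(grid_shape, n_coarse, split_factor, seed = 1L) {
  stopifnot(length(grid_shape) == 3, n_coarse >= 2, split_factor >= 1)
  nv <- prod(grid_shape)
  # each blob needs roughly a (4 voxel)^3 neighbourhood to stay distinct
  if (nv < n_coarse * max(split_factor, 2) * 48)
    stop("grid too small for ", n_coarse, " x ", split_factor, " distinct sources")
  set.seed(seed)

  ax <- lapply(grid_shape, function(n) seq_len(n))
  coords <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))

  gauss_blob <- function(center, sigma) {
    d2 <- (coords[, 1] - center[1])^2 + (coords[, 2] - center[2])^2 +
      (coords[, 3] - center[3])^2
    m <- exp(-d2 / (2 * sigma^2))
    m / vec_norm(m)
  }

  # coarse centers: jittered lattice over the largest two axes, kept away
  # from the grid boundary so the blobs are not clipped asymmetrically
  n_side <- ceiling(sqrt(n_coarse))
  cell <- grid_shape[1:2] / n_side
  centers <- matrix(0, n_coarse, 3)
  k <- 1L
  for (iy in seq_len(n_side)) for (ix in seq_len(n_side)) {
    if (k > n_coarse) break
    centers[k, 1] <- (ix - 0.5) * cell[1] + runif(1, -0.08, 0.08) * cell[1]
    centers[k, 2] <- (iy - 0.5) * cell[2] + runif(1, -0.08, 0.08) * cell[2]
    centers[k, 3] <- grid_shape[3] / 2 + runif(1, -0.05, 0.05) * grid_shape[3]
    k <- k + 1L
  }
  sigma_c <- 0.16 * min(cell[1], cell[2], grid_shape[3]) + 0.9
  coarse <- vapply(seq_len(n_coarse),
                   function(i) gauss_blob(centers[i, ], sigma_c), numeric(nv))

  if (split_factor == 1L) {
    fine <- coarse
    hierarchy <- seq_len(n_coarse)
  } else {
    sigma_f <- sigma_c * 0.75
    offset <- sigma_c * 0.80
    fine <- matrix(0, nv, n_coarse * split_factor)
    hierarchy <- integer(n_coarse * split_factor)
    for (i in seq_len(n_coarse)) {
      # children sit on a ring around the parent center at a random phase
      phi0 <- runif(1, 0, 2 * pi)
      for (j in seq_len(split_factor)) {
        phi <- phi0 + 2 * pi * (j - 1) / split_factor
        ctr <- centers[i, ] + c(cos(phi), sin(phi), 0) * offset +
          c(0, 0, runif(1, -0.3, 0.3))
        idx <- (i - 1L) * split_factor + j
        fine[, idx] <- gauss_blob(ctr, sigma_f)
        hierarchy[idx] <- i
      }
    }
  }
  structure(list(grid_shape = as.integer(grid_shape),
                 maps = list(coarse = coarse, fine = fine),
                 hierarchy = hierarchy,
                 n_coarse = as.integer(n_coarse),
                 split_factor = as.integer(split_factor)),
            class = "msfnc_atlas")
}

#' @export
print.msfnc_atlas <- function(x, ...) {
  cat("Hierarchical source atlas\n")
  cat("  grid:", paste(x$grid_shape, collapse = " x "), "\n")
  cat("  coarse sources:", ncol(x$maps$coarse),
      " fine sources:", ncol(x$maps$fine), "\n")
  invisible(x)
}

#' Specify a set of connectivity states
#'
#' A state is a covariance pattern among source time courses; the simulator
#' switches between states with a first-order Markov process whose geometric
#' dwell time has the given mean.
#'
#' @param covariances list of K symmetric positive semi-definite source
#'   covariance matrices with unit diagonal.
#' @param dwell_mean mean dwell time in TRs (geometric dwell); used to build
#'   a default transition matrix with uniform off-diagonal mass.
#' @param transition optional K x K Markov transition matrix (rows sum to 1);
#'   overrides `dwell_mean`.
#' @return an object of class `msfnc_states_spec`.
#' @export
state_spec <- function(covariances, dwell_mean = 20, transition = NULL) {
  stopifnot(is.list(covariances), length(covariances) >= 1)
  K <- length(covariances)
  p <- nrow(covariances[[1]])
  for (C in covariances) {
    stopifnot(is.matrix(C), nrow(C) == p, ncol(C) == p)
    if (max(abs(C - t(C))) > 1e-8) stop("state covariance not symmetric")
    if (max(abs(diag(C) - 1)) > 1e-8) stop("state covariance must have unit diagonal")
    ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) stop("state covariance not positive semi-definite")
  }
  if (is.null(transition)) {
    stay <- if (K == 1) 1 else 1 - 1 / dwell_mean
    transition <- matrix((1 - stay) / max(K - 1, 1), K, K)
    diag(transition) <- stay
  }
  stopifnot(nrow(transition) == K, ncol(transition) == K)
  if (max(abs(rowSums(transition) - 1)) > 1e-8)
    stop("transition rows must sum to 1")
  structure(list(covariances = covariances, dwell_mean = dwell_mean,
                 transition = transition, K = K, n_sources = p),
            class = "msfnc_states_spec")
}

#' Simulate state-switching source time courses
#'
#' Draws a Markov chain of state labels and, within each dwell segment,
#' samples source activity from a zero-mean multivariate normal with that
#' state's covariance.
#'
#' @param states an [state_spec()] object.
#' @param T_len number of time points (TRs).
#' @param tr repetition time in seconds (carried through as metadata).
#' @param seed integer seed.
#' @param init_state optional starting state (default: uniform draw).
#' @param smooth_sigma_trs temporal Gaussian smoothing of the source
#'   samples, in TRs (0 = none).  Smoothing is applied within each dwell
#'   segment and rescaled to preserve the per-state covariance, giving the
#'   sources the low-frequency-dominated spectrum of BOLD signals without
#'   modelling the hemodynamic response itself.
#' @return list with `tc` (T x sources matrix) and `labels` (state per TR).
#' @export
simulate_state_timecourses <- function(states, T_len, tr = 2, seed = 1L,
                                       init_state = NULL,
                                       smooth_sigma_trs = 0) {
  stopifnot(inherits(states, "msfnc_states_spec"), T_len >= 2)
  set.seed(seed)
  K <- states$K
  p <- states$n_sources
  chol_list <- lapply(states$covariances, function(C) {
    ev <- eigen(C, symmetric = TRUE)
    ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), p) %*% t(ev$vectors)
  })
  labels <- integer(T_len)
  labels[1] <- if (is.null(init_state)) sample.int(K, 1) else as.integer(init_state)
  if (K > 1) {
    for (t in 2:T_len)
      labels[t] <- sample.int(K, 1, prob = states$transition[labels[t - 1], ])
  } else labels[] <- 1L
  z <- matrix(rnorm(T_len * p), T_len, p)
  if (smooth_sigma_trs > 0) {
    # smooth the innovations inside each dwell segment; per-sample
    # re-standardisation keeps the covariance structure intact
    half <- ceiling(3 * smooth_sigma_trs)
    kern <- exp(-((-half:half)^2) / (2 * smooth_sigma_trs^2))
    kern <- kern / sum(kern)
    scale_back <- sqrt(sum(kern^2))  # restores unit variance after smoothing
    smooth1 <- function(v) {
      n <- length(v)
      out <- numeric(n)
      for (i in seq_len(n)) {
        lo <- max(1, i - half); hi <- min(n, i + half)
        kk <- kern[(lo - i + half + 1):(hi - i + half + 1)]
        out[i] <- sum(v[lo:hi] * kk) / sqrt(sum(kk^2))
      }
      out
    }
    seg_id <- cumsum(c(1L, diff(labels) != 0))
    for (seg in unique(seg_id)) {
      rows <- which(seg_id == seg)
      if (length(rows) < 3) next
      z[rows, ] <- apply(z[rows, , drop = FALSE], 2, smooth1)
    }
  }
  tc <- matrix(0, T_len, p)
  for (k in seq_len(K)) {
    sel <- labels == k
    if (any(sel)) tc[sel, ] <- z[sel, , drop = FALSE] %*% chol_list[[k]]
  }
  list(tc = tc, labels = labels, tr = tr)
}

#' Specify a synthetic cohort
#'
#' @param n_per_cell subjects per (diagnosis x sex) cell; cells are
#'   CT/male, CT/female, SZ/male, SZ/female.
#' @param effect_pairs data.frame with columns `i`, `j` (source indices),
#'   `diagnosis`, `sex` (cell selectors, `"*"` for any) and `offset`
#'   (added to the covariance entry in every state for matching subjects).
#' @param noise_sd voxel noise standard deviation.
#' @param motion_amp random-walk step scale of the six rigid-body motion
#'   parameters (0 disables motion and its leakage into the data).
#' @param n_sites number of acquisition sites (subjects assigned round-robin).
#' @param seed integer seed.
#' @return an object of class `msfnc_cohort_spec`.
#' @export
cohort_spec <- function(n_per_cell = 8, effect_pairs = NULL, noise_sd = 0.2,
                        motion_amp = 0.02, n_sites = 2, seed = 1L) {
  stopifnot(n_per_cell >= 1)
  if (!is.null(effect_pairs))
    stopifnot(all(c("i", "j", "diagnosis", "sex", "offset") %in% names(effect_pairs)))
  structure(list(n_per_cell = as.integer(n_per_cell),
                 effect_pairs = effect_pairs, noise_sd = noise_sd,
                 motion_amp = motion_amp, n_sites = as.integer(n_sites),
                 seed = as.integer(seed)),
            class = "msfnc_cohort_spec")
}

# random-walk motion: 3 translations (mm) and 3 rotations (radians)
simulate_motion <- function(T_len, amp) {
  steps <- matrix(rnorm(T_len * 6, sd = amp), T_len, 6)
  steps[1, ] <- 0
  apply(steps, 2, cumsum)
}

apply_cell_offsets <- function(states, effect_pairs, diagnosis, sex) {
  if (is.null(effect_pairs)) return(states)
  covs <- states$covariances
  for (r in seq_len(nrow(effect_pairs))) {
    e <- effect_pairs[r, ]
    if ((e$diagnosis == "*" || e$diagnosis == diagnosis) &&
        (e$sex == "*" || e$sex == sex)) {
      for (k in seq_along(covs)) {
        covs[[k]][e$i, e$j] <- covs[[k]][e$i, e$j] + e$offset
        covs[[k]][e$j, e$i] <- covs[[k]][e$j, e$i] + e$offset
      }
    }
  }
  for (C in covs) {
    ev <- min(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < -1e-8) stop("effect offsets make a state covariance indefinite")
  }
  state_spec(covs, dwell_mean = states$dwell_mean, transition = states$transition)
}

#' Render a synthetic cohort of masked fMRI datasets
#'
#' Each subject's voxel-by-time data are built as
#' `fine maps x state-switching time courses + motion leakage + noise`.
#' Motion leakage is a rank-1 term: a fixed random spatial pattern times the
#' subject's summed motion trace, so nuisance regression has a true positive
#' to remove.  Diagnosis/sex cells receive the covariance offsets from the
#' cohort spec; everything else is exchangeable across cells.
#'
#' @param atlas an [make_hierarchical_sources()] atlas.
#' @param states an [state_spec()] whose dimension equals the number of fine
#'   sources.
#' @param cohort a [cohort_spec()].
#' @param T_len time points per subject.
#' @param tr repetition time, seconds.
#' @param smooth_sigma_trs temporal smoothing of source activity in TRs
#'   (default 2, giving the sources a BOLD-like low-frequency spectrum; see
#'   [simulate_state_timecourses()]).
#' @return list with `subjects` (list of `msfnc_dataset`), `phenotype`
#'   (data.frame), and `truth` (per-subject state labels and time courses,
#'   the atlas, the specs).
#' @export
render_cohort <- function(atlas, states, cohort, T_len = 150, tr = 2,
                          smooth_sigma_trs = 2) {
  stopifnot(inherits(atlas, "msfnc_atlas"), inherits(states, "msfnc_states_spec"),
            inherits(cohort, "msfnc_cohort_spec"))
  if (states$n_sources != ncol(atlas$maps$fine))
    stop("state covariance dimension must equal the number of fine sources")
  cells <- expand.grid(diagnosis = c("CT", "SZ"), sex = c("male", "female"),
                       stringsAsFactors = FALSE)
  maps <- atlas$maps$fine                      # voxels x sources
  nv <- nrow(maps)
  set.seed(derive_seed(cohort$seed, 0L))
  motion_pattern <- rnorm(nv)
  motion_pattern <- motion_pattern / vec_norm(motion_pattern)

  subjects <- list()
  pheno <- NULL
  truth_labels <- list()
  truth_tcs <- list()
  sid <- 0L
  for (ci in seq_len(nrow(cells))) {
    st_cell <- apply_cell_offsets(states, cohort$effect_pairs,
                                  cells$diagnosis[ci], cells$sex[ci])
    for (r in seq_len(cohort$n_per_cell)) {
      sid <- sid + 1L
      id <- sprintf("sub-%03d", sid)
      sim <- simulate_state_timecourses(st_cell, T_len, tr,
                                        seed = derive_seed(cohort$seed, sid),
                                        smooth_sigma_trs = smooth_sigma_trs)
      set.seed(derive_seed(cohort$seed, 100000L + sid))
      motion <- simulate_motion(T_len, cohort$motion_amp)
      y <- maps %*% t(sim$tc)
      if (cohort$motion_amp > 0)
        y <- y + outer(motion_pattern, rowSums(motion)) * 3
      if (cohort$noise_sd > 0)
        y <- y + matrix(rnorm(nv * T_len, sd = cohort$noise_sd), nv, T_len)
      site <- sprintf("site%d", ((sid - 1L) %% cohort$n_sites) + 1L)
      age <- round(runif(1, 18, 65), 1)
      symptom <- if (cells$diagnosis[ci] == "SZ") round(runif(1, 40, 100)) else NA
      subjects[[id]] <- masked_dataset(
        data = y, subject_id = id, tr = tr, motion = motion,
        site = site, diagnosis = cells$diagnosis[ci], sex = cells$sex[ci],
        age = age, grid_shape = atlas$grid_shape, normalize = FALSE)
      pheno <- rbind(pheno, data.frame(
        subject_id = id, diagnosis = cells$diagnosis[ci], sex = cells$sex[ci],
        age = age, site = site, mean_fd = NA_real_,
        panss_total = symptom, stringsAsFactors = FALSE))
      truth_labels[[id]] <- sim$labels
      truth_tcs[[id]] <- sim$tc
    }
  }
  # mean FD from the simulated motion, as the analysis stage would compute it
  pheno$mean_fd <- vapply(subjects, function(s)
    framewise_displacement(s$motion)$mean_fd, numeric(1))
  list(subjects = subjects, phenotype = pheno,
       truth = list(labels = truth_labels, timecourses = truth_tcs,
                    atlas = atlas, states = states, cohort = cohort))
}

#' Construct a masked dataset container
#'
#' The standard in-memory unit of the pipeline: a voxels-in-mask by time
#' matrix plus acquisition and phenotype metadata.  When `normalize = TRUE`
#' each voxel time course is z-scored, the variance normalisation applied
#' before ICA.
#'
#' @param data voxels x time numeric matrix.
#' @param subject_id character id.
#' @param tr repetition time, seconds.
#' @param motion optional time x 6 motion parameter matrix.
#' @param site,diagnosis,sex,age phenotype fields.
#' @param grid_shape original 3D grid (for writing volumes back).
#' @param mask logical vector of in-mask voxels on the grid (default: all).
#' @param normalize z-score each voxel time course.
#' @return object of class `msfnc_dataset`.
#' @export
masked_dataset <- function(data, subject_id, tr = 2, motion = NULL,
                           site = NA, diagnosis = NA, sex = NA, age = NA,
                           grid_shape = NULL, mask = NULL, normalize = TRUE) {
  stopifnot(is.matrix(data))
  if (any(!is.finite(data))) stop("non-finite values in dataset ", subject_id)
  if (normalize) {
    mu <- rowMeans(data)
    s <- apply(data, 1, sd)
    if (any(s == 0)) stop("zero-variance voxel time course in ", subject_id)
    data <- (data - mu) / s
  }
  structure(list(data = data, subject_id = subject_id, tr_seconds = tr,
                 motion = motion, site = site, diagnosis = diagnosis,
                 sex = sex, age = age, grid_shape = grid_shape, mask = mask),
            class = "msfnc_dataset")
}

#' @export
print.msfnc_dataset <- function(x, ...) {
  cat("Masked fMRI dataset", x$subject_id, ":", nrow(x$data), "voxels x",
      ncol(x$data), "time points, TR =", x$tr_seconds, "s\n")
  invisible(x)
}

#' Write a simulated cohort to disk as NIfTI + sidecar files
#'
#' Renders each subject to a 4D NIfTI volume, an SPM-convention `rp_*.txt`
#' motion file (3 translations in mm, 3 rotations in radians), writes the
#' shared binary mask, a tab-separated phenotype table and a JSON
#' ground-truth sidecar with the per-subject state labels.
#'
#' @param cohort_data result of [render_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_cohort <- function(cohort_data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  grid <- cohort_data$truth$atlas$grid_shape
  mask <- array(1L, dim = grid)
  RNifti::writeNifti(RNifti::asNifti(mask), file.path(dir, "mask.nii.gz"))
  for (id in names(cohort_data$subjects)) {
    s <- cohort_data$subjects[[id]]
    arr <- array(0, dim = c(grid, ncol(s$data)))
    arr[] <- s$data                      # all-ones mask: direct fill
    RNifti::writeNifti(RNifti::asNifti(arr, datatype = "double"),
                       file.path(dir, paste0(id, "_bold.nii.gz")))
    write.table(format(s$motion, digits = 8), file.path(dir, paste0("rp_", id, ".txt")),
                row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  write.table(cohort_data$phenotype, file.path(dir, "phenotype.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(state_labels = cohort_data$truth$labels,
         n_states = cohort_data$truth$states$K,
         transition = cohort_data$truth$states$transition),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
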