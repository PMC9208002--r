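#' Load a masked 4D NIfTI dataset
#'
#' Reads a 4D functional image and a binary mask on the same grid, extracts
#' the voxels-in-mask by time matrix and z-scores each voxel time course.
#'
#' @param nifti_path path to the 4D image.
#' @param mask_path path to the 3D binary mask.
#' @param subject_id id to attach (default: file stem).
#' @param tr repetition time in seconds; if `NULL`, read from the header.
#' @param motion_path optional whitespace-delimited time x 6 motion file.
#' @param normalize z-score voxel time courses (default TRUE).
#' @return an `msfnc_dataset`.
#' @export
load_masked <- function(nifti_path, mask_path, subject_id = NULL, tr = NULL,
                        motion_path = NULL, normalize = TRUE) {
  img <- RNifti::readNifti(nifti_path)
  msk <- RNifti::readNifti(mask_path)
  di <- dim(img); dm <- dim(msk)
  if (length(di) != 4) stop("expected a 4D image, got ", length(di), "D")
  if (!identical(as.integer(di[1:3]), as.integer(dm[1:3])))
    stop("image grid ", paste(di[1:3], collapse = "x"),
         " does not match mask grid ", paste(dm[1:3], collapse = "x"))
  mask <- as.vector(msk) > 0
  mat <- matrix(as.vector(img), prod(di[1:3]), di[4])[mask, , drop = FALSE]
  if (any(!is.finite(mat))) stop("non-finite voxel values in ", nifti_path)
  if (is.null(tr)) {
    pd <- RNifti::pixdim(img)
    tr <- if (length(pd) >= 4 && pd[4] > 0) pd[4] else 2
  }
  if (is.null(subject_id))
    subject_id <- sub("\\.nii(\\.gz)?$", "", basename(nifti_path))
  motion <- NULL
  if (!is.null(motion_path))
    motion <- as.matrix(read.table(motion_path))
  masked_dataset(mat, subject_id = subject_id, tr = tr, motion = motion,
                 grid_shape = as.integer(di[1:3]), mask = mask,
                 normalize = normalize)
}

#' Write component maps to a 4D NIfTI file
#'
#' Unmasks each map onto the original grid and stacks the components along
#' the fourth axis.  Optionally writes a thresholded overlay (|Z| above the
#' threshold after z-scaling) instead of the raw maps.
#'
#' @param maps components x voxels-in-mask matrix (a single map may be a
#'   vector).
#' @param mask logical vector over the full grid.
#' @param grid_shape 3D grid dimensions.
#' @param path output path.
#' @param z_threshold `NULL` for raw maps, or a threshold (e.g. 1.96) to
#'   write a thresholded overlay.
#' @return invisibly, the path.
#' @export
write_maps <- function(maps, mask, grid_shape, path, z_threshold = NULL) {
  if (is.vector(maps)) maps <- matrix(maps, nrow = 1)
  stopifnot(ncol(maps) == sum(mask))
  if (!is.null(z_threshold)) {
    maps <- t(apply(maps, 1, function(m) {
      z <- (m - mean(m)) / sd(m)
      ifelse(abs(z) > z_threshold, z, 0)
    }))
  }
  arr <- array(0, dim = c(grid_shape, nrow(maps)))
  nv <- prod(grid_shape)
  for (i in seq_len(nrow(maps))) {
    vol <- numeric(nv)
    vol[mask] <- maps[i, ]
    arr[, , , i] <- array(vol, dim = grid_shape)
  }
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "double"), path)
  invisible(path)
}

# ---- run configuration ----------------------------------------------------

config_defaults <- function() {
  list(
    paths = list(data_dir = NULL, mask = NULL, phenotype = NULL,
                 output_dir = "msfnc_out"),
    orders = c(25L, 50L, 75L, 100L),
    master_seed = 1L,
    log_level = "info",
    simulate = list(enabled = FALSE, grid_shape = c(16L, 16L, 8L),
                    n_coarse = 4L, split_factor = 2L, n_states = 2L,
                    dwell_mean = 20, n_per_cell = 8L, noise_sd = 0.2,
                    motion_amp = 0.02, T_len = 150L, tr = 2,
                    smooth_sigma_trs = 2),
    decompose = list(n_runs = 10L, var_retained = 0.9999, normalize = TRUE,
                     ica_tol = 1e-6, ica_max_iter = 1024L),
    icnselect = list(stability_min = 0.8, gm_min = 0.5, artifact_max = 0.5,
                     freq_ratio_min = 2.0),
    clean = list(detrend_order = 3L, motion_regression = TRUE,
                 mad_threshold = 4, band = c(0.01, 0.15), filter_order = 5L,
                 target_tr = 2),
    fnc = list(rect_seconds = 44, sigma_seconds = 6),
    states = list(k = NULL, k_range = 1:15, strategy = "exemplar_two_stage",
                  distance = "cityblock", n_rep = 100L),
    stats = list(n_perm = 5000L, fdr_q = 0.05)
  )
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected; missing keys take package defaults.  The
#' round trip `read_config(write_config(x))` reproduces the configuration.
#'
#' @param path YAML file path.
#' @return a nested configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  def <- config_defaults()
  check_keys <- function(u, d, prefix = "") {
    bad <- setdiff(names(u), names(d))
    if (length(bad) > 0)
      stop("unknown configuration key(s): ",
           paste0(prefix, bad, collapse = ", "))
    for (k in names(u))
      if (is.list(d[[k]]) && !is.null(names(d[[k]])) && is.list(u[[k]]))
        check_keys(u[[k]], d[[k]], paste0(prefix, k, "."))
  }
  check_keys(user, def)
  modifyList(def, user)
}

#' Write a run configuration to YAML
#'
#' @param config configuration list.
#' @param path output YAML path.
#' @return invisibly, the path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

msg <- function(config, ...) {
  if (identical(config$log_level, "quiet")) return(invisible())
  message("[msfnc] ", ...)
}

# ---- pipeline -------------------------------------------------------------

#' Run the full multiscale FNC pipeline
#'
#' Executes, in order: synthetic-cohort simulation (or loading from disk),
#' multiscale group ICA with stability analysis, ICN selection, time-course
#' cleaning, static and windowed FNC, state identification (elbow rule if
#' `states$k` is `NULL`), and the group statistics (per-sex diagnosis
#' contrasts, sex-permutation interaction test, pooled FDR, domain
#' aggregation).  Every stage's outputs, the configuration and the master
#' seed are persisted under the output directory; the run is deterministic
#' given the master seed.
#'
#' @param config configuration list (see [read_config()]), or a path to a
#'   YAML file.
#' @param stop_after optional stage name (`"simulate"`, `"decompose"`,
#'   `"select"`, `"clean"`, `"fnc"`, `"states"`, `"stats"`); execution halts
#'   after that stage with all products so far.
#' @return invisibly, a list with every stage's in-memory results.
#' @export
run_pipeline <- function(config, stop_after = NULL) {
  if (is.character(config)) config <- read_config(config)
  config <- modifyList(config_defaults(), config)
  done <- function(stage_name)
    identical(stop_after, stage_name)
  out_dir <- config$paths$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_config(config, file.path(out_dir, "run_config.yaml"))
  seed <- config$master_seed

  stage <- function(name, expr) {
    msg(config, "stage: ", name)
    tryCatch(expr, error = function(e) {
      where <- deparse(conditionCall(e))[1]
      stop("stage '", name, "' failed: ", conditionMessage(e),
           if (!is.null(conditionCall(e))) paste0(" [in ", where, "]"),
           call. = FALSE)
    })
  }

  # -- inputs ---------------------------------------------------------------
  truth <- NULL
  if (isTRUE(config$simulate$enabled)) {
    sim <- stage("simulate", {
      sc <- config$simulate
      atlas <- make_hierarchical_sources(sc$grid_shape, sc$n_coarse,
                                         sc$split_factor,
                                         seed = derive_seed(seed, 1L))
      nf <- ncol(atlas$maps$fine)
      covs <- default_state_covs(nf, atlas$hierarchy, sc$n_states,
                                 seed = derive_seed(seed, 2L))
      st <- state_spec(covs, dwell_mean = sc$dwell_mean)
      render_cohort(atlas, st,
                    cohort_spec(n_per_cell = sc$n_per_cell,
                                noise_sd = sc$noise_sd,
                                motion_amp = sc$motion_amp,
                                seed = derive_seed(seed, 3L)),
                    T_len = sc$T_len, tr = sc$tr,
                    smooth_sigma_trs = sc$smooth_sigma_trs)
    })
    datasets <- sim$subjects
    pheno <- sim$phenotype
    truth <- sim$truth
    write_cohort(sim, file.path(out_dir, "simulated"))
    if (done("simulate"))
      return(invisible(list(config = config, datasets = datasets,
                            phenotype = pheno, truth = truth)))
  } else {
    datasets <- stage("load", {
      files <- sort(list.files(config$paths$data_dir,
                               pattern = "_bold\\.nii(\\.gz)?$",
                               full.names = TRUE))
      if (length(files) == 0) stop("no *_bold.nii[.gz] files in data_dir")
      lapply(files, function(f) {
        id <- sub("_bold\\.nii(\\.gz)?$", "", basename(f))
        mp <- file.path(dirname(f), paste0("rp_", id, ".txt"))
        load_masked(f, config$paths$mask, subject_id = id,
                    motion_path = if (file.exists(mp)) mp else NULL)
      })
    })
    names(datasets) <- vapply(datasets, `[[`, character(1), "subject_id")
    pheno <- read.table(config$paths$phenotype, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
    pheno <- pheno[match(names(datasets), pheno$subject_id), ]
  }
  if (!("mean_fd" %in% names(pheno)) || any(is.na(pheno$mean_fd)))
    pheno$mean_fd <- vapply(datasets, function(s)
      if (is.null(s$motion)) 0 else framewise_displacement(s$motion)$mean_fd,
      numeric(1))

  # -- decomposition --------------------------------------------------------
  decomps <- stage("decompose", run_multiscale(
    datasets, orders = config$orders, n_runs = config$decompose$n_runs,
    var_retained = config$decompose$var_retained,
    seed = derive_seed(seed, 10L), normalize = config$decompose$normalize,
    tol = config$decompose$ica_tol, max_iter = config$decompose$ica_max_iter))
  for (d in decomps) {
    write_maps(d$group_maps, rep(TRUE, ncol(d$group_maps)),
               grid_of(datasets[[1]], ncol(d$group_maps)),
               file.path(out_dir, sprintf("group_maps_order%d.nii.gz", d$order)))
    write.table(data.frame(component = seq_len(d$order), stability = d$stability),
                file.path(out_dir, sprintf("stability_order%d.tsv", d$order)),
                sep = "\t", row.names = FALSE, quote = FALSE)
  }
  if (done("decompose"))
    return(invisible(list(config = config, datasets = datasets,
                          phenotype = pheno, truth = truth,
                          decompositions = decomps)))

  # -- ICN selection --------------------------------------------------------
  icn_tab <- stage("select", select_icns(
    decomps,
    stability_min = config$icnselect$stability_min,
    gm_min = config$icnselect$gm_min,
    artifact_max = config$icnselect$artifact_max,
    freq_ratio_min = config$icnselect$freq_ratio_min))
  # domain labels for synthetic runs: parent blob of the best-matching truth
  if (!is.null(truth) && all(is.na(icn_tab$domain)))
    icn_tab <- label_domains_from_truth(icn_tab, decomps, truth)
  write.table(icn_tab, file.path(out_dir, "icn_table.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  if (done("select"))
    return(invisible(list(config = config, datasets = datasets,
                          phenotype = pheno, truth = truth,
                          decompositions = decomps, icn_table = icn_tab)))

  # -- cleaning + concatenated ICN time courses -----------------------------
  sel <- icn_tab[which(icn_tab$is_icn), , drop = FALSE]
  if (nrow(sel) < 2) stop("fewer than 2 ICNs selected; nothing to correlate")
  icn_tcs <- stage("clean", lapply(names(datasets), function(id) {
    ds <- datasets[[id]]
    cols <- lapply(seq_len(nrow(sel)), function(r) {
      d <- decomps[[paste0("order", sel$order[r])]]
      d$subject_timecourses[[id]][, sel$component[r]]
    })
    tcs <- do.call(cbind, cols)
    clean_timecourses(tcs, tr = ds$tr_seconds,
                      motion = if (config$clean$motion_regression) ds$motion,
                      detrend_order = config$clean$detrend_order,
                      mad_threshold = config$clean$mad_threshold,
                      band = config$clean$band,
                      filter_order = config$clean$filter_order,
                      target_tr = config$clean$target_tr)
  }))
  names(icn_tcs) <- names(datasets)
  if (done("clean"))
    return(invisible(list(config = config, datasets = datasets,
                          phenotype = pheno, truth = truth,
                          decompositions = decomps, icn_table = icn_tab,
                          icn_timecourses = icn_tcs)))

  # -- FNC ------------------------------------------------------------------
  tr_out <- attr(icn_tcs[[1]], "tr")
  taper <- make_taper(tr_out, config$fnc$rect_seconds, config$fnc$sigma_seconds)
  sfnc <- stage("fnc", lapply(icn_tcs, static_fnc, icn_info = sel))
  wseries <- stage("fnc", lapply(names(icn_tcs), function(id)
    windowed_fnc(icn_tcs[[id]], taper, subject_id = id)))
  names(wseries) <- names(icn_tcs)
  write.table(round(Reduce(`+`, sfnc) / length(sfnc), 6),
              file.path(out_dir, "sfnc_group_mean.tsv"), sep = "\t",
              row.names = FALSE, col.names = FALSE)
  if (done("fnc"))
    return(invisible(list(config = config, datasets = datasets,
                          phenotype = pheno, truth = truth,
                          decompositions = decomps, icn_table = icn_tab,
                          icn_timecourses = icn_tcs, sfnc = sfnc,
                          windows = wseries)))

  # -- states ---------------------------------------------------------------
  st_cfg <- config$states
  k <- st_cfg[["k"]]      # exact: $k would partial-match k_range
  elbow <- NULL
  if (is.null(k)) {
    ex <- select_exemplars(wseries)
    elbow <- stage("states", elbow_k(ex$windows,
                                     k_range = st_cfg$k_range,
                                     distance = st_cfg$distance,
                                     seed = derive_seed(seed, 20L)))
    k <- elbow$k
    msg(config, "elbow selected k = ", k, " (", elbow$confidence, ")")
  }
  model <- stage("states", fit_states(wseries, k, strategy = st_cfg$strategy,
                                      distance = st_cfg$distance,
                                      n_rep = st_cfg$n_rep,
                                      seed = derive_seed(seed, 21L)))
  write.table(model$centroids, file.path(out_dir, "state_centroids.tsv"),
              sep = "\t", row.names = FALSE, col.names = FALSE)
  if (done("states"))
    return(invisible(list(config = config, datasets = datasets,
                          phenotype = pheno, truth = truth,
                          decompositions = decomps, icn_table = icn_tab,
                          icn_timecourses = icn_tcs, sfnc = sfnc,
                          windows = wseries, elbow = elbow, states = model)))

  # -- statistics -----------------------------------------------------------
  stats_out <- stage("stats", {
    feats <- build_feature_matrix(sfnc, model)
    res <- sex_permutation_null(feats$matrix, pheno,
                                n_perm = config$stats$n_perm,
                                seed = derive_seed(seed, 30L))
    pm <- glm_contrast(feats$matrix, pheno, "male")
    pf <- glm_contrast(feats$matrix, pheno, "female")
    pooled <- pooled_fdr(c(pm$p, pf$p, res$p_perm), q = config$stats$fdr_q)
    n <- nrow(res)
    res$q_fdr <- pooled$q_fdr[(2 * n + 1):(3 * n)]
    res$significant <- pooled$significant[(2 * n + 1):(3 * n)]
    res$label <- feats$label
    write.table(res, file.path(out_dir, "contrast_results.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    list(contrasts = res, pooled = pooled,
         male = pm, female = pf)
  })
  dom <- NULL
  if (!all(is.na(sel$domain))) {
    dom <- domain_aggregate(Reduce(`+`, sfnc) / length(sfnc), sel)
    write.table(as.matrix(dom), file.path(out_dir, "domain_sfnc.tsv"),
                sep = "\t", quote = FALSE)
  }

  invisible(list(config = config, datasets = datasets, phenotype = pheno,
                 truth = truth, decompositions = decomps, icn_table = icn_tab,
                 icn_timecourses = icn_tcs, sfnc = sfnc, windows = wseries,
                 elbow = elbow, states = model, stats = stats_out,
                 domain_sfnc = dom))
}

grid_of <- function(ds, nv) {
  if (!is.null(ds$grid_shape)) ds$grid_shape else c(nv, 1L, 1L)
}

# default state covariances for simulated runs: strong within-parent
# coupling at all times, plus state-specific cross-parent couplings
default_state_covs <- function(n_sources, hierarchy, n_states, seed = 1L,
                               within = 0.9, cross = 0.55) {
  set.seed(seed)
  base <- diag(n_sources)
  for (i in seq_len(n_sources - 1)) for (j in (i + 1):n_sources)
    if (hierarchy[i] == hierarchy[j]) base[i, j] <- base[j, i] <- within
  parents <- unique(hierarchy)
  pair_idx <- if (length(parents) >= 2) utils::combn(parents, 2) else NULL
  covs <- vector("list", n_states)
  for (k in seq_len(n_states)) {
    C <- base
    # each state couples two distinct parent pairs (one child each) with
    # opposite signs, so states are well separated connectivity patterns
    if (!is.null(pair_idx)) {
      np <- ncol(pair_idx)
      cols <- ((2 * (k - 1) + 0:1) %% np) + 1
      for (ci in seq_along(cols)) {
        pp <- pair_idx[, cols[ci]]
        i <- which(hierarchy == pp[1])[1]
        j <- which(hierarchy == pp[2])[1]
        C[i, j] <- C[j, i] <- cross * (-1)^(k + ci)
      }
    }
    # nudge toward PSD if the coupling broke it
    ev <- min(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < 1e-6) {
      C <- C + diag(n_sources) * (1e-6 - ev)
      C <- stats::cov2cor(C)
    }
    covs[[k]] <- C
  }
  covs
}

label_domains_from_truth <- function(icn_tab, decomps, truth) {
  atlas <- truth$atlas
  for (r in which(icn_tab$is_icn)) {
    d <- decomps[[paste0("order", icn_tab$order[r])]]
    map <- d$group_maps[icn_tab$component[r], ]
    rc <- abs(cor(map, atlas$maps$fine))
    icn_tab$domain[r] <- paste0("P", atlas$hierarchy[which.max(rc)])
  }
  icn_tab
}

# features for the group statistics: per-subject sFNC pairs plus per-subject
# state-mean pairs for every state (pair-wise, labelled)
build_feature_matrix <- function(sfnc, model) {
  ids <- names(sfnc)
  P <- nrow(sfnc[[1]])
  sf <- t(vapply(ids, function(id) vec_ut(unclass(sfnc[[id]])),
                 numeric(P * (P - 1) / 2)))
  labels <- paste0("sfnc_pair", seq_len(ncol(sf)))
  mats <- list(sf)
  for (s in seq_len(model$k)) {
    sm <- t(vapply(ids, function(id) {
      v <- model$subject_state_means[[id]][[s]]
      if (is.null(v)) rep(NA_real_, P * (P - 1) / 2) else v
    }, numeric(P * (P - 1) / 2)))
    # keep states visited by every subject; partial visits stay out of the GLM
    if (!anyNA(sm)) {
      mats[[length(mats) + 1L]] <- sm
      labels <- c(labels, paste0("state", s, "_pair", seq_len(ncol(sm))))
    }
  }
  list(matrix = do.call(cbind, mats), label = labels)
}

# ---- command-line surface -------------------------------------------------

#' Command-line dispatcher
#'
#' Thin argument-vector interface over the package functions, used by the
#' `msfnc` script: `msfnc <subcommand> --config run.yaml [--key value ...]`.
#' Subcommands: `simulate`, `decompose`, `select`, `clean`, `fnc`,
#' `states`, `stats`, `run` (all of them execute the pipeline up to and
#' including the named stage; `run` executes everything).
#'
#' @param args character vector, e.g. `commandArgs(trailingOnly = TRUE)`.
#' @return invisibly, the pipeline result list.
#' @export
msfnc_cli <- function(args) {
  subcommands <- c("simulate", "decompose", "select", "clean", "fnc",
                   "states", "stats", "run")
  if (length(args) == 0 || !(args[1] %in% subcommands))
    stop("usage: msfnc <", paste(subcommands, collapse = "|"),
         "> --config run.yaml [--seed N] [--out DIR]")
  sub <- args[1]
  opts <- args[-1]
  get_opt <- function(flag) {
    i <- which(opts == flag)
    if (length(i) == 1 && i < length(opts)) opts[i + 1] else NULL
  }
  cfg_path <- get_opt("--config")
  config <- if (is.null(cfg_path)) config_defaults() else read_config(cfg_path)
  if (!is.null(get_opt("--seed")))
    config$master_seed <- as.integer(get_opt("--seed"))
  if (!is.null(get_opt("--out")))
    config$paths$output_dir <- get_opt("--out")
  if (!is.null(get_opt("--k")))
    config$states$k <- as.integer(get_opt("--k"))
  if (sub == "simulate") config$simulate$enabled <- TRUE
  stop_after <- if (sub %in% c("run", "stats")) NULL else sub
  res <- run_pipeline(config, stop_after = stop_after)
  invisible(res)
}
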