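# Shared fixtures, built once per session and cached.  Everything is
# generated in code under fixed seeds; nothing is read from disk.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# small two-scale atlas on the default grid
fix_atlas <- function() fixture("atlas", function()
  make_hierarchical_sources(c(16, 16, 8), n_coarse = 4, split_factor = 2, seed = 1))

# simulated cohort + multiscale decomposition at orders 5 and 10
# (the expensive decomposition fixture, shared across files)
fix_multiscale <- function() fixture("multiscale", function() {
  atlas <- fix_atlas()
  covs <- msfnc:::default_state_covs(8, atlas$hierarchy, n_states = 2, seed = 2,
                                     within = 0.8)
  st <- state_spec(covs, dwell_mean = 20)
  coh <- cohort_spec(n_per_cell = 3, noise_sd = 0.1, motion_amp = 0.02, seed = 3)
  sim <- render_cohort(atlas, st, coh, T_len = 150, tr = 2)
  dec <- run_multiscale(sim$subjects, orders = c(5L, 10L), n_runs = 5,
                        seed = 11, normalize = FALSE)
  list(atlas = atlas, states = st, sim = sim, decomps = dec)
})

# four equidistant connectivity states over 12 sources: +/- 0.9 patterns on
# two disjoint pair sets (city-block distance between any two states equal)
fourstate_spec <- function(r = 0.9, dwell = 40) {
  p <- 12
  mk <- function(pairs, rr) {
    C <- diag(p)
    for (pr in pairs) C[pr[1], pr[2]] <- C[pr[2], pr[1]] <- rr
    C
  }
  A <- list(c(1, 2), c(3, 4), c(5, 6))
  B <- list(c(7, 8), c(9, 10), c(11, 12))
  state_spec(list(mk(A, r), mk(A, -r), mk(B, r), mk(B, -r)), dwell_mean = dwell)
}

# 50 subjects x 150 TRs of windowed FNC from the four-state model
fix_fourstate_windows <- function() fixture("fourstate", function() {
  st <- fourstate_spec()
  taper <- make_taper(2)
  labels <- list()
  ws <- lapply(1:50, function(s) {
    sim <- simulate_state_timecourses(st, 150, 2, seed = 4000 + s)
    labels[[s]] <<- sim$labels
    windowed_fnc(sim$tc, taper, subject_id = sprintf("sub-%02d", s))
  })
  list(spec = st, windows = ws, labels = labels, taper = taper)
})

# phenotype table for statistical tests: balanced diagnosis x sex cells
make_phenotype <- function(n_per_cell = 12, n_sites = 2, seed = 1) {
  set.seed(seed)
  cells <- expand.grid(diagnosis = c("CT", "SZ"), sex = c("male", "female"),
                       stringsAsFactors = FALSE)
  ph <- cells[rep(seq_len(4), each = n_per_cell), ]
  n <- nrow(ph)
  ph$subject_id <- sprintf("sub-%03d", seq_len(n))
  ph$age <- runif(n, 18, 65)
  ph$site <- sprintf("site%d", ((seq_len(n) - 1) %% n_sites) + 1)
  ph$mean_fd <- runif(n, 0.02, 0.4)
  rownames(ph) <- NULL
  ph
}

# all set partitions of seq_len(n) (for brute-force clustering oracles)
all_partitions <- function(n) {
  if (n == 1) return(list(list(1L)))
  smaller <- all_partitions(n - 1)
  out <- list()
  for (p in smaller) {
    for (i in seq_along(p)) {
      q <- p
      q[[i]] <- c(q[[i]], n)
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(p, list(n))
  }
  out
}

# all permutations of a vector (for assignment oracles)
all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in all_perms(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], p)
  out
}

# permutation-corrected Amari index of a gain matrix P = W %*% A
amari_index <- function(P) {
  P <- abs(P)
  n <- nrow(P)
  r <- sum(rowSums(P / apply(P, 1, max)) - 1)
  cl <- sum(colSums(t(t(P) / apply(P, 2, max))) - 1)
  (r + cl) / (2 * n * (n - 1))
}
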