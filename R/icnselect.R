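#' Spectral features of a component time course
#'
#' Computes the power spectrum by Welch's method (mean of Hann-windowed,
#' half-overlapping periodograms) and derives the two criteria used to judge
#' whether a component behaves like a resting-state network: the dynamic
#' range (spectral peak power minus the minimum power at frequencies above
#' the peak) and the ratio of integrated low-frequency to high-frequency
#' power.
#'
#' @param tc numeric time series (>= 64 samples).
#' @param tr_seconds sampling interval in seconds.
#' @param low_band frequency band (Hz) counted as "low" (default 0.01-0.10).
#' @param high_band band counted as "high"; upper edge capped at Nyquist
#'   (default 0.15 Hz upwards).
#' @param nperseg Welch segment length in samples.
#' @return list with `dynamic_range`, `freq_ratio`, `freq`, `power`.
#' @export
spectrum_features <- function(tc, tr_seconds, low_band = c(0.01, 0.10),
                              high_band = c(0.15, Inf), nperseg = 64L) {
  stopifnot(length(tc) >= 64)
  if (tr_seconds <= 0) stop("tr_seconds must be positive")
  if (sd(tc) == 0) stop("constant time course has no defined spectrum")
  n <- length(tc)
  nperseg <- min(nperseg, n)
  step <- max(1L, nperseg %/% 2L)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nperseg) / (nperseg + 1))   # Hann
  starts <- seq(1L, n - nperseg + 1L, by = step)
  nf <- nperseg %/% 2L
  pxx <- numeric(nf)
  for (s in starts) {
    seg <- tc[s:(s + nperseg - 1L)]
    seg <- (seg - mean(seg)) * win
    sp <- Mod(fft(seg))^2 / (sum(win^2) * nperseg)
    pxx <- pxx + sp[2:(nf + 1L)]
  }
  pxx <- pxx / length(starts)
  freq <- (seq_len(nf)) / (nperseg * tr_seconds)
  ipk <- which.max(pxx)
  dyn <- if (ipk < nf) pxx[ipk] - min(pxx[(ipk + 1):nf]) else 0
  nyq <- 1 / (2 * tr_seconds)
  lo <- freq >= low_band[1] & freq <= low_band[2]
  hi <- freq >= high_band[1] & freq <= min(high_band[2], nyq)
  if (!any(lo) || !any(hi))
    stop("frequency bands fall outside the resolvable spectrum")
  list(dynamic_range = dyn, freq_ratio = sum(pxx[lo]) / sum(pxx[hi]),
       freq = freq, power = pxx)
}

#' Spatial plausibility scores of a component map
#'
#' The map is z-scaled and thresholded at |Z| > 1.96; `gm_overlap` is the
#' fraction of suprathreshold voxels falling inside the grey-matter mask,
#' and `artifact_similarity` is the maximum absolute spatial correlation
#' with any of the supplied artifact templates (vascular, ventricular,
#' motion-edge, ...).
#'
#' @param map numeric voxel vector.
#' @param gm_mask logical/0-1 vector on the same grid.
#' @param artifact_maps optional matrix of artifact templates (templates in
#'   rows) on the same grid.
#' @param z_threshold threshold on the z-scaled map (default 1.96).
#' @return list with `gm_overlap` and `artifact_similarity`.
#' @export
spatial_scores <- function(map, gm_mask, artifact_maps = NULL, z_threshold = 1.96) {
  if (length(map) != length(gm_mask)) stop("map and mask grids differ")
  z <- (map - mean(map)) / sd(map)
  supra <- abs(z) > z_threshold
  gm_overlap <- if (any(supra)) mean(gm_mask[supra] > 0) else 0
  artifact_similarity <- 0
  if (!is.null(artifact_maps)) {
    if (is.vector(artifact_maps)) artifact_maps <- matrix(artifact_maps, nrow = 1)
    if (ncol(artifact_maps) != length(map)) stop("artifact template grid differs")
    artifact_similarity <- max(abs(cor(map, t(artifact_maps))))
  }
  list(gm_overlap = gm_overlap, artifact_similarity = artifact_similarity)
}

#' Select intrinsic connectivity networks from decompositions
#'
#' Scores every component of every model order and applies the conjunction
#' of selection criteria: ICASSO stability above `stability_min`,
#' grey-matter overlap at least `gm_min`, artifact similarity at most
#' `artifact_max`, and low/high frequency power ratio at least
#' `freq_ratio_min`.  Domain labels are attached from user-supplied rules:
#' either templates matched by absolute spatial correlation or an explicit
#' (order, component) -> domain lookup.  With `report_only = TRUE` the table
#' is returned with scores but no selection applied.
#'
#' @param decomps list of `msfnc_decomposition` (from [run_multiscale()]).
#' @param gm_mask grey-matter mask vector; `NULL` treats every voxel as
#'   grey matter.
#' @param artifact_maps optional artifact template matrix (templates x voxels).
#' @param domain_rules either a list of labelled templates
#'   (`list(label=, map=)`), or a data.frame with columns `order`,
#'   `component`, `domain`, or `NULL`.
#' @param stability_min,gm_min,artifact_max,freq_ratio_min thresholds.
#' @param min_template_r minimum |r| for a template to assign a domain.
#' @param report_only compute scores without applying thresholds.
#' @return an `msfnc_icn_table` data.frame with one row per component:
#'   order, component, is_icn, domain, stability, dynamic_range,
#'   freq_ratio, gm_overlap, artifact_similarity.
#' @export
select_icns <- function(decomps, gm_mask = NULL, artifact_maps = NULL,
                        domain_rules = NULL, stability_min = 0.8,
                        gm_min = 0.5, artifact_max = 0.5,
                        freq_ratio_min = 2.0, min_template_r = 0.3,
                        report_only = FALSE) {
  if (inherits(decomps, "msfnc_decomposition")) decomps <- list(decomps)
  rows <- list()
  for (dec in decomps) {
    N <- dec$order
    nv <- ncol(dec$group_maps)
    gm <- if (is.null(gm_mask)) rep(1L, nv) else gm_mask
    # average the spectral features over subjects for robustness
    for (ci in seq_len(N)) {
      feats <- vapply(dec$subject_timecourses, function(tc) {
        f <- spectrum_features(tc[, ci], dec$tr_seconds)
        c(f$dynamic_range, f$freq_ratio)
      }, numeric(2))
      sp <- spatial_scores(dec$group_maps[ci, ], gm, artifact_maps)
      rows[[length(rows) + 1L]] <- data.frame(
        order = N, component = ci, is_icn = NA,
        domain = NA_character_,
        stability = dec$stability[ci],
        dynamic_range = mean(feats[1, ]),
        freq_ratio = mean(feats[2, ]),
        gm_overlap = sp$gm_overlap,
        artifact_similarity = sp$artifact_similarity,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  pass <- (is.na(tab$stability) | tab$stability > stability_min) &
    tab$gm_overlap >= gm_min &
    tab$artifact_similarity <= artifact_max &
    tab$freq_ratio >= freq_ratio_min
  # components without a stability index (single-run decompositions) rely on
  # the remaining criteria; with an index, the stability bar is strict
  pass[!is.na(tab$stability) & tab$stability <= stability_min] <- FALSE
  tab$is_icn <- if (report_only) NA else pass
  if (!report_only && !is.null(domain_rules)) {
    tab$domain <- assign_domains(tab, decomps, domain_rules, min_template_r)
    miss <- tab$is_icn & is.na(tab$domain)
    if (any(miss))
      warning(sum(miss), " selected ICN(s) have no matching domain rule")
  }
  class(tab) <- c("msfnc_icn_table", "data.frame")
  tab
}

assign_domains <- function(tab, decomps, domain_rules, min_template_r) {
  domain <- rep(NA_character_, nrow(tab))
  if (is.data.frame(domain_rules)) {
    for (r in seq_len(nrow(domain_rules))) {
      hit <- tab$order == domain_rules$order[r] &
        tab$component == domain_rules$component[r]
      domain[hit & tab$is_icn] <- domain_rules$domain[r]
    }
    return(domain)
  }
  labels <- vapply(domain_rules, `[[`, character(1), "label")
  templates <- do.call(rbind, lapply(domain_rules, `[[`, "map"))
  by_order <- split(seq_len(nrow(tab)), tab$order)
  for (dec in decomps) {
    idx <- by_order[[as.character(dec$order)]]
    R <- abs(cor(t(dec$group_maps), t(templates)))
    for (i in seq_along(idx)) {
      row <- idx[i]
      if (!isTRUE(tab$is_icn[row])) next
      best <- which.max(R[tab$component[row], ])
      if (R[tab$component[row], best] >= min_template_r)
        domain[row] <- labels[best]
    }
  }
  domain
}

#' Tabulate ICN counts by functional domain and model order
#'
#' @param icn_table an `msfnc_icn_table`.
#' @return a domains x orders integer matrix of selected-ICN counts, with a
#'   trailing `total` row.
#' @export
icn_counts <- function(icn_table) {
  sel <- icn_table[which(icn_table$is_icn), , drop = FALSE]
  orders <- sort(unique(icn_table$order))
  domains <- sort(unique(stats::na.omit(sel$domain)))
  m <- matrix(0L, length(domains) + 1L, length(orders),
              dimnames = list(c(domains, "total"), paste0("order", orders)))
  for (d in seq_along(domains)) for (o in seq_along(orders))
    m[d, o] <- sum(sel$domain == domains[d] & sel$order == orders[o], na.rm = TRUE)
  m["total", ] <- vapply(orders, function(o) sum(sel$order == o), integer(1))
  m
}
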