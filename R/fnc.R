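#' Static functional network connectivity
#'
#' Pearson correlation between every pair of ICN time courses over the full
#' scan length, one symmetric matrix per subject.
#'
#' @param tcs time x components matrix (columns in IcnTable order; the
#'   object carries its ordering so domain-major "block" and order-major
#'   "finger" sorts are reproducible downstream).
#' @param icn_info optional data.frame with one row per column (e.g. the
#'   selected rows of an `msfnc_icn_table`); stored as the ordering
#'   metadata.
#' @return an `msfnc_fnc` correlation matrix.
#' @export
static_fnc <- function(tcs, icn_info = NULL) {
  stopifnot(is.matrix(tcs), nrow(tcs) >= 3)
  sds <- apply(tcs, 2, sd)
  if (any(sds == 0))
    stop("constant ICN time course(s): column ",
         paste(which(sds == 0), collapse = ", "))
  m <- cor(tcs)
  structure(m, class = c("msfnc_fnc", "matrix"), icn_info = icn_info)
}

#' Build the tapered sliding window
#'
#' Discrete convolution of a rectangle of width `rect_seconds` with a
#' unit-sum Gaussian kernel of width `sigma_seconds` (truncated at three
#' standard deviations and renormalised), sampled at the TR.  The taper's
#' weight sum equals the rectangle length.
#'
#' @param tr repetition time, seconds.
#' @param rect_seconds rectangle width in seconds (default 44).
#' @param sigma_seconds Gaussian sigma in seconds (default 6).
#' @return an `msfnc_taper` list: `weights`, `rect_len_samples`,
#'   `half_kernel` (samples the taper extends beyond the rectangle on each
#'   side), `step_samples` (always 1), `tr`.
#' @export
make_taper <- function(tr, rect_seconds = 44, sigma_seconds = 6) {
  stopifnot(tr > 0)
  rect_len <- rect_seconds / tr
  if (abs(rect_len - round(rect_len)) > 1e-9) {
    warning("rectangle width is not an integer number of TRs; rounding")
  }
  rect_len <- as.integer(round(rect_len))
  if (rect_len < 2) stop("window shorter than 2 samples")
  if (sigma_seconds <= 0) {
    warning("sigma <= 0; returning the plain rectangle window")
    return(structure(list(weights = rep(1, rect_len),
                          rect_len_samples = rect_len, half_kernel = 0L,
                          step_samples = 1L, tr = tr),
                     class = "msfnc_taper"))
  }
  sig <- sigma_seconds / tr
  half <- as.integer(ceiling(3 * sig))
  kern <- exp(-((-half:half)^2) / (2 * sig^2))
  kern <- kern / sum(kern)
  w <- convolve(rep(1, rect_len), rev(kern), type = "open")
  structure(list(weights = as.numeric(w), rect_len_samples = rect_len,
                 half_kernel = half, step_samples = 1L, tr = tr),
            class = "msfnc_taper")
}

#' Number of sliding windows for a scan length
#'
#' The convention is `T - rect_len_samples` windows at a one-sample step:
#' a scan of 135 two-second volumes with a 44 s rectangle yields 113
#' windows.
#'
#' @param T_len scan length in samples.
#' @param taper an [make_taper()] object.
#' @return integer window count.
#' @export
n_windows <- function(T_len, taper) {
  stopifnot(inherits(taper, "msfnc_taper"))
  w <- T_len - taper$rect_len_samples
  if (w < 1) stop("scan too short for the window length")
  as.integer(w)
}

# weighted Pearson correlation matrix of the rows idx of x with weights w
weighted_corr <- function(x, w) {
  w <- w / sum(w)
  mu <- colSums(x * w)
  xc <- sweep(x, 2, mu)
  cv <- crossprod(xc * w, xc)
  s <- sqrt(diag(cv))
  r <- cv / tcrossprod(s)
  r[!is.finite(r)] <- NA
  diag(r) <- 1
  pmin(pmax(r, -1), 1)
}

#' Tapered sliding-window dynamic FNC
#'
#' For each window onset, computes the weighted Pearson correlation of all
#' ICN pairs using the taper weights (truncated and renormalised where the
#' Gaussian tails run past the scan edges) and stores the vectorised upper
#' triangle.  Windows with zero weighted variance in any column are flagged
#' and excluded downstream.
#'
#' @param tcs time x components matrix.
#' @param taper an [make_taper()] object.
#' @param subject_id carried into the result.
#' @return an `msfnc_window_series`: `windows` (W x P(P-1)/2 matrix),
#'   `window_onsets`, `valid` (logical), `n_components`, `subject_id`.
#' @export
windowed_fnc <- function(tcs, taper, subject_id = NA_character_) {
  stopifnot(is.matrix(tcs), inherits(taper, "msfnc_taper"))
  T_len <- nrow(tcs)
  p <- ncol(tcs)
  W <- n_windows(T_len, taper)
  half <- taper$half_kernel
  L <- length(taper$weights)
  offset <- -half    # taper sample j maps to time  onset + j - 1 - half
  out <- matrix(NA_real_, W, p * (p - 1) / 2)
  valid <- rep(TRUE, W)
  for (i in seq_len(W)) {
    t0 <- i + offset
    idx <- t0:(t0 + L - 1)
    keep <- idx >= 1 & idx <= T_len
    xw <- tcs[idx[keep], , drop = FALSE]
    ww <- taper$weights[keep]
    r <- weighted_corr(xw, ww)
    if (anyNA(r)) { valid[i] <- FALSE; next }
    out[i, ] <- vec_ut(r)
  }
  structure(list(windows = out, window_onsets = seq_len(W), valid = valid,
                 n_components = p, subject_id = subject_id,
                 taper = taper),
            class = "msfnc_window_series")
}

#' @export
print.msfnc_window_series <- function(x, ...) {
  cat("Windowed FNC series", x$subject_id, ":", nrow(x$windows), "windows x",
      ncol(x$windows), "ICN pairs\n")
  invisible(x)
}
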