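#' Remove polynomial trends from a time course
#'
#' OLS projection removing the polynomial basis up to `order` (constant,
#' linear, quadratic, cubic by default).
#'
#' @param tc numeric vector.
#' @param order polynomial order (default 3).
#' @return detrended vector, orthogonal to the polynomial basis.
#' @export
detrend_poly <- function(tc, order = 3L) {
  n <- length(tc)
  if (n <= order + 1) stop("time course too short to remove order-", order, " trend")
  x <- seq_len(n)
  basis <- cbind(1, stats::poly(x, degree = order))
  stats::lm.fit(basis, tc)$residuals
}

#' Regress motion parameters and their derivatives out of a time course
#'
#' Residualises the time course on the six rigid-body parameters, their
#' backward first differences (first row zero), and an intercept.
#' Collinear regressors are dropped with a warning.
#'
#' @param tc numeric vector.
#' @param motion time x 6 matrix of motion parameters.
#' @return residual time course.
#' @export
regress_nuisance <- function(tc, motion) {
  stopifnot(length(tc) == nrow(motion), ncol(motion) == 6)
  d <- rbind(0, diff(motion))
  X <- cbind(1, motion, d)
  q <- qr(X)
  if (q$rank < ncol(X)) {
    warning("dropping ", ncol(X) - q$rank, " collinear nuisance regressor(s)")
    X <- X[, q$pivot[seq_len(q$rank)], drop = FALSE]
  }
  stats::lm.fit(X, tc)$residuals
}

#' Despike a time course by MAD outlier detection and spline replacement
#'
#' Samples deviating from the median by more than `mad_threshold` robust
#' standard deviations (1.4826 x MAD, floored at a small epsilon for
#' near-constant series) are flagged and replaced by a cubic smoothing
#' spline fitted to the clean samples, in the spirit of AFNI 3dDespike.
#'
#' @param tc numeric vector (>= 8 clean points required).
#' @param mad_threshold robust z threshold (default 4).
#' @return list with `tc` (despiked series) and `spike_mask` (logical).
#' @export
despike <- function(tc, mad_threshold = 4) {
  n <- length(tc)
  med <- median(tc)
  scale <- 1.4826 * median(abs(tc - med))
  scale <- max(scale, 1e-12 + 1e-9 * max(abs(tc - med)))
  mask <- abs(tc - med) > mad_threshold * scale
  if (sum(mask) > n / 2) stop("more than half the samples flagged as spikes")
  if (!any(mask)) return(list(tc = tc, spike_mask = mask))
  clean <- which(!mask)
  if (length(clean) < 8) stop("fewer than 8 clean samples")
  out <- tc
  fit <- tryCatch(
    smooth.spline(clean, tc[clean]),
    error = function(e) NULL)
  if (is.null(fit)) {
    out[mask] <- spline(clean, tc[clean], xout = which(mask))$y
  } else {
    out[mask] <- predict(fit, which(mask))$y
  }
  list(tc = out, spike_mask = mask)
}

#' Band-pass filter a time course (zero-phase Butterworth)
#'
#' Fifth-order Butterworth band-pass applied forward and backward
#' (zero-phase), the standard low-frequency filter for connectivity
#' analysis.
#'
#' @param tc numeric vector.
#' @param tr sampling interval, seconds.
#' @param band numeric length-2, pass band in Hz (default 0.01-0.15).
#' @param order filter order (default 5).
#' @return filtered vector.
#' @export
bandpass <- function(tc, tr, band = c(0.01, 0.15), order = 5L) {
  nyq <- 1 / (2 * tr)
  if (band[1] <= 0 || band[2] >= nyq || band[1] >= band[2])
    stop("band must satisfy 0 < low < high < Nyquist (", round(nyq, 3), " Hz)")
  bf <- signal::butter(order, band / nyq, type = "pass")
  as.numeric(signal::filtfilt(bf, tc))
}

#' Resample a time course to a new repetition time
#'
#' Cubic-spline interpolation onto a grid with spacing `target_tr` spanning
#' the original scan; a no-op when the rates already agree.  The series is
#' mirror-padded before fitting so the spline's free boundary does not
#' distort the first and last samples.
#'
#' @param tc numeric vector.
#' @param src_tr source TR, seconds.
#' @param target_tr target TR, seconds (default 2).
#' @return resampled vector.
#' @export
resample_to_tr <- function(tc, src_tr, target_tr = 2) {
  stopifnot(src_tr > 0, target_tr > 0)
  if (src_tr == target_tr) return(tc)
  n <- length(tc)
  pad <- min(8L, n - 1L)
  padded <- c(2 * tc[1] - tc[(pad + 1):2],       # odd (point) reflection
              tc,
              2 * tc[n] - tc[(n - 1):(n - pad)])
  t_pad <- (seq_along(padded) - 1 - pad) * src_tr
  t_new <- seq(0, (n - 1) * src_tr, by = target_tr)
  spline(t_pad, padded, xout = t_new)$y
}

#' Clean a matrix of component time courses
#'
#' Applies the post-hoc cleaning chain in fixed order — polynomial
#' detrending, motion (plus derivative) regression, MAD despiking,
#' zero-phase Butterworth band-pass — column by column, then optionally
#' resamples to the target TR.
#'
#' @param tcs time x components matrix.
#' @param tr repetition time, seconds.
#' @param motion optional time x 6 motion matrix; `NULL` skips nuisance
#'   regression.
#' @param detrend_order polynomial order (default 3).
#' @param mad_threshold despiking threshold (default 4).
#' @param band band-pass in Hz (default 0.01-0.15).
#' @param filter_order Butterworth order (default 5).
#' @param target_tr resample to this TR (default 2; `NULL` disables).
#' @return cleaned time x components matrix (attribute `tr` gives the
#'   output sampling interval).
#' @export
clean_timecourses <- function(tcs, tr, motion = NULL, detrend_order = 3L,
                              mad_threshold = 4, band = c(0.01, 0.15),
                              filter_order = 5L, target_tr = 2) {
  stopifnot(is.matrix(tcs))
  out <- apply(tcs, 2, function(tc) {
    tc <- detrend_poly(tc, detrend_order)
    if (!is.null(motion)) tc <- regress_nuisance(tc, motion)
    tc <- despike(tc, mad_threshold)$tc
    bandpass(tc, tr, band, filter_order)
  })
  if (!is.null(target_tr) && target_tr != tr) {
    out <- apply(out, 2, resample_to_tr, src_tr = tr, target_tr = target_tr)
    tr <- target_tr
  }
  attr(out, "tr") <- tr
  out
}
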