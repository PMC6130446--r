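#' Motion-censoring configuration
#'
#' Frames whose frame displacement exceeds `fd_threshold` are censored, any
#' surviving run of retained frames shorter than `min_segment` is censored
#' too, and a scan is flagged for exclusion when fewer than `min_usable`
#' seconds survive. Defaults follow common rs-fMRI practice for
#' child/adolescent data: 0.2 mm, 5 contiguous volumes, 2.5 minutes.
#'
#' @param fd_threshold censoring threshold in mm (> 0).
#' @param min_segment minimum surviving run length in frames (>= 1).
#' @param min_usable minimum usable time in seconds (>= 0).
#' @return a `censor_config` list.
#' @export
censor_config <- function(fd_threshold = 0.2, min_segment = 5L,
                          min_usable = 150) {
  stopifnot(fd_threshold > 0, min_segment >= 1, min_usable >= 0)
  structure(list(fd_threshold = fd_threshold,
                 min_segment = as.integer(min_segment),
                 min_usable = min_usable),
            class = "censor_config")
}

#' Censor high-motion frames
#'
#' Builds the frame-retention mask: frames with FD above the threshold are
#' dropped, then every maximal surviving run shorter than `min_segment`
#' frames is dropped as well. Scans retaining less than `min_usable` seconds
#' are flagged for exclusion (not an error).
#'
#' @param fd per-frame displacement vector (mm, non-negative).
#' @param tr sampling interval in seconds.
#' @param cfg a [censor_config].
#' @return list with `mask` (logical), `usable_s` (seconds retained) and
#'   `exclude` (logical scan-exclusion flag).
#' @export
censor_frames <- function(fd, tr, cfg = censor_config()) {
  stopifnot(is.numeric(fd), all(is.finite(fd)), all(fd >= 0), tr > 0)
  mask <- fd <= cfg$fd_threshold
  if (any(mask)) {
    runs <- true_runs(mask)
    short <- runs[runs[, "end"] - runs[, "start"] + 1L < cfg$min_segment, ,
                  drop = FALSE]
    for (i in seq_len(nrow(short)))
      mask[short[i, "start"]:short[i, "end"]] <- FALSE
  }
  usable <- sum(mask) * tr
  list(mask = mask, usable_s = usable, exclude = usable < cfg$min_usable)
}

#' Band-pass filter configuration
#'
#' First-order Butterworth band pass, 0.009-0.080 Hz by default (the
#' canonical rs-fMRI band). Applied forward-backward (zero phase) so that
#' frame-wise predictions are not phase-shifted.
#'
#' @param band_lo,band_hi pass band edges in Hz.
#' @param order filter order.
#' @return a `filter_config` list.
#' @export
filter_config <- function(band_lo = 0.009, band_hi = 0.080, order = 1L) {
  stopifnot(band_lo > 0, band_hi > band_lo, order >= 1)
  structure(list(band_lo = band_lo, band_hi = band_hi,
                 order = as.integer(order)),
            class = "filter_config")
}

#' Band-pass filter ROI time courses
#'
#' Zero-phase Butterworth band-pass applied identically to every column.
#' Filtering is applied to the full (uncensored) series; the censor mask is
#' consumed downstream, so filtering never smears across censored gaps that
#' have already been cut out.
#'
#' @param ts a [scan_timeseries] or numeric matrix.
#' @param cfg a [filter_config].
#' @param tr sampling interval in seconds (taken from `ts` when it is a
#'   [scan_timeseries]).
#' @return object of the same type as `ts`, filtered.
#' @export
bandpass <- function(ts, cfg = filter_config(), tr = NULL) {
  is_ts <- inherits(ts, "scan_timeseries")
  x <- if (is_ts) ts$data else as.matrix(ts)
  tr <- if (is_ts) ts$tr else tr
  stopifnot(!is.null(tr), tr > 0)
  nyq <- 1 / (2 * tr)
  if (cfg$band_hi >= nyq)
    stop(sprintf("band_hi (%.4g Hz) must be below the Nyquist frequency (%.4g Hz)",
                 cfg$band_hi, nyq))
  bf <- signal::butter(cfg$order, c(cfg$band_lo, cfg$band_hi) / nyq,
                       type = "pass")
  out <- apply(x, 2, function(col) signal::filtfilt(bf, col))
  if (is_ts) {
    ts$data <- out
    ts
  } else out
}

#' Regress nuisance signals out of ROI time courses
#'
#' Each ROI column is replaced by its least-squares residual against an
#' intercept, a linear trend and the supplied nuisance regressors (e.g.
#' whole-brain, ventricle and white-matter signals, movement parameters).
#' Collinear regressor columns are dropped with a warning.
#'
#' @param ts a [scan_timeseries] or numeric matrix.
#' @param regressors frames x K numeric matrix, or `NULL` for detrending only.
#' @return same type as `ts`, residualized.
#' @export
nuisance_regress <- function(ts, regressors = NULL) {
  is_ts <- inherits(ts, "scan_timeseries")
  x <- if (is_ts) ts$data else as.matrix(ts)
  n <- nrow(x)
  design <- cbind(intercept = 1, trend = seq_len(n) - (n + 1) / 2)
  if (!is.null(regressors)) {
    regressors <- as.matrix(regressors)
    if (nrow(regressors) != n)
      stop(sprintf("regressors have %d rows but the scan has %d frames",
                   nrow(regressors), n))
    design <- cbind(design, regressors)
  }
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    dropped <- qrd$pivot[(qrd$rank + 1):ncol(design)]
    warning(sprintf("dropping %d collinear nuisance column(s): %s",
                    length(dropped),
                    paste(colnames(design)[dropped] %||% dropped,
                          collapse = ", ")))
    design <- design[, qrd$pivot[seq_len(qrd$rank)], drop = FALSE]
    qrd <- qr(design)
  }
  out <- qr.resid(qrd, x)
  if (is_ts) {
    ts$data <- out
    ts
  } else out
}

#' Remove temporal autocorrelation from each ROI (prewhitening)
#'
#' Fits an autoregressive model of the given order per ROI by Yule-Walker
#' and returns its residuals; the first `order` frames are dropped from all
#' ROIs (and from the frame mask) to keep alignment. `order = 0` returns the
#' input unchanged, the appropriate setting for data already cleaned of
#' autocorrelation (e.g. ICA-denoised acquisitions).
#'
#' @param ts a [scan_timeseries] or numeric matrix.
#' @param order AR order (non-negative integer; default 1, a minimal
#'   prewhitening).
#' @return same type as `ts`, with `order` fewer frames; the fitted AR
#'   coefficients are attached as attribute `"ar_coef"` (M x order).
#' @export
remove_autocorrelation <- function(ts, order = 1L) {
  order <- as.integer(order)
  stopifnot(order >= 0)
  if (order == 0L) return(ts)
  is_ts <- inherits(ts, "scan_timeseries")
  x <- if (is_ts) ts$data else as.matrix(ts)
  n <- nrow(x)
  if (n < order + 10L)
    stop(sprintf("need at least %d frames for AR(%d) prewhitening, have %d",
                 order + 10L, order, n))
  m <- ncol(x)
  coefs <- matrix(0, m, order)
  res <- matrix(0, n - order, m)
  clipped <- FALSE
  for (j in seq_len(m)) {
    phi <- tryCatch(
      stats::ar.yw(x[, j], aic = FALSE, order.max = order,
                   demean = TRUE)$ar,
      error = function(e) rep(0, order))
    if (length(phi) < order) phi <- c(phi, rep(0, order - length(phi)))
    if (any(abs(phi) >= 1)) {
      clipped <- TRUE
      phi <- pmin(pmax(phi, -0.999), 0.999)
    }
    coefs[j, ] <- phi
    xc <- x[, j] - mean(x[, j])
    pred <- rep(0, n - order)
    for (k in seq_len(order)) pred <- pred + phi[k] * xc[(order - k + 1):(n - k)]
    res[, j] <- xc[(order + 1):n] - pred
  }
  if (clipped)
    warning("near-nonstationary AR fit: coefficient(s) clipped to |phi| < 1")
  if (is_ts) {
    ts$data <- res
    ts$frame_mask <- ts$frame_mask[(order + 1):n]
    attr(ts, "ar_coef") <- coefs
    ts
  } else {
    attr(res, "ar_coef") <- coefs
    res
  }
}

#' Preprocess one scan with a named profile
#'
#' Two preset profiles mirror the two acquisition styles the pipeline
#' supports. `"oregon"`: nuisance regression (intercept + trend + supplied
#' regressors), zero-phase band-pass, AR(1) prewhitening, then motion
#' censoring of the surviving frames (regression before filtering; filtering
#' on the full series with the mask applied afterwards). `"hcp"`: nuisance
#' regression only (ICA-cleaned data; no censoring, no prewhitening).
#'
#' @param ts a [scan_timeseries].
#' @param profile `"oregon"`, `"hcp"` or `"custom"`.
#' @param fd optional per-frame displacement trace (required for censoring).
#' @param regressors optional frames x K nuisance matrix.
#' @param censor a [censor_config].
#' @param filter a [filter_config] (set `NULL` to skip).
#' @param ar_order prewhitening order (profile default: 1 for oregon,
#'   0 for hcp).
#' @return a [scan_timeseries]; attribute `"exclude"` is TRUE when too little
#'   usable data survives censoring.
#' @export
preprocess_scan <- function(ts, profile = c("oregon", "hcp", "custom"),
                            fd = NULL, regressors = NULL,
                            censor = censor_config(),
                            filter = filter_config(),
                            ar_order = NULL) {
  profile <- match.arg(profile)
  stopifnot(inherits(ts, "scan_timeseries"))
  do_censor <- switch(profile, oregon = TRUE, hcp = FALSE, custom = !is.null(fd))
  do_filter <- switch(profile, oregon = TRUE, hcp = FALSE,
                      custom = !is.null(filter))
  ar_order <- ar_order %||% switch(profile, oregon = 1L, hcp = 0L, custom = 1L)
  exclude <- FALSE
  mask <- ts$frame_mask
  if (do_censor) {
    if (is.null(fd)) stop("profile requires an FD trace for censoring")
    if (length(fd) != nrow(ts$data))
      stop("FD length does not match frame count")
    cen <- censor_frames(fd, ts$tr, censor)
    mask <- mask & cen$mask
    exclude <- cen$exclude
  }
  ts <- nuisance_regress(ts, regressors)
  if (do_filter) ts <- bandpass(ts, filter)
  if (ar_order > 0L) {
    keep_from <- ar_order + 1L
    ts <- remove_autocorrelation(ts, ar_order)
    mask <- mask[keep_from:length(mask)]
  }
  ts$frame_mask <- mask
  attr(ts, "exclude") <- exclude
  ts
}
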