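#' Construct a ROI time-series scan object
#'
#' A light container for one scan: a frames x ROIs BOLD matrix, its TR,
#' subject/condition labels, an optional frames x 9 confound matrix
#' (6 motion + 3 tissue regressors), and a keep/censor mask.
#'
#' @param data Numeric T x N matrix (frames x ROIs), no missing values.
#' @param tr_seconds Repetition time in seconds.
#' @param subject_id,condition Scan labels.
#' @param confounds Optional T x 9 numeric matrix.
#' @param censor_mask Optional length-T logical, `TRUE` = keep.
#' @return An object of class `roi_ts`.
#' @export
roi_timeseries <- function(data, tr_seconds, subject_id = NA_character_,
                           condition = NA_character_, confounds = NULL,
                           censor_mask = NULL) {
  data <- as.matrix(data)
  assert_that(nrow(data) >= 2, "a scan needs at least 2 frames")
  assert_that(!anyNA(data), "data must not contain missing values")
  assert_that(is.numeric(tr_seconds) && tr_seconds > 0,
              "tr_seconds must be a positive duration")
  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    assert_that(nrow(confounds) == nrow(data),
                "confounds must have one row per frame")
  }
  censor_mask <- censor_mask %||% rep(TRUE, nrow(data))
  assert_that(length(censor_mask) == nrow(data),
              "censor_mask length must equal the number of frames")
  structure(list(
    data = data, tr_seconds = tr_seconds, subject_id = subject_id,
    condition = condition, confounds = confounds,
    censor_mask = as.logical(censor_mask)
  ), class = "roi_ts")
}

#' @export
print.roi_ts <- function(x, ...) {
  cat("<roi_ts> ", x$subject_id, "/", x$condition, ": ",
      nrow(x$data), " frames x ", ncol(x$data), " ROIs, TR = ",
      x$tr_seconds, " s; kept ", sum(x$censor_mask), "/",
      length(x$censor_mask), "\n", sep = "")
  invisible(x)
}

#' Tidy a scan into a long tibble
#'
#' @param x A `roi_ts`.
#' @param ... Unused.
#' @return A tibble with columns `frame`, `roi`, `value`, `kept`.
#' @method tidy roi_ts
#' @export
tidy.roi_ts <- function(x, ...) {
  rois <- colnames(x$data) %||% as.character(seq_len(ncol(x$data)))
  tibble::tibble(
    frame = rep(seq_len(nrow(x$data)), times = ncol(x$data)),
    roi = rep(rois, each = nrow(x$data)),
    value = as.numeric(x$data),
    kept = rep(x$censor_mask, times = ncol(x$data))
  )
}

#' Remove the per-ROI linear trend
#'
#' Least-squares fit of an intercept + linear term per ROI column, removed;
#' output columns have (numerically) zero mean.
#'
#' @param ts A [roi_timeseries()] scan.
#' @return The scan with detrended data.
#' @export
detrend <- function(ts) {
  assert_that(inherits(ts, "roi_ts"), "ts must be a roi_ts")
  assert_that(nrow(ts$data) >= 3, "detrending needs at least 3 frames")
  t_idx <- seq_len(nrow(ts$data))
  X <- cbind(1, t_idx - mean(t_idx))
  ts$data <- ts$data - X %*% qr.solve(X, ts$data)
  ts
}

#' Zero-phase band-pass filter
#'
#' Second-order Butterworth band-pass applied forward-backward
#' ([signal::filtfilt()]) to each ROI column, so no phase distortion is
#' introduced. Defaults to the canonical resting-state band 0.01-0.08 Hz.
#'
#' @param ts A [roi_timeseries()] scan.
#' @param low_hz,high_hz Passband edges in Hz; `high_hz` must be below the
#'   Nyquist frequency `1/(2 * tr_seconds)`.
#' @return The scan with filtered data.
#' @export
bandpass <- function(ts, low_hz = 0.01, high_hz = 0.08) {
  assert_that(inherits(ts, "roi_ts"), "ts must be a roi_ts")
  nyq <- 1 / (2 * ts$tr_seconds)
  assert_that(low_hz > 0 && low_hz < high_hz,
              "need 0 < low_hz < high_hz")
  assert_that(high_hz < nyq,
              sprintf("high_hz must be below Nyquist (%.4f Hz)", nyq))
  bf <- signal::butter(2, c(low_hz, high_hz) / nyq, type = "pass")
  ts$data <- apply(ts$data, 2, function(x) signal::filtfilt(bf, x))
  ts
}

#' Regress out motion and tissue nuisance signals
#'
#' OLS of each ROI column on an intercept plus the scan's 9 confound columns
#' (6 motion, 3 tissue: CSF, WM, global signal); the residuals replace the
#' data and are orthogonal to every confound.
#'
#' @param ts A [roi_timeseries()] scan with confounds attached.
#' @return The scan with residualized data.
#' @export
regress_nuisance <- function(ts) {
  assert_that(inherits(ts, "roi_ts"), "ts must be a roi_ts")
  assert_that(!is.null(ts$confounds), "scan has no confounds to regress")
  X <- cbind(intercept = 1, ts$confounds)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    idx <- qrX$pivot[(qrX$rank + 1):ncol(X)]
    nm <- colnames(X)[idx]
    if (is.null(nm) || any(!nzchar(nm))) nm <- paste0("column ", idx)
    abort(paste0("confound design is rank deficient; collinear columns: ",
                 paste(nm, collapse = ", ")))
  }
  ts$data <- ts$data - X %*% qr.coef(qrX, ts$data)
  ts
}

#' Framewise displacement from motion parameters
#'
#' Power-style FD: the sum of absolute frame-to-frame differences of the six
#' rigid-body parameters, with the three rotations (radians) converted to arc
#' length on a 50 mm sphere. `fd[1] = 0` by convention.
#'
#' @param motion_params T x 6 matrix: 3 translations (mm) then 3 rotations
#'   (radians).
#' @param head_radius_mm Sphere radius for the rotation arc length.
#' @return Numeric vector of length T, in mm.
#' @export
compute_fd <- function(motion_params, head_radius_mm = 50) {
  motion_params <- as.matrix(motion_params)
  assert_that(ncol(motion_params) == 6, "motion_params must have 6 columns")
  assert_that(nrow(motion_params) >= 2, "need at least 2 frames")
  d <- abs(diff(motion_params))
  d[, 4:6] <- d[, 4:6] * head_radius_mm
  c(0, rowSums(d))
}

#' DVARS of a ROI series
#'
#' Root-mean-square over ROIs of the frame-to-frame signal difference;
#' `dvars[1] = 0` by convention. Computed on the post-regression,
#' pre-censoring series in the standard pipeline.
#'
#' @param data T x N numeric matrix.
#' @return Numeric vector of length T.
#' @export
compute_dvars <- function(data) {
  data <- as.matrix(data)
  assert_that(nrow(data) >= 2, "need at least 2 frames")
  c(0, sqrt(rowMeans(diff(data)^2)))
}

#' Censor high-motion frames
#'
#' A frame is dropped iff `fd > fd_thresh` OR `dvars > dvars_thresh`
#' (strict inequalities).
#'
#' @param fd,dvars Equal-length numeric series.
#' @param fd_thresh FD threshold in mm.
#' @param dvars_thresh DVARS threshold.
#' @return Logical keep-mask of the same length (`TRUE` = keep).
#' @export
censor_frames <- function(fd, dvars, fd_thresh = 0.5, dvars_thresh = 150) {
  assert_that(length(fd) == length(dvars),
              "fd and dvars must have the same length")
  !(fd > fd_thresh | dvars > dvars_thresh)
}

#' Demean each ROI over the kept frames
#'
#' Subtracts from every ROI column its mean over the kept (non-censored)
#' frames; censored frames are shifted by the same amount.
#'
#' @param ts A [roi_timeseries()] scan.
#' @return The scan with kept-frame column means equal to 0.
#' @export
demean <- function(ts) {
  assert_that(inherits(ts, "roi_ts"), "ts must be a roi_ts")
  keep <- ts$censor_mask
  if (!any(keep)) abort("empty scan: every frame is censored")
  mu <- colMeans(ts$data[keep, , drop = FALSE])
  ts$data <- sweep(ts$data, 2, mu)
  ts
}

#' Full postprocessing chain for one scan
#'
#' Applies, in order: detrend, band-pass (0.01-0.08 Hz), nuisance
#' regression, motion/DVARS frame censoring (FD > 0.5 mm or DVARS > 150),
#' and kept-frame demeaning. Filtering precedes masking so censoring gaps do
#' not create filter artifacts; censored frames are excluded from analysis,
#' not interpolated. A scrubbing report (FD, DVARS, counts, thresholds) is
#' attached as attribute `"scrubbing"`.
#'
#' @param ts A [roi_timeseries()] scan with confounds.
#' @param low_hz,high_hz Band-pass edges (Hz).
#' @param fd_thresh,dvars_thresh Censoring thresholds.
#' @return The postprocessed scan.
#' @export
postprocess <- function(ts, low_hz = 0.01, high_hz = 0.08,
                        fd_thresh = 0.5, dvars_thresh = 150) {
  out <- ts |> detrend() |> bandpass(low_hz, high_hz) |> regress_nuisance()
  fd <- compute_fd(out$confounds[, 1:6, drop = FALSE])
  dvars <- compute_dvars(out$data)
  out$censor_mask <- ts$censor_mask &
    censor_frames(fd, dvars, fd_thresh, dvars_thresh)
  if (!any(out$censor_mask)) abort("empty scan: every frame is censored")
  out <- demean(out)
  attr(out, "scrubbing") <- tibble::tibble(
    frame = seq_along(fd), fd = fd, dvars = dvars, kept = out$censor_mask
  )
  attr(out, "scrub_summary") <- list(
    n_censored = sum(!out$censor_mask),
    fd_thresh = fd_thresh, dvars_thresh = dvars_thresh
  )
  attr(out, "postprocessed") <- TRUE
  out
}
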