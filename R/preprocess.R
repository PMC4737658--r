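#' Remove per-voxel linear trends
#'
#' Fits, per voxel, a least-squares line over the valid frames and subtracts
#' it over all frames, so residuals have exactly zero mean (and zero linear
#' trend) over the valid frames.
#'
#' @param epoch a [ts_epoch()] with at least 3 valid frames.
#' @return the detrended epoch.
#' @export
detrend_linear <- function(epoch) {
  stopifnot_epoch(epoch)
  v <- which(epoch$valid)
  if (length(v) < 3L) stop("detrending needs >= 3 valid frames")
  t_all <- seq_len(ncol(epoch$data))
  X <- cbind(1, t_all)
  fit <- stats::lm.fit(X[v, , drop = FALSE], t(epoch$data[, v, drop = FALSE]))
  epoch$data <- epoch$data - t(X %*% fit$coefficients)
  epoch
}

#' Zero-phase low-pass filtering
#'
#' Retains infra-slow frequencies below `cutoff_hz` with a forward-backward
#' (zero-phase) second-order Butterworth filter — effectively 4th order, with
#' squared magnitude response. Zero phase is mandatory here: any phase shift
#' would bias the measured lags. Filtering runs over the full frame axis;
#' censoring-induced gaps are not interpolated (censoring normally follows
#' filtering in [preprocess_epoch()]).
#'
#' @param epoch a [ts_epoch()].
#' @param cutoff_hz passband edge in Hz (default 0.1); must be below the
#'   Nyquist frequency `1/(2 tr)`.
#' @return the filtered epoch.
#' @export
lowpass <- function(epoch, cutoff_hz = 0.1) {
  stopifnot_epoch(epoch)
  nyq <- 1 / (2 * epoch$tr)
  if (cutoff_hz <= 0 || cutoff_hz >= nyq)
    stop("`cutoff_hz` must lie in (0, Nyquist = ", signif(nyq, 4), " Hz)")
  bf <- signal::butter(2, cutoff_hz / nyq, type = "low")
  nf <- ncol(epoch$data)
  # odd reflection padding suppresses forward-backward edge transients while
  # preserving constants and linear trends
  np <- min(nf - 1L, max(12L, ceiling(3 / (cutoff_hz / nyq))))
  epoch$data <- t(apply(epoch$data, 1L, function(x) {
    head_pad <- 2 * x[1L] - x[(np + 1L):2L]
    tail_pad <- 2 * x[nf] - x[(nf - 1L):(nf - np)]
    y <- signal::filtfilt(bf, c(head_pad, x, tail_pad))
    y[(np + 1L):(np + nf)]
  }))
  epoch
}

#' Regress out nuisance waveforms
#'
#' Projects each voxel series onto the orthogonal complement of the nuisance
#' design (plus intercept, plus optionally the global mean signal) over the
#' valid frames, the standard fMRI nuisance-regression step. Residuals are
#' exactly orthogonal to every regressor column over the valid frames.
#'
#' @param epoch a [ts_epoch()].
#' @param nuisance `n_frames x q` matrix of regressors (may be NULL when
#'   `include_global = TRUE`); columns may be named.
#' @param include_global add the across-voxel mean series as a regressor
#'   (global signal regression). Default TRUE, as in standard lag analyses.
#' @return the residual epoch.
#' @export
regress_nuisance <- function(epoch, nuisance = NULL, include_global = TRUE) {
  stopifnot_epoch(epoch)
  nf <- ncol(epoch$data)
  X <- matrix(1, nrow = nf, ncol = 1L, dimnames = list(NULL, "intercept"))
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != nf)
      stop("nuisance regressors must have one row per frame")
    if (any(apply(nuisance, 2L, function(c) all(c == 0))))
      stop("nuisance set contains a constant-zero column")
    if (is.null(colnames(nuisance)))
      colnames(nuisance) <- paste0("nuis", seq_len(ncol(nuisance)))
    X <- cbind(X, nuisance)
  }
  if (include_global)
    X <- cbind(X, global = colMeans(epoch$data))
  v <- which(epoch$valid)
  Xv <- X[v, , drop = FALSE]
  qrX <- qr(Xv)
  if (qrX$rank < ncol(Xv)) {
    bad <- colnames(Xv)[qrX$pivot[(qrX$rank + 1L):ncol(Xv)]]
    stop("nuisance design is rank-deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qrX, t(epoch$data[, v, drop = FALSE]))
  epoch$data <- epoch$data - t(X %*% beta)
  epoch
}

#' RMS frame-to-frame change (the censoring statistic)
#'
#' For frames `t = 2..T`: `sqrt(mean_v (x[v,t] - x[v,t-1])^2)`, i.e. the
#' DVARS-style root mean square intensity change from the previous frame.
#'
#' @param epoch a [ts_epoch()].
#' @return numeric vector of length `n_frames`; entry 1 is `NA` (no
#'   predecessor).
#' @export
frame_rms_change <- function(epoch) {
  stopifnot_epoch(epoch)
  d <- epoch$data
  c(NA_real_, sqrt(colMeans((d[, -1L, drop = FALSE] -
                             d[, -ncol(d), drop = FALSE])^2)))
}

#' Censor high-motion-like frames and short segments
#'
#' Frames whose normalized RMS change from the previous frame exceeds
#' `threshold_pct` percent of the baseline intensity are marked invalid (the
#' first frame of each epoch has no predecessor and is kept by convention).
#' Afterwards every maximal run of valid frames shorter than `min_run` is
#' invalidated entirely; an epoch in which nothing survives is returned with
#' an all-FALSE mask and attribute `empty = TRUE` — a reportable outcome, not
#' an error.
#'
#' The percentage needs a base. When the data are raw positive intensities
#' (grand mean exceeding twice the grand SD) the epoch's grand mean is used;
#' otherwise — e.g. for detrended, zero-mean series — a nominal mode-1000
#' baseline applies, so 0.5 percent corresponds to 5 intensity units.
#'
#' @param epoch a [ts_epoch()].
#' @param threshold_pct threshold as percent of baseline (default 0.5).
#' @param min_run minimum surviving contiguous-run length (default 10).
#' @param baseline explicit baseline intensity overriding the heuristic.
#' @return the epoch with an updated `valid` mask; attributes
#'   `censored_fraction` (share of previously valid frames dropped) and
#'   `empty`.
#' @export
censor_frames <- function(epoch, threshold_pct = 0.5, min_run = 10L,
                          baseline = NULL) {
  stopifnot_epoch(epoch)
  if (ncol(epoch$data) < 2L) stop("censoring needs >= 2 frames")
  if (is.null(baseline)) {
    gm <- mean(epoch$data)
    gs <- stats::sd(as.vector(epoch$data))
    baseline <- if (is.finite(gs) && gm > 2 * gs) gm else 1000
  }
  thr <- threshold_pct / 100 * baseline
  rms <- frame_rms_change(epoch)
  was_valid <- epoch$valid
  flag <- !is.na(rms) & rms > thr          # flag the arriving frame
  valid <- epoch$valid & !flag
  # drop maximal valid runs shorter than min_run
  r <- rle(valid)
  r$values <- r$values & r$lengths >= min_run
  valid <- inverse.rle(r)
  epoch$valid <- valid
  attr(epoch, "censored_fraction") <-
    if (any(was_valid)) sum(was_valid & !valid) / sum(was_valid) else 0
  attr(epoch, "empty") <- !any(valid)
  epoch
}

#' Full per-epoch preprocessing pipeline
#'
#' Default order: detrend -> low-pass -> nuisance regression -> censoring,
#' each stage optional. Censoring runs on the current data with the
#' mode-1000 convention unless a baseline is given.
#'
#' @param epoch a [ts_epoch()].
#' @param cutoff_hz low-pass edge (Hz); `NA` skips filtering.
#' @param nuisance optional regressor matrix for [regress_nuisance()].
#' @param include_global include global-mean regression.
#' @param censor_threshold_pct,min_run,baseline censoring parameters; set
#'   `censor_threshold_pct = NA` to skip censoring.
#' @param censor_stage `"filtered"` evaluates the censoring statistic on the
#'   fully processed data (the default pipeline order); `"detrended"`
#'   evaluates it right after detrending — low-pass filtering smears sharp
#'   intensity transients below threshold, so scrubbing-style censoring of
#'   raw artifacts belongs before the filter. The resulting mask is applied
#'   to the processed epoch either way.
#' @param detrend run linear detrending.
#' @return the preprocessed epoch (see [censor_frames()] attributes).
#' @export
preprocess_epoch <- function(epoch, cutoff_hz = 0.1, nuisance = NULL,
                             include_global = TRUE,
                             censor_threshold_pct = 0.5, min_run = 10L,
                             baseline = NULL,
                             censor_stage = c("filtered", "detrended"),
                             detrend = TRUE) {
  censor_stage <- match.arg(censor_stage)
  if (detrend) epoch <- detrend_linear(epoch)
  pre_filter <- epoch
  if (!is.na(cutoff_hz)) epoch <- lowpass(epoch, cutoff_hz)
  if (!is.null(nuisance) || include_global)
    epoch <- regress_nuisance(epoch, nuisance, include_global)
  if (!is.na(censor_threshold_pct)) {
    target <- if (censor_stage == "detrended") pre_filter else epoch
    cen <- censor_frames(target, censor_threshold_pct, min_run, baseline)
    epoch$valid <- cen$valid
    attr(epoch, "censored_fraction") <- attr(cen, "censored_fraction")
    attr(epoch, "empty") <- attr(cen, "empty")
  }
  epoch
}
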