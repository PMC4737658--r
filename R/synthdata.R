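#' Generate aperiodic 1/f^alpha latent source signals
#'
#' Infra-slow BOLD fluctuations are aperiodic with approximately 1/f spectral
#' content confined to the infra-slow band. Sources are realized by spectral
#' shaping: white Gaussian noise is Fourier transformed, each frequency bin
#' is scaled by `f^(-alpha/2)` (so power goes as `1/f^alpha`) times a smooth
#' band-limiting rolloff above `f_cutoff` (8th-order Butterworth-style
#' amplitude response), the DC bin is zeroed, and the inverse transform is
#' taken. The band limit matters: sub-sample lag recovery is only possible
#' when the signal stays correlated across neighbouring frames, which is the
#' infra-slow premise of the whole analysis. Each signal is standardized to
#' zero mean and unit standard deviation, so mixing weights and `noise_sd`
#' in a [lag_plan()] directly set the signal-to-noise ratio.
#'
#' @param k number of mutually independent sources (>= 1).
#' @param m_fine number of fine-grid samples per source (>= 64).
#' @param dt_fine fine-grid sampling interval, seconds (> 0).
#' @param alpha spectral exponent (>= 0); `alpha = 0` gives a flat passband,
#'   `alpha = 1` the canonical pink/1-over-f spectrum.
#' @param f_cutoff band limit in Hz (default 0.1, the infra-slow edge);
#'   `Inf` disables band limiting.
#' @param seed integer RNG seed; same seed, same output.
#' @return a `"source_set"`: list with `signals` (k x m_fine matrix),
#'   `dt_fine`, `spectral_exponent`, `rng_seed`.
#' @export
generate_sources <- function(k, m_fine, dt_fine, alpha = 1, f_cutoff = 0.1,
                             seed = 1L) {
  if (!is.numeric(k) || k < 1) stop("`k` must be >= 1")
  if (!is.numeric(m_fine) || m_fine < 64) stop("`m_fine` must be >= 64")
  if (!is.numeric(dt_fine) || dt_fine <= 0) stop("`dt_fine` must be positive")
  if (!is.numeric(alpha) || alpha < 0) stop("`alpha` must be >= 0")
  k <- as.integer(k); m_fine <- as.integer(m_fine)
  set.seed(as.integer(seed))
  # symmetric frequency index: bin j and m-j share |f|
  j <- seq_len(m_fine) - 1L
  fidx <- pmin(j, m_fine - j)
  f <- fidx / (m_fine * dt_fine)
  scale <- c(0, f[-1]^(-alpha / 2))            # DC zeroed -> zero mean
  if (is.finite(f_cutoff))
    scale <- scale / sqrt(1 + (f / f_cutoff)^8)
  signals <- matrix(0, nrow = k, ncol = m_fine)
  for (s in seq_len(k)) {
    w <- stats::rnorm(m_fine)
    x <- Re(stats::fft(stats::fft(w) * scale, inverse = TRUE)) / m_fine
    x <- x - mean(x)
    signals[s, ] <- x / stats::sd(x)
  }
  structure(list(signals = signals, dt_fine = dt_fine,
                 spectral_exponent = alpha, f_cutoff = f_cutoff,
                 rng_seed = as.integer(seed)),
            class = "source_set")
}

#' @export
print.source_set <- function(x, ...) {
  cat(sprintf("<source_set> %d sources x %d fine samples (dt = %g s, alpha = %g)\n",
              nrow(x$signals), ncol(x$signals), x$dt_fine, x$spectral_exponent))
  invisible(x)
}

#' Define a voxel mixing/delay plan
#'
#' A lag plan maps `k` latent sources onto `n_voxels` voxel series: voxel `v`
#' is `sum_k weights[v,k] * s_k(t - delays[v,k]) + noise`. Delays are in
#' seconds and need not be multiples of TR — sub-sample ground truth is the
#' point. For `k = 1` the ground-truth pairwise lag between voxels `i` and
#' `j` is `delays[i] - delays[j]` (positive means `i` later).
#'
#' @param weights `n_voxels x k` mixing matrix (unitless).
#' @param delays `n_voxels x k` delay matrix (seconds, finite).
#' @param noise_sd standard deviation of additive white voxel noise (>= 0).
#' @param tr repetition time of the sampled series (seconds).
#' @param n_frames number of sampled frames.
#' @return a `"lag_plan"` list.
#' @export
lag_plan <- function(weights, delays, noise_sd = 0, tr = 2.08, n_frames = 150L) {
  weights <- as.matrix(weights); delays <- as.matrix(delays)
  if (!all(dim(weights) == dim(delays)))
    stop("`weights` and `delays` must have identical dimensions")
  if (!all(is.finite(delays))) stop("`delays` must be finite")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (tr <= 0 || n_frames < 2) stop("need `tr` > 0 and `n_frames` >= 2")
  structure(list(weights = weights, delays = delays, noise_sd = noise_sd,
                 tr = tr, n_frames = as.integer(n_frames)),
            class = "lag_plan")
}

#' Synthesize one epoch from sources and a lag plan
#'
#' Voxel series are formed by evaluating each delayed source on the fine grid
#' with cubic-spline interpolation, mixing per the plan's weights, sampling
#' every TR, and adding white Gaussian noise. All frames are marked valid.
#'
#' @param sources a [generate_sources()] result.
#' @param plan a [lag_plan()]; its delay range plus the sampled span must fit
#'   inside the fine-grid span, otherwise a domain error is raised.
#' @param noise_seed optional integer seed for the additive noise; `NULL`
#'   uses the current RNG state.
#' @param subject_id,state_label,epoch_id identifiers passed to [ts_epoch()].
#' @return a [ts_epoch()].
#' @export
synthesize_epoch <- function(sources, plan, noise_seed = NULL,
                             subject_id = "s1", state_label = "A",
                             epoch_id = 1L) {
  if (!inherits(sources, "source_set")) stop("`sources` must be a source_set")
  if (!inherits(plan, "lag_plan")) stop("`plan` must be a lag_plan")
  k <- nrow(sources$signals)
  if (ncol(plan$weights) != k)
    stop("plan has ", ncol(plan$weights), " source columns, sources has ", k)
  m <- ncol(sources$signals)
  span <- (m - 1L) * sources$dt_fine
  t_frames <- (seq_len(plan$n_frames) - 1L) * plan$tr
  # origin offset keeps every evaluation time nonnegative for any delay sign
  t0 <- max(0, max(plan$delays))
  t_max <- t0 + max(t_frames) - min(0, min(plan$delays))
  if (t_max > span)
    stop("delay range plus sampled span (", signif(t_max, 4),
         " s) exceeds the fine-grid span (", signif(span, 4), " s)")
  t_fine <- (seq_len(m) - 1L) * sources$dt_fine
  n_vox <- nrow(plan$weights)
  data <- matrix(0, nrow = n_vox, ncol = plan$n_frames)
  for (s in seq_len(k)) {
    sf <- stats::splinefun(t_fine, sources$signals[s, ], method = "natural")
    dls <- unique(plan$delays[, s])
    for (d in dls) {
      rows <- which(plan$delays[, s] == d)
      series <- sf(t0 + t_frames - d)
      data[rows, ] <- data[rows, ] +
        plan$weights[rows, s, drop = FALSE] %*% matrix(series, nrow = 1L)
    }
  }
  if (plan$noise_sd > 0) {
    if (!is.null(noise_seed)) set.seed(as.integer(noise_seed))
    data <- data + matrix(stats::rnorm(length(data), sd = plan$noise_sd),
                          nrow = n_vox)
  }
  ts_epoch(data, tr = plan$tr, subject_id = subject_id,
           state_label = state_label, epoch_id = epoch_id)
}

#' Define a two-state multi-subject study
#'
#' @param n_subjects_per_state subjects per state (each subject belongs to
#'   one state; permutation tests treat subject-state as exchangeable).
#' @param epochs_per_subject epochs per subject.
#' @param state_plans named list of [lag_plan()]s, one per state; names are
#'   the state labels (must be distinct, non-empty).
#' @param partition a [network_partition()] labelling the plan's voxels.
#' @param alpha spectral exponent of the latent sources.
#' @param source_band_hz band limit of the latent sources in Hz (default
#'   0.1, the infra-slow edge).
#' @param dt_fine_divisor fine grid resolution as a fraction of TR (fine step
#'   = TR / divisor; default 32 keeps sub-sample delays representable).
#' @param rng_seed master seed; every subject-epoch draws an independent
#'   source realization from a deterministic sub-seed sequence.
#' @return a `"study_design"` list.
#' @export
study_design <- function(n_subjects_per_state = 6L, epochs_per_subject = 1L,
                         state_plans, partition = NULL, alpha = 1,
                         source_band_hz = 0.1,
                         dt_fine_divisor = 32L, rng_seed = 1L) {
  if (length(state_plans) == 0L) stop("`state_plans` must name at least one state")
  if (is.null(names(state_plans)) || anyDuplicated(names(state_plans)) ||
      any(names(state_plans) == ""))
    stop("`state_plans` must have distinct non-empty names")
  for (p in state_plans) if (!inherits(p, "lag_plan"))
    stop("every element of `state_plans` must be a lag_plan")
  nf <- unique(vapply(state_plans, function(p) p$n_frames, integer(1)))
  if (length(nf) == 1L && nf < 150L)
    warning("frames_per_epoch < 150: epochs shorter than the 5-minute design convention")
  structure(list(n_subjects_per_state = as.integer(n_subjects_per_state),
                 epochs_per_subject = as.integer(epochs_per_subject),
                 state_plans = state_plans, partition = partition,
                 alpha = alpha, source_band_hz = source_band_hz,
                 dt_fine_divisor = as.integer(dt_fine_divisor),
                 rng_seed = as.integer(rng_seed)),
            class = "study_design")
}

#' Generate a labelled multi-subject, multi-state synthetic study
#'
#' Each subject-epoch gets an independent source realization; all epochs of a
#' state share that state's [lag_plan()], so the planted lag structure is the
#' state's ground truth. Deterministic under `design$rng_seed`.
#'
#' @param design a [study_design()].
#' @return list of [ts_epoch()] objects with subject/state/epoch labels, plus
#'   attributes `design`.
#' @export
generate_study <- function(design) {
  if (!inherits(design, "study_design")) stop("`design` must be a study_design")
  states <- names(design$state_plans)
  set.seed(design$rng_seed)
  # sub-seeds drawn once, below 2^31, so each epoch is independently seeded
  n_ep <- length(states) * design$n_subjects_per_state * design$epochs_per_subject
  sub_seeds <- sample.int(.Machine$integer.max - 1L, 2L * n_ep)
  epochs <- vector("list", n_ep)
  i <- 0L
  for (st in states) {
    plan <- design$state_plans[[st]]
    dt_fine <- plan$tr / design$dt_fine_divisor
    pad <- max(plan$delays) - min(0, min(plan$delays)) + 4 * plan$tr
    m_fine <- as.integer(ceiling(((plan$n_frames - 1L) * plan$tr + pad) / dt_fine)) + 2L
    for (sj in seq_len(design$n_subjects_per_state)) {
      sid <- sprintf("%s_s%02d", st, sj)
      for (ep in seq_len(design$epochs_per_subject)) {
        i <- i + 1L
        src <- generate_sources(k = ncol(plan$weights), m_fine = m_fine,
                                dt_fine = dt_fine, alpha = design$alpha,
                                f_cutoff = design$source_band_hz,
                                seed = sub_seeds[2L * i - 1L])
        epochs[[i]] <- synthesize_epoch(src, plan,
                                        noise_seed = sub_seeds[2L * i],
                                        subject_id = sid, state_label = st,
                                        epoch_id = ep)
      }
    }
  }
  attr(epochs, "design") <- design
  epochs
}

#' Add global intensity spikes to selected frames
#'
#' Adds a uniform deviation to every voxel at the listed frames, creating the
#' frame-to-frame intensity jumps that [censor_frames()] must flag. The valid
#' mask is left untouched — censoring is the preprocessing stage's job.
#'
#' @param epoch a [ts_epoch()].
#' @param spike_frames integer frame indices (1-based, within range).
#' @param spike_amplitude added intensity (signal units).
#' @return the spiked epoch.
#' @export
inject_artifacts <- function(epoch, spike_frames, spike_amplitude) {
  stopifnot_epoch(epoch)
  if (length(spike_frames) == 0L) return(epoch)
  spike_frames <- as.integer(spike_frames)
  if (any(spike_frames < 1L) || any(spike_frames > ncol(epoch$data)))
    stop("spike frame index out of range")
  epoch$data[, spike_frames] <- epoch$data[, spike_frames] + spike_amplitude
  epoch
}
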