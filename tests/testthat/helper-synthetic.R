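# shared builders for synthetic fixtures; everything generated in code

# random exactly anti-symmetric TD matrix with full validity
random_td <- function(n, sd = 0.5, seed = NULL, tr = 2.08) {
  if (!is.null(seed)) set.seed(seed)
  E <- matrix(stats::rnorm(n * n, sd = sd), n, n)
  A <- (E - t(E)) / sqrt(2)
  diag(A) <- 0
  structure(list(td = A, amp = matrix(1, n, n),
                 validity = matrix(TRUE, n, n), n = n, tr = tr,
                 max_lag_frames = 4L),
            class = "td_matrix")
}

# TD matrix from an explicit delay vector (ground truth d_i - d_j)
td_from_delays <- function(delays, tr = 2.08) {
  n <- length(delays)
  A <- outer(delays, delays, `-`)
  structure(list(td = A, amp = matrix(1, n, n),
                 validity = matrix(TRUE, n, n), n = n, tr = tr,
                 max_lag_frames = 4L),
            class = "td_matrix")
}

# two-voxel epoch with a planted fractional delay (voxel 2 later by `delta`)
delayed_pair_epoch <- function(delta, noise_sd = 0, n_frames = 150L,
                               tr = 2.08, seed = 1L, alpha = 1) {
  src <- generate_sources(1, m_fine = 32L * (n_frames + 20L),
                          dt_fine = tr / 32, alpha = alpha, seed = seed)
  plan <- lag_plan(matrix(1, 2, 1), matrix(c(0, delta), 2, 1),
                   noise_sd = noise_sd, tr = tr, n_frames = n_frames)
  synthesize_epoch(src, plan, noise_seed = seed + 1L)
}

# multi-voxel single-source epoch with planted per-voxel delays
delayed_epoch <- function(delays, noise_sd = 0, n_frames = 150L, tr = 2.08,
                          seed = 1L) {
  n <- length(delays)
  src <- generate_sources(1, m_fine = 32L * (n_frames + 20L),
                          dt_fine = tr / 32, alpha = 1, seed = seed)
  plan <- lag_plan(matrix(1, n, 1), matrix(delays, n, 1),
                   noise_sd = noise_sd, tr = tr, n_frames = n_frames)
  synthesize_epoch(src, plan, noise_seed = seed + 1L)
}

# brute-force lagged cross-covariance: naive double loop over frames,
# independent of the vectorized estimator it checks
brute_crosscov <- function(x1, x2, mask, max_lag_frames = 4L,
                           normalize = TRUE) {
  nf <- length(x1)
  lags <- seq(-max_lag_frames, max_lag_frames)
  vals <- rep(NA_real_, length(lags))
  for (li in seq_along(lags)) {
    tau <- lags[li]
    a <- c(); b <- c()
    for (t in seq_len(nf)) {
      t1 <- t + tau
      if (t1 >= 1L && t1 <= nf && mask[t1] && mask[t]) {
        a <- c(a, x1[t1]); b <- c(b, x2[t])
      }
    }
    if (length(a) < 2L) next
    am <- a - mean(a); bm <- b - mean(b)
    v <- mean(am * bm)
    if (normalize) v <- v / sqrt(mean(am^2) * mean(bm^2))
    vals[li] <- v
  }
  list(lags = lags, values = vals)
}

# naive transcription of the Laplace PCA evidence, used as an independent
# check of the vectorized scorer
brute_laplace_evidence <- function(lam, N, k) {
  d <- length(lam)
  if (k == 0) return(-N * d / 2 * log(mean(lam)))
  sig2 <- mean(lam[(k + 1):d])
  logpu <- 0
  for (i in 1:k)
    logpu <- logpu - log(2) + lgamma((d - i + 1) / 2) -
      (d - i + 1) / 2 * log(pi)
  m <- d * k - k * (k + 1) / 2
  lamhat <- lam
  for (j in (k + 1):d) lamhat[j] <- sig2
  logaz <- 0
  for (i in 1:k) for (j in (i + 1):d) {
    gap <- (1 / lamhat[j] - 1 / lamhat[i]) * (lam[i] - lam[j]) * N
    if (gap <= 0) return(-Inf)
    logaz <- logaz + log(gap)
  }
  logpu - N / 2 * sum(log(lam[1:k])) - N * (d - k) / 2 * log(sig2) +
    (m + k) / 2 * log(2 * pi) - logaz / 2 - k / 2 * log(N)
}
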