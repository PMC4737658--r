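#' Lag-thread decomposition of a TD matrix
#'
#' Multiple propagation sequences ("lag threads") are extracted by spatial
#' PCA of the TD matrix after zero-centering each column: invalid entries are
#' imputed with their column mean (equivalently zero after centering — the
#' least-informative linear completion), each column's mean is subtracted,
#' the columns are treated as observations of an n-dimensional spatial
#' variable, and their covariance is eigendecomposed. Component maps are
#' eigenvectors scaled by the RMS projection of the centered columns (the
#' square root of the eigenvalue), putting them on a seconds scale; the sign
#' of each component is arbitrary.
#'
#' @param td a [build_td_matrix()] result (n >= 3).
#' @param k_max number of components to retain and the candidate maximum for
#'   the dimensionality estimate (default 10, capped at n - 1).
#' @return a `"thread_decomposition"`: list with `eigenvalues` (all n,
#'   descending, >= 0), `components` (n x k_max, seconds, up to sign),
#'   `dimensionality_ml` (from [ml_dimensionality()]), `n_columns_used`.
#' @export
lag_threads <- function(td, k_max = 10L) {
  M <- td$td
  n <- nrow(M)
  if (n < 3L) stop("thread decomposition needs at least 3 voxels")
  ok <- td$validity
  M[!ok] <- NA
  diag(M) <- 0
  # impute invalid entries with the column mean over valid entries
  cm_valid <- colMeans(M, na.rm = TRUE)
  na_idx <- which(is.na(M), arr.ind = TRUE)
  if (nrow(na_idx) > 0L) M[na_idx] <- cm_valid[na_idx[, 2L]]
  X <- sweep(M, 2L, colMeans(M))           # zero-center each column
  S <- tcrossprod(X) / ncol(X)             # columns as observations
  eg <- eigen(S, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  k_max <- min(as.integer(k_max), n - 1L)
  comps <- eg$vectors[, seq_len(k_max), drop = FALSE] *
    rep(sqrt(ev[seq_len(k_max)]), each = n)
  n_pos <- if (ev[1] > 0) sum(ev > 1e-12 * ev[1]) else 0L
  dml <- if (n_pos < 2L) as.integer(n_pos)   # exact low rank: no noise floor
         else tryCatch(ml_dimensionality(ev, n_obs = ncol(X), k_max = k_max),
                       error = function(e) NA_integer_)
  structure(list(eigenvalues = ev, components = comps,
                 dimensionality_ml = dml, n_columns_used = ncol(X)),
            class = "thread_decomposition")
}

#' @export
print.thread_decomposition <- function(x, ...) {
  tot <- sum(x$eigenvalues)
  k <- min(5L, length(x$eigenvalues))
  cat(sprintf("<thread_decomposition> ML dimensionality = %s\n",
              x$dimensionality_ml))
  cat("  leading eigenvalue shares:",
      paste(sprintf("%.1f%%", 100 * x$eigenvalues[seq_len(k)] / tot),
            collapse = ", "), "\n")
  invisible(x)
}

#' Maximum-likelihood PCA dimensionality (Laplace evidence)
#'
#' Bayesian model selection over the number of principal components, using
#' the Laplace approximation to the model evidence of probabilistic PCA
#' (Minka's criterion). For each candidate dimensionality `k` the
#' log-evidence is, up to k-independent constants,
#' \deqn{\log p(k) = \log p(U) - \frac{N}{2}\sum_{i\le k}\log\lambda_i
#'   - \frac{N(d-k)}{2}\log\hat\sigma^2 + \frac{m+k}{2}\log 2\pi
#'   - \frac12\log|A_Z| - \frac{k}{2}\log N,}
#' with `d` the ambient dimension, `N` the observation count,
#' `sigma^2 = mean of trailing eigenvalues`, `m = dk - k(k+1)/2`,
#' `log p(U)` the Stiefel-manifold prior mass and `|A_Z|` the Hessian
#' determinant over eigenvalue gaps. Candidate `k = 0` (isotropic noise, no
#' structure) is included, so a flat spectrum is reported as 0 (or 1 when
#' sampling noise tips it).
#'
#' @param eigenvalues sample-covariance eigenvalues, descending; zeros (below
#'   `1e-12` of the leading one) are trimmed.
#' @param n_obs number of observations behind the covariance.
#' @param k_max largest candidate (default: all usable ranks).
#' @return the candidate k with the largest Laplace evidence (integer).
#' @export
ml_dimensionality <- function(eigenvalues, n_obs, k_max = NULL) {
  lam <- sort(as.numeric(eigenvalues), decreasing = TRUE)
  lam <- lam[lam > 1e-12 * lam[1L]]
  d <- length(lam)
  if (d < 2L) stop("fewer than 2 usable eigenvalues")
  N <- as.integer(n_obs)
  ks <- 0:min(if (is.null(k_max)) d - 1L else as.integer(k_max), d - 1L)
  score <- vapply(ks, function(k) laplace_evidence(lam, N, k), numeric(1))
  ks[which.max(score)]
}

# log Laplace evidence for one candidate k (k-independent constants dropped)
laplace_evidence <- function(lam, N, k) {
  d <- length(lam)
  if (k == 0L) return(-N * d / 2 * log(mean(lam)))
  sig2 <- mean(lam[(k + 1L):d])
  if (sig2 <= 0) return(-Inf)
  i <- seq_len(k)
  log_pU <- -k * log(2) +
    sum(lgamma((d - i + 1) / 2) - (d - i + 1) / 2 * log(pi))
  m <- d * k - k * (k + 1) / 2
  lam_hat <- c(lam[seq_len(k)], rep(sig2, d - k))
  logAZ <- 0
  for (ii in seq_len(k)) {
    jj <- (ii + 1L):d
    gaps <- (1 / lam_hat[jj] - 1 / lam_hat[ii]) * (lam[ii] - lam[jj]) * N
    if (any(gaps <= 0)) return(-Inf)       # tied eigenvalues: model excluded
    logAZ <- logAZ + sum(log(gaps))
  }
  log_pU - N / 2 * sum(log(lam[i])) - N * (d - k) / 2 * log(sig2) +
    (m + k) / 2 * log(2 * pi) - logAZ / 2 - k / 2 * log(N)
}

#' Build a TD matrix with a planted number of threads
#'
#' Ground-truth generator for thread-recovery experiments: an exactly
#' anti-symmetric matrix whose column-centered column space is exactly
#' `k`-dimensional — the defining property of `k` lag threads. It is built
#' from `k` orthonormal random spatial maps `q_m` (orthogonal to the constant
#' vector) as `A = sum_m q_m s_m' - 1 b'`, where the score vectors
#' `s_m = g_m 1 + sum_l C[m,l] q_l` use an anti-symmetric coefficient matrix
#' `C` and `b = -sum_m g_m q_m`; this choice is what makes `A' = -A` hold
#' exactly while column centering leaves `span{q_1..q_k}`. The matrix is
#' rescaled so its unique (upper-triangle) lags have standard deviation
#' `delay_sd`, and anti-symmetric Gaussian noise is added at the requested
#' signal-to-noise ratio.
#'
#' @param n voxel count.
#' @param k planted thread count (>= 1, `n >= 3k`).
#' @param delay_sd SD of the unique lag entries (seconds, default 0.5).
#' @param snr ratio of planted lag SD to entrywise noise SD; `Inf` for
#'   noiseless.
#' @param tr,max_lag_frames metadata carried on the result.
#' @param seed RNG seed.
#' @return a `"td_matrix"` with full validity, plus attribute `planted_k`.
#' @export
planted_thread_td <- function(n, k, delay_sd = 0.5, snr = Inf,
                              tr = 2.08, max_lag_frames = 4L, seed = 1L) {
  if (k < 1L || n < 3L * k) stop("need k >= 1 and n >= 3k voxels")
  set.seed(as.integer(seed))
  one <- rep(1, n)
  # k orthonormal spatial maps orthogonal to the constant vector
  Q <- qr.Q(qr(cbind(one / sqrt(n), matrix(stats::rnorm(n * k), n, k))))[, -1L,
                                                                        drop = FALSE]
  g <- 1 + 0.35 * (seq_len(k) - 1L)        # distinct thread strengths
  # draw the anti-symmetric mixing coefficients until the planted thread
  # powers are comparable (weakest >= 0.3 x strongest): threads are planted
  # with commensurate, not vanishing, power
  C <- matrix(0, k, k)
  if (k > 1L) {
    for (try in 1:100) {
      C[upper.tri(C)] <- stats::rnorm(k * (k - 1L) / 2, sd = 0.7 * sqrt(n))
      C[lower.tri(C)] <- 0
      C <- C - t(C)
      pow <- eigen(n * outer(g, g) + tcrossprod(C), symmetric = TRUE,
                   only.values = TRUE)$values
      if (min(pow) >= 0.3 * max(pow)) break
    }
  }
  S <- outer(g, one) + C %*% t(Q)          # k x n score vectors (rows)
  A <- Q %*% S - one %*% t(Q %*% g)        # = sum_m q_m s_m' + 1 b', b = -Qg
  A <- (A - t(A)) / 2                      # exact anti-symmetry (numeric)
  A <- A * (delay_sd / stats::sd(A[upper.tri(A)]))
  if (is.finite(snr)) {
    E <- matrix(stats::rnorm(n * n, sd = delay_sd / snr / sqrt(2)), n, n)
    A <- A + (E - t(E))
  }
  diag(A) <- 0
  structure(list(td = A, amp = matrix(1, n, n),
                 validity = matrix(TRUE, n, n), n = n, tr = tr,
                 max_lag_frames = as.integer(max_lag_frames)),
            class = "td_matrix", planted_k = as.integer(k))
}
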