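#' Lagged cross-covariance of two masked series
#'
#' Empirical version of the lagged cross-covariance `C_{x1x2}(tau) =
#' (1/T) integral x1(t + tau) x2(t) dt` at integer frame offsets
#' `tau_f = -L..L`. For each offset the estimator averages the product of the
#' two series demeaned over exactly the frame pairs where both are valid
#' (`x1` at `t + tau_f`, `x2` at `t`); with `normalize = TRUE` it divides by
#' the two standard deviations over those same frames, yielding a lagged
#' correlation. A peak at a positive offset means `x1` is the delayed (later)
#' series.
#'
#' @param x1,x2 numeric series of equal length.
#' @param mask logical valid-frame mask (default all valid).
#' @param max_lag_frames window half-width `L` in frames (default 4, i.e.
#'   +/- 8.32 s at TR 2.08 s).
#' @param normalize divide by the per-offset standard deviations.
#' @param min_overlap minimum valid frame pairs per offset; lag 0 below this
#'   is a domain error, other offsets are marked unusable (`NA`).
#' @return a `"crosscov_curve"`: list with integer `lags`, `values`,
#'   `n_valid`.
#' @export
lagged_crosscov <- function(x1, x2, mask = NULL, max_lag_frames = 4L,
                            normalize = TRUE, min_overlap = 30L) {
  nf <- length(x1)
  if (length(x2) != nf) stop("series lengths differ")
  if (is.null(mask)) mask <- rep(TRUE, nf)
  L <- as.integer(max_lag_frames)
  lags <- seq(-L, L)
  values <- rep(NA_real_, length(lags))
  n_valid <- integer(length(lags))
  for (i in seq_along(lags)) {
    tau <- lags[i]
    if (tau >= 0) { t2 <- seq_len(nf - tau); t1 <- t2 + tau }
    else          { t1 <- seq_len(nf + tau); t2 <- t1 - tau }
    ok <- mask[t1] & mask[t2]
    n_valid[i] <- sum(ok)
    if (n_valid[i] < 2L) next
    a <- x1[t1[ok]]; b <- x2[t2[ok]]
    a <- a - mean(a); b <- b - mean(b)
    v <- mean(a * b)
    if (normalize) {
      den <- sqrt(mean(a^2) * mean(b^2))
      v <- if (den > 0) v / den else NA_real_
    }
    values[i] <- v
  }
  if (n_valid[L + 1L] < min_overlap)
    stop("insufficient valid overlap at lag 0 (", n_valid[L + 1L],
         " < ", min_overlap, ")")
  values[n_valid < min_overlap] <- NA_real_
  structure(list(lags = lags, values = values, n_valid = n_valid),
            class = "crosscov_curve")
}

#' Parabolic interpolation of a cross-covariance extremum
#'
#' Fits the parabola through the extremum sample and its two neighbours on
#' the signed curve and returns the vertex: lag at a resolution finer than
#' the sampling density, plus interpolated amplitude. With
#' `d = (y_prev - y_next) / (2 (y_prev - 2 y_peak + y_next))`, the lag is
#' `(peak_offset + d) * tr` seconds and the amplitude
#' `y_peak - (y_prev - y_next)^2 / (8 (y_prev - 2 y_peak + y_next))`.
#' `|d| <= 0.5` whenever the middle sample is a (weak) extremum of the three.
#'
#' @param y_prev,y_peak,y_next curve values at `peak_offset - 1`,
#'   `peak_offset`, `peak_offset + 1` frames.
#' @param peak_offset integer frame offset of the extremum sample.
#' @param tr seconds per frame.
#' @return a `"lag_estimate"`: list with `tau` (s), `amplitude`, `valid`,
#'   `degenerate` (TRUE when curvature is exactly zero and the integer-lag
#'   estimate is returned unrefined).
#' @export
parabolic_vertex <- function(y_prev, y_peak, y_next, peak_offset = 0L,
                             tr = 2.08) {
  curv <- y_prev - 2 * y_peak + y_next
  if (curv == 0) {
    return(structure(list(tau = peak_offset * tr, amplitude = y_peak,
                          valid = TRUE, degenerate = TRUE),
                     class = "lag_estimate"))
  }
  d <- (y_prev - y_next) / (2 * curv)
  amp <- y_peak - (y_prev - y_next)^2 / (8 * curv)
  structure(list(tau = (peak_offset + d) * tr, amplitude = amp,
                 valid = TRUE, degenerate = FALSE),
            class = "lag_estimate")
}

#' @export
print.lag_estimate <- function(x, ...) {
  if (x$valid)
    cat(sprintf("<lag_estimate> tau = %.4f s, amplitude = %.4f%s\n",
                x$tau, x$amplitude,
                if (isTRUE(x$degenerate)) " (degenerate curvature)" else ""))
  else cat("<lag_estimate> invalid (extremum at window edge or unusable)\n")
  invisible(x)
}

invalid_lag_estimate <- function() {
  structure(list(tau = NA_real_, amplitude = NA_real_, valid = FALSE,
                 degenerate = FALSE), class = "lag_estimate")
}

#' Sub-sample lag between two series
#'
#' Computes the lagged cross-covariance curve, locates the integer offset
#' where `|C|` is maximal, and refines it by [parabolic_vertex()] on the
#' signed curve (so anticorrelated pairs keep a negative amplitude). An
#' extremum at the window edge has no interpolation neighbour and yields an
#' invalid estimate; downstream consumers exclude such pairs rather than
#' clamp them. Positive `tau` means `x1` lags (is later than) `x2`.
#'
#' @inheritParams lagged_crosscov
#' @param tr seconds per frame.
#' @return a `"lag_estimate"` (see [parabolic_vertex()]).
#' @export
estimate_pair_lag <- function(x1, x2, mask = NULL, tr = 2.08,
                              max_lag_frames = 4L, normalize = TRUE,
                              min_overlap = 30L) {
  cc <- lagged_crosscov(x1, x2, mask, max_lag_frames, normalize, min_overlap)
  usable <- which(!is.na(cc$values))
  if (length(usable) == 0L) return(invalid_lag_estimate())
  pk <- usable[which.max(abs(cc$values[usable]))]
  L <- max_lag_frames
  if (pk == 1L || pk == length(cc$lags)) return(invalid_lag_estimate())
  if (is.na(cc$values[pk - 1L]) || is.na(cc$values[pk + 1L]))
    return(invalid_lag_estimate())
  parabolic_vertex(cc$values[pk - 1L], cc$values[pk], cc$values[pk + 1L],
                   peak_offset = cc$lags[pk], tr = tr)
}

#' Anti-symmetric time-delay matrix of an epoch
#'
#' Estimates the pairwise sub-sample lag for every voxel pair of a
#' preprocessed epoch and assembles the time-delay (TD) matrix: entry
#' `td[i, j]` is the lag of voxel `i` relative to voxel `j` in seconds,
#' positive when `i` is later. The upper triangle is estimated; the lower
#' triangle is its exact negation and the diagonal is exactly zero, so
#' anti-symmetry holds to the bit. A paired amplitude matrix (symmetric)
#' records the interpolated extremum of each pair's cross-covariance, and a
#' validity matrix flags pairs whose extremum fell at the window edge or
#' whose overlap was insufficient.
#'
#' Zero-variance voxels are excluded (validity FALSE on their rows/columns)
#' with a warning naming them.
#'
#' @param epoch a preprocessed [ts_epoch()].
#' @param max_lag_frames half-width of the lag window in frames (default 4).
#' @param normalize use normalized (correlation) curves; the lag estimate is
#'   invariant to this, the amplitude is not.
#' @param min_overlap minimum valid frame pairs per offset (default 30).
#' @return a `"td_matrix"`: list with `td`, `amp`, `validity` (n x n),
#'   `n`, `tr`, `max_lag_frames`.
#' @export
build_td_matrix <- function(epoch, max_lag_frames = 4L, normalize = TRUE,
                            min_overlap = 30L) {
  stopifnot_epoch(epoch)
  X <- epoch$data
  n <- nrow(X)
  nf <- ncol(X)
  L <- as.integer(max_lag_frames)
  mask <- epoch$valid
  sds <- apply(X[, mask, drop = FALSE], 1L, stats::sd)
  dead <- which(!is.finite(sds) | sds == 0)
  if (length(dead) > 0L)
    warning("excluding ", length(dead), " zero-variance voxel(s): ",
            paste(utils::head(dead, 10L), collapse = ", "),
            if (length(dead) > 10L) ", ..." else "")
  # stacked per-offset cross-covariance matrices, offsets -L..L
  offs <- seq(-L, L)
  n_off <- length(offs)
  cc <- array(NA_real_, dim = c(n, n, n_off))
  n_pairs_off <- integer(n_off)
  for (oi in seq_len(n_off)) {
    tau <- offs[oi]
    if (tau < 0) next                       # filled from the transpose below
    t2 <- seq_len(nf - tau); t1 <- t2 + tau
    ok <- which(mask[t1] & mask[t2])
    n_pairs_off[oi] <- length(ok)
    if (length(ok) < max(2L, min_overlap)) next
    A <- X[, t1[ok], drop = FALSE]; A <- A - rowMeans(A)
    B <- X[, t2[ok], drop = FALSE]; B <- B - rowMeans(B)
    M <- tcrossprod(A, B) / length(ok)      # M[i,j] = mean x_i(t+tau) x_j(t)
    if (normalize) {
      da <- sqrt(rowMeans(A^2)); db <- sqrt(rowMeans(B^2))
      M <- M / outer(da, db)
      M[!is.finite(M)] <- NA_real_
    }
    cc[, , oi] <- M
    ni <- n_off + 1L - oi                   # C(-tau) = t(C(tau))
    if (tau > 0) { cc[, , ni] <- t(M); n_pairs_off[ni] <- length(ok) }
  }
  if (n_pairs_off[L + 1L] < min_overlap)
    stop("insufficient valid overlap at lag 0 (", n_pairs_off[L + 1L],
         " < ", min_overlap, ")")
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  # curve matrix: one row per upper-triangle pair
  V <- matrix(NA_real_, nrow = nrow(ut), ncol = n_off)
  for (oi in seq_len(n_off)) V[, oi] <- cc[, , oi][upper.tri(cc[, , oi])]
  absV <- abs(V); absV[is.na(absV)] <- -Inf
  pk <- max.col(absV, ties.method = "first")
  td <- matrix(0, n, n)
  amp <- matrix(NA_real_, n, n)
  validity <- matrix(FALSE, n, n)
  rowi <- ut[, 1L]; colj <- ut[, 2L]
  interior <- pk > 1L & pk < n_off
  idx <- seq_len(nrow(ut))
  yp <- yk <- yn <- rep(NA_real_, nrow(ut))
  yk[interior] <- V[cbind(idx[interior], pk[interior])]
  yp[interior] <- V[cbind(idx[interior], pk[interior] - 1L)]
  yn[interior] <- V[cbind(idx[interior], pk[interior] + 1L)]
  good <- interior & is.finite(yp) & is.finite(yk) & is.finite(yn)
  curv <- yp - 2 * yk + yn
  dfrac <- ifelse(curv == 0, 0, (yp - yn) / (2 * curv))
  tau_s <- (offs[pk] + dfrac) * epoch$tr
  amp_s <- ifelse(curv == 0, yk, yk - (yp - yn)^2 / (8 * curv))
  good <- good & !(rowi %in% dead) & !(colj %in% dead)
  sel <- which(good)
  td[cbind(rowi[sel], colj[sel])] <- tau_s[sel]
  td[cbind(colj[sel], rowi[sel])] <- -tau_s[sel]
  amp[cbind(rowi[sel], colj[sel])] <- amp_s[sel]
  amp[cbind(colj[sel], rowi[sel])] <- amp_s[sel]
  validity[cbind(rowi[sel], colj[sel])] <- TRUE
  validity[cbind(colj[sel], rowi[sel])] <- TRUE
  td[!validity] <- NA_real_
  diag(td) <- 0
  diag(validity) <- TRUE
  diag(amp) <- if (normalize) 1 else NA_real_
  structure(list(td = td, amp = amp, validity = validity, n = n,
                 tr = epoch$tr, max_lag_frames = L),
            class = "td_matrix")
}

#' @export
print.td_matrix <- function(x, ...) {
  off <- x$validity; diag(off) <- FALSE
  cat(sprintf("<td_matrix> %d x %d, %.1f%% pairs valid, lag window +/- %g s\n",
              x$n, x$n, 100 * mean(off[upper.tri(off)]),
              x$max_lag_frames * x$tr))
  invisible(x)
}

#' Zero-lag functional-connectivity matrix
#'
#' Pearson correlation between every voxel pair over the valid frames (the
#' conventional FC matrix), with the Fisher z-transform applied off-diagonal
#' for averaging across subjects.
#'
#' @param epoch a preprocessed [ts_epoch()] with at least 30 valid frames.
#' @return an `"fc_matrix"`: list with `r` (correlations, unit diagonal) and
#'   `z` (Fisher z, zero diagonal). Zero-variance voxels yield `NA`
#'   rows/columns and a warning.
#' @export
zero_lag_fc <- function(epoch) {
  stopifnot_epoch(epoch)
  v <- which(epoch$valid)
  if (length(v) < 30L) stop("zero-lag FC needs >= 30 valid frames")
  X <- t(epoch$data[, v, drop = FALSE])
  sds <- apply(X, 2L, stats::sd)
  dead <- which(!is.finite(sds) | sds == 0)
  if (length(dead) > 0L) {
    warning("excluding ", length(dead), " zero-variance voxel(s) from FC")
    X[, dead] <- NA_real_
  }
  r <- suppressWarnings(stats::cor(X))
  diag(r) <- 1
  z <- atanh(pmin(pmax(r, -1 + 1e-15), 1 - 1e-15))
  diag(z) <- 0
  structure(list(r = r, z = z), class = "fc_matrix")
}
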