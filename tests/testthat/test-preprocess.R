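test_that("linear detrending removes exact lines and is idempotent", {
  tt <- seq_len(80)
  a <- c(2, -1, 0.5); b <- c(0.03, -0.07, 0)
  ep <- ts_epoch(outer(a, rep(1, 80)) + outer(b, tt), tr = 2.08)
  out <- detrend_linear(ep)
  expect_lt(max(abs(out$data)), 1e-10)
  # line + sinusoid: residual equals the sinusoid minus its own best-fit line
  s <- sin(2 * pi * 0.02 * tt * 2.08)
  ep2 <- ts_epoch(rbind(5 + 0.1 * tt + s), tr = 2.08)
  fit <- stats::lm(s ~ tt)
  expect_equal(as.numeric(detrend_linear(ep2)$data),
               unname(stats::residuals(fit)), tolerance = 1e-10)
  # idempotence
  expect_equal(detrend_linear(out)$data, out$data, tolerance = 1e-10)
  # residual mean over valid frames is zero
  set.seed(1)
  ep3 <- ts_epoch(matrix(rnorm(5 * 50), 5, 50), tr = 2.08,
                  valid = c(rep(TRUE, 40), rep(FALSE, 10)))
  out3 <- detrend_linear(ep3)
  expect_lt(max(abs(rowMeans(out3$data[, 1:40]))), 1e-10)
  expect_error(detrend_linear(ts_epoch(matrix(1, 2, 2), tr = 1)), "3 valid")
})

test_that("low-pass filter is zero-phase with the specified band behaviour", {
  tr <- 2.08
  tt <- (seq_len(400) - 1) * tr
  const <- ts_epoch(rbind(rep(3, 400)), tr = tr)
  expect_equal(lowpass(const)$data, const$data, tolerance = 1e-6)
  amp_out <- function(f_hz) {
    x <- sin(2 * pi * f_hz * tt)
    y <- lowpass(ts_epoch(rbind(x), tr = tr))$data[1, ]
    mid <- 100:300                         # avoid filter edge transients
    sd(y[mid]) / sd(x[mid])
  }
  expect_lt(amp_out(0.2), 0.1)             # stopband: 2x cutoff
  expect_lt(abs(amp_out(0.02) - 1), 0.05)  # passband preserved
  # zero phase: cross-covariance of input/output peaks at lag 0
  x <- sin(2 * pi * 0.02 * tt)
  y <- lowpass(ts_epoch(rbind(x), tr = tr))$data[1, ]
  cc <- lagged_crosscov(y[100:300], x[100:300], max_lag_frames = 4)
  expect_equal(cc$lags[which.max(cc$values)], 0)
  expect_error(lowpass(const, cutoff_hz = 0.4), "Nyquist")
})

test_that("nuisance regression projects out the design exactly", {
  set.seed(2)
  nf <- 100
  ep <- ts_epoch(matrix(rnorm(6 * nf), 6, nf), tr = 2.08)
  # a voxel's own series as regressor: residual vanishes
  out <- regress_nuisance(ep, nuisance = cbind(ep$data[3, ]),
                          include_global = FALSE)
  expect_lt(max(abs(out$data[3, ])), 1e-10)
  # residuals orthogonal to all regressors over valid frames
  nuis <- cbind(sin(seq_len(nf)), rnorm(nf))
  out2 <- regress_nuisance(ep, nuisance = nuis, include_global = TRUE)
  g <- colMeans(ep$data)
  X <- cbind(1, nuis, g)
  expect_lt(max(abs(out2$data %*% X)), 1e-8)
  # regressor orthogonal to the data leaves it unchanged (up to demeaning)
  Xo <- rep(c(1, -1), nf / 2)
  dat <- matrix(rep(sin(2 * pi * (1:nf) / nf), 2), 2, nf, byrow = TRUE)
  dat <- dat - rowMeans(dat)
  dat <- dat - (dat %*% Xo) %*% t(Xo) / sum(Xo^2)  # force exact orthogonality
  ep3 <- ts_epoch(dat, tr = 2.08)
  out3 <- regress_nuisance(ep3, nuisance = cbind(ortho = Xo),
                           include_global = FALSE)
  expect_equal(out3$data, ep3$data, tolerance = 1e-10)
})

test_that("projection oracle: global-signal contamination is removed", {
  set.seed(3)
  nf <- 120
  sig <- matrix(rnorm(4 * nf), 4, nf)
  g <- rnorm(nf)
  ep <- ts_epoch(sig + 2 * rep(1, 4) %o% g, tr = 2.08)
  out <- regress_nuisance(ep, nuisance = cbind(g = g), include_global = FALSE)
  # oracle: per-voxel residual of lm on (1, g)
  for (v in 1:4) {
    res <- stats::residuals(stats::lm(ep$data[v, ] ~ g))
    expect_equal(out$data[v, ], unname(res), tolerance = 1e-10)
  }
})

test_that("rank-deficient nuisance designs fail naming the collinear column", {
  set.seed(4)
  nf <- 50
  ep <- ts_epoch(matrix(rnorm(3 * nf), 3, nf), tr = 2.08)
  a <- rnorm(nf)
  expect_error(
    regress_nuisance(ep, nuisance = cbind(one = a, two = 2 * a),
                     include_global = FALSE),
    "collinear.*two")
  expect_error(regress_nuisance(ep, nuisance = cbind(bad = rep(0, nf))),
               "constant-zero")
})

test_that("frame censoring flags spikes and applies the contiguous-run rule", {
  set.seed(5)
  base <- ts_epoch(matrix(rnorm(30 * 60), 30, 60), tr = 2.08)
  # constant data: nothing censored
  const <- ts_epoch(matrix(7, 5, 20), tr = 2.08)
  expect_true(all(censor_frames(const, min_run = 1)$valid))
  # a single large spike flags the spike frame and the following frame
  # (both transitions exceed threshold); oracle: the RMS-change statistic
  sp <- inject_artifacts(base, 25, 10)
  rms <- frame_rms_change(sp)
  expect_true(all(rms[c(25, 26)] > 5))
  cen <- censor_frames(sp, threshold_pct = 0.5, min_run = 1)
  expect_identical(which(!cen$valid), c(25L, 26L))
  # maximal valid runs shorter than min_run are dropped entirely
  ep <- ts_epoch(matrix(rnorm(5 * 150), 5, 150), tr = 2.08)
  ep$valid[10] <- FALSE                    # runs of 9 and 140
  out <- censor_frames(ep, threshold_pct = 1e9, min_run = 10)
  expect_false(any(out$valid[1:9]))
  expect_true(all(out$valid[11:150]))
  # spikes at frames 3..12 of a 20-frame epoch: no surviving run >= 10
  short <- ts_epoch(matrix(rnorm(30 * 20, sd = 0.1), 30, 20), tr = 2.08)
  short <- inject_artifacts(short, 3:12, 10)
  out2 <- censor_frames(short, threshold_pct = 0.5, min_run = 10)
  expect_true(isTRUE(attr(out2, "empty")))
  expect_false(any(out2$valid))
})

test_that("censored fraction grows monotonically as the threshold shrinks", {
  set.seed(6)
  ep <- ts_epoch(matrix(rnorm(40 * 200, sd = 3), 40, 200), tr = 2.08)
  fr <- vapply(c(2, 1, 0.6, 0.45, 0.3),
               function(th) attr(censor_frames(ep, th, min_run = 1),
                                 "censored_fraction"),
               numeric(1))
  expect_true(all(diff(fr) >= 0))
  expect_gt(fr[5], fr[1])
})

test_that("raw positive intensities use the grand mean as censoring base", {
  set.seed(7)
  # raw-scale data around 1000: 0.5% of the mean is 5 units
  ep <- ts_epoch(matrix(1000 + rnorm(30 * 60), 30, 60), tr = 2.08)
  sp <- inject_artifacts(ep, 30, 10)
  cen <- censor_frames(sp, threshold_pct = 0.5, min_run = 1)
  expect_identical(which(!cen$valid), c(30L, 31L))
})

test_that("the full pipeline composes and keeps the measurand unbiased", {
  ep <- delayed_pair_epoch(0.7, noise_sd = 0.1, seed = 12)
  out <- preprocess_epoch(ep, include_global = FALSE)
  est <- estimate_pair_lag(out$data[2, ], out$data[1, ], mask = out$valid,
                           tr = out$tr)
  expect_true(est$valid)
  expect_lt(abs(est$tau - 0.7), 0.25)
})
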