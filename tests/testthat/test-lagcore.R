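test_that("cross-covariance curve behaves on canonical constructions", {
  set.seed(1)
  x <- as.numeric(arima.sim(list(ar = 0.7), 200))
  # autocorrelation: peak at offset 0, normalized value 1
  cc <- lagged_crosscov(x, x)
  expect_equal(cc$lags[which.max(cc$values)], 0)
  expect_equal(max(cc$values), 1, tolerance = 1e-12)
  # exact one-frame shift: |curve| maximal at +1 (x1 delayed)
  x1 <- c(NA, x[-length(x)]); x1[1] <- x[1]
  cc2 <- lagged_crosscov(x1, x, max_lag_frames = 3)
  expect_equal(cc2$lags[which.max(abs(cc2$values))], 1)
  # estimator symmetry: C12(tau) = C21(-tau) at every offset
  set.seed(2)
  y <- as.numeric(arima.sim(list(ar = 0.5), 200))
  c12 <- lagged_crosscov(x, y)
  c21 <- lagged_crosscov(y, x)
  expect_equal(c12$values, rev(c21$values), tolerance = 1e-12)
  expect_error(lagged_crosscov(x[1:20], y[1:20]), "overlap")
})

test_that("vectorized cross-covariance matches the brute-force double loop", {
  # oracle equivalence on randomly masked series
  set.seed(42)
  for (case in 1:20) {
    nf <- sample(60:120, 1)
    x1 <- rnorm(nf); x2 <- rnorm(nf)
    mask <- rep(TRUE, nf)
    mask[sample(nf, sample(0:15, 1))] <- FALSE
    if (sum(mask) < 40) mask[] <- TRUE
    for (norm in c(TRUE, FALSE)) {
      got <- lagged_crosscov(x1, x2, mask, max_lag_frames = 3,
                             normalize = norm, min_overlap = 10)
      want <- brute_crosscov(x1, x2, mask, max_lag_frames = 3,
                             normalize = norm)
      expect_equal(got$values, want$values, tolerance = 1e-10)
    }
  }
})

test_that("parabolic vertex has the closed-form location and amplitude", {
  # symmetric triple: vertex at the centre
  v <- parabolic_vertex(0.5, 0.8, 0.5, peak_offset = 0, tr = 2.08)
  expect_equal(v$tau, 0)
  expect_equal(v$amplitude, 0.8)
  # asymmetric triple: d = (yp - yn) / (2 (yp - 2 yk + yn)) = 1/6 frame
  v2 <- parabolic_vertex(0.4, 0.8, 0.6, peak_offset = 0, tr = 2.08)
  expect_equal(v2$tau, 2.08 / 6, tolerance = 1e-12)
  expect_equal(v2$amplitude, 0.8 + 0.04 / 4.8, tolerance = 1e-12)
  # boundary of the admissible vertex range
  v3 <- parabolic_vertex(1, 1, 0, peak_offset = 0, tr = 1)
  expect_equal(v3$tau, -0.5)
  # nonzero peak offset shifts the vertex by whole frames
  v4 <- parabolic_vertex(0.4, 0.8, 0.6, peak_offset = 2, tr = 2.08)
  expect_equal(v4$tau, 2.08 * (2 + 1 / 6), tolerance = 1e-12)
  # exactly flat curvature: integer-lag estimate with degeneracy flag
  v5 <- parabolic_vertex(0.5, 0.6, 0.7, peak_offset = 1, tr = 2)
  expect_true(v5$degenerate)
  expect_equal(v5$tau, 2)
})

test_that("pair lag estimation recovers planted delays with correct signs", {
  # identical series: tau 0, amplitude 1
  set.seed(3)
  x <- as.numeric(arima.sim(list(ar = 0.8), 150))
  est <- estimate_pair_lag(x, x, tr = 2.08)
  expect_true(est$valid)
  expect_equal(est$tau, 0)
  expect_equal(est$amplitude, 1, tolerance = 1e-10)
  # planted fractional delay
  ep <- delayed_pair_epoch(0.7, seed = 9)
  est2 <- estimate_pair_lag(ep$data[2, ], ep$data[1, ], tr = 2.08)
  expect_lt(abs(est2$tau - 0.7), 0.1 * 2.08)
  # anticorrelated shifted pair: lag near +/- 1 frame with negative amplitude
  y <- c(x[1], x[-length(x)])              # y = x delayed one frame
  est3 <- estimate_pair_lag(-x, y, tr = 2.08)
  expect_true(est3$valid)
  expect_lt(est3$amplitude, 0)
  expect_lt(abs(abs(est3$tau) - 2.08), 0.7)
  # consistency: swapping the operands exactly negates the lag
  est4 <- estimate_pair_lag(ep$data[1, ], ep$data[2, ], tr = 2.08)
  expect_equal(est4$tau, -est2$tau, tolerance = 1e-12)
  # rescaling either series leaves the lag unchanged
  est5 <- estimate_pair_lag(3.7 * ep$data[2, ], ep$data[1, ], tr = 2.08)
  expect_equal(est5$tau, est2$tau, tolerance = 1e-12)
})

test_that("extremum at the window edge yields an invalid estimate", {
  set.seed(4)
  x <- as.numeric(arima.sim(list(ar = 0.9), 200))
  y <- c(rep(x[1], 4), x[1:196])           # 4-frame shift = window edge
  est <- estimate_pair_lag(y, x, tr = 2.08, max_lag_frames = 4)
  expect_false(est$valid)
  expect_true(is.na(est$tau))
})

test_that("TD matrices are exactly anti-symmetric with planted structure recovered", {
  d <- c(0, 0.3, 0.9)
  ep <- delayed_epoch(d, seed = 7)
  td <- build_td_matrix(detrend_linear(ep))
  expect_equal(td$td, -t(td$td))
  expect_true(all(diag(td$td) == 0))
  truth <- outer(d, d, `-`)
  expect_lt(max(abs(td$td - truth)), 0.1 * 2.08)
  expect_true(isSymmetric(td$amp))
  # all-equal voxels: zero TD
  ep2 <- delayed_epoch(rep(0.5, 4), seed = 8)
  td2 <- build_td_matrix(detrend_linear(ep2))
  expect_true(all(abs(td2$td) < 1e-8))
  # entry computed as +x implies exact -x across the diagonal
  set.seed(5)
  ep3 <- ts_epoch(matrix(rnorm(6 * 100), 6, 100), tr = 2.08)
  td3 <- build_td_matrix(ep3)
  expect_identical(td3$td[lower.tri(td3$td)], -t(td3$td)[lower.tri(td3$td)])
})

test_that("TD estimation matches pairwise estimation and handles masks", {
  set.seed(6)
  n <- 5; nf <- 120
  ep <- ts_epoch(matrix(rnorm(n * nf), n, nf), tr = 2.08,
                 valid = replace(rep(TRUE, nf), sample(nf, 10), FALSE))
  td <- build_td_matrix(ep)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    est <- estimate_pair_lag(ep$data[i, ], ep$data[j, ], mask = ep$valid,
                             tr = 2.08)
    if (est$valid) {
      expect_true(td$validity[i, j])
      expect_equal(td$td[i, j], est$tau, tolerance = 1e-10)
      expect_equal(td$amp[i, j], est$amplitude, tolerance = 1e-10)
    } else {
      expect_false(td$validity[i, j])
    }
  }
})

test_that("zero-variance voxels are excluded with a report", {
  set.seed(7)
  dat <- matrix(rnorm(4 * 100), 4, 100)
  dat[2, ] <- 5
  ep <- ts_epoch(dat, tr = 2.08)
  expect_warning(td <- build_td_matrix(ep), "zero-variance")
  expect_false(any(td$validity[2, -2]))
  expect_warning(fc <- zero_lag_fc(ep), "zero-variance")
  expect_true(all(is.na(fc$r[2, -2])))
})

test_that("zero-lag FC is a correlation matrix with Fisher z off-diagonal", {
  set.seed(8)
  nf <- 400
  x <- rnorm(nf)
  ep <- ts_epoch(rbind(x, 2 * x, rnorm(nf)), tr = 2.08)
  fc <- zero_lag_fc(ep)
  expect_equal(fc$r[1, 2], 1)              # scale invariance
  expect_lt(abs(fc$r[1, 3]), 3 / sqrt(nf)) # independent noise bound
  expect_true(isSymmetric(fc$r))
  expect_true(all(diag(fc$r) == 1))
  off <- upper.tri(fc$r)
  expect_equal(fc$z[off][abs(fc$r[off]) < 0.99],
               atanh(fc$r[off][abs(fc$r[off]) < 0.99]), tolerance = 1e-10)
  expect_error(zero_lag_fc(ts_epoch(matrix(rnorm(40), 2, 20), tr = 1)),
               "30 valid")
})

test_that("sub-sample recovery holds across the planted delay grid", {
  deltas <- seq(0.1, 1.9, by = 0.3)
  for (i in seq_along(deltas)) {
    ep <- delayed_pair_epoch(deltas[i], seed = 100 + i)
    est <- estimate_pair_lag(ep$data[2, ], ep$data[1, ], tr = 2.08)
    expect_lt(abs(est$tau - deltas[i]), 0.1 * 2.08)
  }
})
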