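# population_geometry module

geom_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      b <- small_session(seed = 2, n_units = 10, n_trials = 40)
      rates <- vapply(b$spikes[1:10], firing_rate, numeric(round(b$duration * 1000)),
                      duration = b$duration)
      tr <- exclude_trials(detect_reach_onset(b$emg, b$trials))
      tr$onset <- tr$onset_detected
      cache <<- list(b = b, rates = rates, tr = tr)
    }
    cache
  }
})

test_that("trial-average matrix: shape contract and single-trial identity", {
  fx <- geom_fixture()
  X <- trial_average_matrix(fx$rates, fx$tr)
  expect_equal(nrow(X$values), 1600)
  expect_equal(ncol(X$values), 10)
  expect_equal(nrow(X$segments), 8)

  # constant-rate neuron -> constant (centered to zero) column
  rates2 <- fx$rates; rates2[, 3] <- 7
  X2 <- trial_average_matrix(rates2, fx$tr)
  expect_true(all(abs(X2$values[, 3]) < 1e-9))

  # a single qualifying trial reproduces that trial's segments exactly
  tr1 <- fx$tr
  tr1$qualifying <- FALSE
  keep <- vapply(1:4, function(sp) which(fx$tr$qualifying & fx$tr$spout == sp)[1], 1L)
  tr1$qualifying[keep] <- TRUE
  X1 <- trial_average_matrix(fx$rates, tr1)
  i0 <- round(tr1$onset[keep[1]] * 1000)
  seg <- fx$rates[i0 + (-99:100), , drop = FALSE]
  expect_equal(X1$values[1:200, ] + rep(X1$col_means, each = 200), seg,
               tolerance = 1e-10, ignore_attr = TRUE)

  # missing spout errors informatively
  tr_bad <- fx$tr; tr_bad$qualifying[fx$tr$spout == 2] <- FALSE
  expect_error(trial_average_matrix(fx$rates, tr_bad), "spout 2")
})

test_that("CCA alignment: identity, rotation invariance, null vs shifted control", {
  fx <- geom_fixture()
  X <- trial_average_matrix(fx$rates, fx$tr)
  self <- cca_align(X, X, k = 8)
  expect_true(all(self$cors > 1 - 1e-8))

  set.seed(3)
  Q <- qr.Q(qr(matrix(rnorm(100), 10)))
  Xr <- X; Xr$values <- X$values %*% Q
  rot <- cca_align(X, Xr, k = 8)
  expect_true(all(rot$cors > 1 - 1e-6))

  # independent smoothed noise aligns no better than the shifted control
  set.seed(4)
  noise <- gauss_smooth(matrix(rnorm(nrow(fx$rates) * 10), ncol = 10), 20)
  Xn <- trial_average_matrix(noise, fx$tr)
  null_cor <- cca_align(X, Xn, k = 8)$weighted_mean_cor
  ctrl <- shifted_time_control(fx$rates, fx$tr, seed = 5)
  ctrl_cor <- cca_align(X, ctrl$matrix, k = 8)$weighted_mean_cor
  expect_lt(abs(null_cor - ctrl_cor), 0.25)
  expect_lt(null_cor, 0.9 * self$weighted_mean_cor)
})

test_that("PLS-SVD: exact identity c = 0.5, sign symmetry, noise floor", {
  fx <- geom_fixture()
  X <- trial_average_matrix(fx$rates, fx$tr)
  expect_equal(pls_svd(X, X)$c, 0.5, tolerance = 1e-10)

  Xneg <- X; Xneg$values <- -X$values
  expect_equal(pls_svd(X, Xneg)$c, 0.5, tolerance = 1e-10)
  expect_true(all(pls_svd(X, Xneg)$singular_values >= 0))

  set.seed(6)
  noise <- gauss_smooth(matrix(rnorm(nrow(fx$rates) * 10), ncol = 10), 20)
  Xn <- trial_average_matrix(noise, fx$tr)
  expect_lt(pls_svd(X, Xn)$c, 0.1 * pls_svd(X, X)$c)

  # orthogonalized cumulative capture never exceeds the PCA bound
  p <- prcomp(X$values, center = FALSE)
  pca_cum <- cumsum(p$sdev^2)
  res <- pls_svd(X, Xn)
  expect_true(all(res$cum_capture_A <= pca_cum[seq_along(res$cum_capture_A)] + 1e-8))
})

test_that("lag scan peaks at the imposed delay and is symmetric for self-alignment", {
  fx <- geom_fixture()
  lags <- seq(-12, 12, by = 2)
  ls0 <- lag_scan(fx$rates, fx$rates, fx$tr, lags = lags, k = 8)
  expect_equal(ls0$lag[which.max(ls0$pls_c)], 0)
  expect_equal(ls0$lag[which.max(ls0$cca_weighted_cor)], 0)
  # symmetry about the peak
  sym_err <- abs(ls0$pls_c[match(-lags, lags)] - ls0$pls_c)
  expect_lt(max(sym_err, na.rm = TRUE), 0.05)

  # B = A delayed by 10 ms -> peak at +10
  rates_del <- rbind(matrix(fx$rates[1, ], 10, ncol(fx$rates), byrow = TRUE),
                     fx$rates[seq_len(nrow(fx$rates) - 10), ])
  ls1 <- lag_scan(fx$rates, rates_del, fx$tr, lags = lags, k = 8)
  expect_equal(ls1$lag[which.max(ls1$pls_c)], 10)
})

test_that("shifted-time control preserves rates and rejects overlaps", {
  fx <- geom_fixture()
  ctrl <- shifted_time_control(fx$rates, fx$tr, seed = 7)
  expect_s3_class(ctrl$matrix, "activity_matrix")
  q <- fx$tr$qualifying
  expect_true(all(ctrl$trials$onset[q] - fx$tr$onset[q] >= 5))
  expect_true(all(ctrl$trials$onset[q] - fx$tr$onset[q] <= 10.001))

  # a rate series too short for non-overlapping placement errors
  short <- fx$rates[seq_len(round(min(fx$tr$onset[q]) * 1000) + 300), , drop = FALSE]
  expect_error(shifted_time_control(short, fx$tr, seed = 8, max_attempts = 20))
})

test_that("population onset: constructed step, flat series, generator lead", {
  tt <- seq(-200, 299)
  nn <- 8
  set.seed(8)
  step_at <- function(t0) {
    base <- matrix(rnorm(length(tt) * nn, sd = 0.01), length(tt), nn)
    bump <- outer(pmax(tt - t0, 0) / 50, runif(nn, 0.5, 1.5))
    base + bump
  }
  po <- population_onset(step_at(0), tt)
  expect_lte(abs(po$onset - 0), 3)

  flat <- matrix(rnorm(length(tt) * nn, sd = 0.01), length(tt), nn)
  expect_true(is.na(population_onset(flat, tt)$onset))

  po_early <- population_onset(step_at(-50), tt)
  expect_lte(abs((po$onset - po_early$onset) - 50), 10)

  # the higher-threshold variant uses the supplied absolute threshold
  po_thr <- population_onset(step_at(0), tt, threshold = po$threshold * 3)
  expect_gte(po_thr$onset, po$onset)
})

test_that("pre-movement variance fraction: boundary cases and noise symmetry", {
  tt <- seq(-150, 150)
  after <- matrix(0, length(tt), 3)
  after[tt >= 0, ] <- matrix(rnorm(sum(tt >= 0) * 3), ncol = 3)
  expect_equal(premovement_variance_fraction(after, tt), 0, tolerance = 1e-12)

  before <- matrix(0, length(tt), 3)
  before[tt < 0, ] <- matrix(rnorm(sum(tt < 0) * 3), ncol = 3)
  expect_equal(premovement_variance_fraction(before, tt), 1, tolerance = 1e-12)

  set.seed(9)
  fr <- replicate(40, premovement_variance_fraction(
    matrix(rnorm(length(tt) * 3), ncol = 3), tt))
  expect_lt(abs(mean(fr) - 0.5), 0.05)

  expect_true(is.na(premovement_variance_fraction(matrix(1, length(tt), 2), tt)))
})

test_that("per-neuron onsets: step recovery, flat neurons missing, selection", {
  tt <- seq(-200, 299)
  set.seed(10)
  nn <- 20
  avg <- matrix(rnorm(length(tt) * nn, sd = 0.01), length(tt), nn)
  steppers <- 1:4
  for (j in steppers) avg[tt >= 10, j] <- avg[tt >= 10, j] + 1
  mean_rates <- c(rep(30, 4), rep(5, 16))   # steppers are also high-rate
  res <- per_neuron_onset(avg, tt, mean_rates, percentile = 90)
  expect_setequal(res$neuron, steppers[mean_rates[steppers] >
                                         quantile(mean_rates, 0.9)])
  expect_true(all(abs(res$onset - 10) <= 3))

  # flat high-rate neuron reports NA
  avg2 <- avg; avg2[, 1] <- rnorm(length(tt), sd = 0.01)
  res2 <- per_neuron_onset(avg2, tt, mean_rates, percentile = 80)
  expect_true(is.na(res2$onset[res2$neuron == 1]))
})
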