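# preprocess module

test_that("EMG envelope: DC removal, impulse response, band behavior", {
  n <- 4000
  # DC input vanishes
  expect_lt(max(abs(emg_envelope(rep(3, n), 1000))), 1e-6)

  # impulse -> Gaussian bump of SD ~10 ms
  x <- numeric(n); x[2000] <- 1
  env <- emg_envelope(x, 1000)
  com <- sum(seq_len(n) * env) / sum(env)
  sdw <- sqrt(sum((seq_len(n) - com)^2 * env) / sum(env))
  expect_lt(abs(sdw - 10), 2)

  # 400 Hz passes (>= 90% amplitude pre-rectification gain), 50 Hz blocked
  tt <- seq_len(n) / 1000
  hp <- function(f) {
    y <- sin(2 * pi * f * tt)
    yf <- emg_envelope(y, 1000, sigma = 0)  # high-pass + rectify only
    sqrt(mean(yf[500:3500]^2)) / sqrt(mean(abs(y[500:3500])^2))
  }
  expect_gt(hp(400), 0.90)
  expect_lt(hp(50), 0.10)

  expect_error(emg_envelope(rnorm(100), 400), "500")
})

test_that("reach-onset detection: analytic ramp, twitch rejection, flat trace", {
  rate <- 1000
  n <- 40000
  set.seed(2)
  env <- abs(rnorm(n, 0, 0.001))
  tone <- c(10, 20, 30)
  onset_true <- tone + 0.12
  for (o in onset_true) {
    idx <- round(o * rate) + 0:399
    env[idx] <- env[idx] + seq(0, 2, length.out = 400)  # linear ramp
  }
  trials <- data.frame(tone = tone, reward = tone, grasp = onset_true + 0.35,
                       success = TRUE)
  tr <- detect_reach_onset(env, trials, rate)
  # analytic: lower threshold ~ 7 * global SD above ~0 baseline; the ramp
  # reaches it essentially immediately (slope 5 units/s)
  expect_true(all(abs(tr$onset_detected - onset_true) < 0.005))

  # burst shape keeping the baseline fraction of reach epochs below 30%
  # (100 ms reaction, 150 ms ramp to 2, held until beam break), so the
  # 30th-percentile upper threshold lands inside the ramp
  add_burst <- function(env, onset) {
    i0 <- round(onset * rate)
    env[i0 + 0:149] <- env[i0 + 0:149] + seq(0, 2, length.out = 150)
    env[i0 + 150:399] <- env[i0 + 150:399] + 2
    env
  }
  # a sub-upper-threshold twitch before the reach must not capture onset
  env2 <- abs(rnorm(n, 0, 0.001))
  for (o in c(5.1, 8.1, 14.1)) env2 <- add_burst(env2, o)
  idx_tw <- round(14.02 * rate) + 0:60
  env2[idx_tw] <- env2[idx_tw] + 0.05 * sin(seq(0, pi, length.out = 61))
  trials2 <- data.frame(tone = c(5, 8, 14), reward = c(5, 8, 14),
                        grasp = c(5.5, 8.5, 14.5), success = TRUE)
  tr2 <- detect_reach_onset(env2, trials2, rate)
  expect_lt(abs(tr2$onset_detected[3] - 14.1), 0.01)

  # flat trace after tone -> flagged, no onset (enough bursting trials that
  # the flat epoch does not drag the percentile threshold into the noise)
  env3 <- abs(rnorm(n, 0, 0.001))
  tones <- seq(5, 26, by = 3)
  for (o in tones[-8] + 0.05) env3 <- add_burst(env3, o)
  trials3 <- data.frame(tone = tones, reward = tones,
                        grasp = tones + 0.45, success = TRUE)
  tr3 <- detect_reach_onset(env3, trials3, rate)
  expect_true(tr3$no_upper_crossing[8])
  expect_true(is.na(tr3$onset_detected[8]))
  expect_false(any(tr3$no_upper_crossing[-8]))
})

test_that("trial exclusion flags outliers with strict inequalities", {
  base <- data.frame(success = TRUE, no_upper_crossing = FALSE,
                     duration = 0.3, reaction = 0.1, ramp_time = 0.02,
                     baseline_sd = 0.01)
  set.seed(11)
  tr <- base[rep(1, 30), ]
  tr$duration <- rnorm(30, 0.3, 0.01)
  out <- exclude_trials(tr)
  expect_true(all(out$qualifying))

  # one trial inflated far beyond the rest: flagged even though the
  # threshold statistics include the outlier itself
  tr2 <- tr
  tr2$duration[5] <- 0.3 + 0.1
  out2 <- exclude_trials(tr2)
  expect_true(out2$flag_duration[5])
  expect_equal(sum(out2$flag_duration), 1)

  # identical trials sit exactly at mean + 3 SD = mean; strict inequality
  # retains them all
  tr4 <- base[rep(1, 5), ]
  out4 <- exclude_trials(tr4)
  expect_false(any(out4$flag_baseline | out4$flag_duration | out4$flag_ramp))

  # reaction below -50 ms flagged
  tr5 <- base[rep(1, 4), ]
  tr5$reaction[2] <- -0.06
  expect_true(exclude_trials(tr5)$flag_reaction[2])
})

test_that("unit curation: violation statistic against brute force, classes", {
  # Poisson train: statistic near the window-width ratio 0.7/40
  tp <- poisson_train(25, 240, seed = 3)
  expect_lt(abs(isi_violation_statistic(tp) - 0.0175), 0.006)

  # absolute 2 ms refractory period -> statistic 0
  tr <- tp[c(TRUE, diff(tp) > 2e-3)]
  expect_equal(isi_violation_statistic(tr), 0)

  # merged mixture: brute-force oracle agreement and inflation
  t1 <- poisson_train(20, 60, seed = 4); t1 <- t1[c(TRUE, diff(t1) > 2e-3)]
  t2 <- poisson_train(20, 60, seed = 5); t2 <- t2[c(TRUE, diff(t2) > 2e-3)]
  merged <- sort(c(t1, t2))
  stat_merged <- isi_violation_statistic(merged)
  oracle <- brute_acg_mass(merged, 0.3e-3, 1.0e-3) /
    brute_acg_mass(merged, 10e-3, 50e-3)
  expect_equal(stat_merged, oracle)
  expect_gt(stat_merged, isi_violation_statistic(t1))
  expect_gt(stat_merged, isi_violation_statistic(t2))

  # curation table: depth cut, width class, exclusion threshold
  spk <- list(tp, tr, merged, poisson_train(5, 240, seed = 6))
  rec <- curate_units(spk, depths = c(100, 300, 500, 1700),
                      widths = c(0.5, 0.3, 0.45, 0.6), duration = 240)
  expect_equal(rec$width_class, c("wide", "narrow", "wide", "wide"))
  expect_true(rec$excluded_depth[4])
  expect_false(any(rec$excluded_stat[1:2]))
})

test_that("channel exclusion flags broadband-power outliers, ignores DC", {
  set.seed(7)
  n <- 4000; nc <- 24
  v <- matrix(rnorm(n * nc), n, nc)
  keep <- exclude_channels(v, rate = 30000)
  expect_gte(sum(keep), nc - 1)     # at most one false positive tolerated

  v2 <- v; v2[, 10] <- v2[, 10] * 10
  keep2 <- exclude_channels(v2, rate = 30000)
  expect_false(keep2[10])

  v3 <- sweep(v2, 2, seq_len(nc) * 5, "+")   # channel-wise DC offsets
  expect_equal(as.logical(exclude_channels(v3, rate = 30000)),
               as.logical(keep2))
})

test_that("firing rate: kernel normalization and long-run mean", {
  fr1 <- firing_rate(1.0, 3)
  expect_lt(abs(sum(fr1) * 1e-3 - 1), 1e-6)

  reg <- seq(0.025, 119.975, by = 0.05)    # regular 20 Hz train
  fr <- firing_rate(reg, 120)
  expect_lt(abs(mean(fr[2000:118000]) - 20), 0.1)

  expect_true(all(firing_rate(numeric(0), 2) == 0))
})

test_that("muscle correlation: perfect correlation flagged, union null rate", {
  T <- 40000
  set.seed(8)
  emg <- matrix(abs(rnorm(T * 2)), T, 2)
  emg <- gauss_smooth(emg, 20)
  rates <- cbind(3 * emg[, 1], gauss_smooth(abs(rnorm(T)), 20))
  res <- muscle_correlation(rates, emg, n_perm = 120, min_shift = 10, seed = 2)
  expect_true(res$flagged[1])

  # independent neurons: per-muscle rejection near 5%, union near
  # 1 - 0.95^m; checked loosely via binomial spread over 60 neurons
  set.seed(9)
  nn <- 60
  rates2 <- gauss_smooth(matrix(abs(rnorm(T * nn)), T, nn), 20)
  res2 <- muscle_correlation(rates2, emg, n_perm = 120, min_shift = 10, seed = 3)
  frac <- mean(res2$flagged)
  expected <- 1 - 0.95^2
  expect_lt(abs(frac - expected), 3 * sqrt(expected * (1 - expected) / nn) + 0.02)
})
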