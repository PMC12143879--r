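# synthetic_data module

test_that("latent generation: zero-delay symmetry, determinism, delay placement", {
  cfg0 <- synth_config(n_trials = 2, latent_delays = 0,
                       n_across_latents = 1, n_within_latents = 0)
  lat <- generate_latents(cfg0)
  expect_equal(lat$trials[[1]]$A, lat$trials[[1]]$B)

  expect_identical(generate_latents(cfg0, seed = 9),
                   generate_latents(cfg0, seed = 9))

  # A leads by 40 ms: cross-correlation of the two copies peaks at +40
  cfgd <- synth_config(n_trials = 1, latent_delays = -40,
                       n_across_latents = 1, n_within_latents = 0, seed = 3)
  ld <- generate_latents(cfgd)
  a <- ld$trials[[1]]$A[, 1]; b <- ld$trials[[1]]$B[, 1]
  n <- length(a)
  cc <- vapply(-60:60, function(k) {
    if (k >= 0) cor(a[seq_len(n - k)], b[k + seq_len(n - k)])
    else cor(a[(1 - k):n], b[seq_len(n + k)])
  }, 0)
  expect_equal((-60:60)[which.max(cc)], 40)

  # delay exceeding the trial window is rejected
  expect_error(synth_config(trial_window = c(-50, 100), latent_delays = 160,
                            n_across_latents = 1),
               "exceeds the trial window")
})

test_that("latent autocorrelation width matches the configured kernel", {
  # oracle: squared-exponential kernel autocorrelation halves at
  # tau = l * sqrt(2 log 2)
  l <- 100
  cfg <- synth_config(n_trials = 60, latent_timescales = l,
                      n_across_latents = 1, n_within_latents = 0, seed = 8)
  lat <- generate_latents(cfg)
  taus <- seq(0, 250, by = 10)
  # non-centered autocovariance (latents are zero-mean, unit-variance by
  # construction; within-trial centering would bias long lags down)
  ac <- vapply(taus, function(tau) {
    mean(vapply(lat$trials, function(tr) {
      x <- tr$A[, 1]; n <- length(x)
      mean(x[seq_len(n - tau)] * x[tau + seq_len(n - tau)]) / mean(x^2)
    }, 0))
  }, 0)
  half_emp <- taus[which(ac < 0.5)[1]]
  half_true <- l * sqrt(2 * log(2))
  expect_lt(abs(half_emp - half_true) / half_true, 0.2)
})

test_that("spike generation: Poisson counts, PSTH recovery, coupling delay", {
  # all loadings zero, constant baseline: total count within 3 SD of Poisson
  cfg <- synth_config(n_units_per_region = 1, n_trials = 2, loading_scale = 0,
                      baseline_rates = c(shape = 1e6, rate = 1e5),  # ~10 sp/s
                      inter_trial_s = 45, seed = 4)
  lat <- generate_latents(cfg)
  spk <- generate_spikes(lat, cfg)
  expected <- 10 * spk$duration
  expect_lt(abs(length(spk$A[[1]]) - expected), 3 * sqrt(expected))

  # PSTH over many trials tracks the generating intensity
  cfg2 <- synth_config(n_units_per_region = 2, n_trials = 500,
                       loading_scale = 20, inter_trial_s = 1.2,
                       trial_window = c(-100, 200), seed = 5)
  lat2 <- generate_latents(cfg2)
  spk2 <- generate_spikes(lat2, cfg2)
  tw <- cfg2$trial_window
  psth <- rep(0, diff(tw))
  lam <- rep(0, diff(tw))
  for (k in seq_len(cfg2$n_trials)) {
    t0 <- spk2$trial_onsets[k] + tw[1] / 1000
    psth <- psth + bin_spikes(spk2$A[[1]], t0, t0 + diff(tw) / 1000, 1e-3)
    lam <- lam + unit_intensity(spk2, lat2, cfg2, k, "A")[, 1]
  }
  psth <- psth / cfg2$n_trials * 1000      # spikes/s
  lam <- lam / cfg2$n_trials
  psth_s <- gauss_smooth(psth, 10)
  lam_s <- gauss_smooth(lam, 10)
  rms <- sqrt(mean((psth_s - lam_s)^2))
  expect_lt(rms / mean(lam_s), 0.10)

  # strong coupling at 7 ms: cross-correlogram peak at 7 +/- 1 ms
  cfg3 <- synth_config(n_units_per_region = 4, n_trials = 80, loading_scale = 0,
                       pair_coupling = list(list(source = 1, target = 2,
                                                 delay = 7, gain = 150)),
                       seed = 7)
  b <- generate_session(cfg3)
  sA <- b$spikes[[1]]; sB <- b$spikes[[4 + 2]]
  d <- outer(sB, sA, "-"); d <- d[abs(d) < 0.03] * 1000
  h <- hist(d, breaks = seq(-30.5, 30.5, 1), plot = FALSE)
  expect_lte(abs(h$mids[which.max(h$counts)] - 7), 1)
})

test_that("EMG generation: onset crossing, zero-amplitude null, determinism", {
  cfg <- synth_config(n_trials = 6, seed = 10)
  trials <- data.frame(onset = seq(2, by = 3, length.out = 6))
  emg <- generate_emg(trials, cfg, duration = 25)
  env <- rowSums(emg$envelope)
  base <- mean(env[1:1500]); s <- sd(env[1:1500])
  for (on in trials$onset) {
    i0 <- round(on * 1000)
    cross <- i0 - 200 + which(env[(i0 - 200):(i0 + 200)] > base + 7 * s)[1] - 1
    expect_lte(abs(cross - i0), 15)
  }

  cfg0 <- synth_config(seed = 10,
                       emg_params = list(noise_sd = 0.02, burst_amp = 0,
                                         rise_ms = 30, n_muscles = 2))
  e0 <- generate_emg(trials, cfg0, duration = 25)
  expect_lt(max(e0$envelope), 0.02 * 6)   # pure (smoothed) baseline noise

  expect_identical(generate_emg(trials, cfg, 25, seed = 3)$envelope,
                   generate_emg(trials, cfg, 25, seed = 3)$envelope)
  expect_error(generate_emg(data.frame(onset = c(1, 1.2)), cfg, 10),
               "overlapping")
})

test_that("inactivation dataset: null case and downstream latency", {
  cfg0 <- synth_config(n_units_per_region = 10, n_trials = 40,
                       loading_scale = 0,
                       inactivation = list(target = "A", direct = 0,
                                           downstream = 0, latency = 10),
                       seed = 3)
  b0 <- generate_inactivation_dataset(cfg0)
  # control and light PSTHs statistically indistinguishable per unit
  psth_of <- function(b, unit, which_trials) {
    rowMeans(vapply(which_trials, function(k) {
      t0 <- b$trials$onset[k]
      bin_spikes(b$spikes[[unit]], t0 - 0.2, t0 + 0.8, 20e-3)
    }, numeric(50)))
  }
  pc <- psth_of(b0, 1, which(!b0$trials$light))
  pl <- psth_of(b0, 1, which(b0$trials$light))
  expect_gt(t.test(pc - pl)$p.value, 0.01)

  # direct 0.9 / downstream 0.3 at 10 ms latency: onset of the downstream
  # PSTH drop lags the direct drop by 10 +/- 5 ms
  cfg1 <- synth_config(n_units_per_region = 40, n_trials = 300,
                       loading_scale = 0,
                       baseline_rates = c(shape = 1e6, rate = 5e4), # 20 sp/s
                       inactivation = list(target = "A", direct = 0.9,
                                           downstream = 0.3, latency = 10),
                       inter_trial_s = 1.2, trial_window = c(-100, 200),
                       seed = 6)
  b1 <- generate_inactivation_dataset(cfg1)
  drop_onset <- function(units, frac) {
    light <- which(b1$trials$light)
    psth <- rep(0, 300)
    for (u in units) for (k in light) {
      t0 <- b1$trials$onset[k]
      psth <- psth + bin_spikes(b1$spikes[[u]], t0 - 0.1, t0 + 0.2, 1e-3)
    }
    psth <- gauss_smooth(psth * 1000 / length(light), 3)
    basev <- mean(psth[1:90])
    which(psth < basev * (1 - frac / 2))[1] - 100   # ms after light onset
  }
  dA <- drop_onset(1:40, 0.9)
  dB <- drop_onset(41:80, 0.3)
  expect_lte(abs((dB - dA) - 10), 5)
})

test_that("network targets: lead placement and suppression floor", {
  # cross-correlate the trace derivatives (bump-shaped, so the peak lag is
  # well defined despite the finite window truncating the sigmoids)
  tg0 <- generate_network_targets(synth_config(), lead_ms = 0)
  cc <- ccf(diff(tg0$A[, "control"]), diff(tg0$B[, "control"]), lag.max = 20,
            plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  tg <- generate_network_targets(synth_config(), lead_ms = 50)
  cc <- ccf(diff(tg$A[, "control"]), diff(tg$B[, "control"]), lag.max = 80,
            plot = FALSE)
  expect_lte(abs(cc$lag[which.max(cc$acf)] - (-50)), 2)

  tgs <- generate_network_targets(synth_config(), suppression = 1.0)
  light_epoch <- tgs$time >= 0 & tgs$time < 50
  expect_true(all(abs(tgs$A[light_epoch, "inact_A"] - 0.05) < 1e-9))
})

test_that("session bundle round-trips through the text serialization", {
  b <- small_session(seed = 14, n_units = 3, n_trials = 4)
  dir <- tempfile("bundle")
  write_session_bundle(b, dir)
  b2 <- read_session_bundle(dir)
  expect_equal(b2$duration, b$duration, tolerance = 1e-6)
  expect_equal(length(b2$spikes), length(b$spikes))
  expect_equal(b2$spikes[[2]], b$spikes[[2]], tolerance = 1e-6)
  expect_equal(b2$truth$delays, b$truth$delays)
  expect_equal(dim(b2$emg), dim(b$emg))
  unlink(dir, recursive = TRUE)
})
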