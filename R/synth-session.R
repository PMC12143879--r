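#' Generate two-region spike trains from latents
#'
#' Per-unit intensity within the trial window is
#' `max(0, baseline + loadings . latents)` (rectified-linear link); spikes are
#' drawn as an inhomogeneous Poisson process on a 1 ms grid, and baseline-rate
#' Poisson spiking fills the inter-trial intervals. Optional pairwise coupling
#' adds, for every source spike, an alpha-function hazard increment on the
#' target whose peak sits at the configured delay (2 ms rise), implemented as
#' a superposed Poisson process so the increment is exactly additive.
#'
#' On light trials (when `light` is given and `config$inactivation` is set),
#' the targeted region's intensity is multiplied by `(1 - direct)` from light
#' onset (= reach onset) and the other region's by `(1 - downstream)` from
#' light onset plus the configured latency.
#'
#' @param latents result of [generate_latents()].
#' @param config a [synth_config()].
#' @param seed integer seed.
#' @param trial_onsets reach-onset times in seconds; defaults to a regular
#'   grid with `config$inter_trial_s` spacing starting at 5 s.
#' @param light logical per trial; NULL means all control.
#' @return list with per-region lists of spike-time vectors (`A`, `B`,
#'   seconds), `baselines`, `loadings` (per region), `trial_onsets`,
#'   `duration`, and the coupling realization.
#' @export
generate_spikes <- function(latents, config, seed = config$seed,
                            trial_onsets = NULL, light = NULL) {
  n <- config$n_units_per_region
  p <- latents$n_across + latents$n_within
  ntr <- length(latents$trials)
  tw <- config$trial_window
  if (is.null(trial_onsets))
    trial_onsets <- 5 + (seq_len(ntr) - 1) * config$inter_trial_s
  stopifnot(length(trial_onsets) == ntr)
  # quiet tail long enough for shifted-time controls (5-10 s forward shifts)
  duration <- max(trial_onsets) + tw[2] / 1000 + 12
  if (is.null(light)) light <- rep(FALSE, ntr)
  inact <- config$inactivation

  with_seed(seed, {
    baselines <- list(A = rgamma(n, config$baseline_rates[1], config$baseline_rates[2]),
                      B = rgamma(n, config$baseline_rates[1], config$baseline_rates[2]))
    strengths <- config$latent_strengths %||% rep(1, p)
    draw_loadings <- function()
      sweep(matrix(rnorm(n * p, sd = config$loading_scale / sqrt(p)), n, p),
            2, strengths, "*")
    loadings <- list(A = draw_loadings(), B = draw_loadings())

    region_mult <- function(region, rel_ms) {
      # suppression multiplier time course for one trial (rel_ms grid)
      m <- rep(1, length(rel_ms))
      if (is.null(inact)) return(m)
      if (region == inact$target) {
        m[rel_ms >= 0] <- 1 - inact$direct
      } else {
        m[rel_ms >= inact$latency] <- 1 - inact$downstream
      }
      m
    }

    spikes <- list(A = vector("list", n), B = vector("list", n))
    for (region in c("A", "B")) {
      C <- loadings[[region]]
      b <- baselines[[region]]
      for (u in seq_len(n)) {
        # inter-trial baseline spiking over the whole session
        nb <- rpois(1, b[u] * duration)
        st <- sort(runif(nb, 0, duration))
        # remove baseline spikes inside trial windows (windows get their own)
        in_win <- rep(FALSE, length(st))
        for (k in seq_len(ntr)) {
          w0 <- trial_onsets[k] + tw[1] / 1000
          w1 <- trial_onsets[k] + tw[2] / 1000
          in_win <- in_win | (st >= w0 & st < w1)
        }
        st <- st[!in_win]
        spikes[[region]][[u]] <- st
      }
      for (k in seq_len(ntr)) {
        L <- latents$trials[[k]][[region]]
        lam <- pmax(sweep(L %*% t(C), 2, b, "+"), 0)   # time x units
        if (light[k]) lam <- lam * region_mult(region, latents$time)
        cnt <- matrix(rpois(length(lam), lam * 1e-3), nrow(lam), ncol(lam))
        w0 <- trial_onsets[k] + tw[1] / 1000
        for (u in seq_len(n)) {
          idx <- which(cnt[, u] > 0)
          if (!length(idx)) next
          reps <- cnt[idx, u]
          times <- w0 + (rep(idx - 1, reps) + runif(sum(reps))) * 1e-3
          spikes[[region]][[u]] <- c(spikes[[region]][[u]], times)
        }
      }
      spikes[[region]] <- lapply(spikes[[region]], sort)
    }

    # pairwise coupling: superposed Poisson with alpha-shaped offset density,
    # peak of the hazard at the configured delay (2 ms rise)
    tau_r <- 2
    for (cp in config$pair_coupling) {
      src_region <- if (isTRUE(cp$reverse)) "B" else "A"
      tgt_region <- if (isTRUE(cp$reverse)) "A" else "B"
      ss <- spikes[[src_region]][[cp$source]]
      mass <- cp$gain * tau_r * exp(1) / 1000   # expected extra spikes/source spike
      nx <- rpois(length(ss), mass)
      tot <- sum(nx)
      if (tot > 0) {
        parents <- rep(ss, nx)
        off <- (cp$delay + tau_r * (rgamma(tot, shape = 2, rate = 1) - 1)) / 1000
        extra <- parents + pmax(off, 2.5e-4)
        if (!is.null(inact) && any(light)) {
          # thin induced spikes by the target-region multiplier on light trials
          keep <- rep(TRUE, length(extra))
          for (k in which(light)) {
            rel <- (extra - trial_onsets[k]) * 1000
            inwin <- rel >= tw[1] & rel < tw[2]
            if (!any(inwin)) next
            mlt <- region_mult(tgt_region, rel[inwin])
            keep[inwin] <- runif(sum(inwin)) < mlt
          }
          extra <- extra[keep]
        }
        extra <- extra[extra >= 0 & extra < duration]
        spikes[[tgt_region]][[cp$target]] <-
          sort(c(spikes[[tgt_region]][[cp$target]], extra))
      }
    }

    list(A = spikes$A, B = spikes$B, baselines = baselines,
         loadings = loadings, trial_onsets = trial_onsets,
         duration = duration, light = light, coupling = config$pair_coupling)
  })
}

#' Per-unit generating intensity for one trial
#'
#' Reconstructs the (pre-rectification clipped) intensity used by
#' [generate_spikes()] for a given trial, in spikes/s on the latent 1 ms grid.
#' Does not include pairwise-coupling hazard increments.
#'
#' @param spk result of [generate_spikes()].
#' @param latents the matching [generate_latents()] result.
#' @param config the matching config.
#' @param trial trial index.
#' @param region "A" or "B".
#' @return matrix time x units, spikes/s.
#' @export
unit_intensity <- function(spk, latents, config, trial, region = "A") {
  C <- spk$loadings[[region]]
  b <- spk$baselines[[region]]
  lam <- pmax(sweep(latents$trials[[trial]][[region]] %*% t(C), 2, b, "+"), 0)
  if (spk$light[trial] && !is.null(config$inactivation)) {
    inact <- config$inactivation
    m <- rep(1, length(latents$time))
    if (region == inact$target) m[latents$time >= 0] <- 1 - inact$direct
    else m[latents$time >= inact$latency] <- 1 - inact$downstream
    lam <- lam * m
  }
  lam
}

#' Generate reach-locked EMG envelopes with known onsets
#'
#' Each muscle's 1 kHz envelope is positive-clipped Gaussian baseline noise
#' plus a smooth burst starting at each true reach onset: quadratic rise to
#' the burst amplitude over `rise_ms`, a 200 ms hold, and a 200 ms linear
#' decay. Muscles get independent noise and slightly jittered amplitudes.
#'
#' @param trials data.frame with `onset` (s) per trial.
#' @param config a [synth_config()].
#' @param duration session duration, s.
#' @param seed integer seed.
#' @return list(envelope = T x n_muscles matrix at 1 kHz, onsets = s).
#' @export
generate_emg <- function(trials, config, duration, seed = config$seed) {
  pars <- config$emg_params
  onsets <- trials$onset
  if (any(diff(sort(onsets)) < 0.5)) stop("overlapping trials in EMG generation")
  nt <- round(duration * 1000)
  hold <- 200; decay <- 200
  shape_len <- pars$rise_ms + hold + decay
  u <- seq_len(shape_len)
  shape <- c((u[u <= pars$rise_ms] / pars$rise_ms)^2,
             rep(1, hold),
             seq(1, 0, length.out = decay))
  with_seed(seed, {
    env <- matrix(abs(rnorm(nt * pars$n_muscles, 0, pars$noise_sd)),
                  nt, pars$n_muscles)
    # emulate the conditioned envelope: same 10 ms Gaussian smoothing the
    # preprocessing applies to measured EMG
    env <- gauss_smooth(env, 10, dt = 1)
    for (m in seq_len(pars$n_muscles)) {
      amp <- pars$burst_amp * runif(length(onsets), 0.8, 1.2)
      for (k in seq_along(onsets)) {
        i0 <- round(onsets[k] * 1000)
        idx <- i0 + seq_len(shape_len)
        ok <- idx >= 1 & idx <= nt
        env[idx[ok], m] <- env[idx[ok], m] + amp[k] * shape[ok]
      }
    }
    list(envelope = env, onsets = onsets, rate = 1000)
  })
}

#' Generate a complete synthetic session with ground truth
#'
#' Assembles trial structure (regularly spaced non-overlapping reaches with
#' >= `inter_trial_s` spacing, spouts cycling 1..4), latents, two-region
#' spikes, EMG, and the ground-truth record into a `session_bundle`.
#'
#' @param config a [synth_config()].
#' @param seed integer seed.
#' @return object of class `session_bundle`: list with `units` (data.frame:
#'   unit_id, region, depth, width, peak_sign), `spikes` (list of spike-time
#'   vectors, seconds), `emg` (1 kHz envelope matrix), `trials` (data.frame
#'   with times in seconds: cue, tone, reward, onset, grasp, spout, success,
#'   light), `duration` (s), and `truth`.
#' @export
generate_session <- function(config, seed = config$seed) {
  ntr <- config$n_trials
  onsets <- 5 + (seq_len(ntr) - 1) * config$inter_trial_s
  light <- rep(FALSE, ntr)
  if (!is.null(config$inactivation)) {
    nl <- round(ntr * config$light_fraction)
    light[seq(2, by = 2, length.out = nl)] <- TRUE   # interleaved
  }
  trials <- data.frame(trial = seq_len(ntr),
                       cue = onsets - 1.5,
                       tone = onsets - 0.10,
                       reward = onsets - 0.10,
                       onset = onsets,
                       grasp = onsets + 0.30,
                       spout = rep_len(1:4, ntr),
                       success = TRUE,
                       light = light)
  lat <- generate_latents(config, seed = child_seed(seed, "latents"))
  spk <- generate_spikes(lat, config, seed = child_seed(seed, "spikes"),
                         trial_onsets = onsets, light = light)
  emg <- generate_emg(trials, config, spk$duration,
                      seed = child_seed(seed, "emg"))
  n <- config$n_units_per_region
  units <- data.frame(unit_id = seq_len(2 * n),
                      region = rep(c("A", "B"), each = n),
                      depth = with_seed(child_seed(seed, "depth"),
                                        round(runif(2 * n, 0, 1400))),
                      width = with_seed(child_seed(seed, "width"),
                                        round(runif(2 * n, 0.45, 0.7), 3)),
                      peak_sign = -1L)
  bundle <- list(units = units,
                 spikes = c(spk$A, spk$B),
                 emg = emg$envelope,
                 emg_rate = 1000,
                 trials = trials,
                 duration = spk$duration,
                 truth = list(latents = lat,
                              delays = config$latent_delays,
                              coupling = config$pair_coupling,
                              onsets = onsets,
                              baselines = spk$baselines,
                              loadings = spk$loadings,
                              inactivation = config$inactivation),
                 config = config)
  class(bundle) <- "session_bundle"
  bundle
}

#' Generate a session with interleaved control and inactivation trials
#'
#' Convenience wrapper: requires `config$inactivation` to be set and returns
#' a [generate_session()] bundle whose trial table interleaves control and
#' light trials.
#'
#' @inheritParams generate_session
#' @export
generate_inactivation_dataset <- function(config, seed = config$seed) {
  if (is.null(config$inactivation))
    stop("config$inactivation must be set")
  generate_session(config, seed)
}

#' @export
print.session_bundle <- function(x, ...) {
  cat("<session_bundle>", nrow(x$units), "units,", nrow(x$trials), "trials,",
      round(x$duration, 1), "s,", ncol(x$emg), "muscles\n")
  invisible(x)
}

#' Smooth target traces for the three network-fitting conditions
#'
#' Builds muscle and per-region summed-activity targets on a 1 ms grid from
#' 50 ms before to 100 ms after reach onset, for the control,
#' inactivate-A and inactivate-B conditions. The region-A trace leads the
#' region-B trace by `lead_ms`; on inactivation trials the inactivated
#' region's trace is pulled toward its floor by `suppression` during the
#' light epoch (0 to 50 ms plus a 10 ms ramp-off).
#'
#' @param config a [synth_config()] (reserved for future trace shaping).
#' @param lead_ms region-A lead, ms (positive = A earlier).
#' @param suppression direct suppression fraction toward the floor for the
#'   inactivated region's own trace (that trace is excluded from the
#'   training loss; it documents the experimentally silenced region).
#' @param downstream c(on_B, on_A): fractional suppression of the recorded
#'   (non-inactivated) region's trace under inactivation of the other
#'   region. The default asymmetry (region-A inactivation hits region B
#'   harder than vice versa) is the phenomenon the trained networks must
#'   reproduce.
#' @return list(time, muscle, A, B) where `muscle`, `A`, `B` are matrices
#'   time x condition with columns control, inact_A, inact_B.
#' @export
generate_network_targets <- function(config, lead_ms = 30, suppression = 0.9,
                                     downstream = c(on_B = 0.6, on_A = 0.2)) {
  tt <- seq(-50, 100 - 1)
  rise <- function(center, width = 15) 1 / (1 + exp(-(tt - center) / width))
  base_B <- rise(30)
  base_A <- rise(30 - lead_ms)
  muscle <- rise(40, 10)
  light_env <- numeric(length(tt))
  light_env[tt >= 0 & tt < 50] <- 1
  idx <- tt >= 50 & tt < 60
  light_env[idx] <- 1 - (tt[idx] - 50) / 10
  floorv <- 0.05
  direct <- function(x) x * (1 - suppression * light_env) +
    floorv * suppression * light_env
  down <- function(x, frac) x * (1 - frac * light_env)
  list(time = tt,
       muscle = cbind(control = muscle,
                      inact_A = muscle * (1 - 0.4 * light_env),
                      inact_B = muscle * (1 - 0.6 * light_env)),
       A = cbind(control = base_A, inact_A = direct(base_A),
                 inact_B = down(base_A, downstream[["on_A"]])),
       B = cbind(control = base_B, inact_A = down(base_B, downstream[["on_B"]]),
                 inact_B = direct(base_B)))
}
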