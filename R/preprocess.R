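#' EMG conditioning: downsample, high-pass, rectify, smooth
#'
#' Conditions raw multi-muscle EMG into a 1 kHz envelope: decimation to
#' 1 kHz (with an anti-alias low-pass when the input rate exceeds 1 kHz),
#' zero-phase 4th-order Butterworth high-pass at 250 Hz (realized as the
#' squared Butterworth magnitude response applied in the frequency domain,
#' the zero-phase forward-backward equivalent), full-wave rectification, and
#' convolution with a Gaussian of 10 ms standard deviation.
#'
#' @param raw numeric vector or T x muscles matrix.
#' @param rate input sampling rate, Hz (>= 500).
#' @param highpass high-pass edge, Hz.
#' @param sigma smoothing SD, ms.
#' @return matrix (or vector) at 1 kHz.
#' @export
emg_envelope <- function(raw, rate, highpass = 250, sigma = 10) {
  if (rate < 500) stop("sampling rate below 500 Hz cannot represent the 250 Hz edge")
  x <- if (is.matrix(raw)) raw else matrix(raw, ncol = 1)

  butter_mag2 <- function(n, fs, fc, order = 4, type = "high") {
    f <- seq(0, n - 1) / n * fs
    f <- pmin(f, fs - f)                     # two-sided frequency axis
    if (type == "high") {
      g <- 1 / (1 + ifelse(f == 0, Inf, (fc / f)^(2 * order)))
    } else {
      g <- 1 / (1 + (f / fc)^(2 * order))
    }
    g
  }
  apply_fft_gain <- function(x, gain) {
    Re(mvfft(mvfft(x) * gain, inverse = TRUE)) / nrow(x)
  }

  if (rate > 1000) {
    dec <- rate / 1000
    if (abs(dec - round(dec)) > 1e-9)
      stop("input rate must be an integer multiple of 1 kHz")
    g <- butter_mag2(nrow(x), rate, 450, order = 8, type = "low")
    x <- apply_fft_gain(x, g)
    x <- x[seq(1, nrow(x), by = round(dec)), , drop = FALSE]
  }
  g <- butter_mag2(nrow(x), 1000, highpass, order = 4, type = "high")
  x <- apply_fft_gain(x, g)
  x <- abs(x)
  out <- gauss_smooth(x, sigma, dt = 1)
  if (!is.matrix(raw)) drop(out) else out
}

# 1 s window of minimal variance of the summed envelope -> quiescent epoch
find_quiescent_epoch <- function(env_sum, rate = 1000, window_s = 1, stride = 100) {
  w <- round(window_s * rate)
  if (length(env_sum) < w) stop("series shorter than the quiescent window")
  starts <- seq(1, length(env_sum) - w + 1, by = stride)
  cs <- cumsum(c(0, env_sum)); cs2 <- cumsum(c(0, env_sum^2))
  m <- (cs[starts + w] - cs[starts]) / w
  v <- (cs2[starts + w] - cs2[starts]) / w - m^2
  i <- starts[which.min(v)]
  c(start = i, end = i + w - 1)
}

#' Detect reach onset from summed EMG by the double-threshold rule
#'
#' The per-trial baseline is the mean summed envelope in \[-500, -100\] ms
#' before the tone; the lower threshold is baseline plus 7 times a global
#' quiescent-period SD (quiescent epoch found automatically as the 1 s window
#' of minimal envelope variance); the upper threshold is the 30th percentile
#' of envelope values over tone-to-beam-break epochs of successful trials.
#' Onset is the lower-threshold upcrossing immediately preceding the first
#' upper-threshold crossing after the tone; trials whose envelope never
#' crosses the upper threshold are flagged for exclusion.
#'
#' @param envelope summed envelope vector at 1 kHz (or matrix, summed).
#' @param trials data.frame with seconds-valued `tone`, `grasp` (beam break
#'   at the correct port), `reward`, and logical `success`.
#' @param rate envelope rate, Hz.
#' @param k_sd lower-threshold multiple of the global SD.
#' @param upper_quantile upper-threshold quantile of within-reach values.
#' @return `trials` with added columns `onset_detected` (s), `baseline_mean`,
#'   `baseline_sd`, `ramp_time` (s), `duration` (s), `reaction` (s), and
#'   logical flag `no_upper_crossing`.
#' @export
detect_reach_onset <- function(envelope, trials, rate = 1000, k_sd = 7,
                               upper_quantile = 0.30) {
  env <- if (is.matrix(envelope)) rowSums(envelope) else envelope
  q <- find_quiescent_epoch(env, rate)
  global_sd <- sd(env[q["start"]:q["end"]])
  succ <- which(trials$success)
  if (!length(succ)) stop("no successful trials")
  reach_vals <- unlist(lapply(succ, function(i) {
    i0 <- round(trials$tone[i] * rate); i1 <- round(trials$grasp[i] * rate)
    env[max(1, i0):min(length(env), i1)]
  }))
  upper <- quantile(reach_vals, upper_quantile, names = FALSE)

  trials$onset_detected <- NA_real_
  trials$baseline_mean <- NA_real_
  trials$baseline_sd <- NA_real_
  trials$ramp_time <- NA_real_
  trials$no_upper_crossing <- FALSE
  for (i in succ) {
    i_tone <- round(trials$tone[i] * rate)
    b0 <- max(1, i_tone - round(0.5 * rate)); b1 <- i_tone - round(0.1 * rate)
    trials$baseline_mean[i] <- mean(env[b0:b1])
    trials$baseline_sd[i] <- sd(env[b0:b1])
    lower <- trials$baseline_mean[i] + k_sd * global_sd
    i_end <- min(length(env), round(trials$grasp[i] * rate) + round(0.5 * rate))
    seg <- env[i_tone:i_end]
    up <- which(seg >= upper)
    if (!length(up)) {
      trials$no_upper_crossing[i] <- TRUE
      next
    }
    i_up <- up[1]
    below <- which(seg[seq_len(i_up)] < lower)
    if (length(below)) {
      i_on <- below[length(below)] + 1L   # upcrossing through the lower threshold
    } else {
      warning("no lower-threshold crossing before upper crossing; using upper crossing")
      i_on <- i_up
    }
    trials$onset_detected[i] <- (i_tone + i_on - 2L) / rate
    trials$ramp_time[i] <- (i_up - i_on + 1L) / rate
  }
  trials$duration <- trials$grasp - trials$onset_detected
  trials$reaction <- trials$onset_detected - trials$reward
  attr(trials, "global_sd") <- global_sd
  attr(trials, "upper_threshold") <- upper
  trials
}

#' Flag outlying successful trials
#'
#' Applies the exclusion rules on successful trials: duration greater than
#' the successful-trial mean plus 3 SD, reaction time less than -50 ms,
#' ramp time greater than mean plus 3 SD, and per-trial baseline SD greater
#' than mean plus 3 SD. All inequalities are strict, so ties are retained.
#'
#' @param trials data.frame as returned by [detect_reach_onset()] (columns
#'   `duration`, `reaction`, `ramp_time`, `baseline_sd`, `success`,
#'   `no_upper_crossing`).
#' @return `trials` with logical columns `flag_duration`, `flag_reaction`,
#'   `flag_ramp`, `flag_baseline` and `qualifying`.
#' @export
exclude_trials <- function(trials) {
  succ <- trials$success & !trials$no_upper_crossing
  if (sum(succ, na.rm = TRUE) < 2)
    stop("need at least 2 successful trials with detected onsets")
  gt3sd <- function(x) {
    m <- mean(x[succ], na.rm = TRUE); s <- sd(x[succ], na.rm = TRUE)
    ifelse(is.na(x), FALSE, x > m + 3 * s)
  }
  trials$flag_duration <- gt3sd(trials$duration) & succ
  trials$flag_reaction <- succ & !is.na(trials$reaction) & trials$reaction < -0.050
  trials$flag_ramp <- gt3sd(trials$ramp_time) & succ
  trials$flag_baseline <- gt3sd(trials$baseline_sd) & succ
  trials$qualifying <- succ & !(trials$flag_duration | trials$flag_reaction |
                                  trials$flag_ramp | trials$flag_baseline)
  trials
}

# ordered-pair autocorrelogram mass with lags in [lo, hi) seconds
acg_mass <- function(spikes, lo, hi) {
  if (length(spikes) < 2) return(0L)
  t <- sort(spikes)
  sum(findInterval(t + hi - 1e-12, t) - findInterval(t + lo - 1e-12, t))
}

#' Refractory-violation statistic of a spike train
#'
#' Ratio of autocorrelogram mass at lags in \[0.3, 1.0) ms to mass in
#' \[10, 50) ms, normalizing violation counts by overall rate. A flat
#' (Poisson) autocorrelogram gives the window-width ratio 0.7/40 = 0.0175.
#'
#' @param spikes spike times, seconds.
#' @return the statistic (NA when the normalizing mass is zero).
#' @export
isi_violation_statistic <- function(spikes) {
  denom <- acg_mass(spikes, 10e-3, 50e-3)
  if (denom == 0) return(NA_real_)
  acg_mass(spikes, 0.3e-3, 1.0e-3) / denom
}

#' Post-sorting unit curation
#'
#' Computes the refractory-violation statistic, assigns waveform width class
#' and peak sign, references depths to the most superficial unit, and marks
#' units for retention: statistic <= 0.18 (strictly greater excluded, and
#' undefined statistics excluded with a warning), depth within 1500 um of the
#' most superficial unit.
#'
#' @param spikes list of spike-time vectors (seconds).
#' @param depths numeric depths, um (larger = deeper).
#' @param widths trough-to-peak widths, ms; computed from `templates` when
#'   NULL.
#' @param templates optional list of waveform template vectors (used for the
#'   peak sign, and for widths when `widths` is NULL, assuming 30 kHz).
#' @param duration session duration, s (for mean rates).
#' @param stat_threshold exclusion threshold on the violation statistic.
#' @param width_threshold wide/narrow boundary, ms.
#' @param depth_range retention span below the most superficial unit, um.
#' @return data.frame of unit records with `retained` and its reasons.
#' @export
curate_units <- function(spikes, depths, widths = NULL, templates = NULL,
                         duration = NULL, stat_threshold = 0.18,
                         width_threshold = 0.417, depth_range = 1500) {
  n <- length(spikes)
  stopifnot(length(depths) == n)
  stat <- vapply(spikes, isi_violation_statistic, 0)
  if (any(is.na(stat)))
    warning("undefined violation statistic for ", sum(is.na(stat)),
            " unit(s); excluded")
  if (is.null(widths)) {
    stopifnot(!is.null(templates))
    widths <- vapply(templates, function(w) {
      tr <- which.min(w)
      pk <- tr + which.max(w[tr:length(w)]) - 1
      (pk - tr) / 30   # 30 kHz template -> ms
    }, 0)
  }
  peak_sign <- if (!is.null(templates)) {
    vapply(templates, function(w) if (abs(max(w)) >= abs(min(w))) 1L else -1L,
           1L)
  } else rep(-1L, n)
  depth_rel <- depths - min(depths)
  rate <- if (!is.null(duration)) vapply(spikes, length, 1L) / duration else NA_real_
  rec <- data.frame(unit_id = seq_len(n),
                    isi_stat = stat,
                    depth_rel = depth_rel,
                    width = widths,
                    width_class = ifelse(widths > width_threshold, "wide", "narrow"),
                    peak_sign = peak_sign,
                    mean_rate = rate)
  rec$excluded_stat <- is.na(stat) | stat > stat_threshold
  rec$excluded_depth <- depth_rel > depth_range
  rec$retained <- !rec$excluded_stat & !rec$excluded_depth
  rec
}

#' Flag pathological recording channels from high-frequency power
#'
#' Sums the FFT magnitude over 300-1000 Hz per channel, subtracts a running
#' median over a 10-channel window, and flags channels whose residual lies
#' beyond 3 SD of the residuals.
#'
#' @param volts T x channels matrix of raw voltages.
#' @param rate sampling rate, Hz.
#' @param window running-median window (channels).
#' @param k_sd flagging threshold in residual SDs.
#' @return logical keep-mask (TRUE = keep), with the per-channel weights as
#'   attribute `weights`.
#' @export
exclude_channels <- function(volts, rate = 30000, window = 10, k_sd = 3) {
  stopifnot(ncol(volts) >= 20)
  n <- nrow(volts)
  f <- seq(0, n - 1) / n * rate
  sel <- f >= 300 & f <= 1000
  w <- apply(volts, 2, function(v) sum(Mod(fft(v))[sel]))
  half <- floor(window / 2)
  med <- vapply(seq_along(w), function(i) {
    idx <- max(1, i - half):min(length(w), i + half)
    median(w[idx])
  }, 0)
  resid <- w - med
  keep <- abs(resid) <= k_sd * sd(resid)
  attr(keep, "weights") <- w
  keep
}

#' Gaussian-kernel firing rate on a 1 ms grid
#'
#' rate(t) = sum over spikes of a normal density with 10 ms SD, in spikes/s,
#' so that the integral over the session equals the spike count.
#'
#' @param spikes spike times, seconds.
#' @param duration session duration, seconds.
#' @param sigma kernel SD, ms.
#' @return numeric vector of length `round(duration * 1000)`.
#' @export
firing_rate <- function(spikes, duration, sigma = 10) {
  counts <- bin_spikes(spikes, 0, duration, 1e-3)
  gauss_smooth(counts * 1000, sigma, dt = 1)
}

#' Identify neurons significantly correlated with muscle activity
#'
#' Pearson correlation of each neuron's 1 ms firing-rate series with each
#' muscle envelope, tested against a null of circular shifts of at least
#' `min_shift` seconds (and at most T - `min_shift`); two-tailed empirical
#' p per muscle; a neuron is flagged when any muscle p < `alpha`.
#'
#' @param rates T x neurons matrix (1 kHz).
#' @param emg T x muscles matrix (1 kHz).
#' @param n_perm permutations.
#' @param min_shift s.
#' @param alpha per-muscle significance level.
#' @param seed integer.
#' @return list(p = neurons x muscles matrix, r = observed correlations,
#'   flagged = logical vector).
#' @export
muscle_correlation <- function(rates, emg, n_perm = 300, min_shift = 10,
                               alpha = 0.05, seed = 1) {
  T <- nrow(rates)
  stopifnot(nrow(emg) == T)
  if (T <= 2 * min_shift * 1000) stop("series too short for the shift range")
  with_seed(seed, {
    shifts <- sample(seq.int(min_shift * 1000, T - min_shift * 1000), n_perm,
                     replace = TRUE)
    nn <- ncol(rates); nm <- ncol(emg)
    p <- matrix(NA_real_, nn, nm)
    r <- matrix(NA_real_, nn, nm)
    for (i in seq_len(nn)) {
      for (j in seq_len(nm)) {
        cc <- circ_cor_all(rates[, i], emg[, j])
        if (all(is.na(cc))) next
        r[i, j] <- cc[1]
        null <- cc[shifts + 1]
        p[i, j] <- perm_pvalue(r[i, j], null, "two.sided")$p
      }
    }
    list(p = p, r = r, flagged = apply(p, 1, function(z) any(z < alpha, na.rm = TRUE)))
  })
}
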