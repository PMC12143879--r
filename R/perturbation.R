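# Perturbation-effect quantification: EMG and firing-rate effects of
# optogenetic-style inactivation, with chance-level correction, and the
# modified stimulus-associated spike latency test.

# mean pairwise Euclidean distance of pre-onset segments, per trial
pre_onset_distance <- function(segs) {
  # segs: trials x time (x muscles collapsed by the caller)
  d <- as.matrix(dist(segs))
  rowSums(d) / (nrow(segs) - 1)
}

#' EMG outlier-trial mask
#'
#' Pools control and light trials, computes each trial's mean pairwise
#' Euclidean distance between pre-onset EMG segments summed across muscles,
#' and excludes trials above mean + 1 SD.
#'
#' @param segments array trials x time x muscles of envelope segments over
#'   the pre-onset window (default \[-50, 0\] ms).
#' @param k_sd threshold multiple of the SD (1 for EMG).
#' @return logical keep-mask over trials.
#' @export
emg_outlier_mask <- function(segments, k_sd = 1) {
  stopifnot(length(dim(segments)) == 3, dim(segments)[1] >= 3)
  d <- 0
  for (m in seq_len(dim(segments)[3]))
    d <- d + pre_onset_distance(segments[, , m])
  d <= mean(d) + k_sd * sd(d)
}

#' Neural outlier-trial mask
#'
#' Same structure as [emg_outlier_mask()] but over per-trial across-neuron
#' firing-rate segments in the 20 ms pre-onset window, with the threshold at
#' mean + SD/4.
#'
#' @param segments array trials x time x neurons of rate segments.
#' @return logical keep-mask over trials.
#' @export
neural_outlier_mask <- function(segments) {
  stopifnot(length(dim(segments)) == 3, dim(segments)[1] >= 3)
  d <- 0
  for (j in seq_len(dim(segments)[3]))
    d <- d + pre_onset_distance(segments[, , j])
  d <- d / dim(segments)[3]
  d <= mean(d) + sd(d) / 4
}

#' Chance-corrected absolute EMG inactivation effect
#'
#' |control mean - light mean| per time point and muscle, minus the mean of
#' `n_resample` split-half control |differences| (the chance level), minus
#' the mean over the 20 ms preceding light/trial onset. Values below zero
#' are expected and retained.
#'
#' @param control,light arrays trials x time (single muscle) or
#'   trials x time x muscles.
#' @param onset_index sample index of light/trial onset within the time axis.
#' @param n_resample split-half resamples for the chance level.
#' @param seed integer.
#' @param rate samples per second of the time axis.
#' @return list(effect = time x muscles matrix of corrected |differences|,
#'   chance = the subtracted chance series, sem).
#' @export
inactivation_emg_effect <- function(control, light, onset_index,
                                    n_resample = 1000, seed = 1, rate = 1000) {
  as3 <- function(a) if (length(dim(a)) == 2) array(a, c(dim(a), 1)) else a
  control <- as3(control); light <- as3(light)
  nc <- dim(control)[1]
  stopifnot(nc >= 4, dim(light)[2] == dim(control)[2])
  nm <- dim(control)[3]
  tlen <- dim(control)[2]
  base_idx <- max(1, onset_index - round(0.020 * rate)):(onset_index - 1)
  with_seed(seed, {
    use <- seq_len(nc)
    if (nc %% 2 == 1) use <- sample(nc, nc - 1)   # drop one at random
    half <- length(use) / 2
    eff <- matrix(0, tlen, nm)
    chance <- matrix(0, tlen, nm)
    for (m in seq_len(nm)) {
      dc <- abs(colMeans(control[, , m, drop = FALSE][, , 1]) -
                  colMeans(light[, , m, drop = FALSE][, , 1]))
      ch <- numeric(tlen)
      for (r in seq_len(n_resample)) {
        h <- sample(use, half)
        ch <- ch + abs(colMeans(control[h, , m]) -
                         colMeans(control[setdiff(use, h), , m]))
      }
      ch <- ch / n_resample
      e <- dc - ch
      e <- e - mean(e[base_idx])
      eff[, m] <- e
      chance[, m] <- ch
    }
    list(effect = eff, chance = chance)
  })
}

#' Per-neuron z-scored inactivation effect
#'
#' Difference of control and light trial-average firing rates, z-scored by
#' each neuron's session-wide rate mean and SD, averaged over a window
#' (default 45-55 ms after light/trial onset), restricted to the `top_n`
#' highest session-mean-rate neurons.
#'
#' @param control,light arrays trials x time x neurons of 1 kHz rate
#'   segments aligned on light/trial onset at `onset_index`.
#' @param session_stats data.frame with per-neuron `mean` and `sd` of the
#'   session-wide rate series.
#' @param onset_index sample index of onset.
#' @param window ms window relative to onset, default c(45, 55).
#' @param top_n number of highest-rate neurons retained.
#' @return data.frame(neuron, delta_z) for retained neurons.
#' @export
per_neuron_effect <- function(control, light, session_stats, onset_index,
                              window = c(45, 55), top_n = 50) {
  nn <- dim(control)[3]
  stopifnot(nrow(session_stats) == nn)
  ok <- session_stats$sd > 0
  ord <- order(session_stats$mean, decreasing = TRUE)
  keep <- head(ord[ok[ord]], top_n)
  idx <- (onset_index + window[1]):(onset_index + window[2])
  delta <- vapply(keep, function(j) {
    dc <- mean(colMeans(control[, idx, j, drop = FALSE][, , 1])) -
      mean(colMeans(light[, idx, j, drop = FALSE][, , 1]))
    dc / session_stats$sd[j]
  }, 0)
  data.frame(neuron = keep, delta_z = delta)
}

#' Average absolute firing-rate difference time series and window summaries
#'
#' Per neuron |control mean - light mean|(t), averaged across neurons
#' (optionally subsampled to a matched count), baseline-corrected by the
#' 20 ms pre-onset mean, with summaries over 10-25, 10-50 and 10-100 ms
#' after onset.
#'
#' @param control,light arrays trials x time x neurons (1 kHz).
#' @param onset_index onset sample index.
#' @param n_match number of neurons to subsample (NULL = all), seeded.
#' @param seed integer.
#' @return list(time_series, summaries = named numeric over the three
#'   windows).
#' @export
abs_effect_timeseries <- function(control, light, onset_index,
                                  n_match = NULL, seed = 1) {
  nn <- dim(control)[3]
  keep <- seq_len(nn)
  if (!is.null(n_match) && n_match < nn)
    keep <- with_seed(seed, sample(nn, n_match))
  d <- vapply(keep, function(j)
    abs(colMeans(control[, , j, drop = FALSE][, , 1]) -
          colMeans(light[, , j, drop = FALSE][, , 1])),
    numeric(dim(control)[2]))
  ts <- rowMeans(d)
  base_idx <- max(1, onset_index - 20):(onset_index - 1)
  ts <- ts - mean(ts[base_idx])
  win <- function(a, b) mean(ts[(onset_index + a):(onset_index + b)])
  list(time_series = ts,
       summaries = c(ms25 = win(10, 25), ms50 = win(10, 50),
                     ms100 = win(10, 100)))
}

# first-spike-latency histogram over 5 ms epochs at 1 ms resolution;
# categories: latency bin 1..win_ms, plus "no spike"
latency_hist <- function(spikes, epoch_starts, win_ms = 5) {
  win_ms <- as.integer(win_ms)
  lat <- vapply(epoch_starts, function(t0) {
    s <- spikes[spikes >= t0 & spikes < t0 + win_ms * 1e-3]
    if (!length(s)) return(win_ms + 1L)
    min(as.integer(floor((s[1] - t0) * 1000)) + 1L, win_ms + 1L)
  }, 1L)
  tabulate(lat, nbins = win_ms + 1L)
}

#' Modified stimulus-associated spike latency test
#'
#' Compares the first-spike-latency distribution in the 5 ms epoch after
#' each light onset with distributions from randomly placed baseline epochs
#' (>= 500 ms away from any light onset, 10x as many as light events).
#' The observed statistic is the Jensen-Shannon divergence between the
#' light-epoch histogram and the histogram of one randomly chosen baseline
#' group; the null is built from divergences between disjoint baseline
#' groups, which makes the test-epoch draw exchangeable with the null under
#' no light effect and the p-value uniform.
#'
#' @param spikes spike times, s.
#' @param light_onsets light-onset times, s (>= 50).
#' @param duration session duration, s.
#' @param win_ms epoch/test window, ms.
#' @param n_null null divergence draws.
#' @param seed integer.
#' @return list(p, statistic) or NULL when the neuron never spikes in any
#'   epoch.
#' @export
salt_modified <- function(spikes, light_onsets, duration, win_ms = 5,
                          n_null = 1000, seed = 1) {
  ne <- length(light_onsets)
  win_ms <- as.integer(win_ms)
  if (ne < 50) stop("need at least 50 light events")
  with_seed(seed, {
    n_base <- ne * 10
    cand <- runif(n_base * 3, 0.5, duration - 0.5)
    far <- vapply(cand, function(t0)
      all(abs(t0 - light_onsets) >= 0.5), TRUE)
    base_starts <- head(cand[far], n_base)
    h_test <- latency_hist(spikes, light_onsets, win_ms)
    if (sum(h_test) == 0) return(NULL)
    base_lat <- vapply(base_starts, function(t0) {
      s <- spikes[spikes >= t0 & spikes < t0 + win_ms * 1e-3]
      if (!length(s)) win_ms + 1L else as.integer(floor((s[1] - t0) * 1000)) + 1L
    }, 1L)
    if (all(base_lat == win_ms + 1L) && all(h_test[seq_len(win_ms)] == 0))
      return(NULL)
    group_hist <- function(idx) tabulate(base_lat[idx], nbins = win_ms + 1L)
    # observed: light hist vs one random baseline group of matched size
    obs_grp <- sample(n_base, ne)
    obs <- js_divergence(h_test + 0.5, group_hist(obs_grp) + 0.5)
    null <- numeric(n_null)
    for (r in seq_len(n_null)) {
      pick <- sample(n_base, 2 * ne)
      null[r] <- js_divergence(group_hist(pick[seq_len(ne)]) + 0.5,
                               group_hist(pick[ne + seq_len(ne)]) + 0.5)
    }
    list(p = perm_pvalue(obs, null)$p, statistic = obs)
  })
}
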