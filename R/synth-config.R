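#' Configuration for the synthetic dual-region session generator
#'
#' Describes the stated world the generator emulates: two simultaneously
#' recorded populations ("A", the premotor-like region, and "B", the primary
#' motor-like region) driven by shared smooth latents carrying known temporal
#' delays plus region-private latents, with Poisson spiking, reach-locked EMG
#' bursts, and optional interleaved control/inactivation trials.
#'
#' Delay sign convention matches the delayed-latent model: negative delay
#' means region A leads (region B expresses the same latent later).
#'
#' @param n_units_per_region units per region.
#' @param n_trials number of trials in the session.
#' @param trial_window c(start, end) in ms around reach onset.
#' @param n_across_latents,n_within_latents latent counts.
#' @param latent_delays ms per across-latent (length `n_across_latents`;
#'   negative = region A leads). Bounded to +/-200 ms.
#' @param latent_timescales ms smoothness timescale of the squared-exponential
#'   latent kernel; recycled across all latents.
#' @param loading_scale dimensionless scale of latent loadings, in units of
#'   spikes/s of rate modulation per unit-variance latent.
#' @param latent_strengths relative amplitude of each latent's loadings
#'   (recycled over across then within latents). The default geometric decay
#'   emulates the decaying eigen-spectrum of real population activity and
#'   makes shared components identifiable.
#' @param baseline_rates c(shape, rate) of the gamma distribution of per-unit
#'   baseline rates in spikes/s.
#' @param pair_coupling list of lists with fields `source` (unit index in A),
#'   `target` (unit index in B), `delay` ms, `gain` (spikes/s peak hazard
#'   increment per source spike). Negative `source`/`target` conventions are
#'   not used; coupling is A -> B unless `reverse = TRUE` in the entry.
#' @param inactivation list(target = "A"|"B", direct = fraction,
#'   downstream = fraction, latency = ms) or NULL.
#' @param light_fraction fraction of trials that are light (inactivation)
#'   trials when `inactivation` is set.
#' @param emg_params list(noise_sd, burst_amp, rise_ms, n_muscles).
#' @param inter_trial_s minimum spacing between consecutive reach onsets, s.
#' @param seed integer seed.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_units_per_region = 30,
                         n_trials = 60,
                         trial_window = c(-200, 800),
                         n_across_latents = 4,
                         n_within_latents = 4,
                         latent_delays = c(-40, -15, 10, 25),
                         latent_timescales = 100,
                         loading_scale = 6,
                         latent_strengths = NULL,
                         baseline_rates = c(shape = 4, rate = 0.4),
                         pair_coupling = list(),
                         inactivation = NULL,
                         light_fraction = 0.5,
                         emg_params = list(noise_sd = 0.02, burst_amp = 1,
                                           rise_ms = 30, n_muscles = 4),
                         inter_trial_s = 2.5,
                         seed = 1L) {
  latent_delays <- rep_len(latent_delays, n_across_latents)
  latent_timescales <- rep_len(latent_timescales, n_across_latents + n_within_latents)
  if (is.null(latent_strengths))
    latent_strengths <- c(0.8^(seq_len(n_across_latents) - 1),
                          0.8^(seq_len(n_within_latents) - 1))
  latent_strengths <- rep_len(latent_strengths, n_across_latents + n_within_latents)
  stopifnot(all(abs(latent_delays) <= 200),
            all(latent_timescales > 0),
            n_units_per_region >= 1, n_trials >= 1,
            trial_window[1] < trial_window[2],
            all(baseline_rates > 0),
            inter_trial_s * 1000 >= diff(trial_window))
  if (max(abs(latent_delays)) >= diff(trial_window))
    stop("latent delay exceeds the trial window")
  if (!is.null(inactivation)) {
    stopifnot(inactivation$target %in% c("A", "B"),
              inactivation$direct >= 0, inactivation$direct <= 1,
              inactivation$downstream >= 0, inactivation$downstream <= 1)
    inactivation$latency <- inactivation$latency %||% 10
  }
  cfg <- list(n_units_per_region = as.integer(n_units_per_region),
              n_trials = as.integer(n_trials),
              trial_window = trial_window,
              n_across_latents = as.integer(n_across_latents),
              n_within_latents = as.integer(n_within_latents),
              latent_delays = latent_delays,
              latent_timescales = latent_timescales,
              loading_scale = loading_scale,
              latent_strengths = latent_strengths,
              baseline_rates = baseline_rates,
              pair_coupling = pair_coupling,
              inactivation = inactivation,
              light_fraction = light_fraction,
              emg_params = emg_params,
              inter_trial_s = inter_trial_s,
              seed = as.integer(seed))
  class(cfg) <- "synth_config"
  cfg
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config>", x$n_units_per_region, "units/region,",
      x$n_trials, "trials,", x$n_across_latents, "across +",
      x$n_within_latents, "within latents\n")
  cat("  delays (ms):", paste(signif(x$latent_delays, 3), collapse = ", "),
      " [negative = region A leads]\n")
  if (!is.null(x$inactivation))
    cat("  inactivation of", x$inactivation$target, ": direct",
        x$inactivation$direct, ", downstream", x$inactivation$downstream,
        "at", x$inactivation$latency, "ms latency\n")
  invisible(x)
}
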