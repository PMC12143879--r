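#' Generate smooth shared and private latents for each trial
#'
#' Across-latents are a single squared-exponential Gaussian-process draw per
#' trial, expressed in both regions with a configurable temporal offset:
#' region B's copy at time t equals the master process at t + D, so that
#' negative delays D mean region A leads. Within-latents are drawn
#' independently per region. All latents have unit marginal variance and are
#' sampled on a 1 ms grid spanning the trial window.
#'
#' @param config a [synth_config()].
#' @param seed integer; overrides `config$seed` when given.
#' @return list with elements `time` (ms grid), and `trials`: per trial a
#'   list with matrices `A`, `B` of size length(time) x
#'   (n_across + n_within); across-latents occupy the leading columns.
#' @export
generate_latents <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "synth_config"))
  if (max(abs(config$latent_delays)) >= diff(config$trial_window))
    stop("latent delay exceeds the trial window")
  tw <- config$trial_window
  tt <- seq(tw[1], tw[2] - 1)           # 1 ms grid, length = window in ms
  pad <- ceiling(max(c(abs(config$latent_delays), 0))) + 1
  text <- seq(tw[1] - pad, tw[2] - 1 + pad)
  na <- config$n_across_latents
  nw <- config$n_within_latents

  chol_cache <- new.env(parent = emptyenv())
  chol_for <- function(ts, n) {
    key <- paste0(format(ts), "_", n)
    if (!is.null(chol_cache[[key]])) return(chol_cache[[key]])
    d <- outer(seq_len(n), seq_len(n), "-")
    K <- exp(-0.5 * (d / ts)^2) + diag(1e-8, n)
    L <- chol(K)
    chol_cache[[key]] <- L
    L
  }

  interp_shift <- function(z, shift_ms) {
    # value of master process at t + shift, linear interpolation on text grid
    pos <- seq_along(text) + shift_ms
    lo <- floor(pos); hi <- lo + 1; w <- pos - lo
    lo <- pmin(pmax(lo, 1L), length(z)); hi <- pmin(pmax(hi, 1L), length(z))
    (1 - w) * z[lo] + w * z[hi]
  }

  keep <- which(text >= tw[1] & text <= tw[2] - 1)
  with_seed(seed, {
    trials <- vector("list", config$n_trials)
    for (i in seq_len(config$n_trials)) {
      A <- matrix(0, length(tt), na + nw)
      B <- matrix(0, length(tt), na + nw)
      for (j in seq_len(na)) {
        L <- chol_for(config$latent_timescales[j], length(text))
        z <- drop(crossprod(L, rnorm(length(text))))
        A[, j] <- z[keep]
        B[, j] <- interp_shift(z, config$latent_delays[j])[keep]
      }
      for (j in seq_len(nw)) {
        L <- chol_for(config$latent_timescales[na + j], length(tt))
        A[, na + j] <- drop(crossprod(L, rnorm(length(tt))))
        B[, na + j] <- drop(crossprod(L, rnorm(length(tt))))
      }
      trials[[i]] <- list(A = A, B = B)
    }
    list(time = tt, trials = trials,
         n_across = na, n_within = nw,
         delays = config$latent_delays)
  })
}
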