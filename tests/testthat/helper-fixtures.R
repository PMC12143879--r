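# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small so the whole suite stays well inside its budget.

small_session <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 5, n_units = 6, n_trials = 30, ...) {
    key <- paste(seed, n_units, n_trials, ...)
    if (is.null(cache[[key]])) {
      cfg <- synth_config(n_units_per_region = n_units, n_trials = n_trials,
                          seed = seed, ...)
      cache[[key]] <- generate_session(cfg)
    }
    cache[[key]]
  }
})

# homogeneous Poisson spike train
poisson_train <- function(rate, duration, seed = 1) {
  with_seed_test(seed, sort(runif(rpois(1, rate * duration), 0, duration)))
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(expr)
}

# brute-force autocorrelogram mass oracle (all ordered pairs)
brute_acg_mass <- function(spikes, lo, hi) {
  d <- outer(spikes, spikes, "-")
  sum(d >= lo & d < hi & d > 0)
}

# draw Gaussian observations directly from the delayed-latent model
draw_dlag_data <- function(delays, l = 100, nA = 10, nB = 10, ntr = 50,
                           noise = 0.5, T = 50, binw = 20, q_within = 0,
                           seed = 1) {
  with_seed_test(seed, {
    tt <- (seq_len(T) - 1) * binw
    p <- length(delays)
    CA <- matrix(rnorm(nA * (p + q_within)), nA)
    CB <- matrix(rnorm(nB * (p + q_within)), nB)
    chs <- lapply(delays, function(D)
      chol(dualpop:::se_kernel_block(tt, l, D)))
    chw <- chol(dualpop:::se_kernel_block(tt, l))
    YA <- array(0, c(nA, T, ntr)); YB <- array(0, c(nB, T, ntr))
    for (i in seq_len(ntr)) {
      XA <- matrix(0, T, p + q_within); XB <- matrix(0, T, p + q_within)
      for (j in seq_len(p)) {
        x <- drop(crossprod(chs[[j]], rnorm(2 * T)))
        XA[, j] <- x[seq_len(T)]; XB[, j] <- x[T + seq_len(T)]
      }
      for (j in seq_len(q_within)) {
        XA[, p + j] <- drop(crossprod(chw, rnorm(T)))
        XB[, p + j] <- drop(crossprod(chw, rnorm(T)))
      }
      YA[, , i] <- CA %*% t(XA) + matrix(rnorm(nA * T, sd = noise), nA) + 2
      YB[, , i] <- CB %*% t(XB) + matrix(rnorm(nB * T, sd = noise), nB) + 2
    }
    list(A = YA, B = YB, CA = CA, CB = CB)
  })
}

# bind two trials x time x units arrays along the trial axis
abind_simple <- function(a, b) {
  out <- array(0, c(dim(a)[1] + dim(b)[1], dim(a)[2], dim(a)[3]))
  out[seq_len(dim(a)[1]), , ] <- a
  out[dim(a)[1] + seq_len(dim(b)[1]), , ] <- b
  out
}
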