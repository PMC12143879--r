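#' @useDynLib dualpop, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import stats
#' @importFrom utils head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Gaussian kernel smoothing of a uniformly sampled series
#'
#' Convolves a series sampled at `dt` ms with a Gaussian kernel of standard
#' deviation `sigma` ms. The kernel is truncated at 5 sigma and normalized to
#' unit mass so that the operation preserves the series integral.
#'
#' @param x numeric vector (or matrix, smoothed column-wise).
#' @param sigma kernel standard deviation in ms.
#' @param dt sample step in ms.
#' @return smoothed object of the same shape as `x`.
#' @export
gauss_smooth <- function(x, sigma, dt = 1) {
  if (sigma <= 0) return(x)
  half <- max(1L, ceiling(5 * sigma / dt))
  tt <- seq(-half, half) * dt
  k <- exp(-0.5 * (tt / sigma)^2)
  k <- k / sum(k)
  smooth1 <- function(v) {
    n <- length(v)
    # reflect-pad to avoid edge shrinkage of local mass
    vp <- c(rev(v[seq_len(min(half, n))]), v, rev(v[seq.int(max(1, n - half + 1), n)]))
    out <- stats::filter(vp, k, sides = 2)
    out <- as.numeric(out)
    lead <- min(half, n)
    out[seq.int(lead + 1, lead + n)]
  }
  if (is.matrix(x)) apply(x, 2, smooth1) else smooth1(x)
}

#' Bin spike times into counts on a uniform grid
#'
#' @param spikes spike times in seconds.
#' @param t0,t1 window edges in seconds; bins are `[t0 + (i-1)w, t0 + iw)`.
#' @param width bin width in seconds.
#' @return integer vector of counts, length `round((t1 - t0)/width)`.
#' @export
bin_spikes <- function(spikes, t0, t1, width) {
  nb <- as.integer(round((t1 - t0) / width))
  idx <- floor((spikes - t0) / width) + 1
  idx <- idx[idx >= 1 & idx <= nb]
  tabulate(idx, nbins = nb)
}

# Pearson correlation of x with every circular shift of y, via FFT.
# Returns vector r[k] = cor(x, shift(y, k-1)), k = 1..T (shift 0..T-1),
# where shift moves y forward (y_shifted[t] = y[t - k mod T]).
circ_cor_all <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n)
  xc <- x - mean(x)
  yc <- y - mean(y)
  denom <- sqrt(sum(xc^2) * sum(yc^2))
  if (denom == 0) return(rep(NA_real_, n))
  # circular cross-correlation sum_t xc[t] * yc[t - k]
  s <- Re(fft(fft(xc) * Conj(fft(yc)), inverse = TRUE)) / n
  s / denom
}

# Jensen-Shannon divergence (base-2) between two probability vectors.
js_divergence <- function(p, q) {
  p <- p / sum(p)
  q <- q / sum(q)
  m <- (p + q) / 2
  h <- function(w) {
    w <- w[w > 0]
    -sum(w * log2(w))
  }
  h(m) - (h(p) + h(q)) / 2
}

# Deterministic child seed derived from a parent seed and a tag, kept < 2^31.
child_seed <- function(seed, tag) {
  (as.integer(seed) * 1009L + as.integer(sum(utf8ToInt(as.character(tag))))) %% 2147483563L
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Empirical permutation p-value: smoothed (never exactly 0) and raw fraction.
perm_pvalue <- function(observed, null_values, tail = c("greater", "two.sided")) {
  tail <- match.arg(tail)
  n <- length(null_values)
  if (tail == "greater") {
    k <- sum(null_values >= observed)
  } else {
    k <- sum(abs(null_values) >= abs(observed))
  }
  list(p = (1 + k) / (n + 1), p_raw = k / n)
}
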