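# Population geometry: concatenated trial-average matrices, CCA and PLS-SVD
# alignment with lag scans and shifted-time controls, and activity-onset and
# pre-movement variance measures.

#' Concatenated trial-averaged activity matrix
#'
#' Builds the 1600 x N matrix of trial-averaged firing rates: eight
#' concatenated 200 ms segments (reach-onset- and grasp-aligned, for each of
#' the four spouts), each spanning -99 to +100 ms around the alignment point
#' at 1 ms resolution. Columns are mean-centered over the concatenation.
#'
#' @param rates T x N rate matrix at 1 kHz covering the whole session.
#' @param trials data.frame with seconds-valued `onset`, `grasp`, integer
#'   `spout`, logical `qualifying`.
#' @param window ms window around each alignment point (length 200 grid).
#' @param spouts spout identities expected (each must have a qualifying
#'   trial).
#' @return object of class `activity_matrix`: list(values, segments, v,
#'   col_means) where `v` is the summed per-neuron variance of the centered
#'   columns.
#' @export
trial_average_matrix <- function(rates, trials, window = c(-99, 100),
                                 spouts = 1:4) {
  q <- trials[trials$qualifying, , drop = FALSE]
  offs <- seq(window[1], window[2])
  rows <- list(); seg <- list(); r0 <- 0
  for (align in c("onset", "grasp")) {
    for (sp in spouts) {
      tr <- q[q$spout == sp, , drop = FALSE]
      if (!nrow(tr))
        stop("no qualifying trial for spout ", sp, " (", align, " alignment)")
      acc <- 0
      for (i in seq_len(nrow(tr))) {
        i0 <- round(tr[[align]][i] * 1000)
        idx <- i0 + offs
        if (any(idx < 1 | idx > nrow(rates)))
          stop("alignment window out of range for spout ", sp)
        acc <- acc + rates[idx, , drop = FALSE]
      }
      rows[[length(rows) + 1]] <- acc / nrow(tr)
      seg[[length(seg) + 1]] <- data.frame(align = align, spout = sp,
                                           row_start = r0 + 1,
                                           row_end = r0 + length(offs))
      r0 <- r0 + length(offs)
    }
  }
  values <- do.call(rbind, rows)
  col_means <- colMeans(values)
  values <- sweep(values, 2, col_means)
  out <- list(values = values, segments = do.call(rbind, seg),
              v = sum(apply(values, 2, var)), col_means = col_means)
  class(out) <- "activity_matrix"
  out
}

#' @export
print.activity_matrix <- function(x, ...) {
  cat("<activity_matrix>", nrow(x$values), "time points x", ncol(x$values),
      "neurons; total variance", signif(x$v, 4), "\n")
  invisible(x)
}

vals <- function(x) if (inherits(x, "activity_matrix")) x$values else
  sweep(as.matrix(x), 2, colMeans(as.matrix(x)))

# additional variance captured per region by successively orthogonalized
# component weight vectors
orthogonalized_capture <- function(X, W) {
  qr_ <- qr(W)
  Q <- qr.Q(qr_)[, seq_len(qr_$rank), drop = FALSE]
  proj <- X %*% Q
  addl <- apply(proj, 2, var)
  addl
}

#' Canonical correlation alignment of two population matrices
#'
#' Reduces each matrix to its first `k` principal components (mitigating
#' rank deficiency), computes canonical pairs, and reports per-pair
#' correlations, orthogonalized cumulative variance capture, and the
#' variance-weighted mean correlation (each pair's correlation weighted by
#' the average additional variance captured by its orthogonalized weight
#' vectors in the two regions). Component signs are chosen so each pair's
#' covariance is nonnegative.
#'
#' @param X_A,X_B `activity_matrix` objects or plain matrices (time x
#'   neurons; columns are centered internally).
#' @param k number of principal components retained before CCA.
#' @return object of class `alignment_result`.
#' @export
cca_align <- function(X_A, X_B, k = 25) {
  A <- vals(X_A); B <- vals(X_B)
  kA <- min(k, qr(A)$rank); kB <- min(k, qr(B)$rank)
  kk <- min(kA, kB)
  if (kk < k) warning("rank below k; using k = ", kk)
  pA <- prcomp(A, center = FALSE); pB <- prcomp(B, center = FALSE)
  SA <- pA$x[, seq_len(kk), drop = FALSE]
  SB <- pB$x[, seq_len(kk), drop = FALSE]
  cc <- cancor(SA, SB, xcenter = FALSE, ycenter = FALSE)
  nd <- length(cc$cor)
  WA <- pA$rotation[, seq_len(kk), drop = FALSE] %*% cc$xcoef[, seq_len(nd), drop = FALSE]
  WB <- pB$rotation[, seq_len(kk), drop = FALSE] %*% cc$ycoef[, seq_len(nd), drop = FALSE]
  projA <- A %*% WA; projB <- B %*% WB
  sgn <- sign(colSums(projA * projB)); sgn[sgn == 0] <- 1
  WB <- sweep(WB, 2, sgn, "*"); projB <- sweep(projB, 2, sgn, "*")
  addA <- orthogonalized_capture(A, WA)
  addB <- orthogonalized_capture(B, WB)
  w <- (addA + addB) / 2
  res <- list(method = "cca",
              weights_A = WA, weights_B = WB,
              cors = cc$cor,
              proj_A = projA, proj_B = projB,
              capture_A = addA, capture_B = addB,
              cum_capture_A = cumsum(addA), cum_capture_B = cumsum(addB),
              weighted_mean_cor = sum(cc$cor * w) / sum(w),
              v_A = sum(apply(A, 2, var)), v_B = sum(apply(B, 2, var)))
  class(res) <- "alignment_result"
  res
}

#' Partial-least-squares (PLS-SVD) alignment
#'
#' Singular value decomposition of the cross-covariance matrix
#' `t(X_A) %*% X_B / (n - 1)`: projections of the two matrices onto paired
#' singular vectors have pairwise covariance equal to the singular values,
#' and the alignment scalar is `c = trace(S) / (v_A + v_B)`, with `v` the
#' summed per-neuron variance per region. `c` is bounded above by 0.5, with
#' equality when `X_B` is an orthogonal transform of `X_A`.
#'
#' @inheritParams cca_align
#' @return object of class `alignment_result` with element `c`.
#' @export
pls_svd <- function(X_A, X_B) {
  A <- vals(X_A); B <- vals(X_B)
  n <- nrow(A)
  CC <- crossprod(A, B) / (n - 1)
  sv <- svd(CC)
  projA <- A %*% sv$u; projB <- B %*% sv$v
  addA <- orthogonalized_capture(A, sv$u)
  addB <- orthogonalized_capture(B, sv$v)
  vA <- sum(apply(A, 2, var)); vB <- sum(apply(B, 2, var))
  res <- list(method = "pls",
              weights_A = sv$u, weights_B = sv$v,
              singular_values = sv$d,
              cors = vapply(seq_along(sv$d), function(i)
                if (sd(projA[, i]) * sd(projB[, i]) > 0)
                  cor(projA[, i], projB[, i]) else NA_real_, 0),
              proj_A = projA, proj_B = projB,
              capture_A = addA, capture_B = addB,
              cum_capture_A = cumsum(addA), cum_capture_B = cumsum(addB),
              c = sum(sv$d) / (vA + vB),
              v_A = vA, v_B = vB)
  class(res) <- "alignment_result"
  res
}

#' @export
print.alignment_result <- function(x, ...) {
  cat("<alignment_result:", x$method, "> ",
      length(x$cors), "component pairs\n")
  if (!is.null(x$c)) cat("  c =", signif(x$c, 4), "\n")
  if (!is.null(x$weighted_mean_cor))
    cat("  variance-weighted mean correlation =",
        signif(x$weighted_mean_cor, 4), "\n")
  invisible(x)
}

#' Alignment quality versus imposed temporal lag
#'
#' Keeps the region-A matrix fixed and rebuilds the region-B matrix after
#' shifting every reach and grasp alignment time by each lag, recording the
#' CCA variance-weighted mean correlation and the PLS alignment scalar c at
#' each lag. Trials whose shifted window falls outside the rate series are
#' dropped with a warning.
#'
#' @param rates_A,rates_B T x N rate matrices (1 kHz).
#' @param trials trial table as for [trial_average_matrix()].
#' @param lags integer lags in ms.
#' @param k CCA rank.
#' @return data.frame(lag, cca_weighted_cor, pls_c).
#' @export
lag_scan <- function(rates_A, rates_B, trials, lags = -30:30, k = 25) {
  X_A <- trial_average_matrix(rates_A, trials)
  out <- data.frame(lag = lags, cca_weighted_cor = NA_real_, pls_c = NA_real_)
  for (i in seq_along(lags)) {
    tr <- trials
    tr$onset <- tr$onset + lags[i] / 1000
    tr$grasp <- tr$grasp + lags[i] / 1000
    maxi <- nrow(rates_B)
    bad <- (round(tr$onset * 1000) - 99 < 1) | (round(tr$grasp * 1000) + 100 > maxi)
    if (any(bad & tr$qualifying)) {
      warning("dropping ", sum(bad & tr$qualifying), " trial(s) at lag ", lags[i])
      tr$qualifying <- tr$qualifying & !bad
    }
    X_B <- trial_average_matrix(rates_B, tr)
    out$cca_weighted_cor[i] <- cca_align(X_A, X_B, k)$weighted_mean_cor
    out$pls_c[i] <- pls_svd(X_A, X_B)$c
  }
  out
}

#' Shifted-time control matrix
#'
#' Rebuilds one region's activity matrix after displacing every reach and
#' grasp alignment time by an independent random shift of 5000-10000 ms into
#' the future, rejecting shifts whose 200 ms window overlaps any original or
#' already-placed shifted window (up to `max_attempts` draws per event).
#' This destroys behavior-locked correlation while preserving per-neuron
#' statistics in expectation.
#'
#' @param rates T x N rate matrix (1 kHz).
#' @param trials trial table.
#' @param shift_range ms range of the random shift.
#' @param seed integer.
#' @param max_attempts placement attempts per event before erroring.
#' @return list(matrix = `activity_matrix`, trials = shifted trial table).
#' @export
shifted_time_control <- function(rates, trials, shift_range = c(5000, 10000),
                                 seed = 1, max_attempts = 1000) {
  with_seed(seed, {
    tr <- trials
    q <- which(tr$qualifying)
    win <- c(-99, 100)
    occupied <- c(lapply(q, function(i) round(tr$onset[i] * 1000) + win),
                  lapply(q, function(i) round(tr$grasp[i] * 1000) + win))
    place <- function(t_ms) {
      for (a in seq_len(max_attempts)) {
        s <- t_ms + runif(1, shift_range[1], shift_range[2])
        cand <- round(s) + win
        if (cand[2] > nrow(rates)) next
        ok <- all(vapply(occupied, function(o)
          cand[2] < o[1] || cand[1] > o[2], TRUE))
        if (ok) {
          occupied[[length(occupied) + 1]] <<- cand
          return(s / 1000)
        }
      }
      stop("no non-overlapping placement found after ", max_attempts,
           " attempts")
    }
    for (i in q) {
      tr$onset[i] <- place(tr$onset[i] * 1000)
      tr$grasp[i] <- place(tr$grasp[i] * 1000)
    }
    list(matrix = trial_average_matrix(rates, tr), trials = tr)
  })
}

#' Population activity-onset time
#'
#' Projects trial-averaged activity onto the top principal components
#' jointly capturing at least `var_threshold` of the variance, sums the
#' absolute deviation from the baseline-epoch mean across components, and
#' reports the first time after the baseline epoch at which this summed
#' deviation exceeds baseline mean + `k_sd` SD (computed over the baseline
#' epoch). Returns NA when the threshold is never crossed.
#'
#' @param avg time x neurons trial-averaged rate matrix.
#' @param time ms time axis (relative to reach onset).
#' @param var_threshold cumulative variance fraction for component count.
#' @param baseline ms epoch c(start, end) for baseline statistics.
#' @param k_sd threshold multiple.
#' @param threshold optional absolute threshold overriding the internally
#'   computed one (used to apply the higher of two regions' thresholds).
#' @return list(onset = ms or NA, threshold, signal, n_components).
#' @export
population_onset <- function(avg, time, var_threshold = 0.95,
                             baseline = c(-150, -100), k_sd = 11,
                             threshold = NULL) {
  stopifnot(nrow(avg) == length(time))
  X <- sweep(avg, 2, colMeans(avg))
  p <- prcomp(X, center = FALSE)
  cumfrac <- cumsum(p$sdev^2) / sum(p$sdev^2)
  m <- which(cumfrac >= var_threshold)[1]
  proj <- p$x[, seq_len(m), drop = FALSE]
  bidx <- time >= baseline[1] & time <= baseline[2]
  if (!any(bidx)) stop("baseline epoch outside the time axis")
  dev <- abs(sweep(proj, 2, colMeans(proj[bidx, , drop = FALSE])))
  signal <- rowSums(dev)
  thr_int <- mean(signal[bidx]) + k_sd * sd(signal[bidx])
  thr <- threshold %||% thr_int
  after <- which(time > baseline[2] & signal > thr)
  onset <- if (length(after)) time[after[1]] else NA_real_
  list(onset = onset, threshold = thr_int, signal = signal, n_components = m)
}

#' Fraction of activity variance preceding movement onset
#'
#' Summed (across neurons) squared deviation of trial-averaged activity from
#' each sub-window's mean, in the `window` ms before muscle-activity onset,
#' as a fraction of the pre- plus post-window total.
#'
#' @param avg time x neurons trial-averaged rates.
#' @param time ms axis relative to muscle activity onset.
#' @param window half-window, ms.
#' @return fraction in \[0, 1\] (NA when total variance is zero).
#' @export
premovement_variance_fraction <- function(avg, time, window = 150) {
  pre <- time >= -window & time < 0
  post <- time >= 0 & time <= window
  ssd <- function(idx) {
    Y <- avg[idx, , drop = FALSE]
    sum(sweep(Y, 2, colMeans(Y))^2)
  }
  a <- ssd(pre); b <- ssd(post)
  if (a + b == 0) return(NA_real_)
  a / (a + b)
}

#' Per-neuron activity-onset times
#'
#' Applies the [population_onset()] threshold rule to single-neuron
#' trial-averaged rates, for neurons whose mean rate exceeds the
#' `percentile` quantile across all provided neurons.
#'
#' @param avg time x neurons trial-averaged rates.
#' @param time ms axis.
#' @param mean_rates per-neuron session mean rates used for selection.
#' @param percentile selection percentile (0-100).
#' @inheritParams population_onset
#' @return data.frame(neuron, onset) for qualifying neurons (onset NA when
#'   never crossing).
#' @export
per_neuron_onset <- function(avg, time, mean_rates, percentile = 90,
                             baseline = c(-150, -100), k_sd = 11) {
  thr_rate <- quantile(mean_rates, percentile / 100, names = FALSE)
  keep <- which(mean_rates > thr_rate)
  bidx <- time >= baseline[1] & time <= baseline[2]
  onset <- vapply(keep, function(j) {
    x <- avg[, j]
    dev <- abs(x - mean(x[bidx]))
    thr <- mean(dev[bidx]) + k_sd * sd(dev[bidx])
    after <- which(time > baseline[2] & dev > thr)
    if (length(after)) time[after[1]] else NA_real_
  }, 0)
  data.frame(neuron = keep, onset = onset)
}
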