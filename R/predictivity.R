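# Pairwise directed predictivity between regions: transfer entropy,
# point-process Granger causality, convergent cross mapping, with pair
# selection, rate matching, circular-permutation nulls, and false-null
# estimation.

#' Mean firing rate over trial windows
#'
#' @param spikes list of spike-time vectors (s).
#' @param onsets qualifying-trial reach onsets (s).
#' @param window ms window around onset.
#' @return spikes/s per unit.
#' @export
trial_mean_rates <- function(spikes, onsets, window = c(-200, 800)) {
  span <- diff(window) / 1000
  vapply(spikes, function(s) {
    n <- sum(vapply(onsets, function(o)
      sum(s >= o + window[1] / 1000 & s < o + window[2] / 1000), 0))
    n / (span * length(onsets))
  }, 0)
}

#' Select the highest rate-product directed pairs
#'
#' Cross-region pairs (both orderings) ranked by the product of the two
#' units' mean rates over trial windows; only wide-waveform units with
#' negative-going peaks qualify. Returns up to `n` pairs per direction.
#'
#' @param units data.frame with `unit_id`, `region`, `width_class`,
#'   `peak_sign`, `mean_rate` (and optionally `session`).
#' @param n pairs retained per direction.
#' @return data.frame of class `pair_set`: a_id, b_id, rate_a, rate_b,
#'   product, session.
#' @export
top_pairs <- function(units, n = 10000) {
  u <- units[units$width_class == "wide" & units$peak_sign < 0, , drop = FALSE]
  a <- u[u$region == "A", ]; b <- u[u$region == "B", ]
  if (!nrow(a) || !nrow(b)) stop("need wide negative-peak units in both regions")
  if (is.null(u$session)) { a$session <- 1L; b$session <- 1L }
  grid <- expand.grid(ia = seq_len(nrow(a)), ib = seq_len(nrow(b)))
  same <- a$session[grid$ia] == b$session[grid$ib]
  grid <- grid[same, , drop = FALSE]
  pairs <- data.frame(a_id = a$unit_id[grid$ia], b_id = b$unit_id[grid$ib],
                      rate_a = a$mean_rate[grid$ia], rate_b = b$mean_rate[grid$ib],
                      session = a$session[grid$ia])
  pairs$product <- pairs$rate_a * pairs$rate_b
  pairs <- pairs[order(-pairs$product), , drop = FALSE]
  if (nrow(pairs) > n) pairs <- pairs[seq_len(n), , drop = FALSE]
  else if (nrow(pairs) < n) warning("only ", nrow(pairs), " eligible pairs")
  rownames(pairs) <- NULL
  class(pairs) <- c("pair_set", "data.frame")
  pairs
}

log_rate_bin <- function(rate, width = 0.05) floor(log10(rate) / width)

#' Match the per-region firing-rate distributions of a pair set
#'
#' Iteratively replaces the B-side cell of randomly chosen pairs: a rate bin
#' (0.05 log10 spikes/s) with a B surplus is selected, a pair with its B
#' cell in that bin and its A cell in a bin with an A surplus is drawn, and
#' the B cell is replaced by a B cell from the same session and the A cell's
#' bin (drawn with replacement). Each swap strictly reduces the total
#' bin-count discrepancy; the procedure stops when distributions match or no
#' legal swap remains.
#'
#' @param pairs a `pair_set`.
#' @param units the unit table used to draw replacement cells.
#' @param bin_width log10 bin width.
#' @param seed integer.
#' @return the adjusted `pair_set` with attribute `n_swaps`.
#' @export
match_rate_distributions <- function(pairs, units, bin_width = 0.05, seed = 1) {
  u <- units[units$width_class == "wide" & units$peak_sign < 0, , drop = FALSE]
  if (is.null(u$session)) u$session <- 1L
  ub <- u[u$region == "B", ]
  ub$bin <- log_rate_bin(ub$mean_rate, bin_width)
  with_seed(seed, {
    n_swaps <- 0L
    repeat {
      bins_a <- log_rate_bin(pairs$rate_a, bin_width)
      bins_b <- log_rate_bin(pairs$rate_b, bin_width)
      all_bins <- sort(unique(c(bins_a, bins_b)))
      ca <- vapply(all_bins, function(b) sum(bins_a == b), 0L)
      cb <- vapply(all_bins, function(b) sum(bins_b == b), 0L)
      surplus_b <- all_bins[cb > ca]
      deficit_b <- all_bins[ca > cb]      # A surplus = B deficit
      if (!length(surplus_b) || !length(deficit_b)) break
      # legal candidate pairs: B cell in a surplus bin, A cell in a deficit
      # bin, and a replacement B cell available in the A cell's bin
      cand <- which(bins_b %in% surplus_b & bins_a %in% deficit_b)
      cand <- cand[vapply(cand, function(i)
        any(ub$bin == bins_a[i] & ub$session == pairs$session[i]), TRUE)]
      if (!length(cand)) break
      i <- cand[sample.int(length(cand), 1)]
      repl <- which(ub$bin == bins_a[i] & ub$session == pairs$session[i])
      j <- repl[sample.int(length(repl), 1)]
      pairs$b_id[i] <- ub$unit_id[j]
      pairs$rate_b[i] <- ub$mean_rate[j]
      pairs$product[i] <- pairs$rate_a[i] * pairs$rate_b[i]
      n_swaps <- n_swaps + 1L
    }
    attr(pairs, "n_swaps") <- n_swaps
    pairs
  })
}

#' Movement epochs from the summed EMG envelope
#'
#' Epochs where the summed envelope exceeds the quiescent mean plus 7 SD;
#' sub-threshold gaps of 100 ms or less are reclassified as movement, and
#' movement epochs shorter than 10 ms are dropped.
#'
#' @param env_sum summed envelope at 1 kHz.
#' @param quiescent c(mean, sd) of a quiescent period; found automatically
#'   (minimum-variance 1 s window) when NULL.
#' @param merge_gap ms; gaps at or below this are merged.
#' @param min_len ms; epochs strictly shorter are dropped.
#' @return data.frame(start, end) in ms (1-based sample indices).
#' @export
movement_epochs <- function(env_sum, quiescent = NULL, merge_gap = 100,
                            min_len = 10) {
  if (is.null(quiescent)) {
    q <- find_quiescent_epoch(env_sum)
    quiescent <- c(mean(env_sum[q["start"]:q["end"]]),
                   sd(env_sum[q["start"]:q["end"]]))
  }
  thr <- quiescent[1] + 7 * quiescent[2]
  above <- env_sum > thr
  r <- rle(above)
  # merge short FALSE runs (interior only)
  if (length(r$lengths) > 2) {
    interior <- seq(2, length(r$lengths) - 1)
    r$values[interior][!r$values[interior] & r$lengths[interior] <= merge_gap] <- TRUE
  }
  above <- inverse.rle(r)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_len
  if (!any(keep)) stop("no movement epochs found")
  data.frame(start = starts[keep], end = ends[keep])
}

#' Concatenate a spike train over movement epochs with zero pads
#'
#' @param spikes spike times (s).
#' @param epochs data.frame from [movement_epochs()] (ms).
#' @param pad_ms zero-pad length inserted between epochs (longer than the
#'   maximum metric delay).
#' @return binary integer vector at 1 ms.
#' @export
concat_movement_train <- function(spikes, epochs, pad_ms = 100) {
  segs <- lapply(seq_len(nrow(epochs)), function(i) {
    t0 <- (epochs$start[i] - 1) / 1000
    t1 <- epochs$end[i] / 1000
    cnt <- bin_spikes(spikes, t0, t1, 1e-3)
    c(as.integer(cnt > 0), integer(pad_ms))
  })
  unlist(segs)
}

#' Delayed transfer entropy between two binary trains
#'
#' Plug-in estimator on 1 ms bins with single-bin source and target
#' histories, evaluated at source delays d = 0..`d_max` ms; reports the
#' maximum and its delay.
#'
#' @param source,target binary integer vectors (1 ms bins).
#' @param d_max maximum delay, ms.
#' @return list(te, best_d, curve).
#' @export
transfer_entropy <- function(source, target, d_max = 30) {
  if (!sum(source) || !sum(target)) stop("empty train; pair excluded")
  curve <- te_delay_scan_cpp(as.integer(source), as.integer(target), d_max)
  list(te = max(curve), best_d = which.max(curve) - 1L, curve = curve)
}

#' Circular-permutation p-value for a directed pair metric
#'
#' Circularly permutes the source train by uniform shifts of at least
#' `min_shift` seconds (at most T - `min_shift`), re-evaluating the metric
#' with best-delay re-optimization for each permutation. The default fast
#' path evaluates transfer entropy in compiled code; any metric can be
#' supplied as `evaluator(source, target)` returning a scalar.
#'
#' @param source,target binary trains (1 ms).
#' @param n permutations.
#' @param min_shift s.
#' @param d_max delay grid maximum (TE fast path).
#' @param evaluator optional function(source, target) -> scalar.
#' @param seed integer.
#' @return list(observed, p, p_raw, null).
#' @export
circular_perm_pvalue <- function(source, target, n = 300, min_shift = 3,
                                 d_max = 30, evaluator = NULL, seed = 1) {
  T_s <- length(source) / 1000
  if (T_s <= 2 * min_shift) stop("train shorter than twice the minimum shift")
  with_seed(seed, {
    shifts <- sample(seq.int(min_shift * 1000, length(source) - min_shift * 1000),
                     n, replace = TRUE)
    if (is.null(evaluator)) {
      obs <- transfer_entropy(source, target, d_max)$te
      null <- te_perm_scan_cpp(as.integer(source), as.integer(target), d_max,
                               as.integer(shifts))
    } else {
      obs <- evaluator(source, target)
      null <- vapply(shifts, function(k) {
        idx <- ((seq_along(source) - 1 - k) %% length(source)) + 1
        evaluator(source[idx], target)
      }, 0)
    }
    pv <- perm_pvalue(obs, null)
    list(observed = obs, p = pv$p, p_raw = pv$p_raw, null = null)
  })
}

# lagged history design matrix for one binary train within one trial
history_block <- function(x, h) {
  n <- length(x)
  out <- matrix(0L, n - h, h)
  for (l in seq_len(h)) out[, l] <- x[(h - l + 1):(n - l)]
  out
}

#' Point-process Granger causality for one directed pair
#'
#' Logistic point-process regression of the target train on 30 ms of
#' ensemble spiking history plus a piecewise-constant exogenous trial-time
#' modulation whose bin width is selected by AIC from a candidate set. The
#' statistic is the deviance difference between the full model and the model
#' excluding the source's history terms, referred to a chi-square law with
#' 30 degrees of freedom.
#'
#' @param ens array units x ms x trials of binary spikes (trial windows).
#' @param target,source unit indices within `ens`.
#' @param history history span, ms (fixed at 30 so all statistics share one
#'   chi-square reference).
#' @param exog_bins candidate exogenous bin widths, ms.
#' @return list(stat, p, df, exog_width, converged, excluded, reason).
#' @export
pp_granger <- function(ens, target, source, history = 30,
                       exog_bins = c(1, 5, 8, 10, 20, 25)) {
  nt <- dim(ens)[2]; ntr <- dim(ens)[3]
  units <- seq_len(dim(ens)[1])
  rows_per <- nt - history
  y <- as.vector(vapply(seq_len(ntr), function(k)
    ens[target, (history + 1):nt, k], numeric(rows_per)))
  H <- do.call(cbind, lapply(units, function(u)
    do.call(rbind, lapply(seq_len(ntr), function(k)
      history_block(ens[u, , k], history)))))
  tt <- rep(seq_len(rows_per), ntr)
  fit_with <- function(X) {
    fit <- suppressWarnings(glm.fit(cbind(1, X), y,
                                    family = binomial()))
    fit
  }
  pick <- NULL; best_aic <- Inf
  exog_for <- function(w) {
    f <- factor(floor((tt - 1) / w))
    stats::model.matrix(~ f)[, -1, drop = FALSE]
  }
  src_cols <- (which(units == source) - 1) * history + seq_len(history)
  for (w in exog_bins) {
    Ex <- exog_for(w)
    fit <- fit_with(cbind(H, Ex))
    aic <- fit$deviance + 2 * (ncol(Ex) + ncol(H) + 1)
    if (fit$converged && aic < best_aic) {
      best_aic <- aic; pick <- list(w = w, Ex = Ex, fit = fit)
    }
  }
  if (is.null(pick))
    return(list(stat = NA_real_, p = NA_real_, df = history,
                exog_width = NA, converged = FALSE, excluded = TRUE,
                reason = "no converged full model"))
  if (pick$fit$deviance < 1e-8)
    return(list(stat = NA_real_, p = NA_real_, df = history,
                exog_width = pick$w, converged = TRUE, excluded = TRUE,
                reason = "perfect fit"))
  Hred <- H[, -src_cols, drop = FALSE]
  fit0 <- fit_with(cbind(Hred, pick$Ex))
  if (!fit0$converged)
    return(list(stat = NA_real_, p = NA_real_, df = history,
                exog_width = pick$w, converged = FALSE, excluded = TRUE,
                reason = "reduced model did not converge"))
  stat <- fit0$deviance - pick$fit$deviance
  list(stat = stat, p = pchisq(stat, df = history, lower.tail = FALSE),
       df = history, exog_width = pick$w, converged = TRUE,
       excluded = FALSE, reason = NA_character_)
}

#' Post-hoc exclusion of the low-rate high-p Granger cluster
#'
#' Removes pairs with p above `p_thresh` whose rate product lies below the
#' `rate_quantile` quantile of all pairs (the cluster that does not meet the
#' model's assumptions).
#'
#' @param results data.frame with columns `p` and `product`.
#' @param p_thresh p-value threshold.
#' @param rate_quantile quantile defining "low rate".
#' @return logical keep-mask.
#' @export
gc_lowrate_exclusion <- function(results, p_thresh = 0.95, rate_quantile = 0.2) {
  cut <- quantile(results$product, rate_quantile, names = FALSE, na.rm = TRUE)
  !(results$p > p_thresh & results$product < cut) | is.na(results$p)
}

delay_embed <- function(x, E, tau) {
  first <- (E - 1) * tau + 1
  idx <- first:length(x)
  emb <- vapply(seq_len(E) - 1, function(e) x[idx - e * tau],
                numeric(length(idx)))
  list(emb = matrix(emb, ncol = E), times = idx)
}

#' Optimal embedding dimension by simplex projection
#'
#' Leave-one-out simplex forecast of a series' own next value at candidate
#' embedding dimensions; returns the dimension maximizing forecast skill
#' (correlation of forecasts with actual values).
#'
#' @param x numeric series (1 ms bins, smoothed).
#' @param E_candidates candidate dimensions.
#' @param tau embedding lag, samples.
#' @param tol skill tolerance: the smallest dimension within `tol` of the
#'   best skill is returned (ties in near-deterministic series resolve to
#'   the most parsimonious embedding).
#' @return list(E, skill = per-candidate skills) or NULL for a constant
#'   series.
#' @export
simplex_optimal_E <- function(x, E_candidates = 1:10, tau = 1, tol = 1e-3) {
  if (sd(x) == 0) return(NULL)
  skills <- vapply(E_candidates, function(E) {
    de <- delay_embed(x, E, tau)
    usable <- de$times < length(x)
    emb <- de$emb[usable, , drop = FALSE]
    tms <- de$times[usable]
    if (nrow(emb) < E + 2) return(NA_real_)
    nb <- knn_simplex_cpp(emb, rep(1L, nrow(emb)), as.integer(tms),
                          E + 1L, as.integer(tau))
    pred <- rowSums(nb$w * matrix(x[tms[nb$idx] + 1], nrow(emb)))
    actual <- x[tms + 1]
    if (sd(pred) == 0 || sd(actual) == 0) return(0)
    cor(pred, actual)
  }, 0)
  best <- max(skills, na.rm = TRUE)
  list(E = E_candidates[which(skills >= best - tol)[1]], skill = skills)
}

#' Convergent cross-mapping skill for a directed pair
#'
#' Builds shadow manifolds from the target neuron's delay-embedded activity
#' within each of `n_trials` randomly sampled trials (points formed once at
#' least `history_span` ms of within-trial history exists), cross-maps the
#' source's activity from the K nearest manifold neighbors, and reports the
#' correlation between predicted and actual source series, maximized over
#' the delay grid. The permutation null circularly shifts the concatenated
#' source series while reusing the same manifold neighbors and optimal
#' delay.
#'
#' @param source,target lists of per-trial numeric vectors (1 ms, smoothed).
#' @param E,tau,K embedding dimension, lag (samples), neighbor count.
#' @param delays delay grid, ms.
#' @param history_span ms of history required before a manifold point.
#' @param n_trials trials sampled.
#' @param stride manifold/prediction point spacing, ms (compute control).
#' @param theiler ms: same-trial neighbors closer in time than this are
#'   excluded from the neighbor search, so autocorrelation alone (about
#'   3x the 10 ms smoothing kernel) cannot masquerade as cross-map skill.
#' @param n_perm permutations for the p-value (0 = skip).
#' @param min_shift_s minimum circular shift, s.
#' @param seed integer.
#' @return list(skill, best_delay, p, p_raw, skills_by_delay).
#' @export
ccm_skill <- function(source, target, E = 4, tau = 1, K = E + 1,
                      delays = seq(0, 30, by = 3), history_span = 500,
                      n_trials = 30, stride = 1, theiler = 35, n_perm = 300,
                      min_shift_s = 3, seed = 1) {
  stopifnot(length(source) == length(target))
  with_seed(seed, {
    pickt <- if (length(target) > n_trials) sample(length(target), n_trials)
    else seq_along(target)
    pts <- list(); trial_id <- c(); t_in_trial <- c(); offs <- c(0)
    for (ii in seq_along(pickt)) {
      k <- pickt[ii]
      x <- target[[k]]
      tsel <- seq(history_span + 1, length(x), by = stride)
      tsel <- tsel[tsel - (E - 1) * tau >= 1]
      emb <- vapply(seq_len(E) - 1, function(e) x[tsel - e * tau],
                    numeric(length(tsel)))
      pts[[ii]] <- matrix(emb, ncol = E)
      trial_id <- c(trial_id, rep(ii, length(tsel)))
      t_in_trial <- c(t_in_trial, tsel)
      offs <- c(offs, offs[ii] + length(x))
    }
    emb <- do.call(rbind, pts)
    if (nrow(emb) < K + 1) stop("fewer than K + 1 manifold points; pair excluded")
    src_cat <- unlist(source[pickt])
    L <- length(src_cat)
    cat_idx <- offs[trial_id] + t_in_trial     # concatenated source index
    nb <- knn_simplex_cpp(emb, as.integer(trial_id), as.integer(t_in_trial),
                          as.integer(K), as.integer(theiler))
    skill_at <- function(d, svec) {
      vi <- cat_idx - d
      pred <- rowSums(nb$w * matrix(svec[vi[nb$idx]], nrow(emb)))
      actual <- svec[vi]
      if (sd(pred) == 0 || sd(actual) == 0) return(0)
      cor(pred, actual)
    }
    skills <- vapply(delays, skill_at, 0, svec = src_cat)
    best <- which.max(skills)
    obs <- skills[best]
    p <- NA_real_; p_raw <- NA_real_
    if (n_perm > 0) {
      lo <- min_shift_s * 1000
      if (L <= 2 * lo) stop("concatenated series too short for the shift range")
      shifts <- sample(seq.int(lo, L - lo), n_perm, replace = TRUE)
      # the null re-optimizes the delay per permutation: comparing a
      # maximized observed skill to fixed-delay nulls is anti-conservative
      # (the permutation p-values would pile up near zero under the null)
      null <- vapply(shifts, function(s) {
        svec <- src_cat[((seq_len(L) - 1 - s) %% L) + 1]
        max(vapply(delays, skill_at, 0, svec = svec))
      }, 0)
      pv <- perm_pvalue(obs, null)
      p <- pv$p; p_raw <- pv$p_raw
    }
    list(skill = obs, best_delay = delays[best], p = p, p_raw = p_raw,
         skills_by_delay = setNames(skills, delays))
  })
}

#' Estimated fraction of false null hypotheses
#'
#' One minus the Storey-style smoothed estimate of the a priori true-null
#' fraction pi0: pi0(lambda) = #\{p > lambda\} / ((1 - lambda) m) over a
#' lambda grid, smoothed by a cubic spline and evaluated at the largest
#' lambda, clamped to \[0, 1\].
#'
#' @param p p-values (>= 100 recommended).
#' @return list(false_null_fraction, pi0).
#' @export
false_null_fraction <- function(p) {
  m <- length(p)
  lam <- seq(0.05, 0.9, by = 0.05)
  pi0l <- vapply(lam, function(l) mean(p > l) / (1 - l), 0)
  fit <- smooth.spline(lam, pi0l, df = 3)
  pi0 <- min(max(predict(fit, x = max(lam))$y, 0), 1)
  list(false_null_fraction = 1 - pi0, pi0 = pi0)
}

#' Benjamini-Hochberg display threshold at a target false discovery rate
#'
#' @param p p-values.
#' @param fdr target rate.
#' @return the largest p-value cutoff achieving the target FDR (0 when no
#'   rejection is possible).
#' @export
fdr_threshold <- function(p, fdr = 0.10) {
  m <- length(p)
  ps <- sort(p)
  ok <- which(ps <= seq_len(m) / m * fdr)
  if (!length(ok)) 0 else ps[max(ok)]
}
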