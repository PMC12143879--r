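# Two-population delayed-latent factor model.
#
# Observations in each region are linear-Gaussian readouts of smooth latent
# processes: across-latents are shared between regions with a continuous
# per-latent temporal delay (region B's copy of across-latent j at time t
# equals the master process at t + D_j, so negative D_j means region A
# leads); within-latents are private to one region. Latent priors are
# squared-exponential Gaussian-process kernels on the 20 ms bin grid with
# unit marginal variance; observation noise is diagonal. The model is fit by
# expectation-maximization: closed-form loading/mean/noise updates and
# numerically optimized per-latent kernel parameters (delay and timescale)
# against the expected complete-data log-likelihood.

KERNEL_NUGGET <- 1e-3

se_kernel_block <- function(tt, l, D = NULL) {
  # D = NULL: single-stream T x T kernel with nugget.
  # D given: 2T x 2T joint kernel of (a(t), b(t)) with b(t) = z(t + D).
  if (is.null(D)) {
    dt <- outer(tt, tt, "-")
    return((1 - KERNEL_NUGGET) * exp(-0.5 * (dt / l)^2) +
             diag(KERNEL_NUGGET, length(tt)))
  }
  pts <- c(tt, tt + D)
  dt <- outer(pts, pts, "-")
  (1 - KERNEL_NUGGET) * exp(-0.5 * (dt / l)^2) + diag(KERNEL_NUGGET, 2 * length(tt))
}

#' Bin spikes into per-trial count matrices for the two regions
#'
#' Counts in 20 ms bins over the trial window (default -200 to +800 ms
#' around reach onset, 50 bins). Neurons spiking strictly fewer times than
#' half the number of qualifying trials (over the windows) are excluded;
#' a region must keep at least `min_neurons` neurons or the session is
#' ineligible.
#'
#' @param spikes list of spike-time vectors (s).
#' @param regions character vector "A"/"B" per unit.
#' @param onsets qualifying-trial reach-onset times (s).
#' @param window ms window around onset.
#' @param binw bin width, ms.
#' @param min_neurons eligibility threshold per region.
#' @return list(A, B) of arrays neurons x bins x trials, with attribute
#'   `kept` (unit indices), or an error when ineligible.
#' @export
prepare_counts <- function(spikes, regions, onsets, window = c(-200, 800),
                           binw = 20, min_neurons = 12) {
  nb <- as.integer(diff(window) / binw)
  out <- list()
  for (r in c("A", "B")) {
    idx <- which(regions == r)
    if (!length(idx)) stop("region ", r, " is empty; session skipped")
    arr <- array(0L, c(length(idx), nb, length(onsets)))
    for (k in seq_along(onsets)) {
      t0 <- onsets[k] + window[1] / 1000
      t1 <- onsets[k] + window[2] / 1000
      for (u in seq_along(idx))
        arr[u, , k] <- bin_spikes(spikes[[idx[u]]], t0, t1, binw / 1000)
    }
    tot <- apply(arr, 1, sum)
    keep <- tot >= length(onsets) / 2    # strictly fewer than trials/2 excluded
    if (sum(keep) < min_neurons)
      stop("region ", r, " has fewer than ", min_neurons,
           " neurons after exclusion; session skipped")
    arr <- arr[keep, , , drop = FALSE]
    attr(arr, "kept") <- idx[keep]
    out[[r]] <- arr
  }
  out
}

# stream layout helpers: region A streams 1..(p+q) = across then within;
# region B streams (p+q)+(1..p) across, (2p+q)+(1..q) within
stream_maps <- function(p, q) {
  list(A = seq_len(p + q),
       B = c(p + q + seq_len(p), 2 * p + q + seq_len(q)),
       across_pairs = lapply(seq_len(p), function(j) c(j, p + q + j)),
       within = c(p + seq_len(q), 2 * p + q + seq_len(q)))
}

build_prior <- function(delays, l_across, l_within, T, binw, p, q) {
  tt <- (seq_len(T) - 1) * binw
  S <- 2 * p + 2 * q
  M <- S * T
  Kinv <- matrix(0, M, M)
  logdetK <- 0
  maps <- stream_maps(p, q)
  blk_idx <- function(streams) as.vector(outer(seq_len(T), (streams - 1) * T, "+"))
  for (j in seq_len(p)) {
    K <- se_kernel_block(tt, l_across[j], delays[j])
    ch <- chol(K)
    logdetK <- logdetK + 2 * sum(log(diag(ch)))
    ii <- blk_idx(maps$across_pairs[[j]])
    Kinv[ii, ii] <- chol2inv(ch)
  }
  wl <- rep_len(l_within, 2 * q)
  for (m in seq_len(2 * q)) {
    s <- maps$within[m]
    K <- se_kernel_block(tt, wl[m])
    ch <- chol(K)
    logdetK <- logdetK + 2 * sum(log(diag(ch)))
    ii <- blk_idx(s)
    Kinv[ii, ii] <- chol2inv(ch)
  }
  list(Kinv = Kinv, logdetK = logdetK)
}

#' Fit the delayed-latent model by EM
#'
#' @param counts list(A, B) from [prepare_counts()].
#' @param n_across,n_within latent dimensionalities.
#' @param binw bin width, ms.
#' @param bounds delay box constraint, ms.
#' @param max_iter maximum EM iterations.
#' @param tol relative log-likelihood convergence tolerance.
#' @param sqrt_transform square-root-stabilize counts before fitting.
#' @param refine_delays after EM, pin each delay at the optimum of its
#'   profile marginal likelihood (coarse-to-fine grid) with all other
#'   parameters fixed.
#' @param verbose print progress.
#' @return object of class `delayed_latent_model`: loadings `C_A`, `C_B`
#'   (columns: across then within), means, noise variances, `delays` (ms,
#'   negative = region A leads), timescales, the log-likelihood trace,
#'   per-latent `boundary` flags and the `converged` flag, plus posterior
#'   latent means of the training data.
#' @export
dlag_fit <- function(counts, n_across = 4, n_within = 4, binw = 20,
                     bounds = c(-200, 200), max_iter = 200, tol = 1e-6,
                     sqrt_transform = TRUE, refine_delays = TRUE,
                     verbose = FALSE) {
  p <- n_across; q <- n_within
  YA <- counts$A; YB <- counts$B
  if (sqrt_transform) { YA <- sqrt(YA); YB <- sqrt(YB) }
  nA <- dim(YA)[1]; nB <- dim(YB)[1]
  T <- dim(YA)[2]; ntr <- dim(YA)[3]
  stopifnot(dim(YB)[2] == T, dim(YB)[3] == ntr)
  maps <- stream_maps(p, q)
  S <- 2 * p + 2 * q; M <- S * T

  # ---- initialization
  # Across-latents: greedy SVD of the lagged cross-covariance. For each
  # latent, find the lag maximizing the leading singular value of the
  # cross-covariance between regions, refine the lag to sub-bin resolution
  # by parabolic interpolation, take the singular vectors as loadings, and
  # deflate that component at every lag. (Plain EM from zero delays moves
  # delays only over thousands of iterations; a data-driven start converges
  # within the iteration budget and is refined continuously by the M-step.)
  flatA <- matrix(YA, nA, T * ntr); flatB <- matrix(YB, nB, T * ntr)
  dA <- rowMeans(flatA); dB <- rowMeans(flatB)
  ZA <- flatA - dA; ZB <- flatB - dB
  n_obs <- T * ntr
  Ai <- array(ZA, c(nA, T, ntr)); Bi <- array(ZB, c(nB, T, ntr))
  max_lag_bins <- max(1L, min(T - 3L, floor(max(abs(bounds)) / binw)))
  lag_list <- -max_lag_bins:max_lag_bins
  Ms <- lapply(lag_list, function(k) {
    acc <- matrix(0, nA, nB)
    if (k >= 0) { ta <- seq_len(T - k); tb <- k + ta }
    else { tb <- seq_len(T + k); ta <- tb - k }
    for (i in seq_len(ntr))
      acc <- acc + Ai[, ta, i, drop = FALSE][, , 1] %*%
        t(Bi[, tb, i, drop = FALSE][, , 1])
    acc / (ntr * length(ta) - 1)
  })
  C_A <- matrix(0, nA, p + q); C_B <- matrix(0, nB, p + q)
  delays <- numeric(p)
  for (j in seq_len(p)) {
    s1 <- vapply(Ms, function(M) svd(M, nu = 0, nv = 0)$d[1], 0)
    kbest <- which.max(s1)
    off <- 0
    if (kbest > 1 && kbest < length(s1)) {
      y1 <- s1[kbest - 1]; y2 <- s1[kbest]; y3 <- s1[kbest + 1]
      den <- y1 - 2 * y2 + y3
      if (den < 0) off <- max(min(0.5 * (y1 - y3) / den, 1), -1)
    }
    delta_ms <- (lag_list[kbest] + off) * binw   # lag of B relative to A
    delays[j] <- min(max(-delta_ms, bounds[1]), bounds[2])
    sv1 <- svd(Ms[[kbest]], nu = 1, nv = 1)
    C_A[, j] <- sv1$u * sqrt(sv1$d[1])
    C_B[, j] <- sv1$v * sqrt(sv1$d[1])
    Ms <- lapply(Ms, function(M)
      M - sv1$u %*% (t(sv1$u) %*% M %*% sv1$v) %*% t(sv1$v))
  }
  # Within-latents: leading principal components of the residual covariance
  res_pc <- function(Z, C_ac) {
    Sres <- Z %*% t(Z) / (n_obs - 1) - C_ac %*% t(C_ac)
    e <- eigen((Sres + t(Sres)) / 2, symmetric = TRUE)
    e$vectors[, seq_len(q), drop = FALSE] %*%
      diag(sqrt(pmax(e$values[seq_len(q)], 1e-6)), q)
  }
  if (q > 0) {
    C_A[, p + seq_len(q)] <- res_pc(ZA, C_A[, seq_len(p), drop = FALSE])
    C_B[, p + seq_len(q)] <- res_pc(ZB, C_B[, seq_len(p), drop = FALSE])
  }
  R_A <- pmax(apply(flatA, 1, var) - rowSums(C_A^2), 1e-3)
  R_B <- pmax(apply(flatB, 1, var) - rowSums(C_B^2), 1e-3)
  l_across <- rep(2 * binw, p)
  l_within <- rep(2 * binw, 2 * q)

  Y <- array(0, c(nA + nB, T, ntr))
  Y[seq_len(nA), , ] <- YA; Y[nA + seq_len(nB), , ] <- YB
  blk_idx <- function(streams) as.vector(outer(seq_len(T), (streams - 1) * T, "+"))
  ll_trace <- numeric(0)
  tt <- (seq_len(T) - 1) * binw
  converged <- FALSE

  for (it in seq_len(max_iter)) {
    prior <- build_prior(delays, l_across, l_within, T, binw, p, q)
    RiA <- 1 / R_A; RiB <- 1 / R_B
    LamA <- t(C_A) %*% (C_A * RiA)
    LamB <- t(C_B) %*% (C_B * RiB)
    P <- prior$Kinv
    add_lambda <- function(P, Lam, map) {
      for (u in seq_along(map)) for (v in seq_along(map)) {
        iu <- (map[u] - 1) * T + seq_len(T)
        iv <- (map[v] - 1) * T + seq_len(T)
        P[cbind(iu, iv)] <- P[cbind(iu, iv)] + Lam[u, v]
      }
      P
    }
    P <- add_lambda(P, LamA, maps$A)
    P <- add_lambda(P, LamB, maps$B)
    chP <- chol(P)
    logdetP <- 2 * sum(log(diag(chP)))

    # RHS for all trials: rows M, cols ntr
    RHS <- matrix(0, M, ntr)
    quad_y <- 0
    for (i in seq_len(ntr)) {
      Za <- YA[, , i] - dA; Zb <- YB[, , i] - dB
      quad_y <- quad_y + sum(Za^2 * RiA) + sum(Zb^2 * RiB)
      Ga <- t(C_A * RiA) %*% Za        # (p+q) x T
      Gb <- t(C_B * RiB) %*% Zb
      for (s in seq_along(maps$A)) RHS[(maps$A[s] - 1) * T + seq_len(T), i] <- Ga[s, ]
      for (s in seq_along(maps$B)) RHS[(maps$B[s] - 1) * T + seq_len(T), i] <- Gb[s, ]
    }
    MU <- backsolve(chP, forwardsolve(t(chP), RHS))   # posterior means

    ll <- -0.5 * (ntr * ((nA + nB) * T * log(2 * pi) +
                           T * (sum(log(R_A)) + sum(log(R_B))) +
                           prior$logdetK + logdetP) +
                    quad_y - sum(RHS * MU))
    ll_trace <- c(ll_trace, ll)
    if (verbose) message("iter ", it, " ll = ", format(ll, digits = 10))
    if (it > 1) {
      rel <- (ll - ll_trace[it - 1]) / abs(ll_trace[it - 1])
      if (abs(rel) < tol) { converged <- TRUE; break }
    }

    Sigma <- chol2inv(chP)
    # equal-time covariance sums: SigSum[u, v] = sum_t Sigma[(u,t),(v,t)]
    SigSum <- matrix(0, S, S)
    for (u in seq_len(S)) for (v in seq_len(S)) {
      iu <- (u - 1) * T + seq_len(T); iv <- (v - 1) * T + seq_len(T)
      SigSum[u, v] <- sum(Sigma[cbind(iu, iv)])
    }

    # ---- M-step: loadings, means, noise per region
    update_region <- function(Yr, map) {
      pq <- length(map)
      EX <- matrix(0, pq, T * ntr)          # posterior means, streams x obs
      for (s in seq_len(pq))
        EX[s, ] <- as.vector(MU[(map[s] - 1) * T + seq_len(T), ])
      Yf <- matrix(Yr, dim(Yr)[1], T * ntr)
      Sxx <- ntr * SigSum[map, map, drop = FALSE] + EX %*% t(EX)
      sx <- rowSums(EX)
      n_all <- T * ntr
      Sxx_aug <- rbind(cbind(Sxx, sx), c(sx, n_all))
      Syx_aug <- cbind(Yf %*% t(EX), rowSums(Yf))
      W <- Syx_aug %*% solve(Sxx_aug)
      Cn <- W[, seq_len(pq), drop = FALSE]
      dn <- W[, pq + 1]
      Rn <- pmax((rowSums(Yf^2) - rowSums(W * Syx_aug)) / n_all, 1e-4)
      list(C = Cn, d = dn, R = Rn)
    }
    upA <- update_region(YA, maps$A); upB <- update_region(YB, maps$B)
    C_A <- upA$C; dA <- upA$d; R_A <- upA$R
    C_B <- upB$C; dB <- upB$d; R_B <- upB$R

    # ---- M-step: kernel parameters per latent
    second_moment <- function(streams) {
      ii <- blk_idx(streams)
      ntr * Sigma[ii, ii] + MU[ii, , drop = FALSE] %*% t(MU[ii, , drop = FALSE])
    }
    for (j in seq_len(p)) {
      Sj <- second_moment(maps$across_pairs[[j]])
      obj <- function(par) {
        K <- se_kernel_block(tt, exp(par[2]), par[1])
        ch <- tryCatch(chol(K), error = function(e) NULL)
        if (is.null(ch)) return(1e12)
        ntr * 2 * sum(log(diag(ch))) + sum(chol2inv(ch) * Sj)
      }
      # coarse delay grid at the current timescale, then joint local refine
      grid <- seq(max(bounds[1], -3 * 60), min(bounds[2], 3 * 60), by = 5)
      gv <- vapply(grid, function(g) obj(c(g, log(l_across[j]))), 0)
      d0 <- grid[which.min(gv)]
      if (obj(c(delays[j], log(l_across[j]))) < min(gv)) d0 <- delays[j]
      o <- optim(c(d0, log(l_across[j])), obj, method = "L-BFGS-B",
                 lower = c(bounds[1], log(binw / 4)),
                 upper = c(bounds[2], log(50 * binw)))
      delays[j] <- o$par[1]; l_across[j] <- exp(o$par[2])
    }
    for (m in seq_len(2 * q)) {
      Sj <- second_moment(maps$within[m])
      obj <- function(lpar) {
        K <- se_kernel_block(tt, exp(lpar))
        ch <- tryCatch(chol(K), error = function(e) NULL)
        if (is.null(ch)) return(1e12)
        ntr * 2 * sum(log(diag(ch))) + sum(chol2inv(ch) * Sj)
      }
      o <- optim(log(l_within[m]), obj, method = "Brent",
                 lower = log(binw / 4), upper = log(50 * binw))
      l_within[m] <- exp(o$par)
    }
  }

  model0 <- list(C_A = C_A, C_B = C_B, d_A = dA, d_B = dB,
                 R_A = R_A, R_B = R_B,
                 delays = delays, l_across = l_across, l_within = l_within,
                 n_across = p, n_within = q, binw = binw, T = T,
                 sqrt_transform = FALSE)
  if (refine_delays && p > 0) {
    # profile marginal likelihood over each delay, coarse to fine (EM moves
    # delays very slowly; this pins them at the likelihood optimum)
    counts_t <- list(A = YA, B = YB)   # already transformed
    for (j in seq_len(p)) {
      prof <- function(cands) {
        vapply(cands, function(d0) {
          m2 <- model0; m2$delays[j] <- d0
          sum(dlag_trial_ll(m2, counts_t))
        }, 0)
      }
      coarse <- unique(pmin(pmax(model0$delays[j] + seq(-20, 20, by = 5),
                                 bounds[1]), bounds[2]))
      best <- coarse[which.max(prof(coarse))]
      fine <- unique(pmin(pmax(best + seq(-4, 4, by = 1), bounds[1]), bounds[2]))
      model0$delays[j] <- fine[which.max(prof(fine))]
    }
    delays <- model0$delays
  }

  model <- list(C_A = C_A, C_B = C_B, d_A = dA, d_B = dB,
                R_A = R_A, R_B = R_B,
                delays = delays, l_across = l_across, l_within = l_within,
                n_across = p, n_within = q, binw = binw, T = T,
                bounds = bounds,
                boundary = abs(delays) >= max(abs(bounds)) - 1e-6,
                converged = converged,
                ll_trace = ll_trace,
                sqrt_transform = sqrt_transform)
  class(model) <- "delayed_latent_model"
  model
}

#' @export
print.delayed_latent_model <- function(x, ...) {
  cat("<delayed_latent_model>", x$n_across, "across +", x$n_within,
      "within latents,", x$T, "bins of", x$binw, "ms\n")
  cat("  delays (ms):", paste(signif(x$delays, 3), collapse = ", "),
      " [negative = region A leads]\n")
  cat("  converged:", x$converged, "; boundary:",
      paste(x$boundary, collapse = ","), "\n")
  invisible(x)
}

# per-trial marginal log-likelihood of data under a model (optionally with
# one latent's delay zeroed)
dlag_trial_ll <- function(model, counts, zero_delay = NULL) {
  YA <- counts$A; YB <- counts$B
  if (model$sqrt_transform) { YA <- sqrt(YA); YB <- sqrt(YB) }
  p <- model$n_across; q <- model$n_within
  T <- model$T; ntr <- dim(YA)[3]
  maps <- stream_maps(p, q)
  delays <- model$delays
  if (!is.null(zero_delay)) delays[zero_delay] <- 0
  prior <- build_prior(delays, model$l_across, model$l_within, T, model$binw, p, q)
  RiA <- 1 / model$R_A; RiB <- 1 / model$R_B
  P <- prior$Kinv
  add_lambda <- function(P, Lam, map) {
    for (u in seq_along(map)) for (v in seq_along(map)) {
      iu <- (map[u] - 1) * T + seq_len(T)
      iv <- (map[v] - 1) * T + seq_len(T)
      P[cbind(iu, iv)] <- P[cbind(iu, iv)] + Lam[u, v]
    }
    P
  }
  P <- add_lambda(P, t(model$C_A) %*% (model$C_A * RiA), maps$A)
  P <- add_lambda(P, t(model$C_B) %*% (model$C_B * RiB), maps$B)
  chP <- chol(P)
  logdetP <- 2 * sum(log(diag(chP)))
  nA <- nrow(model$C_A); nB <- nrow(model$C_B)
  const <- -0.5 * ((nA + nB) * T * log(2 * pi) +
                     T * (sum(log(model$R_A)) + sum(log(model$R_B))) +
                     prior$logdetK + logdetP)
  M <- (2 * p + 2 * q) * T
  RHS <- matrix(0, M, ntr)
  quad <- numeric(ntr)
  for (i in seq_len(ntr)) {
    Za <- YA[, , i] - model$d_A; Zb <- YB[, , i] - model$d_B
    Ga <- t(model$C_A * RiA) %*% Za
    Gb <- t(model$C_B * RiB) %*% Zb
    for (s in seq_along(maps$A)) RHS[(maps$A[s] - 1) * T + seq_len(T), i] <- Ga[s, ]
    for (s in seq_along(maps$B)) RHS[(maps$B[s] - 1) * T + seq_len(T), i] <- Gb[s, ]
    quad[i] <- sum(Za^2 * RiA) + sum(Zb^2 * RiB)
  }
  MU <- backsolve(chP, forwardsolve(t(chP), RHS))
  const - 0.5 * (quad - colSums(RHS * MU))
}

#' Bootstrap significance of fitted delays
#'
#' For each across-latent, compares the data likelihood of the fitted model
#' against the same model with that latent's delay set to zero, over
#' bootstrap resamples of trials (with replacement). A delay is significant
#' when fewer than `alpha` of resamples score the zero-delay model at least
#' as well.
#'
#' @param model fitted `delayed_latent_model`.
#' @param counts the count matrices the model was fit to.
#' @param trials_per_resample trials drawn per bootstrap resample.
#' @param n_resamples number of resamples (>= 20).
#' @param alpha significance level.
#' @param seed integer.
#' @return data.frame(latent, delay, frac_zero_as_good, significant).
#' @export
delay_significance <- function(model, counts, trials_per_resample = 100,
                               n_resamples = 100, alpha = 0.05, seed = 1) {
  if (n_resamples < 20) stop("n_resamples must be at least 20")
  ntr <- dim(counts$A)[3]
  ll_fit <- dlag_trial_ll(model, counts)
  out <- data.frame(latent = seq_len(model$n_across),
                    delay = model$delays,
                    frac_zero_as_good = NA_real_,
                    significant = FALSE)
  with_seed(seed, {
    draws <- matrix(sample.int(ntr, trials_per_resample * n_resamples,
                               replace = TRUE), n_resamples)
    for (j in seq_len(model$n_across)) {
      ll_zero <- dlag_trial_ll(model, counts, zero_delay = j)
      dll <- ll_fit - ll_zero              # per-trial advantage of fitted delay
      stat <- apply(draws, 1, function(ix) sum(dll[ix]))
      out$frac_zero_as_good[j] <- mean(stat <= 0)
      out$significant[j] <- out$frac_zero_as_good[j] < alpha
    }
  })
  out
}

#' Fractional variance capture per latent and region
#'
#' Shared-signal variance of each latent in each region (squared loading
#' norms times the unit latent variance) normalized by the region's total
#' modeled variance (all latents plus observation noise). Fractions sum to
#' one per region with the noise fraction included.
#'
#' @param model fitted `delayed_latent_model`.
#' @return list(per_latent = data.frame(latent, type, frac_A, frac_B),
#'   noise_frac = c(A, B)).
#' @export
variance_capture <- function(model) {
  p <- model$n_across; q <- model$n_within
  vars_A <- colSums(model$C_A^2)
  vars_B <- colSums(model$C_B^2)
  tot_A <- sum(vars_A) + sum(model$R_A)
  tot_B <- sum(vars_B) + sum(model$R_B)
  per <- data.frame(latent = seq_len(p + q),
                    type = rep(c("across", "within"), c(p, q)),
                    frac_A = vars_A / tot_A,
                    frac_B = vars_B / tot_B)
  list(per_latent = per,
       noise_frac = c(A = sum(model$R_A) / tot_A, B = sum(model$R_B) / tot_B))
}

#' Summarize significant lags across sessions
#'
#' Pools significant, in-window, non-boundary across-latent delays, and
#' reports per-session medians and variance-weighted mean lags (weights =
#' each latent's fractional variance capture in the chosen region).
#'
#' @param models list of fitted models.
#' @param significance list of [delay_significance()] results (same order).
#' @param window lag window, ms.
#' @return list(lags, median_lag, session_medians, weighted_mean_A,
#'   weighted_mean_B).
#' @export
lag_summary <- function(models, significance, window = 60) {
  lags <- c(); wA <- c(); wB <- c(); sess_med <- c()
  for (i in seq_along(models)) {
    m <- models[[i]]; sig <- significance[[i]]
    vc <- variance_capture(m)$per_latent
    ok <- sig$significant & !m$boundary & abs(m$delays) <= window
    if (!any(ok)) next
    lags <- c(lags, m$delays[ok])
    wA <- c(wA, vc$frac_A[seq_len(m$n_across)][ok])
    wB <- c(wB, vc$frac_B[seq_len(m$n_across)][ok])
    sess_med <- c(sess_med, median(m$delays[ok]))
  }
  if (!length(lags))
    return(list(lags = numeric(0), median_lag = NA_real_,
                session_medians = numeric(0),
                weighted_mean_A = NA_real_, weighted_mean_B = NA_real_))
  list(lags = lags, median_lag = median(lags), session_medians = sess_med,
       weighted_mean_A = sum(lags * wA) / sum(wA),
       weighted_mean_B = sum(lags * wB) / sum(wB))
}

#' Dimensionality sweep of the delayed-latent fit
#'
#' Refits the model over a range of across- or within-latent counts with the
#' other dimensionality fixed, reporting lagging-region variance capture by
#' significant across-latents grouped by lead direction.
#'
#' @param counts list(A, B) from [prepare_counts()].
#' @param vary "across" or "within".
#' @param range dimensionalities to sweep.
#' @param fixed the held-fixed dimensionality.
#' @param ... passed to [dlag_fit()].
#' @return data.frame(dim, capture_A_led_in_B, capture_B_led_in_A).
#' @export
dlag_dim_sweep <- function(counts, vary = c("within", "across"), range = 2:6,
                           fixed = 4, ...) {
  vary <- match.arg(vary)
  out <- data.frame(dim = range, capture_A_led_in_B = NA_real_,
                    capture_B_led_in_A = NA_real_)
  for (i in seq_along(range)) {
    na <- if (vary == "across") range[i] else fixed
    nw <- if (vary == "within") range[i] else fixed
    m <- dlag_fit(counts, n_across = na, n_within = nw, ...)
    vc <- variance_capture(m)$per_latent
    ac <- seq_len(na)
    a_led <- m$delays < 0 & !m$boundary
    b_led <- m$delays > 0 & !m$boundary
    out$capture_A_led_in_B[i] <- sum(vc$frac_B[ac][a_led])
    out$capture_B_led_in_A[i] <- sum(vc$frac_A[ac][b_led])
  }
  out
}
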