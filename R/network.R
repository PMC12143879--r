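# Dual-population excitatory/inhibitory recurrent rate network with Dale and
# sparsity constraints, trained against condition-specific muscle and
# per-region neural readout targets.

#' Specification of the dual-population network
#'
#' @param units_per_region units per region (paper-scale default 500).
#' @param exc_frac excitatory fraction.
#' @param p_within within-region connection probability.
#' @param p_across across-region probability (excitatory sources only;
#'   muscle-readout units never project across).
#' @param n_muscle_readout,n_neural_readout sizes of the disjoint excitatory
#'   readout subsets per region.
#' @param dt integration step, ms.
#' @param tau unit time constant, ms.
#' @param noise_sd state noise SD (0 for deterministic training).
#' @param g recurrent weight scale.
#' @return object of class `dual_network_spec`.
#' @export
dual_network_spec <- function(units_per_region = 500, exc_frac = 0.8,
                              p_within = 0.05, p_across = 0.001,
                              n_muscle_readout = 100, n_neural_readout = 100,
                              dt = 1, tau = 10, noise_sd = 0, g = 1.0) {
  stopifnot(exc_frac > 0, exc_frac < 1,
            n_muscle_readout + n_neural_readout <= units_per_region * exc_frac)
  out <- as.list(environment())
  class(out) <- "dual_network_spec"
  out
}

#' Build a network instance
#'
#' Draws connectivity masks (within-region at `p_within`; across-region at
#' `p_across` from excitatory, non-muscle-readout sources only; inhibitory
#' units never project across), selects the disjoint muscle- and
#' neural-readout subsets, and draws initial weights signed per Dale's law
#' (inhibitory magnitudes scaled by the E/I ratio for balance).
#'
#' @param spec a [dual_network_spec()].
#' @param seed integer.
#' @return object of class `network_instance` with sparse weight matrix `W`
#'   (entry \[i, j\] = weight from unit j to unit i), sign and zero masks
#'   implied by `w_sign`/`nz`, input weights, readout definitions.
#' @export
build_dual_network <- function(spec, seed = 1) {
  N <- spec$units_per_region
  n_exc <- round(N * spec$exc_frac)
  n2 <- 2L * N
  region <- rep(c("A", "B"), each = N)
  exc <- c(seq_len(n_exc), N + seq_len(n_exc))
  is_exc <- seq_len(n2) %in% exc
  muscle_subset <- c(seq_len(spec$n_muscle_readout),
                     N + seq_len(spec$n_muscle_readout))
  neural_subset <- c(spec$n_muscle_readout + seq_len(spec$n_neural_readout),
                     N + spec$n_muscle_readout + seq_len(spec$n_neural_readout))
  with_seed(seed, {
    blocks <- list()
    for (pre_reg in c("A", "B")) for (post_reg in c("A", "B")) {
      pre_all <- which(region == pre_reg)
      post_all <- which(region == post_reg)
      if (pre_reg == post_reg) {
        p <- spec$p_within
        pre_ok <- pre_all
      } else {
        p <- spec$p_across
        pre_ok <- pre_all[is_exc[pre_all] & !(pre_all %in% muscle_subset)]
      }
      nconn <- rbinom(1, length(pre_ok) * length(post_all), p)
      if (nconn == 0) next
      pick <- sample(length(pre_ok) * length(post_all), nconn)
      pre_i <- pre_ok[((pick - 1) %% length(pre_ok)) + 1]
      post_i <- post_all[((pick - 1) %/% length(pre_ok)) + 1]
      self <- pre_i == post_i
      blocks[[length(blocks) + 1]] <- cbind(post_i[!self], pre_i[!self])
    }
    ij <- do.call(rbind, blocks)
    dup <- duplicated(ij)
    ij <- ij[!dup, , drop = FALSE]
    nnz <- nrow(ij)
    sgn <- ifelse(is_exc[ij[, 2]], 1, -1)
    ei_ratio <- spec$exc_frac / (1 - spec$exc_frac)
    mag <- abs(rnorm(nnz, sd = spec$g / sqrt(N * spec$p_within)))
    mag[sgn < 0] <- mag[sgn < 0] * ei_ratio
    w <- sgn * mag
    W <- Matrix::sparseMatrix(i = ij[, 1], j = ij[, 2], x = w,
                              dims = c(n2, n2))
    net <- list(spec = spec, region = region, is_exc = is_exc,
                muscle_subset = muscle_subset, neural_subset = neural_subset,
                ij = ij, w_sign = sgn, W = W,
                w_go = abs(rnorm(n2, sd = 0.4)),
                w_light = ifelse(!is_exc, abs(rnorm(n2, sd = 3)), 0),
                bias = rnorm(n2, 0.1, 0.05),
                w_muscle = abs(rnorm(length(muscle_subset), sd = 0.02)),
                w_neural = rep(1 / spec$n_neural_readout,
                               length(neural_subset)))
    class(net) <- "network_instance"
    net
  })
}

#' @export
print.network_instance <- function(x, ...) {
  cat("<network_instance>", length(x$region), "units,", nrow(x$ij),
      "connections (", sum(x$w_sign > 0), "excitatory )\n")
  invisible(x)
}

#' Go and light input signals for a condition
#'
#' The go signal is a rising sigmoid `1/(1 + exp(-k t))` with k = 0.3 whose
#' ramp (first value above 0.01) starts 40 ms before reach onset; the light
#' signal rises with k = 0.5 starting at reach onset, plateaus at 1 until
#' +50 ms, and falls as a k = 1 sigmoid centered on the plateau end (value
#' below 0.01 within 5 ms). The light is routed to the inactivated region's
#' inhibitory units only.
#'
#' @param condition "control", "inact_A" or "inact_B".
#' @param t time grid, ms relative to reach onset (must cover -50..+100).
#' @return list(go, light, light_region).
#' @export
input_signals <- function(condition = c("control", "inact_A", "inact_B"),
                          t = seq(-50, 99)) {
  condition <- match.arg(condition)
  sig <- function(tt, k) 1 / (1 + exp(-k * tt))
  # center chosen so the 0.01 crossing sits at the stated ramp start
  go <- sig(t - (-40 + log(99) / 0.3), 0.3)
  rise <- sig(t - log(99) / 0.5, 0.5)
  fall <- sig(-(t - 50), 1)
  light <- ifelse(t < 50, rise, fall)
  if (condition == "control") light <- light * 0
  list(go = go, light = light,
       light_region = switch(condition, control = NA, inact_A = "A",
                             inact_B = "B"))
}

#' Simulate the network for one condition
#'
#' Discrete-time leaky rate dynamics `u <- (1 - a) u + a (W r + inputs + b)`
#' with `a = dt/tau` and rectified-linear rates. The muscle readout is the
#' trainable weighted sum over the 200 designated units; per-region neural
#' readouts are fixed-weight sums over each region's neural subset.
#'
#' @param net a `network_instance`.
#' @param condition condition name.
#' @param t time grid, ms.
#' @param noise_seed optional seed for state noise (spec$noise_sd > 0).
#' @return list(rates = units x T, muscle, neural_A, neural_B, u).
#' @export
simulate_network <- function(net, condition = "control", t = seq(-50, 99),
                             noise_seed = NULL) {
  spec <- net$spec
  a <- spec$dt / spec$tau
  sigs <- input_signals(condition, t)
  n2 <- length(net$region)
  Tn <- length(t)
  light_mask <- if (is.na(sigs$light_region)) numeric(n2) else
    as.numeric(net$region == sigs$light_region) * net$w_light
  noise <- if (spec$noise_sd > 0) {
    if (!is.null(noise_seed))
      with_seed(noise_seed, matrix(rnorm(n2 * Tn, sd = spec$noise_sd), n2, Tn))
    else matrix(rnorm(n2 * Tn, sd = spec$noise_sd), n2, Tn)
  } else NULL
  u <- numeric(n2)
  R <- matrix(0, n2, Tn)
  for (k in seq_len(Tn)) {
    drive <- as.numeric(net$W %*% pmax(u, 0)) + net$w_go * sigs$go[k] +
      light_mask * sigs$light[k] + net$bias
    if (!is.null(noise)) drive <- drive + noise[, k]
    u <- (1 - a) * u + a * drive
    if (!all(is.finite(u))) stop("numerical divergence in simulation")
    R[, k] <- pmax(u, 0)
  }
  nsub <- net$neural_subset
  nA <- nsub[net$region[nsub] == "A"]; nB <- nsub[net$region[nsub] == "B"]
  list(rates = R,
       muscle = as.numeric(crossprod(R[net$muscle_subset, , drop = FALSE],
                                     net$w_muscle)),
       neural_A = colMeans(R[nA, , drop = FALSE]),
       neural_B = colMeans(R[nB, , drop = FALSE]),
       time = t)
}

relu_deriv <- function(u) as.numeric(u > 0)

# forward pass storing states, loss and gradients via BPTT for one condition
net_backprop <- function(net, condition, targets, lambda_dir = NULL) {
  spec <- net$spec
  a <- spec$dt / spec$tau
  t <- targets$time
  sigs <- input_signals(condition, t)
  n2 <- length(net$region)
  Tn <- length(t)
  light_mask <- if (is.na(sigs$light_region)) numeric(n2) else
    as.numeric(net$region == sigs$light_region) * net$w_light
  U <- matrix(0, n2, Tn)
  u <- numeric(n2)
  for (k in seq_len(Tn)) {
    drive <- as.numeric(net$W %*% pmax(u, 0)) + net$w_go * sigs$go[k] +
      light_mask * sigs$light[k] + net$bias
    u <- (1 - a) * u + a * drive
    U[, k] <- u
  }
  R <- pmax(U, 0)
  msub <- net$muscle_subset
  nsub <- net$neural_subset
  nA <- nsub[net$region[nsub] == "A"]; nB <- nsub[net$region[nsub] == "B"]
  muscle <- as.numeric(crossprod(R[msub, , drop = FALSE], net$w_muscle))
  neur_A <- colMeans(R[nA, , drop = FALSE])
  neur_B <- colMeans(R[nB, , drop = FALSE])

  tgt_m <- targets$muscle[, condition]
  use_A <- condition != "inact_A"
  use_B <- condition != "inact_B"
  err_m <- muscle - tgt_m
  err_A <- if (use_A) neur_A - targets$A[, condition] else numeric(Tn)
  err_B <- if (use_B) neur_B - targets$B[, condition] else numeric(Tn)
  loss <- mean(err_m^2) + (if (use_A) mean(err_A^2) else 0) +
    (if (use_B) mean(err_B^2) else 0)

  # dL/dr at each time from the readouts
  G <- matrix(0, n2, Tn)
  G[msub, ] <- G[msub, ] + outer(net$w_muscle, 2 * err_m / Tn)
  if (use_A) G[nA, ] <- G[nA, ] + matrix(2 * err_A / Tn / length(nA),
                                         length(nA), Tn, byrow = TRUE)
  if (use_B) G[nB, ] <- G[nB, ] + matrix(2 * err_B / Tn / length(nB),
                                         length(nB), Tn, byrow = TRUE)

  Wt <- Matrix::t(net$W)
  Delta <- matrix(0, n2, Tn)
  delta_next <- numeric(n2)
  for (k in rev(seq_len(Tn))) {
    d <- relu_deriv(U[, k])
    back <- if (k < Tn) (1 - a) * delta_next +
      d * (a * as.numeric(Wt %*% delta_next)) else numeric(n2)
    Delta[, k] <- d * G[, k] + back
    delta_next <- Delta[, k]
  }
  # r at t-1 feeding the update at t (r_0 = 0)
  Rlag <- cbind(0, R[, -Tn, drop = FALSE])
  ii <- net$ij[, 1]; jj <- net$ij[, 2]
  dW <- a * rowSums(Delta[ii, , drop = FALSE] * Rlag[jj, , drop = FALSE])
  dwm <- as.numeric(R[msub, , drop = FALSE] %*% (2 * err_m / Tn))
  list(loss = loss, dW = dW, dwm = dwm,
       norm_err = loss / (var(tgt_m) +
                            (if (use_A) var(targets$A[, condition]) else 0) +
                            (if (use_B) var(targets$B[, condition]) else 0)))
}

#' Train a network instance against condition targets
#'
#' Gradient-based (Adam) minimization of the summed readout mean squared
#' error over the three conditions, optionally with the symmetric penalty
#' `lambda * |sum W_AtoB - sum W_BtoA|` on across-region weights. Sign and
#' zero masks are enforced by projection after every update; biases, input
#' weights and neural-readout weights stay fixed. Training stops early when
#' the normalized error plateaus or falls below `target_error`.
#'
#' @param net a `network_instance`.
#' @param targets result of [generate_network_targets()].
#' @param max_iter maximum gradient steps (each step uses all three
#'   conditions; the stated cap of 100,000 single-condition trials is
#'   realized as early stopping on a plateau).
#' @param lr Adam learning rate.
#' @param lambda symmetric-penalty weight (0 disables).
#' @param target_error stop when normalized error falls below this.
#' @param patience plateau length (steps) for early stopping.
#' @return list(net, error_trace, norm_error_trace, converged).
#' @export
train_network <- function(net, targets, max_iter = 400, lr = 2e-3,
                          lambda = 0, target_error = 0.05, patience = 60) {
  conds <- c("control", "inact_A", "inact_B")
  nnz <- nrow(net$ij)
  across <- net$region[net$ij[, 2]] != net$region[net$ij[, 1]]
  a2b <- across & net$region[net$ij[, 2]] == "A"
  b2a <- across & net$region[net$ij[, 2]] == "B"
  m_w <- numeric(nnz); v_w <- numeric(nnz)
  m_m <- numeric(length(net$w_muscle)); v_m <- numeric(length(net$w_muscle))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  err_trace <- c(); nerr_trace <- c()
  best <- Inf; stall <- 0
  wvec <- as.numeric(net$W[net$ij])
  for (it in seq_len(max_iter)) {
    dW <- numeric(nnz); dwm <- numeric(length(net$w_muscle))
    loss <- 0; nerr <- 0
    for (cond in conds) {
      bp <- net_backprop(net, cond, targets)
      dW <- dW + bp$dW; dwm <- dwm + bp$dwm
      loss <- loss + bp$loss; nerr <- nerr + bp$norm_err
    }
    nerr <- nerr / length(conds)
    if (!is.finite(loss)) stop("non-finite loss; aborting training")
    if (lambda > 0) {
      gap <- sum(wvec[a2b]) - sum(wvec[b2a])
      dW[a2b] <- dW[a2b] + lambda * sign(gap)
      dW[b2a] <- dW[b2a] - lambda * sign(gap)
    }
    m_w <- b1 * m_w + (1 - b1) * dW; v_w <- b2 * v_w + (1 - b2) * dW^2
    m_m <- b1 * m_m + (1 - b1) * dwm; v_m <- b2 * v_m + (1 - b2) * dwm^2
    mh <- m_w / (1 - b1^it); vh <- v_w / (1 - b2^it)
    wvec <- wvec - lr * mh / (sqrt(vh) + eps)
    # projection: Dale signs kept, structural zeros implicit in ij
    wvec <- ifelse(net$w_sign > 0, pmax(wvec, 0), pmin(wvec, 0))
    net$W <- Matrix::sparseMatrix(i = net$ij[, 1], j = net$ij[, 2], x = wvec,
                                  dims = dim(net$W))
    mhm <- m_m / (1 - b1^it); vhm <- v_m / (1 - b2^it)
    net$w_muscle <- net$w_muscle - lr * mhm / (sqrt(vhm) + eps)
    err_trace <- c(err_trace, loss); nerr_trace <- c(nerr_trace, nerr)
    if (nerr < target_error) break
    if (loss < best - 1e-6) { best <- loss; stall <- 0 } else stall <- stall + 1
    if (stall >= patience) break
  }
  list(net = net, error_trace = err_trace, norm_error_trace = nerr_trace,
       converged = tail(nerr_trace, 1) < target_error)
}

#' Audit the structural constraints of an instance
#'
#' @param net a `network_instance` (typically after training).
#' @return list of logical checks: Dale signs intact, no new connections,
#'   no inhibitory across-region entries.
#' @export
audit_constraints <- function(net) {
  wvec <- as.numeric(net$W[net$ij])
  sign_ok <- all(ifelse(net$w_sign > 0, wvec >= 0, wvec <= 0))
  nz_total <- Matrix::nnzero(net$W)
  zero_ok <- nz_total <= nrow(net$ij)
  across <- net$region[net$ij[, 2]] != net$region[net$ij[, 1]]
  dale_across_ok <- all(net$is_exc[net$ij[across, 2]])
  list(sign_ok = sign_ok, zero_ok = zero_ok, dale_across_ok = dale_across_ok)
}

#' Summed across-region input per direction and epoch
#'
#' For each direction, the sum over across-region connections of weight
#' times presynaptic activity, summed over each requested time window.
#'
#' @param net a `network_instance`.
#' @param rates units x T activity matrix from [simulate_network()].
#' @param windows list of index ranges into the time axis.
#' @return matrix directions (AtoB, BtoA) x windows.
#' @export
across_region_input <- function(net, rates, windows) {
  across <- net$region[net$ij[, 2]] != net$region[net$ij[, 1]]
  a2b <- which(across & net$region[net$ij[, 2]] == "A")
  b2a <- which(across & net$region[net$ij[, 2]] == "B")
  wvec <- as.numeric(net$W[net$ij])
  one <- function(sel, win) {
    if (!length(sel)) return(0)
    pre <- net$ij[sel, 2]
    sum(wvec[sel] * rowSums(rates[pre, win, drop = FALSE]))
  }
  out <- vapply(windows, function(win) c(AtoB = one(a2b, win),
                                         BtoA = one(b2a, win)),
                numeric(2))
  t(out)
}

#' Within-region inhibitory weight comparison across instances
#'
#' Pools |weights| of within-region inhibitory connections per region across
#' trained instances and reports a two-sample t-test of the region means.
#'
#' @param nets list of `network_instance`s.
#' @return list(mean_A, mean_B, p, statistic, weights_A, weights_B).
#' @export
inhibitory_weight_stats <- function(nets) {
  stopifnot(length(nets) >= 1)
  wA <- c(); wB <- c()
  for (net in nets) {
    within <- net$region[net$ij[, 2]] == net$region[net$ij[, 1]]
    inh <- !net$is_exc[net$ij[, 2]]
    wvec <- abs(as.numeric(net$W[net$ij]))
    wA <- c(wA, wvec[within & inh & net$region[net$ij[, 2]] == "A"])
    wB <- c(wB, wvec[within & inh & net$region[net$ij[, 2]] == "B"])
  }
  if (sd(wA) == 0 && sd(wB) == 0)
    return(list(mean_A = mean(wA), mean_B = mean(wB), p = 1,
                statistic = 0, weights_A = wA, weights_B = wB))
  tt <- t.test(wA, wB)
  list(mean_A = mean(wA), mean_B = mean(wB), p = tt$p.value,
       statistic = unname(tt$statistic), weights_A = wA, weights_B = wB)
}
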