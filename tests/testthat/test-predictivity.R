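# predictivity module

test_that("top pairs: brute-force product ranking, rescale invariance", {
  set.seed(1)
  units <- data.frame(unit_id = 1:12,
                      region = rep(c("A", "B"), each = 6),
                      width_class = "wide", peak_sign = -1L,
                      mean_rate = c(runif(6, 1, 30), runif(6, 1, 30)))
  ps <- top_pairs(units, n = 10)
  # exhaustive oracle
  grid <- expand.grid(a = 1:6, b = 7:12)
  prod <- units$mean_rate[grid$a] * units$mean_rate[grid$b]
  oracle <- grid[order(-prod)[1:10], ]
  expect_equal(ps$a_id, oracle$a)
  expect_equal(ps$b_id, oracle$b)

  units2 <- units; units2$mean_rate <- units2$mean_rate * 3.7
  expect_equal(top_pairs(units2, n = 10)$a_id, ps$a_id)

  # two units only -> a single pair, with warning about the shortfall
  u2 <- units[c(1, 7), ]
  expect_warning(p2 <- top_pairs(u2, n = 10), "eligible")
  expect_equal(nrow(p2), 1)

  # narrow or positive-peak units never enter
  units3 <- units; units3$width_class[1] <- "narrow"
  expect_false(1 %in% top_pairs(units3, n = 10)$a_id)
})

test_that("rate matching: no-op when matched, exact match when possible", {
  units <- data.frame(unit_id = 1:8, region = rep(c("A", "B"), each = 4),
                      width_class = "wide", peak_sign = -1L, session = 1L,
                      mean_rate = rep(c(1.0, 1.3, 2.0, 3.1), 2))
  # identity pairing: per-bin counts already equal, so no swap occurs
  pairs <- data.frame(a_id = 1:4, b_id = 5:8,
                      rate_a = units$mean_rate[1:4],
                      rate_b = units$mean_rate[5:8], session = 1L)
  pairs$product <- pairs$rate_a * pairs$rate_b
  class(pairs) <- c("pair_set", "data.frame")
  matched <- match_rate_distributions(pairs, units, seed = 2)
  expect_equal(attr(matched, "n_swaps"), 0L)

  # mismatch with an available replacement: B cell in a surplus bin swapped
  # into the A cell's bin, achieving an exact per-bin match
  units2 <- data.frame(unit_id = 1:9, region = c(rep("A", 4), rep("B", 5)),
                       width_class = "wide", peak_sign = -1L, session = 1L,
                       mean_rate = c(1.0, 1.3, 2.0, 3.1,
                                     1.0, 1.3, 2.0, 10.0, 3.1))
  pairs2 <- data.frame(a_id = 1:4, b_id = c(5, 6, 7, 8),
                       rate_a = units2$mean_rate[1:4],
                       rate_b = units2$mean_rate[c(5, 6, 7, 8)],
                       session = 1L)
  pairs2$product <- pairs2$rate_a * pairs2$rate_b
  class(pairs2) <- c("pair_set", "data.frame")
  m2 <- match_rate_distributions(pairs2, units2, seed = 3)
  bin <- function(r) floor(log10(r) / 0.05)
  expect_equal(sort(bin(m2$rate_a)), sort(bin(m2$rate_b)))
  expect_gt(attr(m2, "n_swaps"), 0L)
})

test_that("movement epochs: exact boundaries, merge/split rules, error path", {
  env <- rep(0, 5000)
  env[1001:1500] <- 1; env[2001:2600] <- 1
  ep <- movement_epochs(env, quiescent = c(0, 0.01))
  expect_equal(ep$start, c(1001, 2001))
  expect_equal(ep$end, c(1500, 2600))

  # 90 ms dip inside movement merged; 120 ms dip splits
  env2 <- rep(0, 5000)
  env2[1001:1500] <- 1; env2[1591:2000] <- 1       # 90 ms gap
  env2[3001:3400] <- 1; env2[3521:3900] <- 1       # 120 ms gap
  ep2 <- movement_epochs(env2, quiescent = c(0, 0.01))
  expect_equal(nrow(ep2), 3)
  expect_equal(ep2$start[1], 1001); expect_equal(ep2$end[1], 2000)

  # sub-10 ms epochs dropped
  env3 <- rep(0, 3000); env3[501:505] <- 1; env3[1001:1200] <- 1
  ep3 <- movement_epochs(env3, quiescent = c(0, 0.01))
  expect_equal(nrow(ep3), 1)

  expect_error(movement_epochs(rep(0, 3000), quiescent = c(0, 0.01)),
               "no movement")

  # concatenation pads preserve spike counts and zero the seams
  spk <- c(1.05, 1.2, 2.25)
  tr <- concat_movement_train(spk, ep, pad_ms = 50)
  expect_equal(sum(tr), 3)
  expect_equal(length(tr), (500 + 50) + (600 + 50))
})

test_that("transfer entropy: delayed copy, independence, permutation p", {
  set.seed(5)
  n <- 50000
  src <- rbinom(n, 1, 0.05)
  tgt <- c(rep(0L, 7), src[seq_len(n - 7)])
  te <- transfer_entropy(src, tgt)
  expect_equal(te$best_d, 7L)
  h_src <- -(0.05 * log2(0.05) + 0.95 * log2(0.95))
  expect_lt(abs(te$te - h_src) / h_src, 0.05)

  # independent trains: observed TE within 3 SD of its own null
  s2 <- rbinom(n, 1, 0.04); t2 <- rbinom(n, 1, 0.04)
  pp <- circular_perm_pvalue(s2, t2, n = 60, seed = 6)
  expect_lt(abs(pp$observed - mean(pp$null)), 3 * sd(pp$null))
  expect_gt(pp$p, 0.01)

  # strongly coupled pair: no null exceeds the observed value
  pc <- circular_perm_pvalue(src, tgt, n = 60, seed = 7)
  expect_equal(pc$p_raw, 0)

  expect_error(transfer_entropy(integer(100), rbinom(100, 1, 0.5)), "empty")
  expect_error(circular_perm_pvalue(rbinom(4000, 1, 0.1),
                                    rbinom(4000, 1, 0.1), n = 10),
               "shorter")
})

test_that("point-process Granger: true coupling detected, nested null calm", {
  set.seed(6)
  ntr <- 12; nt <- 500
  ens <- array(0L, c(2, nt, ntr))
  for (k in seq_len(ntr)) {
    src <- rbinom(nt, 1, 0.05)
    p <- 0.02 + 0.5 * c(rep(0, 5), src[seq_len(nt - 5)])
    ens[1, , k] <- src
    ens[2, , k] <- rbinom(nt, 1, pmin(p, 0.9))
  }
  g <- pp_granger(ens, target = 2, source = 1, exog_bins = c(20, 25))
  expect_false(g$excluded)
  expect_lt(g$p, 0.01)
  expect_equal(g$df, 30)

  # reverse (uncoupled) direction: statistic within the chi-square bulk
  g0 <- pp_granger(ens, target = 1, source = 2, exog_bins = c(20, 25))
  expect_lt(g0$stat, qchisq(0.999, df = 30))

  # low-rate high-p exclusion keeps ordinary pairs
  res <- data.frame(p = c(0.97, 0.2, 0.98), product = c(0.1, 5, 8))
  keep <- gc_lowrate_exclusion(res, rate_quantile = 0.4)
  expect_equal(keep, c(FALSE, TRUE, TRUE))
})

test_that("simplex projection: sine parsimony, noise, logistic map", {
  set.seed(7)
  x <- sin(2 * pi * seq_len(800) / 50) + rnorm(800, 0, 0.01)
  so <- simplex_optimal_E(x)
  expect_lte(so$E, 3)
  expect_gt(max(so$skill), 0.99)

  wn <- rnorm(600)
  sw <- simplex_optimal_E(wn)
  expect_lt(max(sw$skill, na.rm = TRUE), 0.3)

  # chaotic logistic map: skill high and E small; constant series excluded
  lm <- numeric(800); lm[1] <- 0.3
  for (t in 2:800) lm[t] <- 3.9 * lm[t - 1] * (1 - lm[t - 1])
  sl <- simplex_optimal_E(lm)
  expect_gt(max(sl$skill), 0.95)
  expect_null(simplex_optimal_E(rep(2, 100)))
})

test_that("CCM: self-map skill ~1 at zero delay, independent noise flat", {
  set.seed(8)
  mk_trials <- function(n = 6, len = 700)
    lapply(seq_len(n), function(i) gauss_smooth(abs(rnorm(len)), 10))
  tr <- mk_trials()
  self <- ccm_skill(tr, tr, history_span = 200, n_trials = 6, stride = 4,
                    n_perm = 0, seed = 1)
  # skill ~1 at zero delay (smoothness makes nearby delays nearly tied)
  expect_gt(self$skills_by_delay[["0"]], 0.95)
  expect_gt(self$skill, 0.95)

  other <- mk_trials()
  ind <- ccm_skill(other, tr, history_span = 200, n_trials = 6, stride = 4,
                   n_perm = 0, seed = 2)
  expect_lt(abs(ind$skill), 0.3)

  expect_error(ccm_skill(tr[1], tr[1], history_span = 690, n_trials = 1,
                         K = 40, n_perm = 0),
               "manifold")
})

test_that("false-null fraction: uniform, degenerate, and known mixture", {
  set.seed(9)
  u <- runif(10000)
  expect_lt(abs(false_null_fraction(u)$false_null_fraction), 0.05)

  expect_gt(false_null_fraction(rep(1e-12, 500))$false_null_fraction, 0.95)

  mix <- c(rbeta(3000, 0.08, 8), runif(7000))
  est <- false_null_fraction(mix)$false_null_fraction
  expect_lt(abs(est - 0.30), 0.05)

  # FDR display threshold: monotone in the target rate, zero when hopeless
  p <- c(rbeta(200, 0.05, 5), runif(800))
  expect_gte(fdr_threshold(p, 0.2), fdr_threshold(p, 0.05))
  expect_equal(fdr_threshold(runif(100, 0.9, 1), 0.1), 0)
})
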