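# Reduced rate network: fixed points, RK4 integration, Lyapunov
# machinery, state classification and rate-trajectory statistics.

toy_params <- function(J, n = nrow(J), I_nA = 5.0) {
  rateParams(J, I_exc = rep(I_nA / 66, n), V_E = 66, V_I = -14,
             k_f = 0.107, I_th = 4.513)
}

test_that("the uncoupled model converges to its closed-form fixed point
           and quiescence is absorbing", {
  p <- toy_params(matrix(0, 5, 5))
  fp <- uncoupledFixedPoint(p)
  tr <- integrateRates(p, T_s = 1, transient_s = 10, seed = 1)
  expect_equal(tail(tr$alpha, 1)[1, ], fp, tolerance = 1e-6)
  expect_true(all(abs(rateDerivatives(fp, p)) < 1e-12))
  # all sub-threshold: zero state has zero derivative
  p0 <- toy_params(matrix(0, 3, 3), I_nA = 4.0)
  expect_true(all(rateDerivatives(rep(0, 3), p0) == 0))
  expect_true(all(uncoupledFixedPoint(p0) == 0))
})

test_that("RK4 integration is permutation-equivariant and step-halving
           leaves the fixed-point end state unchanged to 1e-6", {
  J <- matrix(0, 4, 4); J[1, 2] <- 0.01; J[3, 4] <- 0.02
  p <- toy_params(J)
  perm <- c(3, 1, 4, 2)
  p_perm <- rateParams(J[perm, perm], p$I_exc[perm], p$V_E, p$V_I,
                       p$tau_alpha, p$delta_t, p$k_f, p$I_th)
  a0 <- runif(4, 0, 0.1)
  tr <- integrateRates(p, T_s = 2, transient_s = 0, alpha0 = a0)
  trp <- integrateRates(p_perm, T_s = 2, transient_s = 0, alpha0 = a0[perm])
  expect_lt(max(abs(trp$alpha[, order(perm)] - tr$alpha)), 1e-9)
  tr2 <- integrateRates(p, T_s = 2, dt = 0.5, transient_s = 0, alpha0 = a0)
  end1 <- tail(tr$alpha, 1); end2 <- tail(tr2$alpha, 1)
  expect_lt(max(abs(end1 - end2)) / max(end1), 1e-6)
})

test_that("strong mutual inhibition yields a winner-take-all fixed point
           and inhibition is monotone", {
  J <- matrix(c(0, 0.2, 0.2, 0), 2, 2)
  p <- toy_params(J)
  tr <- integrateRates(p, T_s = 5, transient_s = 30, seed = 1)
  end <- tail(tr$alpha, 1)
  expect_equal(sum(end > 1e-6), 1)   # exactly one winner
  # brute-force phase plane: from many starts, always exactly one active
  for (s in 2:6) {
    trs <- integrateRates(p, T_s = 5, transient_s = 30, seed = s)
    expect_equal(sum(tail(trs$alpha, 1) > 1e-6), 1)
  }
  # monotonicity: strengthening J_12 weakly decreases alpha_1*
  Jw <- matrix(c(0, 0.001, 0.001, 0), 2, 2)
  fp_of <- function(j12) {
    Jx <- Jw; Jx[1, 2] <- j12
    px <- toy_params(Jx)
    tail(integrateRates(px, T_s = 2, transient_s = 20,
                        alpha0 = c(0.05, 0.05))$alpha, 1)[1, 1]
  }
  vals <- vapply(c(0.001, 0.003, 0.01), fp_of, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("the Lyapunov estimator is negative on attracting fixed points,
           validated on the chaotic benchmark flow, and a three-cell
           inhibitory ring is classified periodic", {
  p0 <- toy_params(matrix(0, 5, 5))
  lam0 <- maxLyapunov(p0, T_s = 2, transient_s = 5, seed = 1)
  expect_lt(lam0, 0)
  tr0 <- integrateRates(p0, T_s = 2, transient_s = 10, seed = 1)
  expect_equal(classifyState(tr0, lam0), "fixed")
  # benchmark: classical chaotic flow, literature exponent ~0.9056
  lam_l <- lorenzBenchmarkLyapunov()
  expect_lt(abs(lam_l - 0.9056) / 0.9056, 0.05)
  # asymmetric inhibitory ring: a limit cycle, negative exponent but
  # non-vanishing rate variance
  J <- matrix(0, 3, 3); J[2, 1] <- J[3, 2] <- J[1, 3] <- 0.08
  pr <- toy_params(J, I_nA = 5.2)
  trr <- integrateRates(pr, T_s = 20, transient_s = 60, seed = 2)
  lam_r <- maxLyapunov(pr, T_s = 20, transient_s = 60, seed = 2)
  expect_equal(classifyState(trr, lam_r), "periodic")
})

test_that("rate-trajectory statistics: active fraction and relative
           entropy behave as designed at the extremes", {
  p <- toy_params(matrix(0, 6, 6))
  tr <- integrateRates(p, T_s = 1, transient_s = 5, seed = 1)
  expect_equal(activeFractionRates(tr), 1.0)
  psub <- toy_params(matrix(0, 4, 4), I_nA = 4.0)
  trs <- integrateRates(psub, T_s = 1, transient_s = 5,
                        alpha0 = rep(0, 4))
  expect_equal(activeFractionRates(trs), 0.0)
  # identical rate distributions: zero divergence
  tr_same <- tr; tr_same$alpha <- matrix(rep(tr$alpha[, 1], 6), ncol = 6)
  expect_equal(relativeEntropyRates(tr_same)$D_bar, 0, tolerance = 1e-12)
  # disjoint constant rates: the scaled statistic saturates at 8
  tr_disj <- tr
  tr_disj$alpha <- matrix(rep(c(0.05, 0.1, 0.2, 0.4, 0.6, 0.8),
                              each = nrow(tr$alpha)), ncol = 6)
  expect_equal(relativeEntropyRates(tr_disj)$scaled, 8, tolerance = 1e-9)
})

test_that("rate-model parameters assemble from the spiking objects with
           reversal-minus-rest driving forces", {
  cell <- fix_cell(); fi <- fix_fi()
  net <- buildRandomNetwork(networkConfig(N = 20, p = 0.3, seed = 1))
  st <- drawStimulus(driveParams(n_inputs = 500), cell, fi$I_th, 20,
                     seed = 1)
  rp <- rateParamsFromNetwork(net, st, cell, synapseParams(), fi)
  rest <- restingState(cell, 0)$v
  expect_equal(rp$V_E, -rest)
  expect_equal(rp$V_I, synapseParams()$E_inh - rest)
  expect_equal(rp$V_E * rp$I_exc, st$mean_current, tolerance = 1e-12)
  expect_equal(rp$k_f, fi$k_f / 1000)
})
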