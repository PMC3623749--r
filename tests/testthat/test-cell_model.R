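# The two-variable Type-1 cell: activation curves, vector field, rheobase
# location and the square-root f-I law near the SNIC bifurcation.

test_that("steady-state activation is the Boltzmann sigmoid", {
  expect_equal(steadyStateActivation(-25, -25, 5), 0.5)
  expect_equal(steadyStateActivation(-20, -25, 5), 1 / (1 + exp(-1)),
               tolerance = 1e-12)
  expect_equal(steadyStateActivation(1e4, -25, 5), 1)
  expect_equal(steadyStateActivation(-1e4, -25, 5), 0)
  v <- seq(-90, 20, 1)
  expect_true(all(diff(steadyStateActivation(v, -20, 15)) > 0))
  expect_error(steadyStateActivation(NaN, -25, 5), "non-finite")
})

test_that("membrane derivatives vanish at the resting equilibrium and scale
           linearly with conductances and current", {
  cell <- fix_cell()
  rs <- restingState(cell, 0)
  d <- membraneDerivatives(rs, 0, cell)
  expect_lt(max(abs(d)), 1e-8)
  # linearity: scaling all conductances and I by c scales dv/dt by c
  st <- cellState(-55, 0.2)
  c2 <- cellParams(C = cell$C, gL = 3 * cell$gL, gNa = 3 * cell$gNa,
                   gK = 3 * cell$gK)
  d1 <- membraneDerivatives(st, 2, cell)
  d3 <- membraneDerivatives(st, 6, c2)
  expect_equal(d3[["dv"]], 3 * d1[["dv"]], tolerance = 1e-12)
})

test_that("with v clamped, w relaxes exponentially to w_inf with tau_w", {
  cell <- fix_cell()
  v <- -50
  winf <- steadyStateActivation(v, cell$Vw_half, cell$kw)
  w0 <- 0.9
  # exact solution of the linear ODE dw/dt = (winf - w)/tau_w
  t <- 2.5
  w_exact <- winf + (w0 - winf) * exp(-t / cell$tau_w)
  # integrate with small Euler steps at fixed v
  w <- w0
  dt <- 1e-4
  for (k in seq_len(t / dt))
    w <- w + dt * membraneDerivatives(cellState(v, w), 0, cell)[["dw"]]
  expect_equal(w, w_exact, tolerance = 1e-3)
})

test_that("bisection rheobase agrees with a brute-force scan and the
           analytic saddle-node current", {
  cell <- fix_cell()
  tol <- 0.01
  ith <- findRheobase(cell, bracket = c(4.3, 4.8), tol = tol)
  # brute-force scan with step = tol (the independent oracle)
  grid <- seq(4.3, 4.8, by = tol)
  fires <- vapply(grid, function(I)
    length(simulateCell(cell, I, T_s = 4)$spikes) >= 2, logical(1))
  ith_scan <- grid[which(fires)[1]]
  expect_lt(abs(ith - ith_scan), 2 * tol)
  # analytic oracle: local maximum of the steady-state I-V curve
  expect_equal(ith, saddleNodePoint(cell)$I_th, tolerance = 0.02)
  # monotonicity of spiking around threshold
  expect_gte(length(simulateCell(cell, ith + 0.05, T_s = 4)$spikes),
             length(simulateCell(cell, ith - 0.05, T_s = 4)$spikes))
  # bisection contract: shrinking tol changes the estimate by < previous tol
  ith_fine <- findRheobase(cell, bracket = c(4.3, 4.8), tol = tol / 10)
  expect_lt(abs(ith - ith_fine), tol)
  expect_error(findRheobase(cell, bracket = c(6, 8)), "straddle")
})

test_that("f-I curve follows the square-root law of a SNIC bifurcation", {
  cell <- fix_cell()
  fi <- fix_fi()
  s <- fi$samples
  expect_true(all(s$rate[s$I <= fi$I_th] == 0))
  sup <- s$I > fi$I_th
  expect_true(all(diff(s$rate[sup]) > 0))  # monotone above threshold
  pred <- predict(fi, s$I[sup])
  rel <- (pred - s$rate[sup]) / s$rate[sup]
  expect_lt(sqrt(mean(rel^2)), 0.10)
  # log-log slope near threshold ~ 0.5 +/- 0.1
  dI <- c(0.005, 0.01, 0.02, 0.05, 0.1)
  r <- vapply(fi$I_th + dI, function(I)
    firingRate(cell, I, T_s = 12, transient_s = 2), numeric(1))
  slope <- coef(lm(log(r) ~ log(dI)))[[2]]
  expect_gt(slope, 0.4)
  expect_lt(slope, 0.6)
  expect_error(fitFI(cell, I_grid = c(3, 3.5), I_th = fi$I_th), "quiescent")
})

test_that("no bistability: random initial states converge to one rate", {
  cell <- fix_cell()
  rates <- withSeed(7, {
    vapply(1:20, function(k) {
      v0 <- runif(1, -80, -40); w0 <- runif(1, 0, 0.3)
      sp <- simulateCell(cell, 5, T_s = 4, v0 = v0, w0 = w0)$spikes
      sum(sp > 1000) / 3
    }, numeric(1))
  })
  expect_lt(diff(range(rates)) / mean(rates), 0.02)
})

test_that("spike width and f-I curve round-trip through delimited text", {
  w <- measureSpikeWidth(fix_cell())
  expect_gt(w, 0.1); expect_lt(w, 2)
  fi <- fix_fi()
  path <- tempfile(fileext = ".tsv")
  writeFICurve(fi, path)
  df <- readFICurve(path)
  expect_equal(df$I_nA, fi$samples$I)
  expect_equal(df$rate_Hz, fi$samples$rate)
})
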