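# Population statistics: windowed rates, similarity machinery, ISI
# statistics, relative entropy, k-means assemblies, PCA, PSTH variance
# decomposition and spectra.

test_that("sliding-window counts have the right geometry and conserve
           spikes, and Poisson cells give the expected bin mean", {
  sd1 <- structure(list(spikes = list(c(50)), N = 1, T_ms = 200,
                        transient_ms = 0, meta = list()),
                   class = "spike_data")
  R <- binnedRates(sd1, window = 100, step = 10)
  nz <- R$centers[R$rates[1, ] > 0]
  expect_true(all(nz >= 0 & nz <= 100))
  expect_true(all(R$rates[1, R$centers > 100 + 1e-9] == 0))
  # non-overlapping bins conserve the total count
  ps <- poisson_raster(5, rate_hz = 20, T_s = 10, seed = 2)
  Rn <- binnedRates(ps, window = 100, step = 100)
  expect_equal(sum(Rn$rates),
               sum(vapply(ps$spikes, function(s)
                 sum(s >= 50 - 50 & s < max(Rn$centers) + 50), numeric(1))))
  # mean sliding count ~ rate * window
  Rp <- binnedRates(ps, window = 100, step = 10)
  expect_equal(mean(Rp$rates), 20 * 0.1, tolerance = 0.1)
})

test_that("similarity is the cosine overlap: 1 for identical patterns,
           0 for disjoint ones, scale-free, missing for silent bins", {
  R <- list(rates = cbind(c(1, 2, 0), c(2, 4, 0), c(0, 0, 3), c(0, 0, 0)),
            centers = c(10, 20, 30, 40), window = 100, step = 10)
  class(R) <- "rate_matrix"
  expect_equal(similarity(R, 10, 10), 1)
  expect_equal(similarity(R, 10, 20), 1)        # scale invariance
  expect_equal(similarity(R, 10, 30), 0)        # orthogonal patterns
  expect_true(is.na(similarity(R, 10, 40)))     # flagged missing
  S <- similarityMatrix(R)
  ok <- !is.na(S)
  expect_true(all(S[ok] >= 0 & S[ok] <= 1))
  expect_true(isSymmetric(S))
})

test_that("the folded mean similarity matrix averages aligned blocks of a
           periodic pattern and counts folds correctly", {
  # strictly 4 s periodic rates, 40 s long
  centers <- seq(5, 40000, by = 10)
  phase <- (centers %% 4000) < 2000
  rates <- rbind(ifelse(phase, 5, 0), ifelse(phase, 0, 5), 1)
  R <- structure(list(rates = rates, centers = centers, window = 100,
                      step = 10), class = "rate_matrix")
  ms <- meanSimilarityMatrix(R, period = 8, fold = 4)
  expect_equal(ms$n_folds, (ncol(rates) - 800) %/% 400 + 1)
  # exact 4 s block structure: S_bar(t, t + 4 s) == S_bar(t, t)
  i <- 100
  expect_equal(ms$S_bar[i, i + 400], ms$S_bar[i, i], tolerance = 1e-9)
  expect_lt(ms$S_bar[i, i + 200], ms$S_bar[i, i])
  # white-noise rates: off-diagonal entries concentrate near a constant
  # background level, tighter as more folds are averaged
  mkw <- function(nb, seed) {
    structure(list(rates = matrix(withSeed(seed, rpois(20 * nb, 5)), 20),
                   centers = seq_len(nb) * 10, window = 100, step = 10),
              class = "rate_matrix")
  }
  off <- function(R, ...) {
    S <- meanSimilarityMatrix(R, ...)$S_bar
    sd(S[row(S) > col(S) + 50])
  }
  expect_lt(off(mkw(4800, 31)), off(mkw(1200, 32)))
})

test_that("similarity profiles detect a planted stimulus-locked assembly
           sequence and are flat for unstructured rasters", {
  prot <- makeProtocol(c("A", "B"), 2, total_s = 88, transient_s = 4)
  planted <- planted_raster(N = 60, prot, seed = 3)
  R <- binnedRates(planted)
  prof <- similarityProfile(R, E = 200, prot)
  sm <- summariseProfile(prof)
  expect_gt(sm$P_minus_B, 0.05)   # reproducible onset-locked trajectory
  expect_gt(sm$B_minus_D, 0.05)   # the two stimuli are distinguishable
  # the peak is at lag 4 s: the same epoch in the next presentation
  lag_peak <- prof$lag_ms[which.max(
    prof$mean * (prof$lag_ms > 3000 & prof$lag_ms < 5000))]
  expect_lt(abs(lag_peak - 4000), 300)
  # stationary stimulus-independent rates: no structure
  flat <- poisson_raster(60, 8, T_s = 88, seed = 4, transient_s = 4)
  smf <- summariseProfile(similarityProfile(binnedRates(flat), 200, prot))
  expect_lt(abs(smf$P_minus_B), 0.02)
  expect_lt(abs(smf$B_minus_D), 0.02)
  # "two" stimuli defined identically: distinguishability vanishes
  cell <- fix_cell(); fi <- fix_fi()
  net <- buildRandomNetwork(networkConfig(N = 60, p = 0.18, n_ref = 300,
                                          seed = 13))
  sA <- drawStimulus(driveParams(n_inputs = 2000), cell, fi$I_th, 60,
                     id = "A", seed = 14)
  sB <- sA; sB$id <- "B"
  prot44 <- makeProtocol(c("A", "B"), 2, total_s = 44, transient_s = 4)
  simAB <- runNetwork(net, cell, synapseParams(), driveParams(),
                      list(sA, sB), prot44,
                      simConfig(T_s = 44, transient_s = 4, seed = 15))
  Ri <- binnedRates(simAB)
  Ri$rates <- Ri$rates[activeCells(simAB, 1), , drop = FALSE]
  smi <- summariseProfile(similarityProfile(Ri, 200, prot44))
  expect_lt(abs(smi$B_minus_D), 0.05)
  expect_error(similarityProfile(R, 200, makeProtocol(c("A", "B"), 2, 10, 1)),
               "fewer than 3")
})

test_that("ISI statistics: periodic trains have CV 0, Poisson trains CV 1,
           and merged periodic trains expose the smallest gap", {
  per <- structure(list(spikes = list(seq(0, 1e5, by = 100)), N = 1,
                        T_ms = 1e5, transient_ms = 0, meta = list()),
                   class = "spike_data")
  expect_equal(isiStats(per)$per_cell$cv[1], 0)
  # homogeneous Poisson, ~1e4 spikes: exponential ISIs, CV = 1
  pois <- poisson_raster(1, rate_hz = 100, T_s = 100, seed = 5)
  ist <- isiStats(pois)
  expect_equal(ist$per_cell$cv[1], 1, tolerance = 0.03)
  merged <- structure(list(
    spikes = list(sort(c(seq(0, 1000, 100), seq(33, 1033, 100)))),
    N = 1, T_ms = 1100, transient_ms = 0, meta = list()),
    class = "spike_data")
  expect_equal(isiStats(merged)$per_cell$min_isi[1], 33)
  # cells with < 3 spikes are excluded but flagged
  sparse <- structure(list(spikes = list(c(10, 20), numeric(0)), N = 2,
                           T_ms = 100, transient_ms = 0, meta = list()),
                      class = "spike_data")
  ps <- isiStats(sparse)$per_cell
  expect_true(is.na(ps$cv[1]))
  expect_equal(ps$active1, c(TRUE, FALSE))
  expect_equal(ps$active3, c(FALSE, FALSE))
})

test_that("relative entropy is zero for identical count distributions,
           log(N_act) for disjoint ones, and never negative", {
  mk <- function(rates) {
    structure(list(rates = rates, centers = seq_len(ncol(rates)) * 10,
                   window = 100, step = 10), class = "rate_matrix")
  }
  same <- mk(matrix(rep(c(1, 2, 3, 4), 5), nrow = 5, byrow = TRUE))
  re <- relativeEntropy(same)
  expect_equal(re$D_bar, 0, tolerance = 1e-12)
  disj <- mk(matrix(rep(c(10, 20, 30, 40, 50), times = 8), nrow = 5))
  red <- relativeEntropy(disj)
  expect_equal(red$D_bar, log(5), tolerance = 1e-9)
  expect_equal(red$scaled, 8, tolerance = 1e-9)
  rnd <- mk(matrix(withSeed(6, rpois(5 * 200, 5)), nrow = 5))
  expect_true(all(relativeEntropy(rnd)$D >= 0))
})

test_that("k-means assembly detection recovers planted anticorrelated
           groups, drops empty clusters and reaches a fixed point", {
  # two perfectly anti-correlated groups: correlation rows are exactly
  # +/- the same vector, so surplus duplicate centroids empty out and the
  # plant is recovered exactly
  set.seed(8)
  x <- rnorm(400)
  A <- rbind(matrix(rep(x, 6), nrow = 6, byrow = TRUE),
             matrix(rep(-x, 6), nrow = 6, byrow = TRUE))
  C <- cor(t(A))
  km <- kmeansAssemblies(C, K0 = 8, seed = 2)
  expect_lte(km$K, 8)
  expect_true(km$converged)
  expect_equal(km$K, 2)
  expect_equal(length(unique(km$labels[1:6])), 1)
  expect_equal(length(unique(km$labels[7:12])), 1)
  expect_false(km$labels[1] == km$labels[7])
  # the stock Lloyd implementation agrees on this well-separated plant
  ref <- kmeans(C, centers = C[c(1, 7), ], algorithm = "Lloyd")
  expect_equal(length(unique(paste(km$labels, ref$cluster))), 2)
  # convergence is a fixed point: reassignment changes nothing
  d2 <- outer(rowSums(C^2), rowSums(km$centroids^2), "+") -
    2 * C %*% t(km$centroids)
  expect_equal(max.col(-d2, ties.method = "first"), km$labels)
})

test_that("principal components satisfy the trace identity, are mutually
           uncorrelated, and catch a planted one-dimensional modulation", {
  ps <- poisson_raster(12, 10, T_s = 60, seed = 9)
  R <- binnedRates(ps)
  pc <- pcaComponents(R)
  expect_equal(sum(pc$eigenvalues), nrow(pc$eigenvectors))
  cc <- cor(pc$ts[, 1:5])
  expect_lt(max(abs(cc[upper.tri(cc)])), 1e-8)
  expect_true(all(diff(pc$eigenvalues) <= 1e-12))
  # planted shared modulation: first component dominates
  centers <- seq(55, 60000 - 50, by = 10)
  mod <- 3 + 2 * sin(2 * pi * centers / 5000)
  rates <- t(vapply(1:12, function(i)
    mod * (0.5 + i / 12) + 0.05 * rnorm(length(centers)), numeric(length(centers))))
  Rm <- structure(list(rates = rates, centers = centers, window = 100,
                       step = 10), class = "rate_matrix")
  pcm <- pcaComponents(Rm)
  expect_gt(pcm$eigenvalues[1] / sum(pcm$eigenvalues), 0.9)
})

test_that("PSTH decomposition: zero noise for deterministic repeats, near
           zero signal for pure noise, variances add on planted data", {
  prot <- makeProtocol(c("A", "B"), 2, total_s = 88, transient_s = 4)
  step <- 10
  centers <- seq(4000 + 50, 88000 - 50, by = step)
  template <- function(t_in) sin(2 * pi * t_in / 4000)
  det <- template(centers %% 4000)
  comps <- structure(list(ts = cbind(det), centers = centers, step = step),
                     class = "component_set")
  cp <- componentPsth(comps, prot, 1)
  expect_equal(cp$noise_variance, 0, tolerance = 1e-20)
  expect_gt(cp$psth_variance, 0)
  # pure iid noise: the PSTH averages away, the ratio collapses
  noise <- withSeed(11, rnorm(length(centers)))
  cn <- componentPsth(structure(list(ts = cbind(noise), centers = centers,
                                     step = step), class = "component_set"),
                      prot, 1)
  expect_lt(cn$ratio, 0.3)
  # signal + noise: law of total variance within estimator bias
  sn <- det + noise * 0.5
  cs <- componentPsth(structure(list(ts = cbind(sn), centers = centers,
                                     step = step), class = "component_set"),
                      prot, 1)
  expect_equal(cs$psth_variance + cs$noise_variance,
               cp$psth_variance + 0.25, tolerance = 0.15)
})

test_that("spectra: a sinusoid peaks at its frequency, white noise is
           flat, integrated noise falls off with slope two", {
  step <- 10
  t_ms <- seq(0, 2e5, by = step)
  x <- sin(2 * pi * 0.25 * t_ms / 1000)
  ps <- componentPsd(x, step = step, seg_s = 64)
  expect_equal(psdPeak(ps, f_max = 1), 0.25, tolerance = 0.02)
  wn <- withSeed(12, rnorm(2e4))
  expect_lt(abs(bandSlope(componentPsd(wn, step = step), c(0.5, 5))), 0.1)
  rw <- cumsum(withSeed(13, rnorm(2e4)))
  slope_rw <- bandSlope(componentPsd(rw, step = step), c(0.5, 5))
  expect_equal(slope_rw, 2, tolerance = 0.2)
  expect_error(bandSlope(componentPsd(wn, step = step), c(1e-6, 2e-6)),
               "resolvable")
})
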