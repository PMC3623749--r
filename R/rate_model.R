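# Reduced deterministic rate model: the neurotransmitter variables become
# rate proxies, dalpha_i/dt = -alpha_i/tau + delta_t * f(I_i) with the
# Type-1 square-root transfer f(I) = k_f sqrt(I - I_th) above threshold and
# I_i = V_E I_exc_i + V_I sum_j J_ij alpha_j.  RK4 integration, maximal
# Lyapunov exponent by the two-trajectory renormalisation method, and
# fixed / periodic / chaotic classification.

#' Reduced rate-model parameters
#'
#' `V_E` and `V_I` are fixed scalar driving-force surrogates for the
#' conductance-based synapses, set as the differences between the resting
#' potential and the excitatory / inhibitory reversal potentials; `k_f` and
#' `I_th` come from the fitted f-I curve of the spiking cell, and `delta_t`
#' is its empirical spike width.  Use [rateParamsFromNetwork()] to assemble
#' all of this from the spiking-model objects.
#'
#' @param J N x N inhibitory weight matrix (rows = postsynaptic).
#' @param I_exc per-cell excitatory drive (conductance-sum units such that
#'   `V_E * I_exc` is the noise-free mean current in nA).
#' @param V_E,V_I driving-force surrogates (mV); opposite signs required.
#' @param tau_alpha neurotransmitter timescale (ms).
#' @param delta_t spike width (ms).
#' @param k_f transfer gain (spikes/ms per sqrt(nA)).
#' @param I_th rheobase (nA).
#' @return an object of class `rate_params`.
#' @export
rateParams <- function(J, I_exc, V_E, V_I, tau_alpha = 38, delta_t = 0.4,
                       k_f = 0.12, I_th = 4.51) {
  J <- as.matrix(J)
  stopifnot(nrow(J) == ncol(J), length(I_exc) == nrow(J),
            delta_t > 0, tau_alpha > 0, V_I < 0, V_E > 0)
  structure(list(J = J, I_exc = I_exc, V_E = V_E, V_I = V_I,
                 tau_alpha = tau_alpha, delta_t = delta_t,
                 k_f = k_f, I_th = I_th),
            class = "rate_params")
}

#' @export
print.rate_params <- function(x, ...) {
  cat(sprintf("rate_params: N = %d, V_E = %.1f mV, V_I = %.1f mV, tau = %g ms, delta_t = %g ms, k_f = %g sp/ms/sqrt(nA), I_th = %.3f nA\n",
              nrow(x$J), x$V_E, x$V_I, x$tau_alpha, x$delta_t, x$k_f, x$I_th))
  invisible(x)
}

#' Assemble rate-model parameters from the spiking-model objects
#'
#' @param network a `connectivity`.
#' @param stimulus a `stimulus` (noise-free means are used).
#' @param cell a [cellParams()].
#' @param syn a [synapseParams()].
#' @param fi an `fi_curve` from [fitFI()] (gain converted from Hz to
#'   spikes/ms).
#' @param delta_t spike width (ms); default measured from the cell model.
#' @return a `rate_params`.
#' @export
rateParamsFromNetwork <- function(network, stimulus, cell, syn, fi,
                                  delta_t = NULL) {
  if (is.null(delta_t)) delta_t <- measureSpikeWidth(cell)
  rest <- restingState(cell, 0)$v
  V_E <- 0 - rest          # excitatory reversal minus rest
  V_I <- syn$E_inh - rest  # inhibitory reversal minus rest
  rateParams(J = network$weights, I_exc = stimulus$mean_current / V_E,
             V_E = V_E, V_I = V_I, tau_alpha = syn$tau_alpha,
             delta_t = delta_t, k_f = fi$k_f / 1000, I_th = fi$I_th)
}

#' Rate-model vector field
#'
#' `dalpha_i/dt = -alpha_i/tau_alpha + delta_t * f(I_i)` with
#' `I_i = V_E I_exc_i + V_I (J alpha)_i` and the rectified square-root
#' transfer; the rectification makes the nonnegative orthant forward
#' invariant.
#'
#' @param alpha nonnegative state vector.
#' @param params a `rate_params`.
#' @return the derivative vector (1/ms).
#' @export
rateDerivatives <- function(alpha, params) {
  p <- params
  I <- p$V_E * p$I_exc + p$V_I * drop(p$J %*% alpha)
  f <- ifelse(I > p$I_th, p$k_f * sqrt(pmax(I - p$I_th, 0)), 0)
  -alpha / p$tau_alpha + p$delta_t * f
}

#' Closed-form fixed point of the uncoupled (J = 0) rate model
#'
#' @param params a `rate_params` (its `J` is ignored).
#' @return the fixed-point alpha vector
#'   `tau_alpha * delta_t * f(V_E * I_exc)`.
#' @export
uncoupledFixedPoint <- function(params) {
  p <- params
  I <- p$V_E * p$I_exc
  f <- ifelse(I > p$I_th, p$k_f * sqrt(pmax(I - p$I_th, 0)), 0)
  p$tau_alpha * p$delta_t * f
}

#' Integrate the rate model with classical RK4
#'
#' @param params a `rate_params`.
#' @param T_s post-transient integration time (s).
#' @param dt step (ms), at most 1 ms.
#' @param transient_s discarded transient (s).
#' @param alpha0 initial state; default small uniform random values (seeded).
#' @param sample_every keep every this-many-steps sample.
#' @param seed seed for the default initial state.
#' @return an object of class `rate_trajectory`: `alpha` (samples x N),
#'   `t_ms`, `dt`, and the parameters.
#' @export
integrateRates <- function(params, T_s = 10, dt = 1, transient_s = 100,
                           alpha0 = NULL, sample_every = 1, seed = 1) {
  stopifnot(dt <= 1, dt > 0)
  N <- nrow(params$J)
  if (is.null(alpha0))
    alpha0 <- withSeed(seed, runif(N, 0, 0.1))
  ntrans <- round(transient_s * 1000 / dt)
  if (ntrans > 0) {
    tr <- cpp_rate_integrate(params$J, params$I_exc, params$V_E, params$V_I,
                             params$tau_alpha, params$delta_t, params$k_f,
                             params$I_th, alpha0, dt, ntrans, ntrans)
    alpha0 <- tr[nrow(tr), ]
  }
  nsteps <- round(T_s * 1000 / dt)
  out <- cpp_rate_integrate(params$J, params$I_exc, params$V_E, params$V_I,
                            params$tau_alpha, params$delta_t, params$k_f,
                            params$I_th, alpha0, dt, nsteps,
                            as.integer(sample_every))
  structure(list(alpha = out,
                 t_ms = seq_len(nrow(out)) * dt * sample_every,
                 dt = dt, params = params),
            class = "rate_trajectory")
}

#' @export
print.rate_trajectory <- function(x, ...) {
  cat(sprintf("rate_trajectory: %d samples x %d cells, dt = %g ms\n",
              nrow(x$alpha), ncol(x$alpha), x$dt))
  invisible(x)
}

#' Maximal Lyapunov exponent of the rate dynamics
#'
#' Two-trajectory method: after the transient, a companion trajectory
#' offset by `d0` in a random direction is co-integrated and the separation
#' renormalised every `renorm_interval`; the exponent is the time-averaged
#' log stretch rate.
#'
#' @param params a `rate_params`.
#' @param T_s averaging time (s).
#' @param dt step (ms); 0.1 ms for exponent runs.
#' @param renorm_interval renormalisation interval (ms).
#' @param transient_s transient integrated at 1 ms before the estimate.
#' @param d0 perturbation size.
#' @param seed seed for the initial state and perturbation direction.
#' @return exponent (1/s).
#' @export
maxLyapunov <- function(params, T_s = 10, dt = 0.1, renorm_interval = 1,
                        transient_s = 30, d0 = 1e-6, seed = 1) {
  N <- nrow(params$J)
  alpha0 <- withSeed(seed, runif(N, 0, 0.1))
  ntrans <- round(transient_s * 1000)
  if (ntrans > 0) {
    tr <- cpp_rate_integrate(params$J, params$I_exc, params$V_E, params$V_I,
                             params$tau_alpha, params$delta_t, params$k_f,
                             params$I_th, alpha0, 1, ntrans, ntrans)
    alpha0 <- tr[nrow(tr), ]
  }
  nsteps <- round(T_s * 1000 / dt)
  lam_ms <- withSeed(substreamSeed(seed, "lyapunov"),
    cpp_rate_lyapunov(params$J, params$I_exc, params$V_E, params$V_I,
                      params$tau_alpha, params$delta_t, params$k_f,
                      params$I_th, alpha0, dt, nsteps,
                      max(1L, as.integer(round(renorm_interval / dt))), d0))
  lam_ms * 1000
}

#' Classify the dynamical state of a rate trajectory
#'
#' Chaotic iff the exponent exceeds `tol`; among non-chaotic trajectories,
#' fixed iff the mean per-cell rate variance is below `var_tol` times the
#' squared mean rate, else periodic.
#'
#' @param traj a `rate_trajectory` (post-transient).
#' @param exponent maximal Lyapunov exponent (1/s).
#' @param tol chaos threshold (1/s).
#' @param var_tol relative variance threshold for a fixed point.
#' @return one of `"fixed"`, `"periodic"`, `"chaotic"`.
#' @export
classifyState <- function(traj, exponent, tol = 1e-3, var_tol = 1e-6) {
  if (exponent > tol) return("chaotic")
  v <- mean(apply(traj$alpha, 2, var))
  m <- mean(traj$alpha)
  if (v <= var_tol * max(m^2, .Machine$double.eps)) "fixed" else "periodic"
}

#' Fraction of active cells in a rate trajectory
#'
#' A cell is active if its rate proxy ever exceeds `rate_floor` after the
#' transient.
#'
#' @param traj a `rate_trajectory`.
#' @param rate_floor small positive floor (same units as alpha).
#' @return fraction in `[0, 1]`.
#' @export
activeFractionRates <- function(traj, rate_floor = 1e-4) {
  mean(apply(traj$alpha, 2, max) > rate_floor)
}

#' Relative entropy of per-cell rate distributions in a rate trajectory
#'
#' The rate-model analogue of [relativeEntropy()]: per-cell distributions
#' of sampled rates over 500 bins spanning zero to just above the observed
#' maximum, against the pooled distribution of all active cells; quiescent
#' cells are excluded.
#'
#' @param traj a `rate_trajectory`.
#' @param rate_floor activity floor as in [activeFractionRates()].
#' @param nbins number of bins.
#' @return list with per-cell `D`, `D_bar`, `n_active` and the scaled
#'   statistic `8 * D_bar / log(n_active)`.
#' @export
relativeEntropyRates <- function(traj, rate_floor = 1e-4, nbins = 500) {
  act <- apply(traj$alpha, 2, max) > rate_floor
  n_act <- sum(act)
  if (n_act < 1) stop("no active cells")
  X <- traj$alpha[, act, drop = FALSE]
  brks <- seq(0, max(X) * 1.01, length.out = nbins + 1)
  pm <- matrix(0, nbins, n_act)
  for (j in seq_len(n_act)) {
    h <- tabulate(findInterval(X[, j], brks, all.inside = TRUE), nbins)
    pm[, j] <- h / sum(h)
  }
  q <- rowMeans(pm)
  D <- apply(pm, 2, function(p) {
    s <- p > 0
    sum(p[s] * log(p[s] / q[s]))
  })
  D_bar <- mean(D)
  list(D = D, D_bar = D_bar, n_active = n_act,
       scaled = if (n_act > 1) 8 * D_bar / log(n_act) else 0)
}

#' Lyapunov exponent of the Lorenz benchmark flow
#'
#' Runs the package's two-trajectory renormalisation estimator on the
#' classical three-variable chaotic benchmark (sigma = 10, rho = 28,
#' beta = 8/3, literature exponent about 0.9056), validating the
#' estimator machinery.
#'
#' @param T_total averaging time (model time units).
#' @param dt RK4 step.
#' @param renorm_every steps between renormalisations.
#' @param d0 perturbation size.
#' @param T_transient discarded transient.
#' @return the estimated exponent.
#' @export
lorenzBenchmarkLyapunov <- function(T_total = 300, dt = 0.005,
                                    renorm_every = 20, d0 = 1e-8,
                                    T_transient = 20) {
  cpp_lorenz_lyapunov(10, 28, 8 / 3, T_total, dt, renorm_every, d0,
                      T_transient)
}
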