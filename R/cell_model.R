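# Two-dimensional Type-1 MSN model: leak + instantaneous persistent Na+ +
# slower persistent K+ current, parameterised near a saddle-node on
# invariant circle (SNIC) bifurcation so that firing frequency goes to zero
# at rheobase and there is no spiking/quiescent bistability.

#' Membrane parameters of the Type-1 MSN model
#'
#' Defaults are the canonical persistent-sodium + potassium Type-1
#' (SNIC-regime) parameter set: an instantaneous Na+ activation and a
#' relatively slower K+ activation.  With these values the rheobase is
#' approximately 4.51 nA (see [findRheobase()]) and the cell fires at
#' arbitrarily low rates just above it.
#'
#' @param C membrane capacitance (uF).
#' @param gL,gNa,gK maximal conductances (mS); all must be positive.
#' @param EL,ENa,EK reversal potentials (mV); `EK < EL < ENa` is required.
#' @param Vm_half,km Na-activation sigmoid midpoint and slope (mV).
#' @param Vw_half,kw K-activation sigmoid midpoint and slope (mV).
#' @param tau_w K-activation time constant (ms).
#' @return an object of class `cell_params`.
#' @export
#' @examples
#' p <- cellParams()
#' membraneDerivatives(cellState(-66, 0), I = 0, p)
cellParams <- function(C = 1, gL = 8, gNa = 20, gK = 10,
                       EL = -80, ENa = 60, EK = -90,
                       Vm_half = -20, km = 15,
                       Vw_half = -25, kw = 5, tau_w = 1) {
  stopifnot(C > 0, gL > 0, gNa > 0, gK > 0, tau_w > 0, km > 0, kw > 0,
            EK < EL, EL < ENa)
  structure(list(C = C, gL = gL, gNa = gNa, gK = gK,
                 EL = EL, ENa = ENa, EK = EK,
                 Vm_half = Vm_half, km = km,
                 Vw_half = Vw_half, kw = kw, tau_w = tau_w),
            class = "cell_params")
}

#' @export
print.cell_params <- function(x, ...) {
  cat("Type-1 MSN cell parameters (SNIC regime)\n")
  cat(sprintf("  C = %g uF; gL = %g, gNa = %g, gK = %g mS\n",
              x$C, x$gL, x$gNa, x$gK))
  cat(sprintf("  EL = %g, ENa = %g, EK = %g mV\n", x$EL, x$ENa, x$EK))
  cat(sprintf("  m_inf: half %g mV, slope %g mV; w_inf: half %g mV, slope %g mV; tau_w = %g ms\n",
              x$Vm_half, x$km, x$Vw_half, x$kw, x$tau_w))
  invisible(x)
}

# flat named vector for the compiled integrators
cellParVector <- function(params) {
  unlist(params[c("C", "gL", "EL", "gNa", "ENa", "gK", "EK",
                  "Vm_half", "km", "Vw_half", "kw", "tau_w")])
}

#' Cell state (membrane potential, K-activation)
#'
#' @param v membrane potential (mV).
#' @param w K-channel activation in `[0, 1]`.
#' @return an object of class `cell_state`.
#' @export
cellState <- function(v, w) {
  stopifnot(is.finite(v), w >= 0, w <= 1)
  structure(list(v = v, w = w), class = "cell_state")
}

#' Boltzmann steady-state activation curve
#'
#' `1 / (1 + exp((V_half - v) / k))`: the sigmoid describing both the Na and
#' K steady-state activations.
#'
#' @param v membrane potential (mV); must be finite.
#' @param V_half midpoint (mV).
#' @param k slope (mV), positive.
#' @return activation in `(0, 1)`, strictly increasing in `v`.
#' @export
#' @examples
#' steadyStateActivation(-25, -25, 5)  # 0.5 at the midpoint
steadyStateActivation <- function(v, V_half, k) {
  stopifnot(k > 0)
  if (any(!is.finite(v))) stop("non-finite membrane potential")
  1 / (1 + exp((V_half - v) / k))
}

#' Membrane vector field of the two-dimensional cell model
#'
#' @param state a [cellState()].
#' @param I input current (nA).
#' @param params a [cellParams()].
#' @return named numeric vector `c(dv, dw)` in mV/ms and 1/ms.
#' @export
membraneDerivatives <- function(state, I, params) {
  p <- params
  v <- state$v; w <- state$w
  if (!is.finite(v) || !is.finite(I)) stop("non-finite input")
  m <- steadyStateActivation(v, p$Vm_half, p$km)
  winf <- steadyStateActivation(v, p$Vw_half, p$kw)
  dv <- (-p$gL * (v - p$EL) - p$gNa * m * (v - p$ENa) -
           p$gK * w * (v - p$EK) + I) / p$C
  dw <- (winf - w) / p$tau_w
  c(dv = dv, dw = dw)
}

# steady-state current needed to hold the membrane at v (w = w_inf(v))
steadyStateCurrent <- function(v, params) {
  p <- params
  p$gL * (v - p$EL) +
    p$gNa * steadyStateActivation(v, p$Vm_half, p$km) * (v - p$ENa) +
    p$gK * steadyStateActivation(v, p$Vw_half, p$kw) * (v - p$EK)
}

#' Resting state of the cell at a given holding current
#'
#' Locates the stable low-voltage equilibrium (below the saddle-node
#' voltage).  Errors if the holding current is at or above rheobase, where
#' no such equilibrium exists.
#'
#' @param params a [cellParams()].
#' @param I holding current (nA).
#' @return a [cellState()] at equilibrium.
#' @export
restingState <- function(params, I = 0) {
  sn <- saddleNodePoint(params)
  if (I >= sn$I_th) stop("no resting equilibrium: I at or above rheobase")
  f <- function(v) I - steadyStateCurrent(v, params)
  r <- uniroot(f, lower = params$EK, upper = sn$v_sn, tol = 1e-10)
  cellState(r$root, steadyStateActivation(r$root, params$Vw_half, params$kw))
}

#' Saddle-node (rheobase) point from the steady-state I-V curve
#'
#' The equilibria satisfy `I = I_ss(v)`; the local maximum of `I_ss` below
#' the spike region is the saddle-node current (the analytic rheobase) and
#' its argument the saddle-node voltage.  Serves as an independent check on
#' the simulation-based [findRheobase()] and as the reference voltage at
#' which the excitatory drive is calibrated.
#'
#' @param params a [cellParams()].
#' @return list with `I_th` (nA) and `v_sn` (mV).
#' @export
saddleNodePoint <- function(params) {
  op <- optimize(function(v) steadyStateCurrent(v, params),
                 lower = params$EL + 2, upper = -40, maximum = TRUE,
                 tol = 1e-8)
  list(I_th = op$objective, v_sn = op$maximum)
}

#' Simulate a single isolated cell at constant current
#'
#' Deterministic Heun integration of the two-variable model; spikes are
#' upward crossings of 0 mV located by linear interpolation and stored at
#' 0.01 ms resolution (the model self-repolarises, no reset is applied).
#'
#' @param params a [cellParams()].
#' @param I constant input current (nA).
#' @param T_s simulated time (s).
#' @param dt time step (ms).
#' @param v0,w0 initial state (defaults: resting state at `I = 0`).
#' @param record_every record the voltage trace every this many steps
#'   (0 = no trace).
#' @return list with `spikes` (ms), `widths` (ms above 0 mV per spike),
#'   optional `t`/`v`/`w` trace, and final state.
#' @export
simulateCell <- function(params, I, T_s = 5, dt = 0.02,
                         v0 = NULL, w0 = NULL, record_every = 0) {
  if (is.null(v0)) {
    rs <- restingState(params, 0)
    v0 <- rs$v; w0 <- rs$w
  }
  cpp_cell_sim(cellParVector(params), I, dt, T_s * 1000, v0, w0,
               0, -80, 50, -1, 0, record_every)
}

#' Locate the rheobase current by bisection on spiking
#'
#' Bisects "does a `T_s`-second simulation at current I produce at least two
#' spikes" within `bracket`, which must straddle the quiescent-to-spiking
#' change.
#'
#' @param params a [cellParams()].
#' @param bracket length-2 numeric current interval (nA).
#' @param tol bisection tolerance (nA).
#' @param T_s probe simulation length (s).
#' @param dt time step (ms).
#' @return rheobase estimate `I_th` (nA).
#' @export
findRheobase <- function(params, bracket = c(3, 6), tol = 1e-3,
                         T_s = 4, dt = 0.02) {
  fires <- function(I) {
    length(simulateCell(params, I, T_s = T_s, dt = dt)$spikes) >= 2
  }
  lo <- bracket[1]; hi <- bracket[2]
  if (fires(lo) || !fires(hi))
    stop("bracket does not straddle the quiescent-to-spiking transition")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (fires(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Measure the steady firing rate at a constant current
#'
#' Discards a transient (SNIC rates near threshold settle slowly) and
#' counts spikes over the remainder.
#'
#' @inheritParams simulateCell
#' @param transient_s discarded initial period (s).
#' @return firing rate (Hz).
#' @export
firingRate <- function(params, I, T_s = 6, transient_s = 1, dt = 0.02) {
  sp <- simulateCell(params, I, T_s = T_s, dt = dt)$spikes
  sum(sp > transient_s * 1000) / (T_s - transient_s)
}

#' Fit the square-root f-I law of the Type-1 cell
#'
#' Simulates each grid current, measures the steady rate after a transient,
#' and least-squares fits `rate = k_f * sqrt(I - I_th)` on the
#' supra-threshold points.  Near a SNIC bifurcation this is the leading
#' behaviour of the firing rate, so the grid should stay near threshold.
#'
#' @param params a [cellParams()].
#' @param I_grid currents (nA) spanning sub- and supra-threshold values.
#' @param T_s,transient_s,dt rate-measurement settings per grid point.
#' @param I_th optional rheobase; located with [findRheobase()] if `NULL`.
#' @return an object of class `fi_curve`: `I_th`, `k_f`
#'   (Hz per sqrt(nA)) and the `(I, rate)` samples.
#' @export
fitFI <- function(params, I_grid = NULL, T_s = 6, transient_s = 1,
                  dt = 0.02, I_th = NULL) {
  if (is.null(I_th)) I_th <- findRheobase(params, dt = dt)
  if (is.null(I_grid)) I_grid <- I_th + c(-0.2, -0.05, seq(0.02, 0.32, 0.05))
  rate <- vapply(I_grid, function(I)
    firingRate(params, I, T_s = T_s, transient_s = transient_s, dt = dt),
    numeric(1))
  supra <- I_grid > I_th & rate > 0
  if (!any(supra)) stop("all grid points quiescent: cannot fit f-I curve")
  x <- sqrt(I_grid[supra] - I_th)
  k_f <- sum(rate[supra] * x) / sum(x^2)
  structure(list(I_th = I_th, k_f = k_f,
                 samples = data.frame(I = I_grid, rate = rate)),
            class = "fi_curve")
}

#' @export
print.fi_curve <- function(x, ...) {
  cat(sprintf("f-I curve: I_th = %.4f nA, k_f = %.2f Hz/sqrt(nA), %d samples\n",
              x$I_th, x$k_f, nrow(x$samples)))
  invisible(x)
}

#' Predict the firing rate from a fitted f-I curve
#'
#' @param object an `fi_curve`.
#' @param I currents (nA).
#' @param ... unused.
#' @return rates (Hz); zero at and below threshold.
#' @export
predict.fi_curve <- function(object, I, ...) {
  ifelse(I > object$I_th, object$k_f * sqrt(pmax(I - object$I_th, 0)), 0)
}

#' Measure the spike width of the cell model
#'
#' The time the membrane potential stays above 0 mV during a spike; this is
#' the effective neurotransmitter release duration of the Rall synapse and
#' the `delta_t` of the reduced rate model.
#'
#' @param params a [cellParams()].
#' @param I supra-threshold probe current (nA).
#' @param T_s,dt simulation settings.
#' @return mean spike width (ms).
#' @export
measureSpikeWidth <- function(params, I = 5.5, T_s = 3, dt = 0.01) {
  w <- simulateCell(params, I, T_s = T_s, dt = dt)$widths
  if (!length(w)) stop("probe current produced no spikes")
  mean(w)
}

#' Write / read an f-I curve as two-column delimited text
#'
#' @param fi an `fi_curve`.
#' @param path file path.
#' @return `readFICurve` returns a data.frame with columns `I_nA`, `rate_Hz`.
#' @export
writeFICurve <- function(fi, path) {
  data.table::fwrite(data.frame(I_nA = fi$samples$I, rate_Hz = fi$samples$rate),
                     path, sep = "\t")
  invisible(path)
}

#' @rdname writeFICurve
#' @export
readFICurve <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t"))
}
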