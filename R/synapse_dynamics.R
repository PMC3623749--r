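# Rall-type inhibitory synapse: one bound-neurotransmitter variable alpha
# per presynaptic cell, forced by a Heaviside function of the presynaptic
# voltage and decaying with timescale tau_alpha; the inhibitory current is
# conductance-based, sum_j g_ij alpha_j (E_inh - v_i).

#' Inhibitory synapse parameters
#'
#' The default `tau_alpha` of 38 ms makes the postsynaptically bound
#' neurotransmitter (and hence the modelled IPSP, whose membrane filtering
#' is fast by comparison) recover with a half-life of about 35 ms, the
#' middle of the experimentally reported 30-40 ms range.  A "fast" preset at
#' one third of that value is available via [synapseParamsFast()] to mirror
#' robustness checks at shorter neurotransmitter timescales.  The release
#' threshold equals the spike-detection threshold (0 mV) so a release event
#' is exactly a detected spike.
#'
#' @param tau_alpha neurotransmitter decay timescale (ms).
#' @param v_release presynaptic release threshold (mV).
#' @param E_inh inhibitory reversal potential (mV); must sit below the
#'   firing-threshold voltage so inhibition hyperpolarises near-threshold
#'   cells.
#' @return an object of class `synapse_params`.
#' @export
synapseParams <- function(tau_alpha = 38, v_release = 0, E_inh = -80) {
  stopifnot(tau_alpha > 0, E_inh < -45)
  structure(list(tau_alpha = tau_alpha, v_release = v_release, E_inh = E_inh),
            class = "synapse_params")
}

#' @rdname synapseParams
#' @export
synapseParamsFast <- function() {
  p <- synapseParams()
  p$tau_alpha <- p$tau_alpha / 3
  p
}

#' @export
print.synapse_params <- function(x, ...) {
  cat(sprintf("synapse_params: tau_alpha = %.3g ms (half-life %.1f ms), v_release = %g mV, E_inh = %g mV\n",
              x$tau_alpha, x$tau_alpha * log(2), x$v_release, x$E_inh))
  invisible(x)
}

#' Advance the bound-neurotransmitter variables one step
#'
#' Integrates `dalpha_j/dt = Theta(v_j - v_release) - alpha_j / tau_alpha`
#' over `dt` with the exact exponential update (the forcing is piecewise
#' constant over a step): below threshold alpha decays exponentially with
#' half-life `tau_alpha * log(2)`; above threshold it relaxes towards
#' `tau_alpha`.
#'
#' @param alpha numeric vector of per-presynaptic-cell levels (>= 0).
#' @param v presynaptic membrane potentials (mV), same length.
#' @param dt step (ms), positive.
#' @param params a [synapseParams()].
#' @return updated alpha vector.
#' @export
updateNeurotransmitter <- function(alpha, v, dt, params) {
  stopifnot(dt > 0, length(alpha) == length(v))
  theta <- as.numeric(v > params$v_release)
  decay <- exp(-dt / params$tau_alpha)
  alpha * decay + theta * params$tau_alpha * (1 - decay)
}

#' Conductance-based inhibitory current into one cell
#'
#' `sum_j g_ij alpha_j (E_inh - v_i)`: linear in each `alpha_j` and in the
#' conductance row, zero at the reversal potential, and non-positive
#' whenever the cell is depolarised above `E_inh`.
#'
#' @param v_i postsynaptic membrane potential (mV).
#' @param alpha bound-neurotransmitter vector (length N).
#' @param g_row conductance row `g_i.` (length N).
#' @param E_inh inhibitory reversal potential (mV).
#' @return current (nA).
#' @export
inhibitoryCurrent <- function(v_i, alpha, g_row, E_inh) {
  stopifnot(length(alpha) == length(g_row))
  sum(g_row * alpha) * (E_inh - v_i)
}

#' Unitary IPSP probe on a two-cell motif
#'
#' Holds a postsynaptic cell just below rheobase, lets it settle, then
#' delivers one presynaptic release event (a Heaviside pulse of the
#' empirical spike width, i.e. exactly what one presynaptic spike injects
#' into the neurotransmitter equation) through a single synapse of
#' conductance `g_single`.  Returns the peak hyperpolarisation relative to
#' the pre-spike baseline and the time from the peak to half recovery.
#'
#' @param cell a [cellParams()].
#' @param syn a [synapseParams()].
#' @param g_single unitary conductance (mS).
#' @param holding_current holding current (nA); default 0.05 nA below the
#'   analytic rheobase.
#' @param spike_width presynaptic release duration (ms); default the
#'   empirical spike width of the cell model.
#' @param settle_ms settling time before the event.
#' @param T_after_ms simulated time after the event.
#' @param dt step (ms).
#' @return list with `peak_deflection` (mV), `half_recovery` (ms),
#'   `baseline` (mV) and the probe `trace` (data.frame `t_ms`, `v_mV`).
#' @export
#' @examples
#' pr <- ipspProbe(cellParams(), synapseParams(), g_single = 0.01)
#' pr$peak_deflection
ipspProbe <- function(cell, syn, g_single, holding_current = NULL,
                      spike_width = 0.4, settle_ms = 300, T_after_ms = 250,
                      dt = 0.02) {
  sn <- saddleNodePoint(cell)
  if (is.null(holding_current)) holding_current <- sn$I_th - 0.05
  rs <- restingState(cell, min(holding_current, sn$I_th - 1e-3))
  T_ms <- settle_ms + T_after_ms
  out <- cpp_cell_sim(cellParVector(cell), holding_current, dt, T_ms,
                      rs$v, rs$w, g_single, syn$E_inh, syn$tau_alpha,
                      settle_ms, spike_width, 1L)
  if (length(out$spikes) > 0)
    stop("postsynaptic cell fired during the probe: probe invalid")
  t <- out$t; v <- out$v
  base <- v[max(which(t <= settle_ms))]
  post <- t > settle_ms
  vpost <- v[post]; tpost <- t[post]
  ipeak <- which.min(vpost)
  peak <- base - vpost[ipeak]
  half_recovery <- NA_real_
  if (peak > 0) {
    after <- seq_along(vpost) > ipeak
    rec <- which(after & vpost >= base - peak / 2)
    if (length(rec)) half_recovery <- tpost[rec[1]] - tpost[ipeak]
  }
  list(peak_deflection = peak, half_recovery = half_recovery,
       baseline = base,
       trace = data.frame(t_ms = t, v_mV = v))
}

#' Write an IPSP probe trace as two-column delimited text
#'
#' @param probe result of [ipspProbe()].
#' @param path file path.
#' @export
writeIpspTrace <- function(probe, path) {
  data.table::fwrite(probe$trace, path, sep = "\t")
  invisible(path)
}

#' Change the neurotransmitter timescale, conserving inhibition per spike
#'
#' Returns the parameters with the new `tau_alpha` and synaptic strengths
#' untouched.  The per-spike time integral of alpha equals the spike width
#' `delta_t` regardless of `tau_alpha` (the forcing integral), so the total
#' quantity of neurotransmitter a presynaptic spike delivers -- and hence
#' the level of inhibition in the network -- is conserved automatically;
#' only the variance of alpha around its mean changes (larger at smaller
#' `tau_alpha`).
#'
#' @param syn a [synapseParams()].
#' @param new_tau new timescale (ms), positive.
#' @return updated `synapse_params`.
#' @export
rescaleTau <- function(syn, new_tau) {
  stopifnot(new_tau > 0)
  syn$tau_alpha <- new_tau
  syn
}
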