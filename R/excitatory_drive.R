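# Feedforward cortical/thalamic drive: each MSN receives ~10000 independent
# Poisson inputs whose rates are quenched draws from a normalized Pareto
# distribution (heavy tail => stimulus specificity across cells).  The sum
# is replaced by its diffusion approximation: a per-cell mean conductance
# drive plus an exponentially correlated (OU) fluctuation with the
# excitatory neurotransmitter timescale and shot-noise stationary variance.

#' Excitatory drive parameters
#'
#' Per-input rates are Pareto with tail `pareto_tail` normalised to
#' expectation `mean_rate`; per-input conductances are uniform with a mean
#' set so the aggregate mean current at the reference (threshold) voltage
#' equals `target_mean_nA`.  Defaults: `pareto_tail = 1.5` (the strong
#' specificity regime `1 < a < 2`, where cross-cell fluctuations of the
#' aggregate stay large even for 10000 inputs), `mean_rate = 0.005`
#' spikes/ms (a few Hz of cortical background per afferent), `tau_eps = 2`
#' ms (AMPA-like), and a mean drive 0.3 nA above rheobase so cells operate
#' in the low-rate SNIC regime just above threshold.
#'
#' @param n_inputs number of excitatory afferents per cell.
#' @param tau_eps excitatory neurotransmitter timescale (ms).
#' @param E_exc excitatory reversal potential (mV).
#' @param pareto_tail Pareto tail parameter `a > 1`.
#' @param mean_rate expected per-input rate (spikes/ms).
#' @param target_mean_nA expected aggregate mean current at the reference
#'   voltage (nA); `NULL` means "rheobase + 0.3 nA" resolved at draw time.
#' @param g_exc_scale mean per-input conductance parameter; `NULL` (the
#'   default) derives it from `target_mean_nA`.
#' @param seed drive RNG seed.
#' @return an object of class `drive_params`.
#' @export
driveParams <- function(n_inputs = 10000, tau_eps = 2, E_exc = 0,
                        pareto_tail = 1.5, mean_rate = 0.005,
                        target_mean_nA = NULL, g_exc_scale = NULL,
                        seed = 1) {
  stopifnot(n_inputs >= 1, pareto_tail > 1, mean_rate > 0, tau_eps > 0)
  structure(list(n_inputs = as.integer(n_inputs), tau_eps = tau_eps,
                 E_exc = E_exc, pareto_tail = pareto_tail,
                 mean_rate = mean_rate, target_mean_nA = target_mean_nA,
                 g_exc_scale = g_exc_scale, seed = as.integer(seed)),
            class = "drive_params")
}

#' @export
print.drive_params <- function(x, ...) {
  cat(sprintf("drive_params: %d inputs, Pareto tail a = %g, mean rate %g sp/ms, tau_eps = %g ms, E_exc = %g mV\n",
              x$n_inputs, x$pareto_tail, x$mean_rate, x$tau_eps, x$E_exc))
  invisible(x)
}

#' Draw from the normalized Pareto distribution
#'
#' Standard Pareto with tail `a` and scale chosen so the expectation equals
#' `mean`: `x_m = mean * (a - 1) / a`, sampled by inversion.
#'
#' @param n number of draws.
#' @param a tail parameter (> 1 so the mean exists).
#' @param mean expectation.
#' @return numeric vector of draws (all `>= x_m`).
#' @export
rparetoMean <- function(n, a, mean = 1) {
  stopifnot(a > 1, mean > 0)
  xm <- mean * (a - 1) / a
  xm * runif(n)^(-1 / a)
}

#' Draw a stimulus: per-cell aggregate mean drive and fluctuation scale
#'
#' For each cell, `n_inputs` rates are drawn from the normalized Pareto law
#' and per-input conductance parameters from a uniform distribution of the
#' configured mean; the diffusion approximation gives the aggregate mean
#' current `(E_exc - v_ref) * tau_eps * sum_k g_k nu_k` and shot-noise
#' fluctuation SD `(E_exc - v_ref) * sqrt(sum_k g_k^2 nu_k tau_eps / 2)`,
#' both referenced to the threshold voltage `v_ref` where near-threshold
#' cells operate.  Any cell whose mean lands at or below `I_th` has its
#' draws repeated, so every cell is driven above firing threshold.
#'
#' @param params a [driveParams()].
#' @param cell a [cellParams()] (supplies the reference voltage).
#' @param I_th rheobase current (nA).
#' @param N number of MSN cells.
#' @param id stimulus label.
#' @param seed RNG seed for this stimulus (default: from `params$seed`).
#' @param max_redraw redraw cap per cell; exceeding it signals an
#'   infeasible parameterisation.
#' @return an object of class `stimulus`: `id`, `mean_current` (nA, length
#'   N), `noise_sd` (nA, length N), `v_ref`, `seed`.
#' @export
drawStimulus <- function(params, cell, I_th, N, id = "A", seed = NULL,
                         max_redraw = 1e4) {
  if (is.null(seed)) seed <- substreamSeed(params$seed, paste0("stimulus.", id))
  v_ref <- saddleNodePoint(cell)$v_sn
  force_v <- params$E_exc - v_ref
  target <- params$target_mean_nA
  if (is.null(target)) target <- I_th + 0.3
  gbar <- params$g_exc_scale
  if (is.null(gbar))
    gbar <- target / (params$n_inputs * params$mean_rate * params$tau_eps *
                        force_v)
  n <- params$n_inputs
  mean_current <- numeric(N)
  noise_sd <- numeric(N)
  withSeed(seed, {
    for (i in seq_len(N)) {
      for (attempt in seq_len(max_redraw)) {
        nu <- rparetoMean(n, params$pareto_tail, params$mean_rate)
        g <- runif(n, 0, 2 * gbar)
        mc <- force_v * params$tau_eps * sum(g * nu)
        if (mc > I_th) break
        if (attempt == max_redraw)
          stop("redraw cap exceeded: drive parameterisation infeasible")
      }
      mean_current[i] <- mc
      noise_sd[i] <- force_v * sqrt(sum(g^2 * nu) * params$tau_eps / 2)
    }
  })
  structure(list(id = id, mean_current = mean_current, noise_sd = noise_sd,
                 v_ref = v_ref, seed = seed),
            class = "stimulus")
}

#' @export
print.stimulus <- function(x, ...) {
  cat(sprintf("stimulus '%s': N = %d cells, mean current %.3f nA (cross-cell SD %.3f), mean noise SD %.3f nA\n",
              x$id, length(x$mean_current), mean(x$mean_current),
              sd(x$mean_current), mean(x$noise_sd)))
  invisible(x)
}

#' One-step exact update of the OU drive fluctuation
#'
#' The aggregate fluctuation is an exponentially correlated
#' (Ornstein-Uhlenbeck) process with timescale `tau_eps` and stationary SD
#' `sd`; this advances it by `dt` using the exact discrete transition.
#'
#' @param eta current fluctuation values (nA).
#' @param dt step (ms).
#' @param sd stationary SD (nA), recycled.
#' @param tau_eps correlation time (ms).
#' @return updated fluctuation vector.
#' @export
ouUpdate <- function(eta, dt, sd, tau_eps) {
  decay <- exp(-dt / tau_eps)
  eta * decay + sd * sqrt(1 - decay^2) * rnorm(length(eta))
}

#' Instantaneous excitatory current into one cell
#'
#' The mean-plus-fluctuation drive scaled by the conductance driving-force
#' factor `(E_exc - v) / (E_exc - v_ref)`: with the noise off (`eta = 0`)
#' it returns exactly the mean term.
#'
#' @param v_i membrane potential (mV).
#' @param stim a `stimulus`.
#' @param i cell index.
#' @param eta current fluctuation value (nA); 0 for deterministic mode.
#' @param E_exc excitatory reversal potential (mV).
#' @return current (nA).
#' @export
excitatoryCurrent <- function(v_i, stim, i, eta = 0, E_exc = 0) {
  (stim$mean_current[i] + eta) * (E_exc - v_i) / (E_exc - stim$v_ref)
}

#' Stimulus-switching protocol
#'
#' An ordered schedule of (stimulus id, duration) pairs repeated to fill
#' `total_s` seconds; the default is the two-stimulus 2 s / 2 s alternation.
#'
#' @param ids stimulus labels cycled through.
#' @param duration_s presentation duration (s), recycled over `ids`.
#' @param total_s total simulated time (s).
#' @param transient_s initial period discarded from analysis (s); must be
#'   smaller than `total_s`.
#' @return an object of class `protocol`: data.frame `schedule` with
#'   `id`, `start_s`, `end_s`, plus `total_s` and `transient_s`.
#' @export
#' @examples
#' pr <- makeProtocol(total_s = 180, transient_s = 12)
#' nrow(presentationOnsets(pr))   # 42 complete presentations per stimulus
makeProtocol <- function(ids = c("A", "B"), duration_s = 2, total_s = 180,
                         transient_s = 12) {
  stopifnot(all(duration_s > 0), transient_s < total_s, transient_s >= 0)
  dur <- rep_len(duration_s, length(ids))
  starts <- c()
  labs <- c()
  t <- 0
  k <- 1
  while (t < total_s) {
    starts <- c(starts, t)
    labs <- c(labs, ids[k])
    t <- t + dur[k]
    k <- if (k == length(ids)) 1 else k + 1
  }
  sched <- data.frame(id = labs, start_s = starts,
                      end_s = pmin(starts + rep_len(dur, length(starts)),
                                   total_s))
  structure(list(schedule = sched, total_s = total_s,
                 transient_s = transient_s),
            class = "protocol")
}

#' @export
print.protocol <- function(x, ...) {
  cat(sprintf("protocol: %d segments over %g s (transient %g s), stimuli: %s\n",
              nrow(x$schedule), x$total_s, x$transient_s,
              paste(unique(x$schedule$id), collapse = ", ")))
  invisible(x)
}

#' Stimulus active at a given time
#'
#' Piecewise-constant lookup with half-open intervals: a switching instant
#' belongs to the incoming stimulus.
#'
#' @param protocol a `protocol`.
#' @param t time (s), `0 <= t < total_s`.
#' @return the stimulus id (character).
#' @export
activeStimulus <- function(protocol, t) {
  if (any(t < 0 | t >= protocol$total_s)) stop("time outside the protocol")
  s <- protocol$schedule
  idx <- findInterval(t, s$start_s)
  s$id[idx]
}

#' Post-transient presentation onsets of a protocol
#'
#' Returns the onsets (s) of the complete presentations that start at or
#' after the transient, the unit of averaging for similarity profiles and
#' PSTHs.
#'
#' @param protocol a `protocol`.
#' @return data.frame with `id` and `onset_s`.
#' @export
presentationOnsets <- function(protocol) {
  s <- protocol$schedule
  keep <- s$start_s >= protocol$transient_s &
    s$end_s <= protocol$total_s &
    (s$end_s - s$start_s) >= max(s$end_s - s$start_s) - 1e-9
  data.frame(id = s$id[keep], onset_s = s$start_s[keep])
}

#' Write / read a stimulus as delimited text
#'
#' Columns `cell`, `mean_current_nA`, `noise_sd_nA`, with a YAML sidecar
#' holding id, seed and the reference voltage.
#'
#' @param stim a `stimulus`.
#' @param path file path.
#' @return `readStimulus` returns the reconstructed `stimulus`.
#' @export
writeStimulus <- function(stim, path) {
  data.table::fwrite(data.frame(cell = seq_along(stim$mean_current),
                                mean_current_nA = stim$mean_current,
                                noise_sd_nA = stim$noise_sd),
                     path, sep = "\t")
  yaml::write_yaml(list(id = stim$id, seed = stim$seed, v_ref = stim$v_ref),
                   paste0(path, ".meta.yaml"))
  invisible(path)
}

#' @rdname writeStimulus
#' @export
readStimulus <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t"))
  meta <- yaml::read_yaml(paste0(path, ".meta.yaml"))
  structure(list(id = meta$id, mean_current = df$mean_current_nA,
                 noise_sd = df$noise_sd_nA, v_ref = meta$v_ref,
                 seed = meta$seed),
            class = "stimulus")
}
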