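# Seeded experiment orchestration: parameter sweeps over connectivity p,
# strength scale kappa or the neurotransmitter timescale, at the reference
# ("paper") or desk ("scaled") problem size, collecting tidy summary tables
# and optional per-run artifacts.

#' Scale presets for experiments
#'
#' `"paper"` is the reference condition: a 500-cell local network, 180 s
#' runs with a 12 s transient.  `"scaled"` is the desk-scale condition used
#' throughout the test suite: 100 cells, 60 s + 6 s, with connection
#' strengths carrying the reference network's total inhibition (weights
#' rescaled by `n_ref / N = 5`) so the per-cell inhibitory budget matches
#' the reference network.
#'
#' @param preset `"paper"` or `"scaled"`, or a list with fields `N`, `T_s`,
#'   `transient_s`, `n_ref` for a custom problem size.
#' @return list with `N`, `T_s`, `transient_s`, `n_ref`.
#' @export
scalePreset <- function(preset = c("scaled", "paper")) {
  if (is.list(preset)) {
    stopifnot(all(c("N", "T_s", "transient_s", "n_ref") %in% names(preset)))
    return(preset)
  }
  preset <- match.arg(preset)
  if (preset == "paper")
    list(N = 500L, T_s = 180, transient_s = 12, n_ref = 500L)
  else
    list(N = 100L, T_s = 60, transient_s = 6, n_ref = 500L)
}

#' Experiment configuration for a sweep
#'
#' @param axis swept parameter: `"p"`, `"kappa"` or `"tau_alpha"`.
#' @param grid numeric grid of values (non-empty).
#' @param seeds integer vector of master seeds per grid point.
#' @param preset scale preset name (see [scalePreset()]).
#' @param switching if `TRUE`, run the two-stimulus 2 s / 2 s alternation
#'   and compute similarity summaries; otherwise a single constant
#'   stimulus.
#' @param p,kappa,tau_alpha values of the non-swept parameters.
#' @param epoch_ms onset epoch for the similarity summary.
#' @param out_dir optional directory for per-run artifacts (rasters and
#'   metadata); `NULL` keeps everything in memory.
#' @return an object of class `experiment_config`.
#' @export
experimentConfig <- function(axis = c("p", "kappa", "tau_alpha"),
                             grid, seeds = 1:3, preset = "scaled",
                             switching = FALSE, p = 0.18, kappa = 1,
                             tau_alpha = 50, epoch_ms = 200,
                             out_dir = NULL) {
  axis <- match.arg(axis)
  stopifnot(length(grid) >= 1)
  structure(list(axis = axis, grid = grid, seeds = as.integer(seeds),
                 preset = preset, switching = switching, p = p,
                 kappa = kappa, tau_alpha = tau_alpha, epoch_ms = epoch_ms,
                 out_dir = out_dir),
            class = "experiment_config")
}

# one spiking run + analysis; returns a one-row data.frame
.sweep_run <- function(value, seed, cfg, sc, cell, fi) {
  p <- cfg$p; kappa <- cfg$kappa; tau <- cfg$tau_alpha
  if (cfg$axis == "p") p <- value
  if (cfg$axis == "kappa") kappa <- value
  if (cfg$axis == "tau_alpha") tau <- value
  syn <- rescaleTau(synapseParams(), tau)
  net <- buildRandomNetwork(networkConfig(
    N = sc$N, p = p, kappa = kappa, n_ref = sc$n_ref,
    seed = substreamSeed(seed, "network")))
  drv <- driveParams(seed = seed)
  if (cfg$switching) {
    stims <- list(drawStimulus(drv, cell, fi$I_th, sc$N, id = "A",
                               seed = substreamSeed(seed, "stimulus.A")),
                  drawStimulus(drv, cell, fi$I_th, sc$N, id = "B",
                               seed = substreamSeed(seed, "stimulus.B")))
    prot <- makeProtocol(c("A", "B"), 2, sc$T_s, sc$transient_s)
  } else {
    stims <- list(drawStimulus(drv, cell, fi$I_th, sc$N, id = "A",
                               seed = substreamSeed(seed, "stimulus.A")))
    prot <- makeProtocol("A", sc$T_s, sc$T_s, sc$transient_s)
  }
  sim <- runNetwork(net, cell, syn, drv, stims, prot,
                    simConfig(T_s = sc$T_s, transient_s = sc$transient_s,
                              seed = seed))
  ist <- isiStats(sim)
  row <- data.frame(axis = cfg$axis, value = value, seed = seed,
                    N = sc$N, p = p, kappa = kappa, tau_alpha = tau,
                    active_fraction_3 = ist$summary$active_fraction_3,
                    active_fraction_1 = ist$summary$active_fraction_1,
                    mean_cv = ist$summary$mean_cv,
                    mean_min_isi = ist$summary$mean_min_isi,
                    config_hash = sim$meta$config_hash,
                    status = "ok")
  if (cfg$switching) {
    act <- activeCells(sim, 1)
    R <- binnedRates(sim)
    R$rates <- R$rates[act, , drop = FALSE]
    sm <- summariseProfile(similarityProfile(R, cfg$epoch_ms, prot))
    row$B <- sm$B; row$P <- sm$P; row$D <- sm$D
    row$P_minus_B <- sm$P_minus_B; row$B_minus_D <- sm$B_minus_D
  }
  if (!is.null(cfg$out_dir)) {
    dir <- file.path(cfg$out_dir,
                     sprintf("%s_%g_seed%d", cfg$axis, value, seed))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    saveRaster(sim, file.path(dir, "raster.tsv"))
  }
  row
}

#' Run a parameter sweep of the spiking network
#'
#' For every grid value and seed: build the network, draw the stimuli,
#' simulate, analyse, and append one summary row.  Row order is the
#' deterministic grid-major, seed-minor order; failed runs are recorded
#' with their error message in `status`, never dropped.
#'
#' @param cfg an [experimentConfig()].
#' @param cell a [cellParams()].
#' @param fi an `fi_curve` (fitted once and reused across runs).
#' @return a tidy data.frame, one row per (value, seed).
#' @export
runSweep <- function(cfg, cell = cellParams(), fi = NULL) {
  stopifnot(inherits(cfg, "experiment_config"))
  if (is.null(fi)) fi <- fitFI(cell)
  sc <- scalePreset(cfg$preset)
  rows <- list()
  for (value in cfg$grid) for (seed in cfg$seeds) {
    res <- tryCatch(.sweep_run(value, seed, cfg, sc, cell, fi),
                    error = function(e)
                      data.frame(axis = cfg$axis, value = value,
                                 seed = seed, N = sc$N,
                                 status = paste("error:",
                                                conditionMessage(e))))
    rows[[length(rows) + 1]] <- res
  }
  out <- data.table::rbindlist(rows, fill = TRUE)
  as.data.frame(out)
}

#' Run a parameter sweep of the reduced rate model
#'
#' For every grid value and seed: build the network and stimulus exactly as
#' for the spiking model, assemble the rate model, integrate, estimate the
#' maximal Lyapunov exponent and classify the state.
#'
#' @param axis `"p"` or `"kappa"`.
#' @param grid numeric grid.
#' @param seeds master seeds.
#' @param preset scale preset.
#' @param p,kappa non-swept values.
#' @param cell a [cellParams()].
#' @param fi an `fi_curve`.
#' @param T_s,transient_s integration / transient times for the trajectory
#'   and exponent (s).
#' @param rate_floor activity floor for the rate statistics.
#' @return tidy data.frame with `exponent`, `active_fraction`,
#'   `rel_entropy_scaled`, `class` per run.
#' @export
rateSweep <- function(axis = c("p", "kappa"), grid, seeds = 1:3,
                      preset = "scaled", p = 0.18, kappa = 1,
                      cell = cellParams(), fi = NULL,
                      T_s = 10, transient_s = 30, rate_floor = 1e-4) {
  axis <- match.arg(axis)
  if (is.null(fi)) fi <- fitFI(cell)
  sc <- scalePreset(preset)
  syn <- synapseParams()
  rows <- list()
  for (value in grid) for (seed in seeds) {
    pv <- if (axis == "p") value else p
    kv <- if (axis == "kappa") value else kappa
    net <- buildRandomNetwork(networkConfig(
      N = sc$N, p = pv, kappa = kv, n_ref = sc$n_ref,
      seed = substreamSeed(seed, "network")))
    stim <- drawStimulus(driveParams(seed = seed), cell, fi$I_th, sc$N,
                         id = "A", seed = substreamSeed(seed, "stimulus.A"))
    rp <- rateParamsFromNetwork(net, stim, cell, syn, fi)
    traj <- integrateRates(rp, T_s = T_s, transient_s = transient_s,
                           seed = seed)
    lam <- maxLyapunov(rp, T_s = T_s, transient_s = transient_s, seed = seed)
    rows[[length(rows) + 1]] <- data.frame(
      axis = axis, value = value, seed = seed, p = pv, kappa = kv,
      exponent = lam,
      active_fraction = activeFractionRates(traj, rate_floor),
      rel_entropy_scaled = relativeEntropyRates(traj, rate_floor)$scaled,
      class = classifyState(traj, lam))
  }
  do.call(rbind, rows)
}
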