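# Shared fixtures.  Heavy simulations are computed once per test run and
# cached in this environment so that several test files can reuse them.

.fix <- new.env(parent = emptyenv())

fix <- function(key, expr) {
  if (!exists(key, envir = .fix)) assign(key, force(expr), envir = .fix)
  get(key, envir = .fix)
}

fix_cell <- function() fix("cell", cellParams())

fix_fi <- function() fix("fi", fitFI(fix_cell()))

# One switching-protocol network run plus its binned rates (active cells)
# and protocol; used by the similarity / PCA / acceptance tests.
switch_run <- function(p, seed, T_s = 120, kappa = 1) {
  key <- sprintf("switch_%g_%d_%g_%g", p, seed, T_s, kappa)
  fix(key, {
    cell <- fix_cell(); fi <- fix_fi()
    net <- buildRandomNetwork(networkConfig(
      N = 100, p = p, kappa = kappa, n_ref = 500,
      seed = substreamSeed(seed, "network")))
    drv <- driveParams(seed = seed)
    stims <- list(
      drawStimulus(drv, cell, fi$I_th, 100, "A",
                   seed = substreamSeed(seed, "stimulus.A")),
      drawStimulus(drv, cell, fi$I_th, 100, "B",
                   seed = substreamSeed(seed, "stimulus.B")))
    prot <- makeProtocol(c("A", "B"), 2, T_s, 12)
    sim <- runNetwork(net, cell, synapseParams(), drv, stims, prot,
                      simConfig(T_s = T_s, transient_s = 12, seed = seed))
    act <- activeCells(sim, 1)
    R <- binnedRates(sim)
    R$rates <- R$rates[act, , drop = FALSE]
    list(sim = sim, prot = prot, R = R, n_active = length(act))
  })
}

# Constant-stimulus sweep over connectivity at the scaled preset: the
# winners-take-all vs bursty transition data (also the acceptance
# balance-at-the-transition measurement).
fix_p_sweep <- function() {
  fix("p_sweep", {
    cfg <- experimentConfig("p", c(0.03, 0.1, 0.2, 0.5, 1), seeds = 1:3,
                            preset = "scaled")
    runSweep(cfg, fix_cell(), fix_fi())
  })
}

# Constant-stimulus sweep over the strength scale kappa at p = 0.18.
fix_kappa_sweep <- function() {
  fix("kappa_sweep", {
    cfg <- experimentConfig("kappa", c(0.05, 0.5, 1, 3, 8), seeds = 1:3,
                            preset = list(N = 100L, T_s = 36, transient_s = 6,
                                          n_ref = 500L))
    runSweep(cfg, fix_cell(), fix_fi())
  })
}

# Rate-model sweeps (Lyapunov exponent, active fraction, entropy, class).
fix_rate_p_sweep <- function() {
  fix("rate_p_sweep",
      rateSweep("p", c(0.03, 0.1, 0.2, 0.5, 1), seeds = 1:3,
                cell = fix_cell(), fi = fix_fi()))
}

fix_rate_kappa_sweep <- function() {
  fix("rate_kappa_sweep",
      rateSweep("kappa", c(0.2, 1, 5, 10), seeds = 1:3,
                cell = fix_cell(), fi = fix_fi()))
}

# --- synthetic rasters -----------------------------------------------------

# Poisson raster: N independent homogeneous Poisson cells.
poisson_raster <- function(N, rate_hz, T_s, seed = 1, transient_s = 0) {
  withSeed(seed, {
    spikes <- lapply(seq_len(N), function(i) {
      n <- rpois(1, rate_hz * T_s)
      sort(runif(n, 0, T_s * 1000))
    })
  })
  structure(list(spikes = spikes, N = N, T_ms = T_s * 1000,
                 transient_ms = transient_s * 1000, meta = list()),
            class = "spike_data")
}

# Planted stimulus-locked assembly raster: each stimulus activates its own
# sequence of assemblies in the first second after onset, on top of weak
# background firing, so the onset-locked trajectory repeats across
# presentations (the positive control for similarity profiles).
planted_raster <- function(N = 60, protocol, assembly_rate = 40,
                           background_rate = 1, seed = 1) {
  ons <- presentationOnsets(protocol)
  ids <- unique(ons$id)
  n_assembly <- 6
  cells_per <- N / (n_assembly * length(ids))
  assign_tab <- expand.grid(slot = seq_len(n_assembly), id = ids)
  T_ms <- protocol$total_s * 1000
  withSeed(seed, {
    spikes <- lapply(seq_len(N), function(i) {
      grp <- ((i - 1) %/% cells_per) %% nrow(assign_tab) + 1
      slot <- assign_tab$slot[grp]; sid <- as.character(assign_tab$id[grp])
      t <- runif(rpois(1, background_rate * T_ms / 1000), 0, T_ms)
      for (o in ons$onset_s[ons$id == sid] * 1000) {
        # tonic stimulus-specific elevation across the whole presentation
        t <- c(t, runif(rpois(1, 6 * 2), o, o + 2000))
        # plus the assembly's slot in the onset-locked sequence
        w0 <- o + (slot - 1) * 150
        n <- rpois(1, assembly_rate * 0.15)
        t <- c(t, runif(n, w0, w0 + 150))
      }
      sort(t[t < T_ms])
    })
  })
  structure(list(spikes = spikes, N = N, T_ms = T_ms,
                 transient_ms = protocol$transient_s * 1000, meta = list()),
            class = "spike_data")
}
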