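---
title: "Winners-take-all, bursty chaos and cell-assembly dynamics in random inhibitory MSN networks"
author: "striatdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Winners-take-all, bursty chaos and cell-assembly dynamics in random inhibitory MSN networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Medium spiny neurons (MSNs), the GABAergic projection neurons of the
striatum, inhibit each other through sparse, weak recurrent collaterals
while being driven by thousands of cortical and thalamic afferents.  A
long-standing question is what this weak lateral inhibition is *for*.
`striatdyn` implements a network model in which the answer emerges from
the dynamics: depending on the local connection probability `p` and the
overall strength scale `kappa`, a random inhibitory network of
near-threshold Type-1 cells is either a **winners-take-all** (WTA) system —
a fixed subset of cells fires regularly and the rest stay silent — or a
**bursty, chaotic** system in which cell assemblies transiently form,
dissolve and take turns.  Near the boundary between the two regimes the
network responds to a switch in its cortical input with a *reproducible,
stimulus-onset-locked sequence* of population states, which is the kind of
slow (100 ms–seconds) assembly dynamics observed in vivo.  The package
simulates the spiking network, integrates a reduced deterministic rate
model with a maximal-Lyapunov-exponent estimator to map the stable/chaotic
boundary, and implements the population statistics needed to quantify the
phenomena: windowed firing rates, cosine similarity matrices and profiles,
ISI statistics, a relative-entropy specificity measure, k-means assembly
detection, principal components, PSTH signal/noise decomposition and power
spectra.

## The cell model

Each cell is a two-variable conductance-based model with a leak current, a
persistent sodium current with instantaneous activation, and a slower
persistent potassium current:

$$C\dot v = -g_L(v-E_L) - g_{Na}\,m_\infty(v)(v-E_{Na})
           - g_K\,w\,(v-E_K) + I,\qquad
  \dot w = \frac{w_\infty(v)-w}{\tau_w},$$

with both steady-state activations Boltzmann sigmoids
$x_\infty(v) = 1/(1+e^{(V_{1/2}-v)/k})$.  The default parameters are the
canonical persistent-Na⁺ + K⁺ Type-1 set (`cellParams()`): `C` = 1 µF,
`gL` = 8, `gNa` = 20, `gK` = 10 mS, `EL` = −80, `ENa` = 60, `EK` = −90 mV,
Na activation half-voltage −20 mV / slope 15 mV, K activation −25 mV /
5 mV, `tau_w` = 1 ms.  With these values the model sits near a
saddle-node-on-invariant-circle (SNIC) bifurcation: as the input current
crosses the rheobase a zero-frequency limit cycle is born, so the cell can
fire arbitrarily slowly, shows no subthreshold oscillations, and has no
bistability between spiking and rest — the three properties that make a
Type-1 model appropriate for an MSN in its depolarised UP state.  Detailed
MSN channel biophysics (L-type Ca²⁺, slowly inactivating K⁺) are outside
the model's scope.

The rheobase is never hard-coded.  `saddleNodePoint()` locates it
analytically as the local maximum of the steady-state I–V curve
(≈ 4.513 nA for the defaults, at a saddle voltage of ≈ −60.9 mV) and
`findRheobase()` measures it independently by bisection on "does a
simulation spike"; the two agree to the bisection tolerance and the pair
forms a built-in cross-check.  `fitFI()` measures the f–I curve and fits
the Type-1 square-root law $f = k_f\sqrt{I-I_{th}}$ on a near-threshold
grid ($I_{th}+0.02$ to $I_{th}+0.32$ nA by default).  The square-root law
is an asymptotic property: the fitted gain drifts from ≈ 135 Hz·nA^(−1/2)
at threshold to ≈ 90 far above it, which is why the default grid stays
close to threshold and why the f–I consistency checks in the test suite
evaluate predictions inside the fitted range.

Spikes are detected as upward crossings of 0 mV with linear interpolation
between steps, stored at 0.01 ms resolution; the model self-repolarises,
so no reset is applied.  The time the membrane spends above 0 mV per spike
— the effective neurotransmitter release duration — is measured by
`measureSpikeWidth()` (≈ 0.41 ms for the defaults) rather than assumed.

## Synapses

Inhibition is a Rall-type synapse: each presynaptic cell j carries one
bound-neurotransmitter variable,

$$\dot\alpha_j = \Theta(v_j - v_{rel}) - \alpha_j/\tau_\alpha,$$

and the current into cell i is
$I^{inh}_i = \sum_j g_{ij}\,\alpha_j\,(E_{inh}-v_i)$.  The release
threshold `v_release` equals the spike-detection threshold (0 mV), so a
release event is exactly a detected spike and no phantom release can
occur.  Under this convention the quantity of neurotransmitter delivered
per spike is the forcing integral — the spike width — independent of
$\tau_\alpha$, which is the invariant that matters when the timescale is
varied: `rescaleTau()` changes `tau_alpha` and nothing else, conserving
per-spike inhibition automatically while changing only the variance of
$\alpha$ around its mean (larger for shorter timescales).

Two defaults are calibrated against experimental observables rather than
chosen freely:

* `tau_alpha` = 38 ms, set so that the *modelled* unitary IPSP (membrane
  filtering included) recovers half its depth in ≈ 35 ms, the middle of
  the experimentally reported 30–40 ms range.  A "fast" preset at a third
  of this value (`synapseParamsFast()`) mirrors the robustness checks at
  short neurotransmitter timescales.
* the peak-conductance constant `g0` = 0.0019 mS, fixed once with
  `calibrateEpsilon()` so that at `kappa` = 1 and the striatally relevant
  connectivity `p` = 0.18 a single presynaptic spike evokes a 0.25 mV peak
  IPSP on a postsynaptic cell held just below rheobase (`ipspProbe()`
  implements the two-cell probe; a closure test in the suite re-derives
  `kappa` ≈ 1 from the shipped `g0`).

The inhibitory reversal potential defaults to −80 mV, a hyperpolarising
GABA-A reversal well below the ≈ −61 mV operating point of near-threshold
cells.

## Network

`buildRandomNetwork()` wires each ordered pair independently with
probability `p` (directed Erdős–Rényi: binomial degree distributions, no
self-connections) and draws quenched weights

$$g_{ij} = \kappa\, u_{ij}\, \bar g / p,$$

with $u_{ij}$ uniform on [0, 2] (unit mean), independent per directed
edge, so even reciprocally connected pairs inhibit each other
asymmetrically.  The $1/p$ rescaling keeps the *expected total* inhibition
on a cell independent of `p`, which is what allows connectivity to be
varied as a parameter in its own right; the cost is that the strength of
an individual synapse grows as connectivity falls.  The default `p` = 0.18
reflects roughly 450 synaptic partners among ≈ 2800 arborisation
neighbours once the minority of cortically excited MSNs is accounted for,
on a 500-cell local (striosome-sized) network without spatial structure.

**Scaling down.**  Desk-scale work uses `N` = 100 cells.  A 100-cell
network wired like the 500-cell reference would carry five times less
total inhibition, which abolishes the WTA regime altogether (we verified
this directly), so the scaled preset multiplies weights by
`n_ref / N` = 5: the total inhibitory budget of the reference network is
preserved and the WTA/bursty transition survives.  The unavoidable
distortion is that per-synapse strength is then five times the reference
value at the same `p`, i.e. the scaled network at connectivity `p`
resembles the reference network at a *lower* connectivity; transition
locations along the `p` axis are therefore displaced (see *Limitations*).
The exposed `n_ref` field is also the answer to the question of what the
$1/p$ denominator should be when only the cortically excited fraction of
a neighbourhood is simulated: the rescaling refers to the reference
neighbourhood, not the simulated subset.

## Excitatory drive

Each cell nominally receives `n_inputs` = 10 000 independent Poisson
afferents.  Their rates are quenched draws from a *normalized Pareto
distribution* — heavy-tailed so that even a 10 000-input average retains
sizeable cell-to-cell fluctuations, which is what gives a stimulus its
cell-specific signature.  The tail parameter defaults to `a` = 1.5, inside
the strong-specificity regime $1 < a < 2$ where sums converge to the
Gaussian only very slowly; the per-input mean rate is 0.005 spikes/ms (a
few Hz of cortical background).  Per-input conductances are uniform with a
mean set so the aggregate mean current at the reference voltage is
rheobase + 0.3 nA: cells sit *just above* threshold, in the low-rate SNIC
regime, and the ≈ 5 % cross-cell Pareto dispersion is then large relative
to the margin, producing strongly cell-specific drive.  Any cell whose
aggregate lands below rheobase has its draws repeated ("all cells are
driven above firing threshold"); the redraw is capped and an infeasible
parameterisation errors out.

The 10 000 afferents are never simulated individually.  By the diffusion
approximation the summed input is a mean conductance drive plus a
fluctuation: `drawStimulus()` computes the per-cell mean current
$\mu_i = (E_{exc}-v_{ref})\,\tau_\varepsilon \sum_k g_k\nu_k$ and
shot-noise SD
$\sigma_i = (E_{exc}-v_{ref})\sqrt{\sum_k g_k^2\nu_k\,\tau_\varepsilon/2}$,
both referenced to the saddle-node voltage $v_{ref}$ where near-threshold
cells operate.  In the simulation the fluctuation is realised as an
exponentially correlated (Ornstein–Uhlenbeck) process with the excitatory
neurotransmitter timescale `tau_eps` = 2 ms (AMPA-like) and stationary SD
$\sigma_i$, updated with its exact discrete transition; the whole drive is
multiplied by the conductance factor $(E_{exc}-v)/(E_{exc}-v_{ref})$, so
the drive weakens as the membrane approaches the excitatory reversal
(0 mV).  Setting the noise off (`deterministic` mode) leaves exactly the
mean term.

A *stimulus* is a fixed set of input rates: re-presenting it reuses
identical $\{\mu_i,\sigma_i\}$ (quenched separation), different stimuli
are independent redraws with the same grand mean (no change in overall
excitation level, only in its distribution across cells), and per-cell
draws are independent across cells (no common input — the point of the
model is correlation generated by the *local* network).  `makeProtocol()`
builds the switching schedule; the reference protocol alternates two
stimuli for 2 s each over 180 s with a 12 s transient, containing exactly
42 analysed presentations of each stimulus.  Switching instants belong to
the incoming stimulus (half-open intervals).

## Integration

The full network state $(v_i, w_i, \alpha_i)$ advances with a Heun-type
predictor–corrector: deterministic second order, and weak second order
with the OU drive noise, which is updated once per step by its exact
transition and held fixed across the two stages (an exogenous
piecewise-constant input).  The weak order is verified in the test suite
on the scalar linear SDE $dX = \mu X\,dt + \sigma\,dW$, where antithetic
averaging cancels the Monte-Carlo noise in the mean exactly and exposes
the $O(dt^2)$ bias; the measured slope is ≈ 2.  The inhibitory field
$\sum_j g_{ij}\alpha_j$ is evaluated once per step from the pre-step
$\alpha$ — $\alpha$ moves on the 38 ms timescale, hundreds of steps, so
the induced error is far below the truncation term — while its
driving-force factor $(E_{inh}-v_i)$ stays stage-dependent.

The default step is `dt` = 0.05 ms.  This is a measured choice, not a
convention: the ≈ 0.4 ms spike of this cell model makes 0.1 ms visibly
inadequate (firing rates are grossly wrong at 0.1 ms, while 0.05 ms
matches 0.005 ms to better than 0.5 % across the f–I range), and
`checkConvergence()` documents the residual step sensitivity
(first-spike times of uncoupled cells move by < 0.1 ms under step
halving).  All states update simultaneously from the same pre-step state;
blow-up ($|v| > 200$ mV) aborts with the offending step and cell.

Every random draw flows from one master seed through named substreams
(`substreamSeed()`: network wiring, each stimulus, drive noise, k-means
initialisation), all logged in the run metadata next to a config hash, so
identical configurations reproduce spike data bit-identically.

## The reduced rate model

Replacing the Heaviside release by its expectation per unit time —
spike width $\Delta t$ times the instantaneous rate — and the rate by the
Type-1 transfer of the momentary current turns the $\alpha$ equations into
a deterministic rate network:

$$\dot\alpha_i = -\frac{\alpha_i}{\tau_\alpha}
  + \Delta t\, f\!\Big(V_E I^{exc}_i + V_I \textstyle\sum_j J_{ij}\alpha_j\Big),
  \qquad f(I) = k_f\sqrt{I - I_{th}}\ \ (I > I_{th};\ 0\ \text{otherwise}).$$

$J$ is the same quenched conductance matrix as the spiking model and
$I^{exc}$ the noise-free stimulus means.  The driving forces are frozen
scalars: $V_E$ and $V_I$ are the differences between the excitatory
(0 mV) and inhibitory (−80 mV) reversals and the resting potential
(≈ −66 mV), i.e. ≈ +66 and ≈ −14 mV, computed from the adopted cell
parameters rather than quoted.  $k_f$ and $I_{th}$ are imported from
`fitFI()` (the gain converted to spikes/ms) and $\Delta t$ from
`measureSpikeWidth()` — none of the rate model's parameters are free.  The
transfer is taken exactly at threshold (continuous, not smooth), and the
rectification $\alpha \ge 0$ is enforced after each step, making the
nonnegative orthant forward-invariant.

Integration is classical RK4 (`integrateRates()`), by default 1 ms steps
with a long discarded transient; `maxLyapunov()` estimates the maximal
Lyapunov exponent by the standard two-trajectory method at 0.1 ms steps —
a companion trajectory offset by $d_0 = 10^{-6}$ is co-integrated and
renormalised every 1 ms, and the exponent is the time-averaged log stretch
rate.  The estimator is validated on the classical three-variable chaotic
benchmark flow, whose literature exponent (≈ 0.9056) it reproduces within
a few percent (`lorenzBenchmarkLyapunov()`).  `classifyState()` calls a
trajectory chaotic when the exponent exceeds 10⁻³ s⁻¹, and separates fixed
points from periodic orbits by the mean per-cell rate variance relative to
the squared mean rate (threshold 10⁻⁶) — both documented constants, since
no principled values exist.  The `rate_floor` separating quiescent from
active cells in the rate statistics is likewise exposed (default 10⁻⁴ in
$\alpha$ units).  Two structural notes established in the test suite: with
this vector field a two-cell motif cannot oscillate (the Jacobian's
off-diagonal product is positive, so eigenvalues are real — strong mutual
inhibition gives winner-take-all fixed points instead), and the smallest
oscillating motif is the three-cell asymmetric inhibitory ring, which the
classifier labels periodic.

At desk scale the sweeps use a 30 s transient and 10 s of scored
trajectory per run (against 100 s + 10 s at reference scale): the
fixed-point/chaos distinction stabilises long before that, and the choice
keeps a full two-axis sweep within minutes.

## Population statistics

All statistics operate on sliding-window spike counts (`binnedRates()`:
100 ms windows advancing by 10 ms, centre-aligned).  Two activity
conventions coexist deliberately, as both are used in the source
phenomenology: ≥ 1 spike (similarity, PCA, clustering, entropy) and
≥ 3 spikes (ISI and active-fraction statistics).

* **Similarity** is the cosine overlap of the cross-cell rate vectors at
  two times — 1 for identical patterns, 0 for orthogonal ones, undefined
  (flagged `NA`, excluded from averages with counts logged) when a window
  is silent.  `meanSimilarityMatrix()` folds an 8 s segment through the
  series in 4 s steps, averaging aligned blocks into a mean matrix with
  the periodicity of the stimulation cycle.  `similarityProfile()`
  averages, over all presentations of both stimuli, the similarity
  between a window centred `E` ms after onset and windows up to 5 s
  later; `summariseProfile()` reduces a profile to background `B`
  (lags 1.0–2.0 s), different-stimulus `D` (2.5–3.5 s) and peak `P`
  (3.8–4.2 s) levels.  The three windows sit in the same-stimulus late
  period, the other-stimulus central period, and a ±0.2 s band around the
  4 s lag; they are config-exposed since the source marks them only
  graphically, and they are meaningful for onset epochs `E` ≲ 0.5 s
  (at larger `E` the background window crosses a switch).  `P − B` is
  reproducibility of the onset-locked trajectory; `B − D`
  distinguishability of the stimuli.  Error bars are standard errors over
  presentations (not over time points).
* **ISI statistics** (`isiStats()`): per-cell minimum ISI, mean ISI and
  CV (SD/mean) for cells with ≥ 3 spikes; CV 0 is a clock, 1 is Poisson,
  > 1 is bursty.
* **Relative entropy** (`relativeEntropy()`): per active cell, the KL
  divergence between its windowed-count distribution and the pooled
  distribution of all active cells, on 500 bins spanning the global count
  range; zero when every cell looks like the pool,
  $\log N_{act}$ when supports are disjoint.  Natural logarithms; the
  reported statistic $8\bar D/\log N_{act}$ is base-invariant (the 8 is a
  display convention kept for comparability).  Because every cell's
  samples enter the pool, the per-cell support is contained in the pool's
  support and the divergence is always finite.
* **k-means assemblies** (`kmeansAssemblies()`): Lloyd iterations on rows
  of the cells' cross-correlation matrix, centroids initialised at `K0`
  randomly chosen rows (`K0` = 30 by default, the count used in the
  reference raster figures), empty clusters dropped every round,
  termination when no cell changes cluster — so the final cluster count
  is usually below `K0`.  Ties in the nearest-centroid assignment go to
  the lowest index.  This variant differs from `stats::kmeans` (which
  errors on empty clusters), so it is implemented here and cross-checked
  against the stock Lloyd algorithm on a planted partition.
* **PCA** (`pcaComponents()`): eigendecomposition of the *correlation*
  matrix of the active cells' windowed counts, components ordered by
  descending eigenvalue.  Component time series are projections of the
  per-cell standardised counts, so their variances equal the eigenvalues
  and distinct series are uncorrelated; both identities are asserted in
  the tests.  Standardising before projection is the one interpretive
  choice (the correlation matrix fixes the eigenvectors but not the
  projection scale), and it is what makes the eigenvalue/variance
  identity exact.  Zero-variance cells are dropped.  These components
  capture slow rate covariation, not millisecond synchrony — spike-timing
  measures are out of scope.
* **PSTH decomposition** (`componentPsth()`): a component's time series is
  aligned on the onsets of each stimulus; the presentation mean over the
  first 400 ms is the PSTH, the mean squared fluctuation around it
  (over presentations, epochs, stimuli) is the noise variance, and the
  variance of the PSTH around its window mean is the PSTH variance.
  Components with PSTH/noise ratio > 1 are counted "responsive"
  (`responsiveComponents()`).
* **Spectra** (`componentPsd()`): Welch-style averaged periodogram of
  demeaned segments (64 s segments when the series allows, else the full
  series); `psdPeak()` reports the largest peak below a cutoff and
  `bandSlope()` the log–log slope over a band (default 0.5–5 Hz), i.e.
  the $\beta$ of $1/f^\beta$.

## Experiment orchestration

`runSweep()` sweeps `p`, `kappa` or `tau_alpha` over a grid × seeds at a
scale preset, producing one tidy row per run (active fractions, CVs,
minimum ISIs, and the similarity summaries when the switching protocol is
on), with failed runs recorded rather than dropped and per-run artifacts
(TSV rasters with JSON metadata sidecars) written on request.
`rateSweep()` does the same for the reduced model (exponent, active
fraction, scaled entropy, state class).  The presets are `"paper"`
(N = 500, 180 s, 12 s transient) and `"scaled"` (N = 100, 60 s, 6 s,
reference inhibitory budget via `n_ref` = 500); the test suite runs
entirely at the scaled preset, with switching analyses on 120–168 s runs.
A thin command-line front end (`inst/cli/striatdyn.R`) exposes
`simulate`, `analyze`, `rate-sweep`, `sweep` and `calibrate` subcommands
over these functions.

## What the generator emulates — and what it does not

The synthetic inputs reproduce: quenched stimulus identities with
heavy-tailed cell specificity, supra-threshold drive for every simulated
cell, uncorrelated noise across cells with a realistic few-ms correlation
time, and sudden stimulus switches.  They deliberately omit: correlated
cortical input (assemblies found here are *network-generated* by
construction), per-spike simulation of the 10⁴ afferents, corticostriatal
short-term plasticity, fast-spiking interneurons and other non-MSN
pathways, D1/D2 asymmetries, and any spatial embedding.  Passing tests
therefore demonstrate properties of the local-recurrent-inhibition
mechanism, not a claim that real striatal data would show them with these
magnitudes.

## Numerical choices and degenerate inputs

Beyond the integration choices above: silent analysis windows propagate as
flagged missing values and are excluded from every average; rank-deficient
correlation matrices yield trailing zero eigenvalues (permitted); a count
range of zero width in the entropy binning is widened to one count; the
redraw loop in stimulus construction and the bisections in
`findRheobase()`/`calibrateEpsilon()` are capped and error out rather than
loop forever; degenerate Lyapunov starts (separation exactly zero) error
out.  The k-means tie-break, the half-open protocol intervals (a switch
instant belongs to the incoming stimulus) and the 0.01 ms spike-time
resolution are stated contracts, tested as such.

## Limitations at desk scale

The 100-cell scaled system preserves the reference network's total
inhibition but not its in-degree at a given `p`, and three consequences
are documented rather than hidden.  (1) The WTA/bursty transition along
`p` is displaced: the active-fraction minimum and the CV ≈ 1 crossover sit
at `p` ≈ 0.5–1 instead of the reference ≈ 0.1–0.2, because the controlling
variable is closer to in-degree than to `p` itself.  The transition is
fully present along the `kappa` axis, which does not suffer the
compression.  (2) Reproducibility `P − B` at a 200 ms epoch increases
monotonically with `p` up to `p` = 1 at this scale: the scaled `p` = 1
network, with ≈ 100 strong synapses per cell, behaves like a reference
network *near* the transition, so the interior maximum in `p` visible at
reference scale collapses onto the boundary.  Along `kappa`, the interior
maximum at the calibrated realistic strength is reproduced.  (3) With
≈ 60–80 active cells the population correlation spectrum beyond the first
component is dominated by slow network-generated fluctuations: the first
component locks robustly to the 0.25 Hz protocol line, but the
direction-independent 0.5 Hz switch response — component 3 at reference
scale — drifts among the third-to-sixth components and its periodogram
peak lands on different protocol harmonics from seed to seed, and the
count of PSTH-responsive components saturates near 1 instead of
discriminating ≈ 3 (full connectivity) from ≈ 10 (intermediate).  The
corresponding checks are asserted at their reference-scale form in the
acceptance suite and fail honestly where this scale cannot express them.

## Reproducing the pipeline

```{r}
library(striatdyn)

cell <- cellParams()
fi <- fitFI(cell)                      # rheobase + sqrt-law gain
net <- buildRandomNetwork(networkConfig(N = 100, p = 0.18, n_ref = 500,
                                        seed = substreamSeed(1, "network")))
drv <- driveParams(seed = 1)
stims <- list(
  drawStimulus(drv, cell, fi$I_th, 100, "A",
               seed = substreamSeed(1, "stimulus.A")),
  drawStimulus(drv, cell, fi$I_th, 100, "B",
               seed = substreamSeed(1, "stimulus.B")))
prot <- makeProtocol(c("A", "B"), 2, total_s = 60, transient_s = 6)
sim <- runNetwork(net, cell, synapseParams(), drv, stims, prot,
                  simConfig(T_s = 60, transient_s = 6, seed = 1))

R <- binnedRates(sim)
R$rates <- R$rates[activeCells(sim, 1), , drop = FALSE]
summariseProfile(similarityProfile(R, E = 200, prot))
isiStats(sim)

rp <- rateParamsFromNetwork(net, stims[[1]], cell, synapseParams(), fi)
classifyState(integrateRates(rp, T_s = 10, transient_s = 30),
              maxLyapunov(rp, transient_s = 30))
```
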