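# Random directed inhibitory MSN network with connectivity-rescaled quenched
# weights: each ordered pair is wired independently with probability p and
# carries conductance g_ij = kappa * u_ij * g0 / p, with u_ij uniform of unit
# mean, so the expected total inhibition on a cell is independent of p.

# Peak-conductance constant calibrated once with calibrateEpsilon() so that
# at kappa = 1, p = 0.18 and the default synapse a single presynaptic spike
# evokes a 0.25 mV unitary IPSP on a cell held just below rheobase
# (see the closure test in the suite).
.g0_default <- 0.0019

#' Network construction parameters
#'
#' @param N number of cells (>= 2).
#' @param p ordered-pair connection probability in `(0, 1]`.  The striatally
#'   relevant default 0.18 reflects roughly 450 contacts among some 2800
#'   arborization neighbours with only a minority of MSNs cortically excited
#'   in any one task period, scaled to a 500-cell local network.
#' @param kappa overall connection-strength scale (dimensionless).
#' @param g0 peak-conductance constant (mS); default calibrated so the
#'   unitary IPSP near threshold is 0.25 mV at `kappa = 1`, `p = 0.18`.
#' @param u_low,u_high bounds of the uniform quenched weight factor; the
#'   mean `(u_low + u_high)/2` must equal 1 so weights have unit mean.
#' @param n_ref reference neighbourhood size whose total inhibition the
#'   network should carry.  For a scaled-down network (`N < n_ref`) weights
#'   are multiplied by `n_ref / N` so that the expected total inhibition on
#'   a cell matches the reference 500-cell network.  Use `n_ref = N` (or
#'   `NULL`) for no rescaling.
#' @param seed RNG seed for the wiring and quenched weights.
#' @return an object of class `network_config`.
#' @export
networkConfig <- function(N = 500, p = 0.18, kappa = 1, g0 = .g0_default,
                          u_low = 0, u_high = 2, n_ref = NULL, seed = 1) {
  stopifnot(N >= 2, p > 0, p <= 1, kappa >= 0, g0 > 0, u_low >= 0,
            u_high > u_low)
  if (abs((u_low + u_high) / 2 - 1) > 1e-12)
    stop("quenched weight distribution must have unit mean")
  if (is.null(n_ref)) n_ref <- N
  structure(list(N = N, p = p, kappa = kappa, g0 = g0,
                 u_low = u_low, u_high = u_high, n_ref = n_ref,
                 seed = as.integer(seed)),
            class = "network_config")
}

#' @export
print.network_config <- function(x, ...) {
  cat(sprintf("network_config: N = %d, p = %g, kappa = %g, g0 = %g, u ~ U[%g, %g], n_ref = %d, seed = %d\n",
              x$N, x$p, x$kappa, x$g0, x$u_low, x$u_high, x$n_ref, x$seed))
  invisible(x)
}

#' Build the random directed inhibitory network
#'
#' Wires each ordered pair `(j -> i)`, `i != j`, independently with
#' probability `p` (directed Erdos-Renyi, binomial degree distributions, no
#' self-connections) and assigns effective conductances
#' `g_ij = kappa * u_ij * g0 / p` with `u_ij` uniform on
#' `[u_low, u_high]`, independent per directed edge, so reciprocally
#' connected cells receive asymmetric inhibition.  The `1/p` rescaling keeps
#' the expected total inhibition on a cell constant as connectivity varies.
#'
#' @param config a [networkConfig()].
#' @return an object of class `connectivity`: `adjacency` (N x N 0/1,
#'   zero diagonal), `weights` (N x N nonnegative, rows = postsynaptic),
#'   `config` and `seed_used`.
#' @export
#' @examples
#' conn <- buildRandomNetwork(networkConfig(N = 50, p = 0.2, seed = 7))
#' mean(rowSums(conn$adjacency))   # about p * (N - 1)
buildRandomNetwork <- function(config) {
  stopifnot(inherits(config, "network_config"))
  N <- config$N
  withSeed(config$seed, {
    adj <- matrix(runif(N * N) < config$p, N, N)
    diag(adj) <- FALSE
    u <- matrix(runif(N * N, config$u_low, config$u_high), N, N)
  })
  scale_ref <- config$n_ref / N
  w <- ifelse(adj, config$kappa * u * config$g0 / config$p * scale_ref, 0)
  structure(list(adjacency = adj * 1L, weights = w, config = config,
                 seed_used = config$seed),
            class = "connectivity")
}

#' @export
print.connectivity <- function(x, ...) {
  N <- x$config$N
  cat(sprintf("connectivity: N = %d, %d directed edges (p = %g), mean in-weight %.4g mS\n",
              N, sum(x$adjacency), x$config$p, mean(rowSums(x$weights))))
  invisible(x)
}

#' In- and out-degree distribution of a network
#'
#' @param conn a `connectivity`.
#' @return list with integer vectors `in_degree`, `out_degree` and their
#'   tabulated `in_hist` / `out_hist` counts.
#' @export
degreeDistribution <- function(conn) {
  ind <- rowSums(conn$adjacency)
  outd <- colSums(conn$adjacency)
  list(in_degree = ind, out_degree = outd,
       in_hist = table(ind), out_hist = table(outd))
}

#' Chi-squared goodness of fit of degrees against Binomial(N-1, p)
#'
#' Bins the binomial support so every expected count is at least 5 and runs
#' a chi-squared test of the pooled observed degrees.
#'
#' @param degrees integer vector of degrees (possibly pooled over seeds).
#' @param N network size.
#' @param p connection probability.
#' @return the `htest` object from [stats::chisq.test()].
#' @export
degreeChisqTest <- function(degrees, N, p) {
  ks <- 0:(N - 1)
  pk <- dbinom(ks, N - 1, p)
  n <- length(degrees)
  # merge support into contiguous bins with expected count >= 5
  breaks <- c()
  acc <- 0
  for (k in ks) {
    acc <- acc + pk[k + 1] * n
    if (acc >= 5) { breaks <- c(breaks, k); acc <- 0 }
  }
  if (length(breaks) < 2) stop("too few observations for a binned test")
  breaks <- c(-1, breaks[-length(breaks)], N - 1)
  obs <- table(cut(degrees, breaks))
  pr <- diff(pbinom(breaks, N - 1, p))
  suppressWarnings(chisq.test(as.vector(obs), p = pr / sum(pr)))
}

#' Calibrate the overall strength scale against a target unitary IPSP
#'
#' Bisection on `kappa`: the unitary conductance of a typical synapse at
#' connectivity `p` is `kappa * g0 / p` (quenched factor at its unit mean),
#' and [ipspProbe()] measures the peak IPSP it evokes on a postsynaptic cell
#' held just below rheobase.  Returns the `kappa` whose peak matches
#' `target_ipsp` within 5 percent.
#'
#' @param target_ipsp target unitary peak IPSP (mV), positive.
#' @param p connection probability the calibration refers to.
#' @param syn a [synapseParams()].
#' @param cell a [cellParams()].
#' @param g0 peak-conductance constant (mS).
#' @param bracket initial kappa bracket.
#' @param ... further arguments passed to [ipspProbe()].
#' @return calibrated `kappa`.
#' @export
calibrateEpsilon <- function(target_ipsp, p = 0.18, syn = synapseParams(),
                             cell = cellParams(), g0 = .g0_default,
                             bracket = c(1e-3, 100), ...) {
  stopifnot(target_ipsp > 0)
  peak <- function(kappa)
    ipspProbe(cell, syn, g_single = kappa * g0 / p, ...)$peak_deflection
  lo <- bracket[1]; hi <- bracket[2]
  if (peak(lo) > target_ipsp || peak(hi) < target_ipsp)
    stop("target IPSP not bracketed by the kappa interval")
  repeat {
    mid <- sqrt(lo * hi)
    pm <- peak(mid)
    if (abs(pm - target_ipsp) <= 0.05 * target_ipsp) return(mid)
    if (pm < target_ipsp) lo <- mid else hi <- mid
    if (hi / lo < 1 + 1e-6)
      return(mid)
  }
}

#' Write / read a connectivity as an edge list
#'
#' Plain delimited text with columns `src`, `dst`, `g`, plus a YAML sidecar
#' (same path with extension `.meta.yaml`) carrying the full config so the
#' network round-trips losslessly.
#'
#' @param conn a `connectivity`.
#' @param path edge-list file path.
#' @return `readEdgeList` returns the reconstructed `connectivity`.
#' @export
writeEdgeList <- function(conn, path) {
  idx <- which(conn$adjacency == 1L, arr.ind = TRUE)
  df <- data.frame(src = idx[, 2], dst = idx[, 1],
                   g = conn$weights[idx])
  df <- df[order(df$src, df$dst), ]
  data.table::fwrite(df, path, sep = "\t")
  yaml::write_yaml(c(unclass(conn$config), list(seed_used = conn$seed_used)),
                   paste0(path, ".meta.yaml"))
  invisible(path)
}

#' @rdname writeEdgeList
#' @export
readEdgeList <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".meta.yaml"))
  df <- as.data.frame(data.table::fread(path, sep = "\t"))
  N <- meta$N
  adj <- matrix(0L, N, N)
  w <- matrix(0, N, N)
  adj[cbind(df$dst, df$src)] <- 1L
  w[cbind(df$dst, df$src)] <- df$g
  cfg <- networkConfig(N = meta$N, p = meta$p, kappa = meta$kappa,
                       g0 = meta$g0, u_low = meta$u_low, u_high = meta$u_high,
                       n_ref = meta$n_ref, seed = meta$seed)
  structure(list(adjacency = adj, weights = w, config = cfg,
                 seed_used = meta$seed_used),
            class = "connectivity")
}
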