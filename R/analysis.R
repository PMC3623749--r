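# Population statistics on spike rasters: windowed rates, cosine similarity
# machinery, ISI statistics, relative entropy, k-means assemblies, PCA of
# population rates, PSTH signal/noise decomposition and power spectra.

#' Sliding-window spike counts per cell
#'
#' Counts spikes in a `window`-ms window centred on each bin centre, centres
#' advancing in `step`-ms increments over the post-transient period.
#'
#' @param spikes a `spike_data`.
#' @param window window length (ms).
#' @param step centre increment (ms); must not exceed `window`.
#' @param t0,t1 analysis interval (ms); defaults to
#'   `[transient_ms, T_ms]`.
#' @return an object of class `rate_matrix`: `rates` (cells x bins counts),
#'   `centers` (ms), `window`, `step`.
#' @export
binnedRates <- function(spikes, window = 100, step = 10,
                        t0 = NULL, t1 = NULL) {
  stopifnot(window >= step)
  if (is.null(t0)) t0 <- spikes$transient_ms
  if (is.null(t1)) t1 <- spikes$T_ms
  centers <- seq(t0 + window / 2, t1 - window / 2, by = step)
  R <- t(vapply(spikes$spikes, function(s) {
    s <- sort(s)
    findInterval(centers + window / 2 - 1e-9, s) -
      findInterval(centers - window / 2 - 1e-9, s)
  }, numeric(length(centers))))
  structure(list(rates = R, centers = centers, window = window, step = step),
            class = "rate_matrix")
}

#' @export
print.rate_matrix <- function(x, ...) {
  cat(sprintf("rate_matrix: %d cells x %d bins (window %g ms, step %g ms)\n",
              nrow(x$rates), ncol(x$rates), x$window, x$step))
  invisible(x)
}

#' Active-cell indices under the two activity conventions
#'
#' "At least one spike" is the convention for similarity, PCA, clustering
#' and relative entropy; "at least three spikes" for ISI statistics.
#'
#' @param spikes a `spike_data`.
#' @param min_spikes activity threshold (1 or 3).
#' @param t0,t1 counting interval (ms); defaults to the analysis window.
#' @return integer vector of cell indices.
#' @export
activeCells <- function(spikes, min_spikes = 1, t0 = NULL, t1 = NULL) {
  if (is.null(t0)) t0 <- spikes$transient_ms
  if (is.null(t1)) t1 <- spikes$T_ms
  n <- vapply(spikes$spikes, function(s) sum(s >= t0 & s <= t1), numeric(1))
  which(n >= min_spikes)
}

.col_cosine <- function(x, y) {
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) return(NA_real_)
  # clamp rounding spill so the [0, 1] contract is exact
  min(max(sum(x * y) / (nx * ny), 0), 1)
}

#' Two-time population-vector similarity
#'
#' The cosine overlap of the cross-cell firing-rate vectors at two times:
#' 1 for identical patterns, 0 for orthogonal (disjoint) ones.  Returns a
#' flagged missing value (`NA`) if either vector is all zero.
#'
#' @param R a `rate_matrix` (already restricted to the cells of interest).
#' @param t,t_prime times (ms), matched to the nearest bin centre.
#' @return similarity in `[0, 1]`, or `NA`.
#' @export
similarity <- function(R, t, t_prime) {
  i <- which.min(abs(R$centers - t))
  j <- which.min(abs(R$centers - t_prime))
  .col_cosine(R$rates[, i], R$rates[, j])
}

#' Similarity matrix of a block of time bins
#'
#' @param R a `rate_matrix`.
#' @param bins indices of the bins to include (default all).
#' @return symmetric matrix in `[0, 1]` with `NA` at zero-vector times.
#' @export
similarityMatrix <- function(R, bins = seq_along(R$centers)) {
  X <- R$rates[, bins, drop = FALSE]
  nrm <- sqrt(colSums(X^2))
  ok <- nrm > 0
  Xn <- sweep(X, 2, ifelse(ok, nrm, 1), "/")
  S <- crossprod(Xn)
  S[!ok, ] <- NA_real_
  S[, !ok] <- NA_real_
  S[S > 1] <- 1
  S[S < 0] <- 0
  S
}

#' Folded mean similarity matrix
#'
#' Moves a `period`-s segment through the similarity matrix in steps of
#' `fold`-s and averages the aligned blocks, producing an average
#' similarity with the periodicity of the stimulation cycle (defaults:
#' 8 s segment, 4 s step, i.e. twice the 2 s / 2 s alternation period).
#' Flagged-missing entries are excluded from the average.
#'
#' @param R a `rate_matrix`.
#' @param period segment length (s).
#' @param fold step between segments (s).
#' @return list with the mean matrix `S_bar` (bins x bins), `lag_ms`, and
#'   `n_folds`.
#' @export
meanSimilarityMatrix <- function(R, period = 8, fold = 4) {
  per_b <- round(period * 1000 / R$step)
  fold_b <- round(fold * 1000 / R$step)
  B <- ncol(R$rates)
  if (B < per_b) stop("time series shorter than the folding period")
  n_folds <- (B - per_b) %/% fold_b + 1
  acc <- matrix(0, per_b, per_b)
  cnt <- matrix(0, per_b, per_b)
  for (k in seq_len(n_folds)) {
    idx <- (k - 1) * fold_b + seq_len(per_b)
    S <- similarityMatrix(R, idx)
    ok <- !is.na(S)
    acc[ok] <- acc[ok] + S[ok]
    cnt <- cnt + ok
  }
  list(S_bar = acc / pmax(cnt, 1), lag_ms = seq_len(per_b) * R$step,
       n_folds = n_folds)
}

#' Mean similarity profile at a stimulus-onset epoch
#'
#' For every complete post-transient presentation (of both stimuli), takes
#' the similarity between the window centred `E` ms after onset and windows
#' at lags up to `max_lag_s`, then averages across presentations.
#'
#' @param R a `rate_matrix` restricted to active cells.
#' @param E onset epoch (ms).
#' @param protocol the switching [makeProtocol()].
#' @param max_lag_s maximum lag (s).
#' @return an object of class `similarity_profile`: `lag_ms`, `mean`,
#'   `sem` (over presentations), `n_presentations`, `E`.
#' @export
similarityProfile <- function(R, E, protocol, max_lag_s = 5) {
  ons <- presentationOnsets(protocol)
  if (nrow(ons) < 3 || any(table(ons$id) < 3))
    stop("fewer than 3 presentations per stimulus")
  lags <- seq(0, max_lag_s * 1000, by = R$step)
  tmax <- max(R$centers)
  vals <- matrix(NA_real_, nrow(ons), length(lags))
  for (m in seq_len(nrow(ons))) {
    tref <- ons$onset_s[m] * 1000 + E
    if (tref + max(lags) > tmax + R$step / 2) next
    i <- which.min(abs(R$centers - tref))
    x <- R$rates[, i]
    js <- i + round(lags / R$step)
    js[js > ncol(R$rates)] <- NA
    for (k in seq_along(lags))
      if (!is.na(js[k])) vals[m, k] <- .col_cosine(x, R$rates[, js[k]])
  }
  used <- rowSums(!is.na(vals)) > 0
  vals <- vals[used, , drop = FALSE]
  structure(list(lag_ms = lags,
                 mean = colMeans(vals, na.rm = TRUE),
                 sem = apply(vals, 2, function(v)
                   sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v)))),
                 per_presentation = vals,
                 n_presentations = nrow(vals), E = E),
            class = "similarity_profile")
}

#' Summarise a similarity profile into background / peak / different levels
#'
#' `B` is the mean similarity over the same-stimulus late background lags,
#' `D` over the central lags of the other stimulus' presentation, and `P`
#' over a band around the 4 s lag (the same epoch in the next presentation
#' of the current stimulus).  `P - B` quantifies reproducibility of the
#' onset-locked trajectory, `B - D` distinguishability of the two stimuli.
#'
#' @param profile a `similarity_profile`.
#' @param background_s,different_s,peak_s lag windows (s); defaults sit in
#'   the same-stimulus late period, the other-stimulus central period and a
#'   +/- 0.2 s band around lag 4 s.
#' @return an object of class `similarity_summary` with fields `E`, `B`,
#'   `P`, `D`, `P_minus_B`, `B_minus_D` and per-quantity `sem` (over
#'   presentations).
#' @export
summariseProfile <- function(profile,
                             background_s = c(1.0, 2.0),
                             different_s = c(2.5, 3.5),
                             peak_s = c(3.8, 4.2)) {
  lag_s <- profile$lag_ms / 1000
  win <- function(w) {
    if (identical(w, peak_s))
      sel <- lag_s >= w[1] & lag_s <= w[2]
    else
      sel <- lag_s >= w[1] & lag_s < w[2]
    per <- rowMeans(profile$per_presentation[, sel, drop = FALSE],
                    na.rm = TRUE)
    per <- per[is.finite(per)]
    c(mean(per), sd(per) / sqrt(length(per)))
  }
  B <- win(background_s); D <- win(different_s); P <- win(peak_s)
  structure(list(E = profile$E, B = B[1], P = P[1], D = D[1],
                 P_minus_B = P[1] - B[1], B_minus_D = B[1] - D[1],
                 sem = c(B = B[2], P = P[2], D = D[2])),
            class = "similarity_summary")
}

#' @export
print.similarity_summary <- function(x, ...) {
  cat(sprintf("similarity summary at E = %g ms: B = %.3f, P = %.3f, D = %.3f; P-B = %.3f, B-D = %.3f\n",
              x$E, x$B, x$P, x$D, x$P_minus_B, x$B_minus_D))
  invisible(x)
}

#' Interspike-interval statistics
#'
#' Per-cell minimum ISI, mean ISI and ISI coefficient of variation (SD over
#' mean), computed for cells with at least three post-transient spikes;
#' plus active-cell flags under both the >=3-spike and >=1-spike
#' conventions and network summaries.
#'
#' @param spikes a `spike_data`.
#' @param t0,t1 analysis interval (ms); defaults to the post-transient
#'   window.
#' @return an object of class `isi_stats`: data.frame `per_cell`
#'   (`cell`, `n_spikes`, `min_isi`, `mean_isi`, `cv`,
#'   `active1`, `active3`) and a `summary` list (mean min ISI, mean CV,
#'   active fractions).
#' @export
isiStats <- function(spikes, t0 = NULL, t1 = NULL) {
  if (is.null(t0)) t0 <- spikes$transient_ms
  if (is.null(t1)) t1 <- spikes$T_ms
  per <- lapply(seq_len(spikes$N), function(i) {
    s <- spikes$spikes[[i]]
    s <- s[s >= t0 & s <= t1]
    n <- length(s)
    if (n >= 3) {
      isi <- diff(s)
      data.frame(cell = i, n_spikes = n, min_isi = min(isi),
                 mean_isi = mean(isi),
                 cv = sd(isi) / mean(isi),
                 active1 = TRUE, active3 = TRUE)
    } else {
      data.frame(cell = i, n_spikes = n, min_isi = NA_real_,
                 mean_isi = NA_real_, cv = NA_real_,
                 active1 = n >= 1, active3 = FALSE)
    }
  })
  per <- do.call(rbind, per)
  structure(list(
    per_cell = per,
    summary = list(
      mean_min_isi = mean(per$min_isi, na.rm = TRUE),
      mean_cv = mean(per$cv, na.rm = TRUE),
      active_fraction_1 = mean(per$active1),
      active_fraction_3 = mean(per$active3))),
    class = "isi_stats")
}

#' @export
print.isi_stats <- function(x, ...) {
  s <- x$summary
  cat(sprintf("isi_stats: active fraction %.2f (>=3 spikes) / %.2f (>=1); mean CV %.2f; mean min ISI %.1f ms\n",
              s$active_fraction_3, s$active_fraction_1, s$mean_cv,
              s$mean_min_isi))
  invisible(x)
}

#' Relative entropy of per-cell windowed-count distributions
#'
#' For each active cell (>= 1 spike), the Kullback-Leibler divergence
#' between its distribution of 100 ms sliding spike counts and the pooled
#' distribution over all active cells, computed on 500 bins spanning the
#' global min/max count; zero when every cell matches the pool, and equal
#' to `log(N_act)` when the per-cell count ranges are entirely disjoint.
#' Natural logarithms throughout; the scaled statistic
#' `8 * D_bar / log(N_act)` is base-invariant.
#'
#' @param R a `rate_matrix` restricted to active cells.
#' @param nbins number of count bins.
#' @return list with per-cell `D`, `D_bar`, `n_active` and `scaled`.
#' @export
relativeEntropy <- function(R, nbins = 500) {
  X <- R$rates
  n_act <- nrow(X)
  if (n_act < 1) stop("no active cells")
  lo <- min(X); hi <- max(X)
  if (hi <= lo) hi <- lo + 1
  brks <- seq(lo, hi + 1e-9, length.out = nbins + 1)
  pm <- matrix(0, nbins, n_act)
  for (j in seq_len(n_act)) {
    h <- tabulate(findInterval(X[j, ], brks, all.inside = TRUE), nbins)
    pm[, j] <- h / sum(h)
  }
  q <- rowMeans(pm)
  D <- apply(pm, 2, function(p) {
    s <- p > 0
    sum(p[s] * log(p[s] / q[s]))
  })
  list(D = D, D_bar = mean(D), n_active = n_act,
       scaled = if (n_act > 1) 8 * mean(D) / log(n_act) else 0)
}

#' k-means cell-assembly detection on the rate correlation matrix
#'
#' Lloyd iterations on the rows of the cross-correlation matrix of windowed
#' firing rates: centroids are initialised at `K0` randomly chosen rows,
#' cells are assigned to the nearest centroid (Euclidean), empty clusters
#' are removed each round, centroids are recomputed as assigned-row means,
#' and iteration stops when no cell changes cluster.  The final number of
#' clusters is usually less than `K0`.
#'
#' @param C correlation matrix of the active cells (rows = cells).
#' @param K0 initial number of clusters.
#' @param seed RNG seed for the centroid initialisation.
#' @param max_iter iteration cap.
#' @return list with integer `labels` (1..K, relabelled contiguously),
#'   `centroids`, `K`, `iterations`, `converged`.
#' @export
kmeansAssemblies <- function(C, K0 = 30, seed = 1, max_iter = 500) {
  C <- as.matrix(C)
  n <- nrow(C)
  stopifnot(K0 <= n)
  cent <- withSeed(seed, C[sample.int(n, K0), , drop = FALSE])
  lab <- rep(0L, n)
  iter <- 0
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1
    d2 <- outer(rowSums(C^2), rowSums(cent^2), "+") - 2 * C %*% t(cent)
    new_lab <- max.col(-d2, ties.method = "first")
    keep <- sort(unique(new_lab))
    cent <- t(vapply(keep, function(k)
      colMeans(C[new_lab == k, , drop = FALSE]), numeric(ncol(C))))
    new_lab <- match(new_lab, keep)
    if (identical(new_lab, lab)) { converged <- TRUE; break }
    lab <- new_lab
  }
  list(labels = lab, centroids = cent, K = nrow(cent),
       iterations = iter, converged = converged)
}

#' Principal components of the population firing rates
#'
#' Eigendecomposition of the correlation matrix of windowed firing rates of
#' the active cells; component time series are projections of the per-cell
#' standardised counts onto the eigenvectors, so their variances equal the
#' eigenvalues and distinct component series are uncorrelated.  Cells with
#' zero count variance (degenerate correlation entries) are dropped.
#'
#' @param R a `rate_matrix` restricted to active cells.
#' @return an object of class `component_set`: `eigenvectors`
#'   (cells x components), `eigenvalues` (descending), `ts` (bins x
#'   components), `centers` (ms), `step`, `cells_used`.
#' @export
pcaComponents <- function(R) {
  X <- R$rates
  sds <- apply(X, 1, sd)
  use <- sds > 0
  if (sum(use) < 2) stop("need at least 2 active cells with varying rates")
  X <- X[use, , drop = FALSE]
  C <- cor(t(X))
  eg <- eigen(C, symmetric = TRUE)
  Z <- scale(t(X))  # bins x cells, standardised per cell
  ts <- Z %*% eg$vectors
  structure(list(eigenvectors = eg$vectors,
                 eigenvalues = pmax(eg$values, 0),
                 ts = ts, centers = R$centers, step = R$step,
                 cells_used = which(use)),
            class = "component_set")
}

#' @export
print.component_set <- function(x, ...) {
  ev <- x$eigenvalues
  cat(sprintf("component_set: %d cells, %d bins; leading eigenvalues: %s\n",
              nrow(x$eigenvectors), nrow(x$ts),
              paste(sprintf("%.2f", head(ev, 5)), collapse = ", ")))
  invisible(x)
}

#' Component PSTH and its signal / noise variance decomposition
#'
#' Aligns a component's time series on the post-transient onsets of each
#' stimulus, averages across presentations to get the PSTH over the first
#' `E_range` ms, and decomposes the variability: noise variance is the mean
#' squared fluctuation around the PSTH (over presentations, epochs and
#' stimuli) and PSTH variance is the variance of the PSTH around its window
#' mean (over epochs, averaged over stimuli).  Their ratio measures how
#' strongly the component responds reproducibly to the stimulus.
#'
#' @param comps a `component_set`.
#' @param protocol the switching protocol.
#' @param component component index.
#' @param E_range onset-epoch window (ms), default 0-400.
#' @return list with per-stimulus `psth` (epochs x stimuli), `epoch_ms`,
#'   `psth_variance`, `noise_variance`, `ratio`.
#' @export
componentPsth <- function(comps, protocol, component = 1,
                          E_range = c(0, 400)) {
  ons <- presentationOnsets(protocol)
  ids <- unique(ons$id)
  stopifnot(all(table(ons$id) >= 3))
  epochs <- seq(E_range[1], E_range[2], by = comps$step)
  x <- comps$ts[, component]
  tmax <- max(comps$centers)
  psth <- matrix(NA_real_, length(epochs), length(ids),
                 dimnames = list(NULL, ids))
  noise_acc <- 0; noise_n <- 0; psth_var <- numeric(length(ids))
  for (s in seq_along(ids)) {
    o <- ons$onset_s[ons$id == ids[s]] * 1000
    o <- o[o + max(epochs) <= tmax + comps$step / 2 &
             o + min(epochs) >= comps$centers[1] - comps$step / 2]
    M <- vapply(o, function(t0) {
      idx <- round((t0 + epochs - comps$centers[1]) / comps$step) + 1
      x[idx]
    }, numeric(length(epochs)))  # epochs x presentations
    ps <- rowMeans(M)
    psth[, s] <- ps
    dev <- M - ps
    noise_acc <- noise_acc + sum(dev^2)
    noise_n <- noise_n + length(dev)
    psth_var[s] <- mean((ps - mean(ps))^2)
  }
  nv <- noise_acc / noise_n
  pv <- mean(psth_var)
  list(psth = psth, epoch_ms = epochs,
       psth_variance = pv, noise_variance = nv,
       ratio = if (nv > 0) pv / nv else Inf)
}

#' Number of stimulus-responsive components
#'
#' Counts the leading components whose PSTH-to-noise variance ratio
#' exceeds `threshold`: the measure of how many population dimensions
#' respond reproducibly to stimulus switching.
#'
#' @param comps a `component_set`.
#' @param protocol the switching protocol.
#' @param n_components leading components examined.
#' @param threshold ratio threshold (default 1).
#' @return list with `n_responsive` and the per-component `ratio`s.
#' @export
responsiveComponents <- function(comps, protocol, n_components = 10,
                                 threshold = 1) {
  k <- min(n_components, ncol(comps$ts))
  ratios <- vapply(seq_len(k), function(f)
    componentPsth(comps, protocol, f)$ratio, numeric(1))
  list(n_responsive = sum(ratios > threshold), ratio = ratios)
}

#' Power spectral density of a component time series
#'
#' Welch-style averaged periodogram: the demeaned series is split into
#' segments of `seg_s` seconds (full series if shorter) and the raw
#' periodograms of the segments are averaged.
#'
#' @param x numeric time series (one component).
#' @param step sampling interval (ms).
#' @param seg_s segment length (s).
#' @return an object of class `psd_estimate`: `freq` (Hz), `spec`.
#' @export
componentPsd <- function(x, step = 10, seg_s = 64) {
  fs <- 1000 / step
  seg_n <- min(length(x), round(seg_s * fs))
  nseg <- max(1, floor(length(x) / seg_n))
  acc <- NULL
  for (k in seq_len(nseg)) {
    xi <- x[(k - 1) * seg_n + seq_len(seg_n)]
    sp <- spec.pgram(ts(xi - mean(xi), frequency = fs), taper = 0,
                     detrend = FALSE, plot = FALSE)
    acc <- if (is.null(acc)) sp$spec else acc + sp$spec
  }
  structure(list(freq = sp$freq, spec = acc / nseg), class = "psd_estimate")
}

#' Frequency of the largest spectral peak below a cutoff
#'
#' @param psd a `psd_estimate`.
#' @param f_max cutoff (Hz).
#' @return peak frequency (Hz).
#' @export
psdPeak <- function(psd, f_max = 1) {
  sel <- psd$freq <= f_max
  psd$freq[sel][which.max(psd$spec[sel])]
}

#' Log-log slope of a PSD band
#'
#' Least-squares slope of `log10(spec)` against `log10(freq)` over the
#' band; returns `beta` of `PSD ~ 1/f^beta` (positive for decaying
#' spectra, ~0 for white noise, ~2 for a random walk).
#'
#' @param psd a `psd_estimate`.
#' @param f_band length-2 band (Hz).
#' @return the exponent `beta`.
#' @export
bandSlope <- function(psd, f_band = c(0.5, 5)) {
  sel <- psd$freq >= f_band[1] & psd$freq <= f_band[2] & psd$spec > 0
  if (sum(sel) < 4) stop("band outside resolvable frequencies")
  -coef(lm(log10(psd$spec[sel]) ~ log10(psd$freq[sel])))[[2]]
}
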