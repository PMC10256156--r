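ens_check <- function(ens) {
  stopifnot(inherits(ens, "replication_ensemble"), length(ens$records) >= 1L)
}

#' Replication fork directionality of an ensemble
#'
#' Per bin, `(n_R - n_L) / n_sims` where `n_R` (`n_L`) counts simulations in
#' which the bin was replicated by a rightward (leftward) fork; bins where
#' an initiation or termination occurred contribute 0.
#'
#' @param ens a `replication_ensemble`.
#' @return a `profile` of kind `RFD`.
#' @export
compute_rfd <- function(ens) {
  ens_check(ens)
  lat <- ens$lattice
  s <- numeric(lat$n_bins)
  for (rec in ens$records) {
    sg <- rec$fork_sign
    sg[is.na(sg)] <- 0L
    s <- s + sg
  }
  v <- s / ens$n_sims
  v[lat$mask] <- NA_real_
  profile(v, kind = "RFD", lattice = lat)
}

#' Repli-seq-style mean replication timing
#'
#' Emulates an S-phase-fractionated Repli-seq measurement: each bin's
#' replicated-genome-fraction at its own replication moment is mapped into
#' `n_fractions` equal fractions, and
#' `MRT(x) = sum_i p_i(x) * i / S + 1 / (2 S)` with `S = n_fractions` and
#' `p_i(x)` the share of simulations falling in fraction `i`. Fraction
#' boundaries are half-open `[i/S, (i+1)/S)` with the last closed.
#'
#' @param ens a `replication_ensemble`.
#' @param n_fractions number of S-phase fractions (default 6).
#' @return a `profile` of kind `MRT_fraction`.
#' @export
compute_mrt_fractions <- function(ens, n_fractions = 6) {
  ens_check(ens)
  if (n_fractions < 1) stop("n_fractions must be >= 1")
  S <- n_fractions
  lat <- ens$lattice
  acc <- numeric(lat$n_bins)
  for (rec in ens$records) {
    idx <- pmin(floor(rec$replicated_fraction_at_rt * S), S - 1)
    idx[is.na(idx)] <- 0
    acc <- acc + idx
  }
  v <- acc / ens$n_sims / S + 1 / (2 * S)
  v[lat$mask] <- NA_real_
  profile(v, kind = "MRT_fraction", lattice = lat)
}

#' Mean replication timing in minutes
#'
#' Per-bin average of the true replication times across the ensemble.
#'
#' @param ens a `replication_ensemble`.
#' @return a `profile` of kind `MRT_time_min`.
#' @export
compute_mrt_time <- function(ens) {
  ens_check(ens)
  lat <- ens$lattice
  s <- numeric(lat$n_bins)
  for (rec in ens$records) {
    rt <- rec$rt_min
    rt[is.na(rt)] <- 0
    s <- s + rt
  }
  v <- s / ens$n_sims
  v[lat$mask] <- NA_real_
  profile(v, kind = "MRT_time_min", lattice = lat)
}

#' Observed origin efficiency
#'
#' Per bin, the fraction of simulations in which at least one origin fired
#' in that bin (binary per simulation).
#'
#' @param ens a `replication_ensemble`.
#' @return a `profile` (generic kind) with values in \[0, 1\].
#' @export
compute_oe <- function(ens) {
  ens_check(ens)
  lat <- ens$lattice
  s <- numeric(lat$n_bins)
  for (rec in ens$records) s <- s + (rec$fired > 0)
  v <- s / ens$n_sims
  v[lat$mask] <- NA_real_
  profile(v, kind = "generic", lattice = lat)
}

#' S-phase kinetics summary
#'
#' Per-simulation T95 / T99 / T100 (times at which 95 / 99 / 100% of the
#' unmasked genome is replicated) summarised as ensemble medians, plus the
#' genome-wide origin firing rate per length of unreplicated DNA,
#' `I(t) = firings in [t, t + dt) / (unreplicated length * dt)`, pooled
#' over the ensemble (ratio of summed counts to summed unreplicated
#' length). Windows in which less than 1% of the pooled genome remains
#' unreplicated are dropped: past that point the per-unreplicated-length
#' normalisation is dominated by a handful of terminal gaps and no longer
#' describes genome-wide kinetics.
#'
#' @param ens a `replication_ensemble`.
#' @param dt_min time window for `I(t)`, minutes (default 5).
#' @return a `kinetics_summary`: `T95`, `T99`, `T100` (min, medians),
#'   `I_t` (data.frame with `t_min`, `I`), `I_max` (per Mb per min).
#' @export
kinetics_summary <- function(ens, dt_min = 5) {
  ens_check(ens)
  lat <- ens$lattice
  bin_mb <- lat$bin_kb / 1000
  t95 <- t99 <- t100 <- numeric(ens$n_sims)
  for (i in seq_along(ens$records)) {
    rt <- sort(ens$records[[i]]$rt_min[!lat$mask])
    n <- length(rt)
    t95[i] <- rt[ceiling(0.95 * n)]
    t99[i] <- rt[ceiling(0.99 * n)]
    t100[i] <- rt[n]
  }
  t_max <- max(t100)
  breaks <- seq(0, t_max + dt_min, by = dt_min)
  nw <- length(breaks) - 1L
  fir <- numeric(nw)
  unrep <- numeric(nw)
  mids <- breaks[-length(breaks)] + dt_min / 2
  for (rec in ens$records) {
    h <- hist(rec$fire_t, breaks = c(breaks, Inf), plot = FALSE)$counts
    fir <- fir + h[seq_len(nw)]
    rt <- rec$rt_min[!lat$mask]
    # unreplicated length at each window midpoint
    repl <- findInterval(mids, sort(rt))
    unrep <- unrep + (length(rt) - repl) * bin_mb
  }
  tot_mb <- sum(!lat$mask) * bin_mb * ens$n_sims
  keep <- unrep > 0.01 * tot_mb
  I <- ifelse(keep, fir / (unrep * dt_min), NA_real_)
  structure(list(
    T95 = stats::median(t95), T99 = stats::median(t99),
    T100 = stats::median(t100),
    T95_all = t95, T99_all = t99, T100_all = t100,
    I_t = data.frame(t_min = mids, I = I),
    I_max = suppressWarnings(max(I, na.rm = TRUE))
  ), class = "kinetics_summary")
}

#' @export
print.kinetics_summary <- function(x, ...) {
  cat(sprintf(
    "kinetics: median T95 = %.0f min, T99 = %.0f min, T100 = %.0f min; I_max = %.4g /Mb/min\n",
    x$T95, x$T99, x$T100, x$I_max))
  invisible(x)
}

#' Replication-time variability across the ensemble
#'
#' Per-bin interquartile width of a replication-time proxy, aggregated by
#' MRT decile. With the replicated-genome-fraction proxy (as used by
#' FACS-based measurements) the curve is bell-shaped; with the true
#' simulated time it increases monotonically through S phase, as expected
#' for stochastic origin firing.
#'
#' @param ens a `replication_ensemble` (>= 20 simulations).
#' @param proxy `"replicated_fraction"` or `"true_time"`.
#' @return data.frame with `decile`, `mrt_mid` (mean MRT in the decile) and
#'   `iqr` (mean per-bin interquartile width of the proxy).
#' @export
rt_variability <- function(ens, proxy = c("replicated_fraction", "true_time")) {
  ens_check(ens)
  proxy <- match.arg(proxy)
  if (ens$n_sims < 20) stop("need at least 20 simulations")
  lat <- ens$lattice
  get <- function(rec)
    if (proxy == "true_time") rec$rt_min else rec$replicated_fraction_at_rt
  m <- do.call(cbind, lapply(ens$records, get))
  ok <- !lat$mask
  q1 <- apply(m[ok, , drop = FALSE], 1, stats::quantile, probs = 0.25)
  q3 <- apply(m[ok, , drop = FALSE], 1, stats::quantile, probs = 0.75)
  iqr <- q3 - q1
  mrt <- compute_mrt_fractions(ens)$values[ok]
  dec <- pmin(floor(mrt * 10) + 1L, 10L)
  data.frame(
    decile = sort(unique(dec)),
    mrt_mid = as.numeric(tapply(mrt, dec, mean)),
    iqr = as.numeric(tapply(iqr, dec, mean))
  )
}

#' Ensemble-averaged free-firing-factor trace
#'
#' Averages the event-driven per-simulation traces of free firing factors
#' onto a regular time grid (step interpolation, exact for event traces).
#'
#' @param ens a `replication_ensemble`.
#' @param dt_min grid step in minutes (default 1).
#' @return an `f_free_trace`: `times` (min), `counts` (mean free factors).
#' @export
mean_f_free_trace <- function(ens, dt_min = 1) {
  ens_check(ens)
  t_max <- max(vapply(ens$records, function(r) r$t_end, 0))
  grid <- seq(0, t_max, by = dt_min)
  acc <- numeric(length(grid))
  for (rec in ens$records) {
    # step function: value between events is the value set at the last event
    idx <- findInterval(grid, rec$f_free_t)
    idx[idx < 1L] <- 1L
    v <- rec$f_free_n[idx]
    # after the last event the genome is replicated and all factors are free
    acc <- acc + v
  }
  structure(list(times = grid, counts = acc / ens$n_sims),
            class = "f_free_trace")
}

#' Integrated free-factor availability
#'
#' `int_0^t F_free(u) du` for a step-interpolated trace, evaluated at
#' arbitrary times (exact trapezoid-free step quadrature).
#'
#' @param trace an `f_free_trace` (fields `times`, `counts`).
#' @param t times (min) at which to evaluate the integral.
#' @return numeric vector, factor-minutes.
#' @export
f_free_integral <- function(trace, t) {
  tt <- trace$times
  cc <- trace$counts
  n <- length(tt)
  cum <- c(0, cumsum(cc[-n] * diff(tt)))
  idx <- findInterval(t, tt)
  out <- numeric(length(t))
  inside <- idx >= 1L & idx <= n
  i <- idx[inside]
  out[inside] <- cum[i] + cc[i] * (t[inside] - tt[i])
  out[idx < 1L] <- 0
  beyond <- idx > n  # cannot happen with findInterval, kept for clarity
  if (any(beyond)) out[beyond] <- cum[n] + cc[n] * (t[beyond] - tt[n])
  out
}
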