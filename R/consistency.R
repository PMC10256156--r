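#' MRT / RFD cross-validation and fork-speed estimation
#'
#' Under a constant fork speed `v`, MRT expressed in time units obeys
#' `RFD(x) = v * d(MRT_t)/dx`; integrating over a window of length `l`,
#' `MRT_t(x + l) - MRT_t(x) = (l / v) * <RFD>` where `<RFD>` is the mean
#' RFD over `[x, x + l]`. For each requested scale this routine forms the
#' x-wise pairs (MRT change across the window, window-mean RFD), fits a
#' through-origin least-squares slope `b = l / v` (hence `v_est = l / b`),
#' and reports the Pearson correlation. MRT is converted to minutes by
#' multiplication with the S-phase duration `T_S`. Windows touching masked
#' or missing bins or a chromosome end are excluded; windows advance by one
#' bin.
#'
#' @param pair a [profile_pair()] (MRT in fraction units).
#' @param scales_kb numeric vector of window lengths in kb, each a multiple
#'   of the bin size.
#' @param T_S S-phase duration in minutes used to convert MRT fractions to
#'   time (default 720, i.e. 12 h).
#' @return a `scale_report` data.frame with `scale_kb`, `v_est` (kb/min),
#'   `pcc` and `n_windows`; attribute `T_S`.
#' @export
mrt_rfd_consistency <- function(pair, scales_kb, T_S = 720) {
  stopifnot(inherits(pair, "profile_pair"), length(scales_kb) >= 1L, T_S > 0)
  lat <- pair$lattice
  scales_kb <- sort(scales_kb)
  if (any(abs(scales_kb / lat$bin_kb - round(scales_kb / lat$bin_kb)) > 1e-9))
    stop("every scale must be a multiple of the bin size")
  mrt_t <- pair$mrt$values * T_S
  rfd <- pair$rfd$values
  bad <- pair$mask | is.na(mrt_t) | is.na(rfd)
  mrt_t[bad] <- NA_real_
  rfd[bad] <- NA_real_
  off <- lattice_chrom_offsets(lat)
  out <- data.frame(scale_kb = scales_kb, v_est = NA_real_,
                    pcc = NA_real_, n_windows = 0L)
  for (k in seq_along(scales_kb)) {
    m <- as.integer(round(scales_kb[k] / lat$bin_kb))
    dmrt_all <- numeric(0)
    mean_rfd_all <- numeric(0)
    for (ci in seq_along(lat$chrom_len_bins)) {
      n <- lat$chrom_len_bins[ci]
      if (n <= m) next
      idx <- seq.int(off[ci] + 1L, off[ci] + n)
      mt <- mrt_t[idx]
      rf <- rfd[idx]
      nw <- n - m
      # MRT change across [x, x + l] and mean RFD over the m bins starting at x
      dmrt <- mt[(1L + m):n] - mt[1:nw]
      cs <- c(0, cumsum(ifelse(is.na(rf), 0, rf)))
      cn <- c(0, cumsum(is.na(rf)))
      mean_rfd <- (cs[(1L + m):n] - cs[1:nw]) / m
      n_na <- cn[(1L + m):n] - cn[1:nw]
      ok <- !is.na(dmrt) & n_na == 0L
      dmrt_all <- c(dmrt_all, dmrt[ok])
      mean_rfd_all <- c(mean_rfd_all, mean_rfd[ok])
    }
    if (length(dmrt_all) >= 3L && sum(mean_rfd_all^2) > 0) {
      b <- sum(dmrt_all * mean_rfd_all) / sum(mean_rfd_all^2)
      out$v_est[k] <- if (b > 0) scales_kb[k] / b else NA_real_
      out$n_windows[k] <- length(dmrt_all)
      if (stats::sd(mean_rfd_all) > 0 && stats::sd(dmrt_all) > 0)
        out$pcc[k] <- stats::cor(dmrt_all, mean_rfd_all)
    }
  }
  attr(out, "T_S") <- T_S
  class(out) <- c("scale_report", class(out))
  out
}
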