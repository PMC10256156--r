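#' Closed-form origin-firing probability
#'
#' With `n` potential origins in a bin, reaction rate `kon` and free-factor
#' trace `F_free(t)`, the probability that the bin has fired by time `t`
#' (ignoring passivation) is `1 - exp(-kon * n * int_0^t F_free(u) du)`.
#' Because a small bin is far more often passivated than internally fired,
#' its mean passivation time is close to its MRT, so evaluating this at
#' `t = MRT_t(x)` predicts the observed origin efficiency.
#'
#' @param n potential origins per bin (vector).
#' @param mrt_t per-bin mean replication time, minutes (vector).
#' @param trace an `f_free_trace` (see [mean_f_free_trace()]).
#' @param kon reaction rate, 1/min.
#' @return predicted observed efficiency in \[0, 1).
#' @export
predicted_oe <- function(n, mrt_t, trace, kon) {
  if (any(n < 0, na.rm = TRUE) || any(mrt_t < 0, na.rm = TRUE) || kon < 0)
    stop("origin counts, times and rate must be non-negative")
  integ <- f_free_integral(trace, mrt_t)
  1 - exp(-kon * n * integ)
}

#' RFD increments (Delta RFD)
#'
#' Smooths the RFD profile (15 kb running mean by default), takes the
#' backward difference between consecutive bins within each chromosome and
#' clips negative increments to zero. Optionally only the top
#' `keep_top_fraction` of unmasked values are kept (the rest set to 0), as
#' used by the closed-form landscape estimators; peak detection is run on
#' the unthresholded increments.
#'
#' @param rfd a `profile` of kind `RFD`.
#' @param smooth_kb smoothing window, kb (default 15).
#' @param keep_top_fraction fraction of top values to keep (default 0.15);
#'   `NULL` to keep all.
#' @return a `profile` (generic kind) of non-negative increments.
#' @export
delta_rfd <- function(rfd, smooth_kb = 15, keep_top_fraction = 0.15) {
  stopifnot(inherits(rfd, "profile"))
  lat <- rfd$lattice
  ok <- !lat$mask & !is.na(rfd$values)
  if (!any(ok)) stop("no unmasked RFD data")
  sm <- smooth_profile(rfd, smooth_kb)
  d <- profile_diff(sm)
  v <- pmax(d$values, 0)
  if (!is.null(keep_top_fraction)) {
    stopifnot(keep_top_fraction > 0, keep_top_fraction <= 1)
    uv <- v[!lat$mask & !is.na(v)]
    k <- ceiling(keep_top_fraction * length(uv))
    thr <- sort(uv, decreasing = TRUE)[k]
    v[!is.na(v) & v < thr] <- 0
  }
  profile(v, kind = "generic", lattice = lat, normalize = FALSE)
}

#' Detect initiation zones as Delta RFD peaks
#'
#' Local maxima of the RFD increment profile with value at least
#' `min_height` and width at half prominence of at least `min_width_bins`
#' bins, detected within chromosomes.
#'
#' @param drfd increment `profile` from [delta_rfd()].
#' @param min_width_bins minimum peak width in bins (default 4).
#' @param min_height minimum increment per bin (default 0.02).
#' @return data.frame of IZ calls: `bin` (global index), `chrom`,
#'   `delta_rfd` (peak value), `width_bins`; sorted by position.
#' @export
detect_izs <- function(drfd, min_width_bins = 4, min_height = 0.02) {
  stopifnot(inherits(drfd, "profile"))
  lat <- drfd$lattice
  off <- lattice_chrom_offsets(lat)
  out <- list()
  for (ci in seq_along(lat$chrom_names)) {
    n <- lat$chrom_len_bins[ci]
    idx <- seq.int(off[ci] + 1L, off[ci] + n)
    x <- drfd$values[idx]
    x[lat$mask[idx]] <- 0
    pk <- find_peaks(x, height = min_height, width = min_width_bins)
    if (nrow(pk))
      out[[ci]] <- data.frame(bin = off[ci] + pk$pos,
                              chrom = lat$chrom_names[ci],
                              delta_rfd = pk$height,
                              width_bins = pk$width)
  }
  if (!length(out))
    return(data.frame(bin = integer(0), chrom = character(0),
                      delta_rfd = numeric(0), width_bins = numeric(0)))
  res <- do.call(rbind, out)
  res[order(res$bin), , drop = FALSE]
}

#' Estimate potential-origin density from Delta RFD and MRT
#'
#' Inverts the closed-form efficiency relation: with `OE ~ dRFD / 2`,
#' `n_e(x) = -log(1 - dRFD(x)/2) / (kon * int_0^MRT_t(x) F_free du)`.
#' Evaluated where the increment is positive; zero elsewhere.
#'
#' @param drfd increment `profile` from [delta_rfd()].
#' @param mrt_t per-bin mean replication time `profile`
#'   (kind `MRT_time_min`).
#' @param trace an `f_free_trace`.
#' @param kon reaction rate, 1/min.
#' @return a `profile` (generic kind) of estimated origins per bin.
#' @export
estimate_n <- function(drfd, mrt_t, trace, kon) {
  stopifnot(inherits(drfd, "profile"), inherits(mrt_t, "profile"), kon > 0)
  v <- drfd$values
  if (any(v / 2 >= 1, na.rm = TRUE))
    stop("Delta RFD / 2 >= 1: log diverges")
  nz <- !is.na(v) & v > 0 & !is.na(mrt_t$values)
  out <- numeric(length(v))
  integ <- f_free_integral(trace, mrt_t$values[nz])
  out[nz] <- -log(1 - v[nz] / 2) / (kon * integ)
  out[is.na(v)] <- NA_real_
  profile(out, kind = "generic", lattice = drfd$lattice, normalize = FALSE)
}

#' Closed-form IPLS estimators from RFD increments and MRT
#'
#' Three estimators of the initiation landscape from measurable profiles,
#' differing in how the time-integrated free-factor availability is
#' approximated:
#' \describe{
#'   \item{`integral`}{`-log(1 - dRFD/2) / (kon * int_0^MRT_t F_free du)`
#'     with the recorded trace (requires `trace` and `kon`).}
#'   \item{`inverse_mrt`}{constant free-factor approximation:
#'     `-log(1 - dRFD/2) / (kon * MRT_t * F_free_const)`; bins with
#'     `MRT = 0` are excluded and reported in attribute `flagged`.}
#'   \item{`exp6`}{empirical exponential-decay weighting
#'     `dRFD * exp(-exponent * MRT)` (MRT as fraction of `T_S`), which
#'     captures the boost of late-firing efficiency by recycled factors.}
#' }
#' Negative values are clipped and the result normalised to unit sum.
#'
#' @param drfd increment `profile` (typically top-15% thresholded).
#' @param mrt `profile` of kind `MRT_fraction`.
#' @param variant `"integral"`, `"inverse_mrt"` or `"exp6"`.
#' @param T_S S-phase duration, minutes (default 720).
#' @param trace `f_free_trace` for the `integral` variant.
#' @param kon reaction rate for `integral` / `inverse_mrt` (default 1;
#'   drops out in the normalisation).
#' @param F_free_const constant free-factor level for `inverse_mrt`
#'   (default 1; drops out in the normalisation).
#' @param exponent decay constant of the `exp6` variant (default 6).
#' @return a `profile` of kind `IPLS`.
#' @export
ipls_from_data <- function(drfd, mrt,
                           variant = c("exp6", "integral", "inverse_mrt"),
                           T_S = 720, trace = NULL, kon = 1,
                           F_free_const = 1, exponent = 6) {
  variant <- match.arg(variant)
  stopifnot(inherits(drfd, "profile"), inherits(mrt, "profile"),
            mrt$kind == "MRT_fraction", T_S > 0)
  lat <- drfd$lattice
  v <- drfd$values
  m <- mrt$values
  ok <- !is.na(v) & !is.na(m) & !lat$mask
  out <- numeric(lat$n_bins)
  flagged <- integer(0)
  if (variant == "exp6") {
    out[ok] <- v[ok] * exp(-exponent * m[ok])
  } else if (variant == "inverse_mrt") {
    zero <- ok & m == 0 & v > 0
    flagged <- which(zero)
    use <- ok & m > 0
    out[use] <- -log(pmin(1 - v[use] / 2, 1)) /
      (kon * m[use] * T_S * F_free_const)
  } else {
    if (is.null(trace)) stop("the integral variant needs a F_free trace")
    ne <- estimate_n(drfd, profile(m * T_S, "MRT_time_min", lat,
                                   normalize = FALSE), trace, kon)
    out <- ne$values
    out[is.na(out)] <- 0
  }
  out <- pmax(out, 0)
  out[lat$mask] <- 0
  res <- profile(out, kind = "IPLS", lattice = lat)
  attr(res, "flagged") <- flagged
  res
}
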