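#' Specification of a synthetic initiation landscape
#'
#' Describes a desk-scale genome and a peaky IPLS over it, emulating the
#' measured structure of inferred human landscapes: most initiation mass
#' concentrated in a minor fraction of the genome (broad initiation zones)
#' over a uniform dispersive floor. Defaults give 2 chromosomes totalling
#' 50 Mb, about 2.5 IZs per Mb of mean width 60 kb carrying 80% of the
#' mass, so that roughly 15-20% of bins hold 80% of the landscape.
#'
#' @param n_chrom number of chromosomes (default 2).
#' @param chrom_len_mb chromosome lengths in Mb (default rep(25, n_chrom)).
#' @param bin_kb bin size, kb (default 5).
#' @param peak_density initiation zones per Mb (default 3.5, the areal
#'   density of RFD upshifts in human cells).
#' @param peak_mass_fraction share of IPLS mass in peaks (default 0.8).
#' @param peak_width_kb mean IZ width, kb (default 60); zones are
#'   flat-topped with 10 kb soft edges, as initiation is internally
#'   dispersed within an initiation zone rather than point-like.
#' @param peak_strength_shape gamma shape of relative IZ strengths
#'   (default 1, i.e. exponential: many weak zones, few strong ones, so
#'   that the strongest per-bin initiation frequencies approach the
#'   maximal per-bin RFD upshifts seen in human data).
#' @param gap_spec optional data.frame(`chrom`, `start_bin`, `end_bin`) of
#'   masked gaps (1-based bin ranges within the chromosome).
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_chrom = 2L, chrom_len_mb = NULL, bin_kb = 5,
                           peak_density = 3.5, peak_mass_fraction = 0.8,
                           peak_width_kb = 60, peak_strength_shape = 1,
                           gap_spec = NULL) {
  if (is.null(chrom_len_mb)) chrom_len_mb <- rep(25, n_chrom)
  stopifnot(length(chrom_len_mb) == n_chrom, all(chrom_len_mb > 0),
            peak_mass_fraction >= 0, peak_mass_fraction <= 1,
            peak_density > 0, peak_width_kb > 0)
  structure(list(n_chrom = as.integer(n_chrom), chrom_len_mb = chrom_len_mb,
                 bin_kb = bin_kb, peak_density = peak_density,
                 peak_mass_fraction = peak_mass_fraction,
                 peak_width_kb = peak_width_kb,
                 peak_strength_shape = peak_strength_shape,
                 gap_spec = gap_spec),
            class = "synthetic_spec")
}

#' Generate a synthetic IPLS with known ground truth
#'
#' Places a Poisson number of initiation zones uniformly along each
#' chromosome, with gamma-distributed relative strengths and Gaussian
#' profiles of the specified width, over a uniform floor carrying
#' `1 - peak_mass_fraction` of the mass. Masked gaps carry no mass. The
#' ground-truth IZ positions, strengths and widths are returned alongside
#' the landscape.
#'
#' @param spec a [synthetic_spec()].
#' @param seed RNG seed.
#' @return list with `ipls` (a `profile`), `lattice`, and `izs`
#'   (data.frame: `chrom`, `bin`, `strength`, `sigma_kb`).
#' @export
generate_ipls <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(seed)
  len_kb <- spec$chrom_len_mb * 1000
  names(len_kb) <- paste0("chr", seq_len(spec$n_chrom))
  lat <- genome_lattice(len_kb, bin_kb = spec$bin_kb)
  if (!is.null(spec$gap_spec)) {
    for (k in seq_len(nrow(spec$gap_spec))) {
      idx <- lattice_chrom_bins(lat, spec$gap_spec$chrom[k])
      lat$mask[idx[spec$gap_spec$start_bin[k]:spec$gap_spec$end_bin[k]]] <- TRUE
    }
  }
  centers <- lattice_bin_center_kb(lat)
  chrom_of <- lattice_chrom_of_bin(lat)
  v <- numeric(lat$n_bins)
  izs <- list()
  edge_kb <- 10   # soft IZ edges: initiation fades over ~2 bins
  for (ci in seq_len(spec$n_chrom)) {
    n_pk <- stats::rpois(1L, spec$peak_density * spec$chrom_len_mb[ci])
    if (n_pk == 0L) next
    pos <- stats::runif(n_pk, 0, len_kb[ci])
    stren <- stats::rgamma(n_pk, shape = spec$peak_strength_shape, rate = 1)
    wid <- spec$peak_width_kb * exp(stats::rnorm(n_pk, 0, 0.3) - 0.045)
    sel <- chrom_of == ci
    x <- centers[sel]
    acc <- numeric(sum(sel))
    for (k in seq_len(n_pk)) {
      # flat-topped zone: difference of two error functions
      shape <- (stats::pnorm((x - pos[k] + wid[k] / 2) / edge_kb) -
                stats::pnorm((x - pos[k] - wid[k] / 2) / edge_kb)) / wid[k]
      acc <- acc + stren[k] * shape
    }
    v[sel] <- v[sel] + acc
    izs[[ci]] <- data.frame(chrom = names(len_kb)[ci],
                            bin = lattice_chrom_bins(lat, names(len_kb)[ci])[
                              pmin(pmax(ceiling(pos / spec$bin_kb), 1L),
                                   lat$chrom_len_bins[ci])],
                            strength = stren, width_kb = wid)
  }
  if (!length(izs) && spec$peak_mass_fraction > 0)
    stop("no peaks drawn and no floor: empty landscape")
  v[lat$mask] <- 0
  s <- sum(v)
  if (s > 0) v <- v / s * spec$peak_mass_fraction
  ok <- !lat$mask
  v[ok] <- v[ok] + (1 - spec$peak_mass_fraction) / sum(ok)
  ipls <- profile(v, kind = "IPLS", lattice = lat)
  list(ipls = ipls, lattice = lat,
       izs = if (length(izs)) do.call(rbind, izs) else NULL)
}

#' Shuffle a profile within fixed windows
#'
#' Uniformly permutes bin values inside each non-overlapping window of
#' `window_kb`, conserving every window sum exactly. Used to test how much
#' positional (as opposed to regional) information an observable carries.
#'
#' @param prof a `profile`.
#' @param window_kb window length, kb (multiple of the bin size;
#'   default 200).
#' @return a `profile` of the same kind.
#' @export
resample_in_windows <- function(prof, window_kb = 200) {
  stopifnot(inherits(prof, "profile"))
  lat <- prof$lattice
  wb <- window_kb / lat$bin_kb
  stopifnot(abs(wb - round(wb)) < 1e-9)
  wb <- as.integer(round(wb))
  v <- prof$values
  off <- lattice_chrom_offsets(lat)
  for (ci in seq_along(lat$chrom_len_bins)) {
    n <- lat$chrom_len_bins[ci]
    starts <- seq.int(1L, n, by = wb)
    for (s in starts) {
      e <- min(s + wb - 1L, n)
      idx <- off[ci] + (s:e)
      v[idx] <- v[idx][sample.int(length(idx))]
    }
  }
  profile(v, kind = prof$kind, lattice = lat, normalize = FALSE)
}

#' Modulate profile amplitude with a slow periodic divisor
#'
#' Divides each bin by `1.1 + cos(2 x / P)` where `x` is the bin-centre
#' coordinate along its chromosome and `P = period_mb` (both in Mb),
#' alternately damping (down to 1/2.1) and amplifying (up to 10x) the
#' signal over a long period. Used to test sensitivity to large-scale
#' amplitude structure. The argument is `2 x / P` (radians); set
#' `two_pi = TRUE` for a `2 pi x / P` period instead.
#'
#' @param prof a non-negative `profile`.
#' @param period_mb modulation period parameter, Mb (default 25).
#' @param two_pi use `2 pi x / P` as the cosine argument (default FALSE).
#' @return a `profile` of the same kind (IPLS renormalised).
#' @export
modulate_amplitude <- function(prof, period_mb = 25, two_pi = FALSE) {
  stopifnot(inherits(prof, "profile"))
  lat <- prof$lattice
  x_mb <- lattice_bin_center_kb(lat) / 1000
  arg <- if (two_pi) 2 * pi * x_mb / period_mb else 2 * x_mb / period_mb
  div <- 1.1 + cos(arg)
  v <- prof$values / div
  profile(v, kind = prof$kind, lattice = lat,
          normalize = prof$kind == "IPLS")
}

#' Add observation noise to an MRT/RFD pair
#'
#' Emulates measurement limitations: the MRT profile is blurred to the
#' stated resolution with a sum-conserving scatter kernel (each bin spreads
#' its value uniformly over its window, truncated at chromosome ends), and
#' iid Gaussian noise is added to RFD, clipped back to \[-1, 1\].
#'
#' @param pair a [profile_pair()].
#' @param mrt_blur_kb MRT resolution, kb (default 100).
#' @param rfd_sigma RFD noise standard deviation (default 0.1).
#' @param seed RNG seed.
#' @return a [profile_pair()].
#' @export
add_observation_noise <- function(pair, mrt_blur_kb = 100, rfd_sigma = 0.1,
                                  seed = 1L) {
  stopifnot(inherits(pair, "profile_pair"), rfd_sigma >= 0)
  set.seed(seed)
  lat <- pair$lattice
  mrt_v <- scatter_blur(pair$mrt$values, lat, mrt_blur_kb)
  mrt <- profile(pmin(pmax(mrt_v, 0), 1), "MRT_fraction", lat)
  rv <- pair$rfd$values
  ok <- !is.na(rv)
  rv[ok] <- rv[ok] + stats::rnorm(sum(ok), 0, rfd_sigma)
  rv <- pmin(pmax(rv, -1), 1)
  rfd <- profile(rv, "RFD", lat)
  profile_pair(mrt, rfd, mask = pair$mask)
}

# sum-conserving blur: each bin distributes its value uniformly over its
# (chromosome-truncated) window; exactly preserves each chromosome's mean
scatter_blur <- function(v, lat, window_kb) {
  half <- floor(window_kb / lat$bin_kb / 2)
  if (half == 0L) return(v)
  out <- numeric(lat$n_bins)
  cnt <- numeric(lat$n_bins)
  off <- lattice_chrom_offsets(lat)
  for (ci in seq_along(lat$chrom_len_bins)) {
    n <- lat$chrom_len_bins[ci]
    idx <- seq.int(off[ci] + 1L, off[ci] + n)
    x <- v[idx]
    x[is.na(x)] <- 0
    lo <- pmax(seq_len(n) - half, 1L)
    hi <- pmin(seq_len(n) + half, n)
    wlen <- hi - lo + 1L
    # scatter x[i]/wlen[i] onto [lo_i, hi_i] via difference arrays
    d <- numeric(n + 1L)
    contrib <- x / wlen
    d_add <- rowsum(contrib, lo)
    d[as.integer(rownames(d_add))] <- d[as.integer(rownames(d_add))] + d_add
    d_sub <- rowsum(contrib, hi + 1L)
    at <- as.integer(rownames(d_sub))
    keep <- at <= n + 1L
    d[at[keep]] <- d[at[keep]] - d_sub[keep]
    out[idx] <- cumsum(d[seq_len(n)])
  }
  out
}
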