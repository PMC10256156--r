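#' Binned genome lattice
#'
#' A `genome_lattice` describes the discretised genome every profile and
#' simulation in this package lives on: a set of named chromosomes, each cut
#' into consecutive bins of `bin_kb` kilobases (5 kb by default), plus a
#' logical mask of bins excluded from analysis (assembly gaps, regions
#' without data).
#'
#' @param chrom_len_kb named numeric vector of chromosome lengths in kb.
#'   Lengths are rounded up to a whole number of bins.
#' @param bin_kb bin size in kb (default 5).
#' @param mask optional logical vector, one entry per bin (`TRUE` =
#'   excluded). Defaults to all `FALSE`.
#' @return an object of class `genome_lattice` with fields `chrom_names`,
#'   `chrom_len_bins`, `bin_kb`, `n_bins` and `mask`.
#' @examples
#' lat <- genome_lattice(c(chrA = 5000, chrB = 2500))
#' lat$n_bins
#' @export
genome_lattice <- function(chrom_len_kb, bin_kb = 5, mask = NULL) {
  stopifnot(is.numeric(chrom_len_kb), length(chrom_len_kb) >= 1L,
            all(chrom_len_kb > 0), bin_kb > 0)
  if (is.null(names(chrom_len_kb)))
    names(chrom_len_kb) <- paste0("chr", seq_along(chrom_len_kb))
  len_bins <- as.integer(ceiling(chrom_len_kb / bin_kb))
  n <- sum(len_bins)
  if (is.null(mask)) mask <- rep(FALSE, n)
  stopifnot(is.logical(mask), length(mask) == n, !anyNA(mask))
  structure(list(
    chrom_names    = names(chrom_len_kb),
    chrom_len_bins = len_bins,
    bin_kb         = bin_kb,
    n_bins         = n,
    mask           = mask
  ), class = "genome_lattice")
}

#' @export
print.genome_lattice <- function(x, ...) {
  cat("genome_lattice:", length(x$chrom_names), "chromosome(s),",
      x$n_bins, "bins of", x$bin_kb, "kb (",
      format(x$n_bins * x$bin_kb / 1000, digits = 4), "Mb );",
      sum(x$mask), "masked bin(s)\n")
  invisible(x)
}

# chromosome index (1-based) of every bin
lattice_chrom_of_bin <- function(lattice) {
  rep.int(seq_along(lattice$chrom_len_bins), lattice$chrom_len_bins)
}

# first global bin index of each chromosome
lattice_chrom_offsets <- function(lattice) {
  c(0L, cumsum(lattice$chrom_len_bins))[seq_along(lattice$chrom_len_bins)]
}

# global bin indices of one chromosome
lattice_chrom_bins <- function(lattice, chrom) {
  i <- match(chrom, lattice$chrom_names)
  if (is.na(i)) stop("unknown chromosome: ", chrom)
  off <- lattice_chrom_offsets(lattice)[i]
  seq.int(off + 1L, off + lattice$chrom_len_bins[i])
}

# bin centre coordinate in kb, measured from the chromosome start
lattice_bin_center_kb <- function(lattice) {
  unlist(lapply(lattice$chrom_len_bins, function(n)
    (seq_len(n) - 0.5) * lattice$bin_kb), use.names = FALSE)
}

PROFILE_KINDS <- c("MRT_fraction", "MRT_time_min", "RFD", "IPLS", "generic")

#' Per-bin genomic profile
#'
#' A `profile` couples a numeric vector (one value per lattice bin, `NA` =
#' missing) with the lattice it is binned on and a `kind` tag stating its
#' units. Kind-specific invariants are checked on construction: RFD values
#' must lie in \[-1, 1\], Repli-seq-style MRT fractions in \[0, 1\], and an
#' IPLS must be non-negative and is renormalised to sum to 1 over unmasked
#' bins when `normalize = TRUE`.
#'
#' @param values numeric vector, one value per bin (`NA` allowed).
#' @param kind one of `"MRT_fraction"`, `"MRT_time_min"`, `"RFD"`,
#'   `"IPLS"`, `"generic"`.
#' @param lattice a [genome_lattice()].
#' @param normalize for `kind = "IPLS"`, renormalise to unit sum (default
#'   `TRUE`).
#' @return an object of class `profile`.
#' @export
profile <- function(values, kind = "generic", lattice, normalize = TRUE) {
  kind <- match.arg(kind, PROFILE_KINDS)
  stopifnot(inherits(lattice, "genome_lattice"),
            is.numeric(values), length(values) == lattice$n_bins)
  values <- as.numeric(values)
  ok <- !is.na(values) & !lattice$mask
  if (kind == "RFD" && any(values[ok] < -1 - 1e-9 | values[ok] > 1 + 1e-9))
    stop("RFD values must lie in [-1, 1]")
  if (kind == "MRT_fraction" && any(values[ok] < -1e-9 | values[ok] > 1 + 1e-9))
    stop("MRT_fraction values must lie in [0, 1]")
  if (kind == "IPLS") {
    if (any(values[ok] < 0)) stop("IPLS values must be non-negative")
    if (normalize) {
      s <- sum(values[ok])
      if (s <= 0) stop("IPLS has zero total mass")
      values[ok] <- values[ok] / s
    }
  }
  structure(list(values = values, kind = kind, lattice = lattice),
            class = "profile")
}

#' @export
print.profile <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat("profile [", x$kind, "] on ", x$lattice$n_bins, " bins; ",
      sum(is.na(x$values)), " missing; range ",
      if (length(v)) paste(signif(range(v), 4), collapse = " .. ") else "-",
      "\n", sep = "")
  invisible(x)
}

#' Aligned MRT / RFD profile pair
#'
#' The unit consumed and produced by the model inverter: an MRT profile (in
#' replicated-fraction units) and an RFD profile on the same lattice, plus a
#' shared mask built from the data-gap rule of [build_gap_mask()] joined
#' with the lattice mask.
#'
#' @param mrt a `profile` of kind `MRT_fraction`.
#' @param rfd a `profile` of kind `RFD`.
#' @param mask optional shared logical mask; defaults to the union of the
#'   lattice mask and the gap mask of the two profiles.
#' @param gap_len_kb,flank_kb passed to [build_gap_mask()] when `mask` is
#'   not supplied.
#' @return an object of class `profile_pair`.
#' @export
profile_pair <- function(mrt, rfd, mask = NULL,
                         gap_len_kb = 1500, flank_kb = 500) {
  stopifnot(inherits(mrt, "profile"), inherits(rfd, "profile"),
            mrt$kind == "MRT_fraction", rfd$kind == "RFD")
  if (!identical(mrt$lattice$chrom_len_bins, rfd$lattice$chrom_len_bins))
    stop("MRT and RFD profiles are on different lattices")
  lat <- mrt$lattice
  if (is.null(mask))
    mask <- build_gap_mask(list(mrt, rfd), gap_len_kb = gap_len_kb,
                           flank_kb = flank_kb)
  stopifnot(is.logical(mask), length(mask) == lat$n_bins)
  mask <- mask | lat$mask
  structure(list(mrt = mrt, rfd = rfd, mask = mask, lattice = lat),
            class = "profile_pair")
}

#' @export
print.profile_pair <- function(x, ...) {
  cat("profile_pair on", x$lattice$n_bins, "bins;",
      sum(x$mask), "masked\n")
  invisible(x)
}

# runs of TRUE in a logical vector -> data.frame(start, end) (inclusive)
logical_runs <- function(x) {
  r <- rle(x)
  end <- cumsum(r$lengths)
  start <- end - r$lengths + 1L
  data.frame(start = start[r$values], end = end[r$values])
}

#' Mask data gaps
#'
#' Builds the analysis mask from missing-data runs. Any run of missing bins
#' longer than `gap_len_kb` in any input profile is masked together with
#' `flank_kb` flanks on each side; with `small_gaps = TRUE` (the
#' profile-comparison rule) shorter missing runs are masked with the same
#' flanks as well. Runs never extend across chromosome boundaries and the
#' mask is the union across profiles.
#'
#' @param profiles a `profile` or list of profiles sharing a lattice.
#' @param gap_len_kb gap length threshold in kb (default 1500).
#' @param flank_kb flank added on each side of a masked run, kb (default
#'   500).
#' @param small_gaps also mask missing runs shorter than `gap_len_kb`
#'   (default `TRUE`, as used before profile comparisons).
#' @return logical vector, one entry per bin, `TRUE` = masked.
#' @export
build_gap_mask <- function(profiles, gap_len_kb = 1500, flank_kb = 500,
                           small_gaps = TRUE) {
  if (inherits(profiles, "profile")) profiles <- list(profiles)
  stopifnot(length(profiles) >= 1L, flank_kb >= 0)
  lat <- profiles[[1L]]$lattice
  for (p in profiles)
    stopifnot(inherits(p, "profile"),
              identical(p$lattice$chrom_len_bins, lat$chrom_len_bins))
  gap_bins <- gap_len_kb / lat$bin_kb
  flank_bins <- as.integer(round(flank_kb / lat$bin_kb))
  mask <- rep(FALSE, lat$n_bins)
  off <- lattice_chrom_offsets(lat)
  for (p in profiles) {
    for (ci in seq_along(lat$chrom_len_bins)) {
      n <- lat$chrom_len_bins[ci]
      idx <- seq.int(off[ci] + 1L, off[ci] + n)
      miss <- is.na(p$values[idx])
      if (!any(miss)) next
      runs <- logical_runs(miss)
      for (k in seq_len(nrow(runs))) {
        len <- runs$end[k] - runs$start[k] + 1L
        if (len > gap_bins || small_gaps) {
          a <- max(1L, runs$start[k] - flank_bins)
          b <- min(n, runs$end[k] + flank_bins)
          mask[idx[a:b]] <- TRUE
        }
      }
    }
  }
  mask
}

#' Running-mean smoothing of a profile
#'
#' Centered running average over a `window_kb` window. At chromosome ends
#' and next to data gaps the window is truncated to the available data;
#' masked bins never contribute. A missing bin is filled by the local mean
#' only when at least half of its window carries data, otherwise it stays
#' missing.
#'
#' @param prof a `profile`.
#' @param window_kb window width in kb; must be a positive multiple of the
#'   bin size (an odd number of bins is used: `window_kb / bin_kb` rounded
#'   to the nearest odd integer).
#' @param circular treat each chromosome as circular (used to verify exact
#'   signal conservation on gapless test lattices).
#' @return a smoothed `profile` of the same kind (IPLS output is not
#'   renormalised).
#' @export
smooth_profile <- function(prof, window_kb, circular = FALSE) {
  stopifnot(inherits(prof, "profile"), window_kb > 0)
  lat <- prof$lattice
  w <- window_kb / lat$bin_kb
  if (w < 1) stop("smoothing window smaller than one bin")
  half <- floor(w / 2)
  vals <- prof$values
  vals[lat$mask] <- NA_real_
  out <- rep(NA_real_, lat$n_bins)
  off <- lattice_chrom_offsets(lat)
  for (ci in seq_along(lat$chrom_len_bins)) {
    n <- lat$chrom_len_bins[ci]
    idx <- seq.int(off[ci] + 1L, off[ci] + n)
    x <- vals[idx]
    out[idx] <- running_mean(x, half, circular = circular)
  }
  # only fill missing bins when >= half the window held data
  filled <- is.na(vals) & !is.na(out)
  if (any(filled)) {
    support <- running_mean_support(vals, lat, half, circular)
    out[filled & support < (half + 1)] <- NA_real_
    out[lat$mask] <- NA_real_
  }
  profile(out, kind = prof$kind, lattice = lat, normalize = FALSE)
}

# centered running mean over +-half bins, NA-aware, truncated at ends
running_mean <- function(x, half, circular = FALSE) {
  n <- length(x)
  if (half == 0L) return(x)
  if (circular) {
    xx <- c(x[(n - half + 1L):n], x, x[1:half])
    rm <- running_mean(xx, half, circular = FALSE)
    return(rm[(half + 1L):(half + n)])
  }
  ok <- !is.na(x)
  xs <- ifelse(ok, x, 0)
  cs <- c(0, cumsum(xs))
  ck <- c(0, cumsum(as.numeric(ok)))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  s <- cs[hi + 1L] - cs[lo]
  k <- ck[hi + 1L] - ck[lo]
  out <- ifelse(k > 0, s / k, NA_real_)
  out
}

# number of data-carrying bins in each bin's window
running_mean_support <- function(vals, lat, half, circular) {
  out <- integer(lat$n_bins)
  off <- lattice_chrom_offsets(lat)
  for (ci in seq_along(lat$chrom_len_bins)) {
    n <- lat$chrom_len_bins[ci]
    idx <- seq.int(off[ci] + 1L, off[ci] + n)
    ok <- as.numeric(!is.na(vals[idx]))
    if (circular && n > 2L * half) {
      ok2 <- c(ok[(n - half + 1L):n], ok, ok[1:half])
      ck <- c(0, cumsum(ok2))
      out[idx] <- as.integer(ck[seq_len(n) + 2L * half + 1L] - ck[seq_len(n)])
    } else {
      ck <- c(0, cumsum(ok))
      lo <- pmax(seq_len(n) - half, 1L)
      hi <- pmin(seq_len(n) + half, n)
      out[idx] <- as.integer(ck[hi + 1L] - ck[lo])
    }
  }
  out
}
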