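#' Read a genomic signal file onto a lattice
#'
#' Parses a bedGraph, BED peak or wiggle file (via \pkg{rtracklayer}) and
#' bins it at the lattice resolution. bedGraph / wig values are aggregated
#' into each bin by the coverage-weighted mean of the records overlapping
#' it; BED peaks are aggregated as summed coverage (bp of peak per bin).
#' Coordinates are 0-based half-open, bin `i` of a chromosome covering
#' `[i * bin, (i + 1) * bin)`.
#'
#' For bedGraph and wig input, bins not covered by any record are flagged
#' missing (`NA`); for BED peaks, zero coverage is data and uncovered bins
#' are 0.
#'
#' @param path file path.
#' @param lattice target [genome_lattice()].
#' @param format `"bedGraph"`, `"BED"` or `"wig"`.
#' @param kind profile kind tag, see [profile()].
#' @return a [profile()].
#' @export
read_profile <- function(path, lattice, format = c("bedGraph", "BED", "wig"),
                         kind = "generic") {
  format <- match.arg(format)
  stopifnot(inherits(lattice, "genome_lattice"))
  gr <- rtracklayer::import(path, format = format)
  chrom <- as.character(GenomeInfoDb::seqnames(gr))
  ci <- match(chrom, lattice$chrom_names)
  if (anyNA(ci))
    stop("unknown chromosome in ", path, ": ",
         paste(unique(chrom[is.na(ci)]), collapse = ", "))
  s <- BiocGenerics::start(gr) - 1L           # back to 0-based
  e <- BiocGenerics::end(gr)
  len_bp <- lattice$chrom_len_bins[ci] * lattice$bin_kb * 1000
  if (any(e > len_bp + 1e-9) || any(s < 0))
    stop("record coordinates outside chromosome bounds in ", path)
  if (format == "BED") {
    v <- rep(1, length(gr))                   # coverage weight
  } else {
    v <- as.numeric(S4Vectors::mcols(gr)$score)
    # overlapping bedGraph records are ambiguous
    o <- order(ci, s)
    ss <- s[o]; ee <- e[o]
    same <- diff(ci[o]) == 0L
    if (length(ss) > 1L && any(same & ss[-1L] < ee[-length(ee)]))
      stop("overlapping intervals in ", path)
  }
  binbp <- lattice$bin_kb * 1000
  off <- lattice_chrom_offsets(lattice)
  b0 <- floor(s / binbp)
  b1 <- floor((e - 1) / binbp)
  nb <- b1 - b0 + 1L
  ri <- rep.int(seq_along(s), nb)
  bin_local <- sequence(nb) - 1L + b0[ri]
  bin_glob <- off[ci[ri]] + bin_local + 1L
  ov <- pmin(e[ri], (bin_local + 1) * binbp) - pmax(s[ri], bin_local * binbp)
  wsum <- numeric(lattice$n_bins)
  w <- numeric(lattice$n_bins)
  acc <- rowsum(cbind(v[ri] * ov, ov), bin_glob)
  at <- as.integer(rownames(acc))
  wsum[at] <- acc[, 1L]
  w[at] <- acc[, 2L]
  if (format == "BED") {
    vals <- wsum                              # total covered bp per bin
  } else {
    vals <- ifelse(w > 0, wsum / w, NA_real_)
  }
  profile(vals, kind = kind, lattice = lattice, normalize = FALSE)
}

#' Write a profile as bedGraph
#'
#' Emits a 4-column bedGraph (0-based half-open). Adjacent bins with
#' identical values are merged into one record; missing bins are omitted.
#' Values are printed with 17 significant digits so that
#' `read_profile(write_profile(p))` reproduces `p` exactly.
#'
#' @param prof a [profile()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(prof, path) {
  stopifnot(inherits(prof, "profile"))
  lat <- prof$lattice
  binbp <- lat$bin_kb * 1000
  off <- lattice_chrom_offsets(lat)
  con <- file(path, "w")
  on.exit(close(con))
  for (ci in seq_along(lat$chrom_len_bins)) {
    n <- lat$chrom_len_bins[ci]
    v <- prof$values[seq.int(off[ci] + 1L, off[ci] + n)]
    r <- rle(sprintf("%.17g", v))
    end_bin <- cumsum(r$lengths)
    start_bin <- end_bin - r$lengths
    keep <- r$values != sprintf("%.17g", NA_real_)
    if (!any(keep)) next
    writeLines(sprintf("%s\t%.0f\t%.0f\t%s",
                       lat$chrom_names[ci],
                       start_bin[keep] * binbp,
                       end_bin[keep] * binbp,
                       r$values[keep]), con)
  }
  invisible(path)
}
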