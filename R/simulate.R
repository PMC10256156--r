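#' Replication model parameters
#'
#' Parameter vector of the stochastic S-phase model. The firing reaction is
#' bimolecular between free firing factors and potential origins with rate
#' `kon`; to keep the kinetic regime invariant under genome size the model
#' is parameterised through the genome-size-invariant constant
#' `kone = kon * L` (kb/min), so that `kon = kone / L` for a genome of `L`
#' kb. Firing factors (`N_F = round(rho_F * L)`, with `rho_F` per Mb)
#' become available progressively with exponential time constant `tau`.
#' Potential origins (`N_PO = round(L / d_PO)`) are drawn from the
#' effective landscape `(1 - r) * IPLS + r * uniform` before each S phase.
#'
#' @param v fork speed, kb/min (default 1.5).
#' @param kone genome-size-invariant reaction constant `kon * L`, kb/min
#'   (default 8.625; for the 2,875 Mb human autosomal genome this gives
#'   `kon = 3e-6` per min).
#' @param rho_F density of firing factors, per Mb (default 0.56).
#' @param d_PO mean distance between potential origins, kb (default 20).
#' @param r fraction of uniform (dispersed) initiation, in \[0, 1\]
#'   (default 0).
#' @param tau firing-factor activation time constant, min (default 60).
#' @param n_sims ensemble size (default 200).
#' @return an object of class `sim_params`.
#' @export
sim_params <- function(v = 1.5, kone = 8.625, rho_F = 0.56, d_PO = 20,
                       r = 0, tau = 60, n_sims = 200) {
  stopifnot(v > 0, kone > 0, rho_F > 0, d_PO > 0,
            r >= 0, r <= 1, tau >= 0, n_sims >= 1)
  structure(list(v = v, kone = kone, rho_F = rho_F, d_PO = d_PO,
                 r = r, tau = tau, n_sims = as.integer(n_sims)),
            class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf(paste0("sim_params: v = %g kb/min, kone = %g kb/min, ",
                     "rho_F = %g /Mb, d_PO = %g kb, r = %g, tau = %g min, ",
                     "n_sims = %d\n"),
              x$v, x$kone, x$rho_F, x$d_PO, x$r, x$tau, x$n_sims))
  invisible(x)
}

#' Rescale the reaction rate to a genome size
#'
#' `kon = kone / L`: the bimolecular firing rate for a genome of length `L`
#' kb given the size-invariant constant `kone`.
#'
#' @param kone size-invariant rate constant, kb/min.
#' @param L_kb genome length in kb.
#' @return `kon` in 1/min.
#' @export
rescale_kon <- function(kone, L_kb) {
  stopifnot(L_kb > 0, kone > 0)
  kone / L_kb
}

# unmasked genome length in kb
lattice_length_kb <- function(lattice) {
  sum(!lattice$mask) * lattice$bin_kb
}

#' Effective initiation landscape
#'
#' Mixes a structured IPLS with a uniform floor: the effective per-bin
#' initiation probability is `(1 - r) * I(x) + r / n_unmasked`, normalised
#' to unit sum over unmasked bins.
#'
#' @param structured a `profile` of kind `IPLS`.
#' @param r uniform fraction in \[0, 1\].
#' @return a `profile` of kind `IPLS` with attribute `r`.
#' @export
effective_ipls <- function(structured, r) {
  stopifnot(inherits(structured, "profile"), r >= 0, r <= 1)
  lat <- structured$lattice
  ok <- !lat$mask & !is.na(structured$values)
  v <- structured$values
  v[!ok] <- 0
  s <- sum(v)
  if (s <= 0 && r <= 0) stop("all-zero landscape")
  if (s > 0) v <- v / s
  eff <- (1 - r) * v
  eff[!lat$mask] <- eff[!lat$mask] + r / sum(!lat$mask)
  eff[lat$mask] <- 0
  profile(eff, kind = "IPLS", lattice = lat, normalize = TRUE)
}

# contiguous unmasked runs within chromosomes
lattice_segments <- function(lattice) {
  chrom <- lattice_chrom_of_bin(lattice)
  key <- ifelse(lattice$mask, 0L, chrom)
  r <- rle(key)
  end <- cumsum(r$lengths)
  start <- end - r$lengths + 1L
  keep <- r$values != 0L
  data.frame(chrom = r$values[keep], bin_start = start[keep],
             bin_end = end[keep],
             len_kb = (end[keep] - start[keep] + 1L) * lattice$bin_kb)
}

#' Draw potential origins from an initiation landscape
#'
#' Multinomial draw with replacement of `n_po` potential origins over bins,
#' with per-bin probability equal to the effective landscape (masked bins
#' have probability zero). Several origins can land in the same bin; they
#' then share the bin-centre position.
#'
#' @param ipls a `profile` of kind `IPLS` (the effective landscape).
#' @param n_po number of potential origins to draw.
#' @return integer vector of per-bin origin counts.
#' @export
draw_potential_origins <- function(ipls, n_po) {
  stopifnot(inherits(ipls, "profile"), n_po >= 1)
  p <- ipls$values
  p[is.na(p) | ipls$lattice$mask] <- 0
  if (sum(p) <= 0) stop("all-zero landscape")
  as.integer(stats::rmultinom(1L, as.integer(n_po), p))
}

#' Simulate one S phase
#'
#' Event-driven stochastic simulation of whole-genome replication: potential
#' origins drawn from the effective landscape fire by a bimolecular reaction
#' with a limiting, progressively activated pool of firing factors; each
#' firing traps one factor and creates two diverging forks moving at `v`;
#' forks passivate the unfired origins they sweep; a fork merge is a
#' termination that releases one factor, and every two forks retired at
#' segment boundaries release one factor.
#'
#' @param lattice a [genome_lattice()].
#' @param ipls structured IPLS `profile` (mixed with the uniform fraction
#'   `params$r` internally).
#' @param params a [sim_params()].
#' @param origin_counts optional per-bin potential-origin counts, bypassing
#'   the multinomial draw (used for controlled experiments).
#' @return a `replication_record`: per-bin `rt_min` and `fork_sign`
#'   (+1/-1/0), `fired` counts, `replicated_fraction_at_rt`, the free-factor
#'   trace (`f_free_t`, `f_free_n`), firing events (`fire_t`, `fire_bin`),
#'   and event counters (`inits`, `merges`, `retired`, `t_end`).
#' @export
simulate_s_phase <- function(lattice, ipls, params, origin_counts = NULL) {
  stopifnot(inherits(lattice, "genome_lattice"), inherits(params, "sim_params"))
  L <- lattice_length_kb(lattice)
  kon <- rescale_kon(params$kone, L)
  n_f <- max(1L, as.integer(round(params$rho_F * L / 1000)))
  n_po <- max(1L, as.integer(round(L / params$d_PO)))
  eff <- effective_ipls(ipls, params$r)
  if (is.null(origin_counts)) origin_counts <- draw_potential_origins(eff, n_po)
  stopifnot(length(origin_counts) == lattice$n_bins)

  segs <- lattice_segments(lattice)
  seg_of_bin <- integer(lattice$n_bins)
  for (si in seq_len(nrow(segs)))
    seg_of_bin[segs$bin_start[si]:segs$bin_end[si]] <- si

  o_bin <- rep.int(seq_len(lattice$n_bins), origin_counts)
  o_seg <- seg_of_bin[o_bin]
  if (any(o_seg == 0L))
    stop("potential origin drawn in a masked bin")
  miss <- setdiff(seq_len(nrow(segs)), unique(o_seg))
  if (length(miss))
    stop("unreplicable segment(s) without potential origins: ",
         paste(sprintf("%s:%d-%d", lattice$chrom_names[segs$chrom[miss]],
                       segs$bin_start[miss], segs$bin_end[miss]),
               collapse = ", "))
  # segment-local bin-centre position in kb
  o_pos <- (o_bin - segs$bin_start[o_seg] + 0.5) * lattice$bin_kb
  ord <- order(o_seg, o_pos)
  o_pos <- o_pos[ord]; o_seg <- o_seg[ord]; o_bin <- o_bin[ord]

  res <- .sim_core(o_pos, o_seg - 1L, segs$len_kb, params$v, kon,
                   n_f, params$tau, max_events = 5e7)

  rt <- rep(NA_real_, lattice$n_bins)
  sign <- rep(NA_integer_, lattice$n_bins)
  for (si in seq_len(nrow(segs))) {
    in_seg <- res$fire_seg == si - 1L
    pf <- .propagate_forks(res$fire_pos[in_seg], res$fire_t[in_seg],
                           segs$len_kb[si],
                           segs$bin_end[si] - segs$bin_start[si] + 1L,
                           lattice$bin_kb, params$v)
    idx <- segs$bin_start[si]:segs$bin_end[si]
    rt[idx] <- pf$rt
    sign[idx] <- pf$sign
  }
  fire_bin <- o_bin[res$fire_origin + 1L]
  fired <- tabulate(fire_bin, nbins = lattice$n_bins)
  ok <- !lattice$mask
  frac <- rep(NA_real_, lattice$n_bins)
  frac[ok] <- (rank(rt[ok], ties.method = "average") - 0.5) / sum(ok)

  structure(list(
    rt_min = rt, fork_sign = sign, fired = fired,
    replicated_fraction_at_rt = frac,
    f_free_t = res$ffree_t, f_free_n = res$ffree_n,
    fire_t = res$fire_t, fire_bin = fire_bin,
    inits = res$inits, merges = res$merges, retired = res$retired,
    t_end = res$t_end, n_f = n_f, n_po_drawn = sum(origin_counts),
    kon = kon
  ), class = "replication_record")
}

#' Simulate an ensemble of S phases
#'
#' Runs `params$n_sims` independent S-phase simulations. Each simulation
#' index `i` uses its own seeded RNG stream (`seed + i - 1`), so results do
#' not depend on how the ensemble is batched.
#'
#' @param lattice a [genome_lattice()].
#' @param ipls structured IPLS `profile`.
#' @param params a [sim_params()].
#' @param seed base RNG seed.
#' @return a `replication_ensemble` holding the per-simulation records.
#' @export
simulate_ensemble <- function(lattice, ipls, params, seed = 1L) {
  records <- vector("list", params$n_sims)
  for (i in seq_len(params$n_sims)) {
    set.seed(seed + i - 1L)
    records[[i]] <- simulate_s_phase(lattice, ipls, params)
  }
  structure(list(records = records, n_sims = params$n_sims,
                 lattice = lattice, params = params, ipls = ipls,
                 seed = seed),
            class = "replication_ensemble")
}

#' @export
print.replication_ensemble <- function(x, ...) {
  cat("replication_ensemble:", x$n_sims, "simulation(s) on",
      x$lattice$n_bins, "bins\n")
  invisible(x)
}
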