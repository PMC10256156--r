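# shared fixtures, built once per test session

.fixture_env <- new.env(parent = emptyenv())

repliscape_test_env <- function() .fixture_env

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# one-chromosome toy lattice
toy_lattice <- function(n_bins = 200L, bin_kb = 5) {
  genome_lattice(c(chrT = n_bins * bin_kb), bin_kb = bin_kb)
}

# reference-parameter ensemble on the default synthetic landscape;
# used by several observable tests
ref_ensemble_small <- function() {
  fixture("ref_ens_small", function() {
    g <- generate_ipls(synthetic_spec(), seed = 3)
    params <- sim_params(n_sims = 60)
    ens <- simulate_ensemble(g$lattice, g$ipls, params, seed = 7)
    list(g = g, ens = ens, params = params)
  })
}

# deterministic single-origin record: one potential origin at `bin`
single_origin_record <- function(bin = 40L, n_bins = 200L, v = 1.5,
                                 seed = 1L) {
  lat <- toy_lattice(n_bins)
  counts <- integer(n_bins)
  counts[bin] <- 1L
  params <- sim_params(v = v, kone = 1000, rho_F = 5, tau = 0, n_sims = 1)
  set.seed(seed)
  uni <- profile(rep(1, n_bins), "IPLS", lat)
  rec <- simulate_s_phase(lat, uni, params, origin_counts = counts)
  list(rec = rec, lat = lat, bin = bin, v = v)
}

# the reference in-model validation ensemble: 100 Mb synthetic landscape,
# 200 simulations, reference parameters
acceptance_ensemble <- function(seed = 101L) {
  fixture("acceptance_ens", function() {
    g <- generate_ipls(synthetic_spec(n_chrom = 4, chrom_len_mb = rep(25, 4)),
                       seed = seed)
    params <- sim_params(n_sims = 200)
    ens <- simulate_ensemble(g$lattice, g$ipls, params, seed = seed + 1L)
    L <- sum(!g$lattice$mask) * g$lattice$bin_kb
    oe <- compute_oe(ens)
    rfd <- compute_rfd(ens)
    drfd <- delta_rfd(rfd, keep_top_fraction = NULL)
    izs <- detect_izs(drfd)
    list(g = g, ens = ens, params = params, L = L,
         kon = rescale_kon(params$kone, L),
         oe = oe, rfd = rfd, drfd = drfd, izs = izs)
  })
}

through_origin_slope <- function(x, y) sum(x * y) / sum(x * x)

expect_profile <- function(p, kind = NULL) {
  expect_s3_class(p, "profile")
  if (!is.null(kind)) expect_identical(p$kind, kind)
}
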