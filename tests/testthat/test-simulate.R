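test_that("kon rescaling", {
  expect_equal(rescale_kon(8.625, 2875000), 3e-6)
  expect_equal(rescale_kon(8.625, 8625), 1e-3)
  expect_equal(rescale_kon(8.625, 1000) / rescale_kon(8.625, 2000), 2)
  expect_error(rescale_kon(8.625, -1))
})

test_that("potential-origin draws follow the landscape", {
  lat <- toy_lattice(1000)
  point <- profile(c(rep(0, 6), 1, rep(0, 993)), "IPLS", lat)
  set.seed(1)
  d <- draw_potential_origins(point, 10)
  expect_equal(d[7], 10L)
  expect_equal(sum(d), 10L)
  zero <- profile(rep(1, 1000), "IPLS", lat, normalize = FALSE)
  zero$values[] <- 0
  expect_error(draw_potential_origins(zero, 5), "all-zero")
  # uniform draw passes a chi-square goodness-of-fit test in >= 48/50 seeds
  uni <- profile(rep(1, 1000), "IPLS", lat)
  pass <- 0L
  for (s in 1:50) {
    set.seed(s)
    cnt <- draw_potential_origins(uni, 1e5)
    pv <- suppressWarnings(chisq.test(cnt)$p.value)
    if (pv > 1e-3) pass <- pass + 1L
  }
  expect_gte(pass, 48L)
})

test_that("pure uniform fraction equals a uniform landscape", {
  lat <- toy_lattice(100)
  peaky <- profile(c(rep(0, 99), 1), "IPLS", lat)
  eff <- effective_ipls(peaky, r = 1)
  expect_equal(eff$values, rep(1 / 100, 100))
})

test_that("single-origin geometry: rt and fork sign", {
  so <- single_origin_record(bin = 40L)
  rec <- so$rec
  x0 <- (so$bin - 0.5) * so$lat$bin_kb
  t0 <- rec$fire_t[1]
  expect_equal(rec$inits, 1L)
  cen <- (seq_len(so$lat$n_bins) - 0.5) * so$lat$bin_kb
  expect_equal(rec$rt_min, t0 + abs(cen - x0) / so$v)
  expect_equal(rec$fork_sign, ifelse(cen < x0, -1L, ifelse(cen > x0, 1L, 0L)))
  expect_equal(rec$fork_sign[so$bin], 0L)
})

test_that("two simultaneous origins terminate at the midpoint and conserve factors", {
  lat <- toy_lattice(200)
  counts <- integer(200)
  counts[c(50, 150)] <- 1L
  params <- sim_params(kone = 1e5, rho_F = 5, tau = 0, n_sims = 1)
  set.seed(2)
  rec <- simulate_s_phase(lat, profile(rep(1, 200), "IPLS", lat), params,
                          origin_counts = counts)
  expect_equal(rec$inits, 2L)
  expect_equal(rec$merges, 1L)
  expect_equal(rec$retired, 2L)
  expect_equal(rec$inits - rec$merges - rec$retired / 2, 0)
  # near-simultaneous firing: termination in the middle bin
  expect_equal(rec$fork_sign[100], 0L)
  expect_equal(rec$fork_sign[c(50, 150)], c(0L, 0L))
  expect_equal(rec$fork_sign[60], 1L)    # right of the left origin
  expect_equal(rec$fork_sign[130], -1L)  # left of the right origin
})

test_that("instant-firing limit matches the distance-transform oracle", {
  lat <- toy_lattice(200)
  set.seed(3)
  bins <- sort(sample(200, 6))
  counts <- integer(200)
  counts[bins] <- 1L
  params <- sim_params(kone = 1e7, rho_F = 50, tau = 0, n_sims = 1)
  set.seed(4)
  rec <- simulate_s_phase(lat, profile(rep(1, 200), "IPLS", lat), params,
                          origin_counts = counts)
  cen <- (seq_len(200) - 0.5) * 5
  dist <- vapply(cen, function(x) min(abs(x - cen[bins])), 0)
  t100_oracle <- max(dist) / params$v
  t95_sim <- max(rec$rt_min) - min(rec$fire_t)
  expect_lt(abs(t95_sim - t100_oracle) / t100_oracle, 0.02)
})

test_that("forced-firing propagation matches an exhaustive oracle", {
  # three origins with chosen firing times; compare the compiled
  # propagation against a direct first-passage computation
  pos <- c(102.5, 302.5, 702.5)
  tf <- c(0, 50, 10)
  v <- 1.5
  n_bins <- 200L
  pf <- repliscape:::.propagate_forks(pos, tf, 1000, n_bins, 5, v)
  cen <- (seq_len(n_bins) - 0.5) * 5
  rt_o <- vapply(cen, function(x) min(tf + abs(x - pos) / v), 0)
  expect_equal(pf$rt, rt_o)
  src <- vapply(cen, function(x) which.min(tf + abs(x - pos) / v), 0L)
  sign_o <- sign(cen - pos[src])
  # origin and termination bins carry 0; elsewhere signs must agree
  nz <- pf$sign != 0L
  expect_equal(pf$sign[nz], sign_o[nz])
  expect_equal(which(pf$sign == 0L & cen %in% pos), match(pos, cen))
  # termination bins: meeting points of consecutive fired origins (a
  # meeting point exactly on a bin edge may fall in either adjacent bin)
  m12 <- (pos[1] + pos[2]) / 2 + v * (tf[2] - tf[1]) / 2
  m23 <- (pos[2] + pos[3]) / 2 + v * (tf[3] - tf[2]) / 2
  zeros <- which(pf$sign == 0L)
  for (mp in c(m12, m23))
    expect_true(min(abs(zeros - (floor(mp / 5) + 0.5))) <= 1)
})

test_that("ensemble conservation and fork-count bound", {
  fx <- ref_ensemble_small()
  for (rec in fx$ens$records[1:20]) {
    expect_equal(rec$inits - rec$merges - rec$retired / 2, 0)
    expect_false(anyNA(rec$rt_min[!fx$ens$lattice$mask]))
    # active forks <= 2 * engaged <= 2 * N_F at all times:
    # engaged never exceeds N_F, so free counts are within [0, N_F]
    expect_true(all(rec$f_free_n >= 0 & rec$f_free_n <= rec$n_f))
  }
})

test_that("per-index seeding makes ensembles batch-invariant", {
  g <- generate_ipls(synthetic_spec(n_chrom = 1, chrom_len_mb = 10), seed = 5)
  p2 <- sim_params(n_sims = 2)
  p4 <- sim_params(n_sims = 4)
  e2 <- simulate_ensemble(g$lattice, g$ipls, p2, seed = 9)
  e4 <- simulate_ensemble(g$lattice, g$ipls, p4, seed = 9)
  expect_identical(e2$records[[1]]$rt_min, e4$records[[1]]$rt_min)
  expect_identical(e2$records[[2]]$fire_t, e4$records[[2]]$fire_t)
})

test_that("more firing factors do not slow replication", {
  g <- generate_ipls(synthetic_spec(n_chrom = 1, chrom_len_mb = 15), seed = 6)
  t95 <- sapply(c(0.4, 0.8), function(rho) {
    p <- sim_params(rho_F = rho, n_sims = 12)
    ens <- simulate_ensemble(g$lattice, g$ipls, p, seed = 11)
    kinetics_summary(ens)$T95
  })
  expect_lte(t95[2], t95[1])
})

test_that("strong-affinity limit: T_S is close to 1 / (2 v rho_F)", {
  lat <- genome_lattice(c(chr1 = 20000), bin_kb = 5)   # 20 Mb
  uni <- profile(rep(1, lat$n_bins), "IPLS", lat)
  p <- sim_params(kone = 8625, rho_F = 0.56, tau = 0, n_sims = 12)
  ens <- simulate_ensemble(lat, uni, p, seed = 13)
  ks <- kinetics_summary(ens)
  ts_theory <- 1 / (2 * p$v * p$rho_F / 1000)
  expect_lt(abs(ks$T99 - ts_theory) / ts_theory, 0.15)
})

test_that("an origin-free segment is reported as unreplicable", {
  lat <- genome_lattice(c(chrA = 500, chrB = 500), bin_kb = 5)
  counts <- integer(200)
  counts[10] <- 5L   # all origins on chrA
  p <- sim_params(n_sims = 1)
  set.seed(1)
  expect_error(
    simulate_s_phase(lat, profile(rep(1, 200), "IPLS", lat), p,
                     origin_counts = counts),
    "unreplicable")
})
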