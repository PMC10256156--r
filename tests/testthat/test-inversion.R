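# a small simulated MRT/RFD pair with a known landscape, shared by the
# inverter tests
inv_fixture <- function() {
  fixture("inv_fixture", function() {
    spec <- synthetic_spec(n_chrom = 3, chrom_len_mb = rep(8, 3))
    g <- generate_ipls(spec, seed = 11)
    params <- sim_params(rho_F = 0.56, r = 0, n_sims = 100)
    ens <- simulate_ensemble(g$lattice, g$ipls, params, seed = 21)
    pair <- profile_pair(compute_mrt_fractions(ens), compute_rfd(ens))
    list(g = g, pair = pair, params = params)
  })
}

test_that("initial IPLS from RFD upshifts follows the percentile rule", {
  fx <- inv_fixture()
  i0 <- init_ipls(fx$pair$rfd)
  expect_profile(i0, "IPLS")
  expect_equal(sum(i0$values), 1)
  # mass concentrates near a real upshift
  top_iz <- fx$g$izs$bin[which.max(fx$g$izs$strength)]
  expect_gt(sum(i0$values[(top_iz - 10):(top_iz + 10)]), 0)
  # continuous random increments: exactly 20% of bins survive
  lat <- toy_lattice(500)
  set.seed(16)
  noisy <- profile(pmin(pmax(rnorm(500, 0, 0.2), -1), 1), "RFD", lat)
  i0n <- init_ipls(noisy)
  expect_equal(sum(i0n$values > 0), round(0.2 * 500))
  # flat or monotone-decreasing RFD carries no initiation signal
  expect_error(init_ipls(profile(rep(0.2, 500), "RFD", lat)), "flat")
  expect_error(init_ipls(profile(seq(1, -1, length.out = 500), "RFD", lat)),
               "monotone|flat")
})

test_that("gradient of the network matches finite differences", {
  set.seed(17)
  net <- repliscape:::cnn_new(41L, n_filters = 3L, kernel = 4L, seed = 5)
  L <- 80L
  X <- matrix(rnorm(L * 2), L, 2)
  starts <- c(3L, 10L, 25L)
  half <- 20L
  y <- c(0.2, 0.7, 0.4)
  loss_of <- function(w) {
    net$w <- w
    fp <- repliscape:::cnn_forward(net, X, starts, training = FALSE)
    repliscape:::bce_loss(fp$p, y)
  }
  fp <- repliscape:::cnn_forward(net, X, starts, training = FALSE)
  dz <- matrix((fp$p - y) / length(y), ncol = 1)
  g <- repliscape:::cnn_backward(net, fp, dz)
  for (nm in c("W1", "W2", "W3", "wd", "bd", "b2")) {
    w0 <- net$w
    theta <- w0[[nm]]
    idx <- seq_len(min(5, length(theta)))
    for (i in idx) {
      eps <- 1e-6
      wp <- w0; wp[[nm]][i] <- wp[[nm]][i] + eps
      wm <- w0; wm[[nm]][i] <- wm[[nm]][i] - eps
      fd <- (loss_of(wp) - loss_of(wm)) / (2 * eps)
      expect_equal(as.numeric(g[[nm]][i]), fd, tolerance = 1e-4)
    }
  }
})

test_that("training is seed-deterministic and augmentation leaves targets alone", {
  fx <- inv_fixture()
  m1 <- train_inverter(fx$pair, fx$g$ipls, r = 0, seed = 3,
                       window_bins = 101L, epochs = 5L, patience = 5L)
  m2 <- train_inverter(fx$pair, fx$g$ipls, r = 0, seed = 3,
                       window_bins = 101L, epochs = 5L, patience = 5L)
  expect_identical(m1$net$w, m2$net$w)
  expect_identical(m1$val_history, m2$val_history)
  # the scaled target only depends on the landscape, not the augmentation
  expect_equal(m1$scale, max(repliscape:::effective_ipls(fx$g$ipls, 0)$values[
    unlist(lapply(m1$split$train, repliscape:::lattice_chrom_bins,
                  lattice = fx$pair$lattice))]))
  expect_error(train_inverter(fx$pair, fx$g$ipls, r = 0,
                              split = list(train = "nope", val = "x",
                                           test = "y")))
})

test_that("split requires three chromosomes unless given explicitly", {
  g <- generate_ipls(synthetic_spec(n_chrom = 1, chrom_len_mb = 8), seed = 1)
  params <- sim_params(n_sims = 20)
  ens <- simulate_ensemble(g$lattice, g$ipls, params, seed = 2)
  pair <- profile_pair(compute_mrt_fractions(ens), compute_rfd(ens))
  expect_error(train_inverter(pair, g$ipls, r = 0), "3 chromosomes")
})

test_that("a trained inverter recovers the landscape on held-out windows", {
  fx <- inv_fixture()
  m <- train_inverter(fx$pair, fx$g$ipls, r = 0, seed = 3,
                      window_bins = 101L, epochs = 100L, patience = 10L)
  pred <- apply_inverter(m, fx$pair)
  expect_profile(pred, "IPLS")
  expect_equal(sum(pred$values), 1)
  test_bins <- repliscape:::lattice_chrom_bins(fx$pair$lattice,
                                               m$split$test)
  expect_gt(cor(pred$values[test_bins], fx$g$ipls$values[test_bins]), 0.8)
  # masked bins give zero output
  pair2 <- fx$pair
  pair2$mask[1:50] <- TRUE
  pred2 <- apply_inverter(m, pair2)
  expect_true(all(pred2$values[1:50] == 0))
  assign("trained_inverter", list(m = m), envir = repliscape_test_env())
})

test_that("convolution predictions are translation-equivariant", {
  fx <- inv_fixture()
  m <- get("trained_inverter", envir = repliscape_test_env())$m
  lat1 <- genome_lattice(c(chrS = 8000), bin_kb = 5)
  idx <- repliscape:::lattice_chrom_bins(fx$pair$lattice, "chr1")
  mk_pair <- function(shift) {
    v_m <- fx$pair$mrt$values[idx]
    v_r <- fx$pair$rfd$values[idx]
    if (shift > 0) {
      v_m <- c(v_m[-seq_len(shift)], v_m[seq_len(shift)])
      v_r <- c(v_r[-seq_len(shift)], v_r[seq_len(shift)])
    }
    profile_pair(profile(v_m, "MRT_fraction", lat1),
                 profile(v_r, "RFD", lat1))
  }
  p0 <- apply_inverter(m, mk_pair(0))
  p7 <- apply_inverter(m, mk_pair(7))
  interior <- 200:1200
  r0 <- p0$values[interior + 7] / sum(p0$values)
  r7 <- p7$values[interior] / sum(p7$values)
  expect_gt(cor(r0, r7), 0.999)
})

test_that("grid search scores by the summed correlations and finds the optimum", {
  fx <- inv_fixture()
  gs1 <- grid_search(fx$pair, fx$g$ipls, rho_grid = 0.56, r_grid = 0,
                     params_base = sim_params(n_sims = 10), n_sims = 10,
                     seed = 41)
  expect_equal(gs1$rho_F, 0.56)
  expect_equal(nrow(gs1$table), 1L)
  # objective = pcc_mrt + pcc_rfd, against an independent computation
  p <- sim_params(n_sims = 10)
  p$rho_F <- 0.56; p$r <- 0
  ens <- simulate_ensemble(fx$pair$lattice, fx$g$ipls, p, seed = 41)
  mrt_s <- compute_mrt_fractions(ens)$values
  rfd_s <- compute_rfd(ens)$values
  lat <- fx$pair$lattice
  pair10 <- function(x) {
    # 10 kb pairing per chromosome
    out <- c()
    for (ch in lat$chrom_names) {
      i <- repliscape:::lattice_chrom_bins(lat, ch)
      xx <- x[i]
      np <- length(i) %/% 2
      out <- c(out, (xx[seq(1, by = 2, length.out = np)] +
                     xx[seq(2, by = 2, length.out = np)]) / 2)
    }
    out
  }
  joint <- cor(pair10(mrt_s), pair10(fx$pair$mrt$values)) +
    cor(rfd_s, fx$pair$rfd$values)
  expect_equal(gs1$joint, joint, tolerance = 1e-12)
})

test_that("grid search recovers the generating factor density", {
  fx <- inv_fixture()
  gs <- grid_search(fx$pair, fx$g$ipls, rho_grid = c(0.35, 0.56, 0.9),
                    r_grid = 0, params_base = sim_params(n_sims = 16),
                    n_sims = 16, seed = 43)
  expect_equal(gs$rho_F, 0.56)
})

test_that("zero iterations return the initial state", {
  fx <- inv_fixture()
  i0 <- init_ipls(fx$pair$rfd)
  res <- iterate_inversion(fx$pair, i0, n_iter = 0, rho_grid = 0.56,
                           r_grid = 0, params_base = sim_params(n_sims = 8),
                           n_sims_grid = 8, n_sims = 8, seed = 3)
  expect_equal(length(res$states), 1L)
  expect_identical(res$ipls_best$values, i0$values)
})
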