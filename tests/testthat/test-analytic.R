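const_trace <- function(level, t_max = 2000) {
  list(times = c(0, t_max), counts = c(level, level))
}

test_that("closed-form firing probability behaves at its limits", {
  tr <- const_trace(10)
  expect_equal(predicted_oe(0, 120, tr, 1e-4), 0)
  expect_gt(predicted_oe(1e6, 120, tr, 1), 1 - 1e-12)
  expect_error(predicted_oe(-1, 10, tr, 1e-4), "non-negative")
  # small exponent 0.04: the linearisation kon * n * int F_free is within ~2%
  kon <- 1e-4
  expect_lt(abs(predicted_oe(4, 100, const_trace(1), kon) - 0.04) / 0.04,
            0.021)
})

test_that("the ~20 MCM per 5 kb estimate for an efficient early bin", {
  # dRFD/2 = 0.17 at MRT_t = 60 min under the whole-genome reaction rate
  # and a constant free-factor level of the simulations' mid-S scale
  kon <- 3e-6
  f_level <- -log(1 - 0.17) / (kon * 60 * 20)   # level implied by ~20 MCMs
  lat <- toy_lattice(4)
  dr <- profile(c(0, 0.34, 0, 0), "generic", lat, normalize = FALSE)
  mrt_t <- profile(rep(60, 4), "MRT_time_min", lat, normalize = FALSE)
  ne <- estimate_n(dr, mrt_t, const_trace(f_level), kon)
  expect_equal(ne$values[2], 20, tolerance = 1e-9)
  expect_equal(ne$values[c(1, 3, 4)], rep(0, 3))
})

test_that("Delta RFD: telescoping, flatness and top-fraction rule", {
  lat <- toy_lattice(100)
  # step -1 -> +1 at the middle
  rfd <- profile(c(rep(-1, 50), rep(1, 50)), "RFD", lat)
  dr <- delta_rfd(rfd, keep_top_fraction = NULL)
  expect_true(all(dr$values[2:100] >= 0))
  expect_equal(sum(dr$values, na.rm = TRUE), 2)
  expect_true(all(dr$values[c(2:47, 54:100)] == 0))
  flat <- delta_rfd(profile(rep(0.3, 100), "RFD", lat),
                    keep_top_fraction = NULL)
  expect_true(all(abs(flat$values[-1]) < 1e-12))
  # continuous random signal: exactly ceiling(0.15 N) nonzero bins survive
  set.seed(10)
  noisy <- profile(pmin(pmax(rnorm(100, 0, 0.3), -1), 1), "RFD", lat)
  dr15 <- delta_rfd(noisy, keep_top_fraction = 0.15)
  expect_equal(sum(dr15$values > 0, na.rm = TRUE), ceiling(0.15 * 100))
  expect_error(delta_rfd(profile(rep(NA_real_, 100), "RFD", lat)), "no unmasked")
})

test_that("IZ detection applies height and width-at-half-prominence rules", {
  lat <- toy_lattice(200)
  tri <- function(c, h, w) h * pmax(0, 1 - abs(seq_len(200) - c) / w)
  v <- tri(30, 0.1, 8) + tri(90, 0.05, 6) + tri(150, 0.01, 8)
  dr <- profile(v, "generic", lat, normalize = FALSE)
  iz <- detect_izs(dr)
  expect_equal(iz$bin, c(30L, 90L))   # 0.01 bump fails the height filter
  expect_equal(iz$delta_rfd, c(0.1, 0.05))
  expect_equal(iz$width_bins, c(8, 6))
  one <- detect_izs(profile(tri(100, 0.1, 4.5), "generic", lat,
                            normalize = FALSE))
  expect_equal(nrow(one), 1L)
  none <- detect_izs(profile(tri(100, 0.01, 8), "generic", lat,
                             normalize = FALSE))
  expect_equal(nrow(none), 0L)
})

test_that("peak finder matches the reference implementation", {
  # frozen oracle: scipy.signal.find_peaks(z, height=1.0, width=3) on the
  # stored signal
  z <- scan(test_path("peaks_signal.txt"), quiet = TRUE)
  pk <- find_peaks(z, height = 1.0, width = 3)
  expect_equal(pk$pos,
               c(12L, 48L, 54L, 79L, 92L, 108L, 139L, 151L, 202L, 235L,
                 260L, 272L, 292L, 296L, 304L, 341L, 359L, 387L))
  expect_equal(pk$width,
               c(4.09431364, 3.02311866, 15.18679120, 3.92366121,
                 21.53193577, 9.44103225, 9.17666598, 8.08321426,
                 29.79893557, 13.49199691, 10.86644085, 8.39416646,
                 3.91818257, 18.56897606, 3.43711900, 11.01995490,
                 5.90172366, 6.86987463), tolerance = 1e-7)
  expect_equal(pk$prominence,
               c(0.35848131, 0.08708420, 0.74353825, 0.36056225, 1.08053475,
                 0.82862849, 0.68236280, 0.41501402, 1.68195357, 0.85811536,
                 0.55053911, 0.49897975, 0.14594234, 0.81595078, 0.26856233,
                 1.14216253, 0.58929698, 0.53159213), tolerance = 1e-7)
})

test_that("estimate_n inverts predicted_oe to machine precision", {
  lat <- toy_lattice(50)
  set.seed(11)
  n_true <- c(rep(0, 20), runif(10, 0.5, 25), rep(0, 20))
  mrt_t <- runif(50, 30, 600)
  tr <- list(times = seq(0, 700, by = 7), counts = cumsum(runif(100)))
  kon <- 2e-4
  oe <- predicted_oe(n_true, mrt_t, tr, kon)
  dr <- profile(2 * oe, "generic", lat, normalize = FALSE)
  ne <- estimate_n(dr, profile(mrt_t, "MRT_time_min", lat, normalize = FALSE),
                   tr, kon)
  # near-saturated efficiencies round-trip through 1 - exp(-x), so agreement
  # is limited by cancellation in 1 - OE rather than by the algebra
  expect_equal(ne$values, n_true, tolerance = 1e-6)
  # dRFD = 0 -> n_e = 0; divergence guard
  expect_equal(ne$values[1], 0)
  bad <- profile(rep(2, 50), "generic", lat, normalize = FALSE)
  expect_error(estimate_n(bad, profile(mrt_t, "MRT_time_min", lat,
                                       normalize = FALSE), tr, kon),
               "diverges")
})

test_that("closed-form IPLS estimators and their relations", {
  lat <- toy_lattice(10)
  dr <- profile(rep(c(0.1, 0), 5), "generic", lat, normalize = FALSE)
  mrt <- profile(c(0, 0.5, rep(0.25, 8)), "MRT_fraction", lat)
  # exp6: equal dRFD at MRT 0 vs 0.5 -> ratio e^3
  e6 <- ipls_from_data(dr, mrt, "exp6")
  expect_equal(e6$values[1] / e6$values[3], exp(-6 * 0) / exp(-6 * 0.25))
  # flat dRFD: output proportional to exp(-6 MRT) alone
  drf <- profile(rep(0.1, 10), "generic", lat, normalize = FALSE)
  e6f <- ipls_from_data(drf, mrt, "exp6")
  w <- exp(-6 * mrt$values)
  expect_equal(e6f$values, w / sum(w))
  # all variants agree (up to normalisation) at constant MRT
  mrt_c <- profile(rep(0.3, 10), "MRT_fraction", lat)
  a <- ipls_from_data(dr, mrt_c, "exp6")$values
  b <- ipls_from_data(dr, mrt_c, "inverse_mrt")$values
  ci <- ipls_from_data(dr, mrt_c, "integral", trace = const_trace(5),
                       kon = 1e-4)$values
  expect_equal(a, b, tolerance = 1e-9)
  expect_equal(a, ci, tolerance = 1e-9)
  # inverse_mrt flags MRT = 0 bins with positive signal
  im <- ipls_from_data(dr, mrt, "inverse_mrt")
  expect_equal(attr(im, "flagged"), 1L)
  expect_equal(im$values[1], 0)
})
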