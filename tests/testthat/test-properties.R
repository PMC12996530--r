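test_that("optical mass conversion is linear with an exact round trip", {
  cc <- conversion_constants()
  expect_equal(ioc_to_mw(2, 1890, cc), 2 * ioc_to_mw(1, 1890, cc))
  expect_equal(ioc_to_mw(1, 2 * 1890, cc), 2 * ioc_to_mw(1, 1890, cc))
  x <- c(0.01, 1, 7.3)
  expect_equal(mw_to_ioc(ioc_to_mw(x, 1890, cc), 1890, cc), x,
               tolerance = 1e-12)
})

test_that("the calibration slope is recoverable from simulated pairs", {
  # 20 (iOC, MW) pairs generated with a known kappa; least squares recovers
  # the generating slope to 1%
  cc_true <- conversion_constants(kappa = 0.007)
  set.seed(11)
  ioc <- runif(20, 0.1, 10)
  mw <- ioc_to_mw(ioc, 1890, cc_true) * (1 + rnorm(20, 0, 0.002))
  fit <- stats::lm(mw ~ 0 + ioc)
  slope_true <- cc_true$kappa * 1890 / cc_true$a
  expect_lt(abs(unname(coef(fit)[1]) - slope_true) / slope_true, 0.01)
})

test_that("Stokes-Einstein conversion matches the closed form", {
  cc <- conversion_constants(temperature_K = 298, viscosity_Pa_s = 8.9e-4)
  rs <- d_to_rs(160, cc)
  closed <- 1.380649e-23 * 298 / (6 * pi * 8.9e-4 * 160e-12) * 1e9
  expect_equal(rs, closed, tolerance = 1e-12)
  expect_equal(round(rs, 2), 1.53)

  d_grid <- c(1, 10, 160, 1000)
  expect_equal(rs_to_d(d_to_rs(d_grid, cc), cc), d_grid, tolerance = 1e-9)
})

test_that("hindered diffusion halves D at H = 0.5 and round-trips", {
  cc <- conversion_constants()
  lk <- hindrance_model("lookup",
                        lookup = data.frame(rs_nm = c(0.1, 100), H = c(0.5, 0.5)))
  rs <- 2
  expect_equal(rs_to_d(rs, cc, lk), 0.5 * rs_to_d(rs, cc))

  ren <- hindrance_model("parametric", r_pore_nm = 15)
  for (rs in c(0.5, 1.5, 3)) {
    d <- rs_to_d(rs, cc, ren)
    expect_equal(d_to_rs(d, cc, ren), rs, tolerance = 1e-6)
  }
  h <- hindrance_factor(ren, c(0.5, 1.5, 3, 6))
  expect_true(all(diff(h) < 0))
  expect_true(all(h > 0 & h <= 1))
})

test_that("dsDNA calculators reproduce the ladder arithmetic", {
  expect_equal(dsdna_length(c(50, 100, 200)), c(17, 34, 68))
  expect_equal(dsdna_length(0), 0)
  expect_equal(dsdna_mw(200), 132)
  expect_equal(dsdna_mw(c(50, 100)), c(33, 66))
  expect_equal(dsdna_mw(1), 0.66)
  expect_error(dsdna_mw(-1), class = "nanokymo_invalid_argument")
})

test_that("the diffusivity bound is sqrt(2/n) and the ML estimator attains it", {
  expect_equal(crlb_diffusivity(200), 0.1)
  expect_equal(crlb_diffusivity(2), 1)
  expect_error(crlb_diffusivity(1), class = "nanokymo_invalid_argument")

  # Monte Carlo: variance of D_hat over 1e4 replicates matches 2 D^2 / n
  D <- 20; dt <- 0.005; n <- 100
  g <- tiny_geometry(128L)
  est <- withr::with_seed(13, {
    vapply(seq_len(1e4), function(i) {
      tr <- sample_trajectory(
        trajectory_params(D = D, v = 0, dt = dt, x0 = 0, k = n + 1L), g)
      estimate_diffusivity(tr$positions, dt, v_um_s = 0)
    }, numeric(1))
  })
  expect_lt(abs(var(est) - 2 * D^2 / n) / (2 * D^2 / n), 0.05)
  expect_lt(abs(mean(est) - D) / D, 0.01)
})

test_that("the amplitude bound scales as 1/(snr sqrt(n))", {
  expect_equal(crlb_amplitude(1e4, 1), 0.01)
  expect_equal(crlb_amplitude(400, 0.5), 2 * crlb_amplitude(1600, 0.5))
  expect_error(crlb_amplitude(100, 0), class = "nanokymo_invalid_argument")
})

test_that("the matched filter attains the amplitude bound", {
  # template of known shape; per-frame snr_eff = a * sqrt(sum g^2) / sigma
  px <- 32L
  template <- dnorm(seq_len(px), px / 2, 4)
  a_true <- 1
  snr_eff <- 0.5
  sigma <- a_true * sqrt(sum(template^2)) / snr_eff
  n <- 400L
  est <- withr::with_seed(17, {
    vapply(seq_len(300), function(i) {
      y <- matrix(a_true * template, n, px, byrow = TRUE) +
        matrix(rnorm(n * px, 0, sigma), n, px)
      matched_filter_amplitude(y, template)
    }, numeric(1))
  })
  bound <- crlb_amplitude(n, snr_eff)
  emp <- sd(est) / mean(est)
  expect_lt(abs(emp - bound) / bound, 0.10)
})

test_that("precision curves pair empirical sigma with the bound", {
  g <- tiny_geometry(128L)
  dt <- 0.005
  sim <- function(n) sample_trajectory(
    trajectory_params(D = 15, v = 0, dt = dt, x0 = 0, k = n + 1L), g)
  est <- function(tr) estimate_diffusivity(tr$positions, dt, v_um_s = 0)
  curve <- precision_vs_n(sim, est, n_grid = c(100L, 400L),
                          n_replicates = 300L, seed = 23)
  expect_s3_class(curve, "nsm_precision_curve")
  expect_equal(curve$sigma_rel_bound, sqrt(2 / c(100, 400)))
  expect_true(all(abs(curve$sigma_rel - curve$sigma_rel_bound) /
                    curve$sigma_rel_bound < 0.10))
  expect_true(all(diff(curve$sigma_rel) < 0))

  flat <- precision_vs_n(function(n) n, function(x) 42,
                         n_grid = c(10L, 20L), n_replicates = 10L,
                         bound_fn = crlb_diffusivity, seed = 1)
  expect_equal(flat$sigma_rel, c(0, 0))
  expect_true(all(flat$degenerate))
})

test_that("theoretical bound curves decrease as 1/sqrt(N)", {
  cc <- crlb_curve(c(100, 400, 1600, 6400), per_frame_snr = 0.1)
  expect_true(all(diff(cc$sigma_rel_mw) < 0))
  expect_true(all(diff(cc$sigma_rel_rs) < 0))
  expect_equal(cc$sigma_rel_mw[1] / cc$sigma_rel_mw[2], 2, tolerance = 1e-12)
  expect_equal(cc$sigma_rel_rs[1] / cc$sigma_rel_rs[3], 4, tolerance = 1e-12)
})
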