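test_that("transverse collapse averages the third axis", {
  const <- array(3.2, c(5, 8, 4))
  expect_equal(collapse_transverse(const), matrix(3.2, 5, 8))

  m <- matrix(rnorm(40), 5, 8)
  expect_identical(collapse_transverse(m), m)

  set.seed(1)
  a <- array(rnorm(5 * 8 * 3), c(5, 8, 3))
  brute <- matrix(0, 5, 8)
  for (i in 1:5) for (j in 1:8) brute[i, j] <- mean(a[i, j, ])
  expect_equal(collapse_transverse(a), brute)
})

test_that("normalization gives zero-time-mean relative contrast", {
  expect_equal(normalize_stack(matrix(7, 10, 4)), matrix(0, 10, 4))

  # I(x,t) = c (1 + delta(t)) with zero-mean delta -> Ibar = delta per pixel
  delta <- c(0.1, -0.1, 0.05, -0.05)
  m <- outer(1 + delta, rep(2.5, 6))
  expect_equal(normalize_stack(m), outer(delta, rep(1, 6)) * 1,
               tolerance = 1e-12)

  set.seed(2)
  r <- matrix(runif(200, 0.5, 2), 20, 10)
  expect_equal(normalize_stack(3 * r), normalize_stack(r), tolerance = 1e-12)
  expect_true(all(abs(colMeans(normalize_stack(r))) < 1e-10))

  bad <- matrix(c(1, -3, 1, 1), 2, 2)
  expect_error(normalize_stack(bad), class = "nanokymo_invalid_argument")
})

test_that("low-pass subtraction matches a brute-force truncated-window filter", {
  expect_equal(lowpass_subtract(matrix(5, 300, 40), 200, 200),
               matrix(0, 300, 40))

  set.seed(3)
  m <- matrix(rnorm(300 * 300), 300, 300)
  out <- lowpass_subtract(m, 200L, 200L)
  smooth_t <- apply(m, 2, brute_running_mean, w = 200)
  low <- t(apply(smooth_t, 1, brute_running_mean, w = 200))
  expect_equal(out, m - low, tolerance = 1e-12)

  expect_error(lowpass_subtract(matrix(1, 1, 5)), class = "nanokymo_invalid_argument")
})

test_that("slow temporal oscillations are strongly attenuated", {
  # period 2000 frames >> 200-frame window; the moving-average response
  # leaves < 2% in the interior and < 5% in RMS including window edges
  tgrid <- seq_len(2000)
  slow <- outer(sin(2 * pi * tgrid / 2000), rep(1, 16))
  out <- lowpass_subtract(slow, 200L, 200L)
  expect_lt(sqrt(mean(out^2)), 0.05 * sqrt(mean(slow^2)))
  expect_lt(max(abs(out[150:1850, ])), 0.02 * max(abs(slow)))
})

test_that("the full preprocessing pipeline is scale invariant", {
  g <- tiny_geometry(32L)
  kym <- simulate_kymograph(mw_kDa = 30, rs_nm = 2, n_frames = 24L,
                            geometry = g, seed = 12)
  p1 <- preprocess_kymograph(kym)
  kym2 <- kym; kym2$values <- 7.3 * kym$values
  p2 <- preprocess_kymograph(kym2)
  expect_equal(p1$values, p2$values, tolerance = 1e-10)
  expect_equal(p1$preprocessing$window_time, 200L)
})

test_that("a molecule's contrast dip survives preprocessing", {
  # high-SNR fixture: correlation with the noise-free response must be
  # significant against a frame-shuffling null
  g <- channel_geometry(63, 30, n_pixels = 64L)
  set.seed(31)
  kym <- simulate_kymograph(mw_kDa = 300, rs_nm = 2, d_um2_s = 0.5,
                            n_frames = 64L, s_nm = 100, geometry = g,
                            noise = quiet_noise())
  pre <- preprocess_kymograph(kym)
  gt <- kym$ground_truth[[1]]
  clean <- 1 - render_molecule_response(gt$trajectory, gt$optics, g)
  obs <- -pre$values   # dip is negative contrast
  r_obs <- cor(as.vector(obs), as.vector(clean))
  expect_gt(r_obs, 0)
  null <- replicate(200, {
    cor(as.vector(obs[sample(nrow(obs)), ]), as.vector(clean))
  })
  p_val <- (1 + sum(null >= r_obs)) / 201
  expect_lt(p_val, 0.01)
})
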