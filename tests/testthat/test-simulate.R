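test_that("differential contrast follows the interference algebra", {
  expect_equal(differential_contrast(1, 0), 0)
  expect_equal(differential_contrast(1, 0.5), -0.5)
  # the interference term dwarfs the direct molecule term for weak scatterers
  i_m <- 10^seq(-8, -2, length.out = 30)
  ratio <- sqrt(2 * 1 * i_m) / i_m
  expect_true(all(ratio > 10))
  expect_equal(differential_contrast(1, i_m), i_m - sqrt(2 * i_m))
  expect_true(all(differential_contrast(1, i_m[i_m < 2]) < 0))
  expect_error(differential_contrast(-1, 0.1), class = "nanokymo_invalid_argument")
  expect_error(differential_contrast(1, -0.1), class = "nanokymo_invalid_argument")
})

test_that("trajectories follow the Brownian recursion with drift", {
  g <- tiny_geometry(128L)
  still <- sample_trajectory(trajectory_params(D = 0, v = 0, x0 = 100, k = 10), g)
  expect_equal(still$positions, rep(100, 10))
  expect_equal(still$n_in_view, 10L)

  drift <- sample_trajectory(
    trajectory_params(D = 0, v = 1, dt = 0.005, x0 = 0, k = 3), g)
  expect_equal(drift$positions, c(0, 5, 10))

  expect_error(trajectory_params(D = 1, k = 0), class = "nanokymo_invalid_argument")
})

test_that("increment statistics match v*dt and 2*D*dt at k = 1e5", {
  g <- tiny_geometry(128L)
  D <- 40; v <- 0.3; dt <- 0.005; k <- 1e5
  tr <- sample_trajectory(
    trajectory_params(D = D, v = v, dt = dt, x0 = 0, k = k, seed = 404), g)
  inc <- diff(tr$positions)
  n <- length(inc)
  true_var <- 2 * D * 1e6 * dt      # nm^2
  true_mean <- v * 1e3 * dt         # nm
  se_mean <- sqrt(true_var / n)
  se_var <- true_var * sqrt(2 / (n - 1))
  expect_lt(abs(mean(inc) - true_mean), 5 * se_mean)
  expect_lt(abs(var(inc) - true_var), 5 * se_var)
})

test_that("mean-squared displacement is linear in lag with slope 2D", {
  # 100 replicates of a pure-diffusion trajectory; MSD regressed on lag
  D <- 10; dt <- 0.005; k <- 1e4
  g <- tiny_geometry(128L)
  lags <- 1:5
  msd <- matrix(0, 100, length(lags))
  withr::with_seed(71, {
    for (r in 1:100) {
      tr <- sample_trajectory(trajectory_params(D = D, v = 0, dt = dt,
                                                x0 = 0, k = k), g)
      x <- tr$positions
      msd[r, ] <- vapply(lags, function(l) mean((x[-(1:l)] - x[1:(k - l)])^2),
                         numeric(1))
    }
  })
  fit <- stats::lm(colMeans(msd) ~ 0 + I(lags * dt))
  slope <- unname(stats::coef(fit)[1]) / 1e6     # nm^2/s -> um^2/s
  expect_lt(abs(slope - 2 * D) / (2 * D), 0.05)
})

test_that("molecule response conserves the integrated optical contrast", {
  g <- channel_geometry(63, 30, n_pixels = 128L)
  L <- view_length_nm(g)
  tr <- sample_trajectory(trajectory_params(D = 0, v = 0, x0 = L / 2, k = 1), g)

  expect_equal(render_molecule_response(tr, optical_params(0, 300), g),
               matrix(1, 1, 128))

  resp <- render_molecule_response(tr, optical_params(10, 300), g)
  deficit <- g$pixel_size_nm * sum(1 - resp)
  expect_lt(abs(deficit - 10), 0.01)

  far <- sample_trajectory(trajectory_params(D = 0, v = 0, x0 = -3000, k = 1), g)
  resp_far <- render_molecule_response(far, optical_params(10, 300), g)
  expect_lt(max(abs(1 - resp_far)), 1e-6)
})

test_that("per-frame contrast deficit equals iOC along a moving in-view path", {
  g <- channel_geometry(63, 30, n_pixels = 256L)
  L <- view_length_nm(g)
  tr <- sample_trajectory(
    trajectory_params(D = 0.5, v = 0, dt = 0.005, x0 = L / 2, k = 50,
                      seed = 9), g)
  resp <- render_molecule_response(tr, optical_params(4, 150), g)
  deficits <- g$pixel_size_nm * rowSums(1 - resp)
  inview <- tr$positions > 1000 & tr$positions < L - 1000
  expect_true(all(abs(deficits[inview] - 4) / 4 < 1e-3))
})

test_that("background reduces to the deterministic envelope when frozen", {
  px <- 64L; ps <- 27.4
  L <- px * ps
  np <- frozen_noise(x0_bg = L / 2, lambda_bg = L / 3)
  bg <- sample_background(np, c(5, px), pixel_size_nm = ps, seed = 1)
  x <- (seq_len(px) - 0.5) * ps
  env <- exp(-(x - L / 2)^2 / (L / 3)^2)
  for (t in 1:5) expect_equal(unname(bg[t, ]), env, tolerance = 1e-12)
})

test_that("the additive shot-noise term has variance (0.4 n_theta)^2", {
  # freeze the envelope at ~0 by looking far into its tail
  px <- 8L; ps <- 27.4; frames <- 1e5
  n_theta <- 0.02
  np <- noise_params(x0_bg = -1e6, lambda_bg = 50, amp_A = 0, d_x = 0,
                     n_theta = n_theta, dirt_amp = 0)
  bg <- sample_background(np, c(frames, px), pixel_size_nm = ps, seed = 2)
  v <- stats::var(as.vector(bg[, 1]))
  true_v <- (0.4 * n_theta)^2
  se <- true_v * sqrt(2 / (frames - 1))
  expect_lt(abs(v - true_v), 5 * se)
})

test_that("kymograph synthesis is the elementwise product of its factors", {
  g <- tiny_geometry(16L)
  set.seed(5)
  bg <- matrix(runif(8 * 16, 0.5, 1.5), 8, 16)
  r1 <- matrix(runif(8 * 16, 0.9, 1), 8, 16)
  r2 <- matrix(runif(8 * 16, 0.9, 1), 8, 16)

  expect_equal(synthesize_kymograph(list(), bg, g)$values, bg)
  expect_equal(synthesize_kymograph(list(r1), matrix(1, 8, 16), g)$values, r1)

  out <- synthesize_kymograph(list(r1, r2), bg, g)$values
  brute <- matrix(0, 8, 16)
  for (i in 1:8) for (j in 1:16) brute[i, j] <- bg[i, j] * r1[i, j] * r2[i, j]
  expect_equal(out, brute)

  # multiplicativity in the background scale
  expect_equal(synthesize_kymograph(list(r1), 3 * bg, g)$values,
               3 * synthesize_kymograph(list(r1), bg, g)$values)

  expect_error(synthesize_kymograph(list(r1[1:4, ]), bg, g),
               class = "nanokymo_shape_error")
})

test_that("embedding in a measured background crops and multiplies", {
  g <- tiny_geometry(32L)
  set.seed(8)
  rec <- kymograph(matrix(runif(40 * 32, 0.5, 1), 40, 32), g,
                   provenance = "measured")
  # no responses: a crop of the recording comes back unchanged
  out0 <- embed_in_measured_background(list(), rec, shape = c(10, 16), seed = 3)
  expect_equal(dim(out0$values), c(10L, 16L))
  out0b <- embed_in_measured_background(list(), rec, shape = c(10, 16), seed = 3)
  expect_identical(out0$values, out0b$values)

  r1 <- matrix(runif(10 * 16, 0.9, 1), 10, 16)
  out <- embed_in_measured_background(list(r1), rec, seed = 3)
  expect_equal(out$values, out0$values * r1)

  expect_error(embed_in_measured_background(list(), rec, shape = c(100, 16)),
               class = "nanokymo_shape_error")
})

test_that("identical seeds give bit-identical simulations", {
  g <- tiny_geometry(32L)
  a <- simulate_kymograph(mw_kDa = 20, rs_nm = 2, n_molecules = 1,
                          n_frames = 16L, geometry = g, seed = 42)
  b <- simulate_kymograph(mw_kDa = 20, rs_nm = 2, n_molecules = 1,
                          n_frames = 16L, geometry = g, seed = 42)
  expect_identical(a$values, b$values)
  expect_identical(a$ground_truth[[1]]$trajectory$positions,
                   b$ground_truth[[1]]$trajectory$positions)

  n1 <- sample_background(noise_params(), c(6, 32), seed = 7)
  n2 <- sample_background(noise_params(), c(6, 32), seed = 7)
  expect_identical(n1, n2)
})

test_that("simulated kymographs carry coherent ground truth", {
  g <- tiny_geometry(32L)
  kym <- simulate_kymograph(mw_kDa = 50, rs_nm = 2, n_molecules = 2L,
                            n_frames = 12L, geometry = g, seed = 10)
  expect_s3_class(kym, "nsm_kymograph")
  expect_length(kym$ground_truth, 2L)
  gt <- kym$ground_truth[[1]]
  expect_equal(gt$mw_kDa, 50)
  expect_equal(gt$ioc, mw_to_ioc(50, g$area_nm2))
  expect_equal(gt$d_um2_s, rs_to_d(2))
  expect_equal(length(gt$trajectory$positions), 12L)
})
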