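test_that("configuration contracts are enforced", {
  expect_error(hvit_config(input_shape = c(100L, 128L), n_scales = 3L),
               class = "nanokymo_shape_error")
  expect_error(hvit_config(filters = c(8L, 16L), n_scales = 3L),
               class = "nanokymo_invalid_argument")
  expect_error(hvit_config(embed_dim = 10L, n_heads = 4L),
               class = "nanokymo_invalid_argument")
  cfg <- hvit_config(input_shape = c(512L, 512L), n_scales = 7L,
                     filters = pmin(8L * 2L^(0:6), 64L))
  expect_equal(cfg$map_shape, c(4L, 4L))   # 512 / 2^7
})

test_that("an untrained model obeys the output shape contract", {
  cfg <- micro_config()
  m <- build_hvit(cfg, seed = 3)
  set.seed(4)
  fw <- nanokymo:::forward_hvit(m, matrix(rnorm(8 * 16), 8, 16), 1890)
  expect_equal(dim(fw$prob_map), c(4L, 8L))          # input / 2^1
  expect_true(all(fw$prob >= 0 & fw$prob <= 1))
  expect_true(all(is.finite(fw$prop)))
  expect_true(all(fw$prop >= 0))
  expect_true(all(is.finite(fw$scale_preds)))
  expect_true(all(is.finite(fw$est_norm)))

  # all-zero input stays finite
  fz <- nanokymo:::forward_hvit(m, matrix(0, 8, 16), 1890)
  expect_true(all(is.finite(fz$prob)) && all(is.finite(fz$prop)))

  # per-item outputs do not depend on what else is processed
  fw2 <- nanokymo:::forward_hvit(m, matrix(rnorm(8 * 16), 8, 16), 1890)
  fw_again <- nanokymo:::forward_hvit(m, matrix(0, 8, 16), 1890)
  expect_identical(fz$prob, fw_again$prob)
})

test_that("standardization is scale invariant and zero-safe", {
  set.seed(5)
  v <- matrix(rnorm(64, 10, 0.1), 8, 8)
  expect_equal(standardize_kymograph(5 * v), standardize_kymograph(v) * 1,
               tolerance = 1e-12)
  expect_equal(standardize_kymograph(matrix(3, 4, 4)), matrix(0, 4, 4))
})

test_that("ground-truth rasterization matches a brute-force membership test", {
  g <- tiny_geometry(32L)
  L <- view_length_nm(g)
  map_shape <- c(4L, 8L)

  expect_equal(rasterize_ground_truth(NULL, map_shape, g, 16L),
               matrix(0, 4, 8))

  # a stationary in-view molecule occupies one space-bin column
  tr <- sample_trajectory(trajectory_params(D = 0, v = 0, x0 = L / 2, k = 16L), g)
  occ <- rasterize_ground_truth(list(list(trajectory = tr)), map_shape, g, 16L)
  expect_equal(colSums(occ > 0), c(0, 0, 0, 0, 4, 0, 0, 0))

  # random trajectories against an independent per-cell membership check
  set.seed(6)
  gt <- lapply(1:3, function(i) {
    list(trajectory = sample_trajectory(
      trajectory_params(D = 5, v = 0, x0 = "uniform", k = 16L), g))
  })
  occ <- rasterize_ground_truth(gt, map_shape, g, 16L)
  brute <- matrix(0, 4, 8)
  for (tb in 1:4) for (pb in 1:8) {
    frames <- ((tb - 1) * 4 + 1):(tb * 4)
    lo <- (pb - 1) * L / 8; hi <- pb * L / 8
    hit <- any(vapply(gt, function(r) {
      x <- r$trajectory$positions[frames]
      any(x >= lo & x < hi) || (pb == 8 && any(x == L))
    }, logical(1)))
    brute[tb, pb] <- as.numeric(hit)
  }
  expect_equal(occ, brute)
})

test_that("probability-weighted readout interpolates the property map", {
  set.seed(7)
  prop <- matrix(runif(32, 1, 9), 4, 8)

  unif <- weighted_estimate(matrix(0.3, 4, 8), prop)
  expect_equal(unif$estimates, mean(prop))

  conc <- matrix(0, 4, 8); conc[2, 5] <- 1
  expect_equal(weighted_estimate(conc, prop)$estimates, prop[2, 5])

  for (r in 1:10) {
    P <- matrix(runif(32), 4, 8)
    est <- weighted_estimate(P, prop)$estimates
    expect_gte(est, min(prop)); expect_lte(est, max(prop))
  }

  z <- weighted_estimate(matrix(0, 4, 8), prop)
  expect_true(z$undefined)
  expect_true(is.na(z$estimates))
  expect_error(weighted_estimate(matrix(1, 2, 2), prop),
               class = "nanokymo_shape_error")
})

test_that("the loss contract holds at its extremes and is linear in L1 error", {
  occ <- matrix(rbinom(32, 1, 0.3), 4, 8)
  tg <- list(mw = 0.4, rs = 0.7, n = 0.2)

  # perfect probability map and exact properties: both terms at the minimum
  perfect <- hvit_loss(occ, occ, scale_preds = matrix(c(0.4, 0.7), 3, 2,
                                                      byrow = TRUE),
                       est = c(0.4, 0.7, 0.2), targets = tg)
  expect_lt(perfect, 1e-10)

  # +1 error on every scale with S scales contributes exactly S
  for (S in c(2, 5)) {
    sp <- matrix(c(0.4 + 1, 0.7), S, 2, byrow = TRUE)
    l <- hvit_loss(occ, occ, scale_preds = sp, est = NULL, targets = tg)
    expect_equal(l, S)
  }

  expect_error(hvit_loss(matrix(0.5, 2, 2), occ, targets = tg),
               class = "nanokymo_shape_error")
})

test_that("the training-path loss equals the stated loss contract", {
  cfg <- micro_config()
  m <- build_hvit(cfg, seed = 8)
  set.seed(9)
  v <- matrix(rnorm(8 * 16), 8, 16)
  occ <- matrix(rbinom(32, 1, 0.3), 4, 8)
  tg <- list(mw = 0.4, rs = 0.7, n = 0.2)
  lg <- nanokymo:::hvit_loss_grads(m, v, 1890, occ, tg, pos_weight = 3)
  fw <- nanokymo:::forward_hvit(m, v, 1890)
  ref <- hvit_loss(fw$prob_map, occ, fw$scale_preds, fw$est_norm, tg,
                   lambda = 1, pos_weight = 3)
  expect_equal(lg$loss, ref, tolerance = 1e-10)
})

test_that("analytic gradients match central finite differences", {
  cfg <- micro_config()
  m <- build_hvit(cfg, seed = 7)
  set.seed(42)
  v <- matrix(rnorm(8 * 16), 8, 16)
  occ <- matrix(rbinom(32, 1, 0.3), 4, 8)
  tg <- list(mw = 0.4, rs = 0.7, n = 0.2)
  lg <- nanokymo:::hvit_loss_grads(m, v, 2000, occ, tg,
                                   detach_prob = FALSE, pos_weight = 2)
  h <- 1e-5
  worst <- 0
  for (nm in names(m$params)) {
    p0 <- m$params[[nm]]
    for (j in sample(length(p0), min(3, length(p0)))) {
      mp <- m; mp$params[[nm]][j] <- p0[j] + h
      mm <- m; mm$params[[nm]][j] <- p0[j] - h
      num <- (nanokymo:::hvit_loss_grads(mp, v, 2000, occ, tg,
                                         detach_prob = FALSE,
                                         pos_weight = 2)$loss -
              nanokymo:::hvit_loss_grads(mm, v, 2000, occ, tg,
                                         detach_prob = FALSE,
                                         pos_weight = 2)$loss) / (2 * h)
      ana <- lg$grads[[nm]][j]
      if (abs(num) > 1e-7 || abs(ana) > 1e-7) {
        worst <- max(worst, abs(num - ana) / max(abs(num), abs(ana)))
      }
    }
  }
  expect_lt(worst, 1e-3)
})

test_that("the curriculum plateau rule fires exactly as stated", {
  expect_false(plateau_reached(rep(1, 19), patience = 10, tol = 0.01))
  expect_true(plateau_reached(rep(1, 20), patience = 10, tol = 0.01))
  steep <- seq(10, 1, length.out = 40)
  expect_false(plateau_reached(steep, patience = 10, tol = 0.01))
  # 1% relative improvement is the boundary: slightly less improvement fires
  flatish <- c(rep(1, 10), rep(1 - 0.005, 10))
  expect_true(plateau_reached(flatish, patience = 10, tol = 0.01))
  better <- c(rep(1, 10), rep(1 - 0.02, 10))
  expect_false(plateau_reached(better, patience = 10, tol = 0.01))
})

test_that("training is deterministic and aborts on divergence", {
  cfg <- hvit_config(input_shape = c(16L, 16L), n_scales = 1L,
                     initial_kernel = 3L, filters = 4L, embed_dim = 8L,
                     n_heads = 2L, mlp_dim = 12L, n_transformer_blocks = 1L)
  m <- build_hvit(cfg, seed = 2)
  g <- channel_geometry(63, 30, n_pixels = 16L)
  gen <- hvit_training_generator(cfg, g, noise = quiet_noise(), s_nm = 100,
                                 d_um2_s = 0.5, mw_values = c(50, 200))
  tc <- hvit_train_config(learning_rate = 1e-3, batch_size = 2L, n_steps = 4L,
                          mw_range = c(50, 200), rs_range = c(2, 2),
                          validation_every = 2L, n_validation = 2L, seed = 99)
  f1 <- train_hvit(m, gen, tc)
  f2 <- train_hvit(m, gen, tc)
  expect_identical(f1$history$loss, f2$history$loss)
  expect_identical(f1$model$params, f2$model$params)
  expect_equal(nrow(f1$history), 4L)
  expect_true(any(!is.na(f1$history$val_loss)))

  # a poisoned generator drives the loss non-finite and must abort loudly
  bad_gen <- function(n, mw_range, rs_range) {
    lapply(seq_len(n), function(i) {
      list(values = matrix(rnorm(256), 16, 16), area = 1890,
           occupancy = matrix(0, 8, 8),
           targets = list(mw = NaN, rs = 0, n = 0))
    })
  }
  expect_error(train_hvit(m, bad_gen, tc), class = "nanokymo_divergence")
})

test_that("predictions expose maps, estimates and broom accessors", {
  cfg <- micro_config(mw_scale = 30, rs_scale = 3, n_scale = 8)
  m <- build_hvit(cfg, seed = 5)
  g <- channel_geometry(63, 30, n_pixels = 16L)
  kym <- simulate_kymograph(mw_kDa = 100, rs_nm = 2, n_frames = 8L,
                            geometry = g, seed = 31)
  pr <- predict_hvit(m, kym)
  expect_s3_class(pr, "nsm_prediction")
  expect_equal(dim(pr$probability_map), c(4L, 8L))
  expect_equal(pr$estimate$p_total, sum(pr$probability_map))
  expect_gte(pr$estimate$mw_kDa, min(pr$property_map[, , 1]))
  expect_lte(pr$estimate$mw_kDa, max(pr$property_map[, , 1]))
  expect_identical(tidy(pr), pr$estimate)

  tbl <- predict_population(m, list(a = kym, b = kym))
  expect_equal(nrow(tbl), 2L)
  expect_equal(tbl$mw_kDa[1], tbl$mw_kDa[2])
})
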