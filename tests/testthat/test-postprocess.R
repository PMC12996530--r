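test_that("probability totals are exact bin sums", {
  expect_equal(probability_total(matrix(0, 4, 7)), 0)
  expect_equal(probability_total(matrix(1, 4, 89)), 356)
  set.seed(4)
  m <- matrix(runif(4 * 89), 4, 89)
  brute <- 0
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) brute <- brute + m[i, j]
  expect_equal(probability_total(m), brute)
})

test_that("the detection threshold is half the control average", {
  expect_equal(compute_threshold(c(10, 20, 30)), 10)
  expect_equal(compute_threshold(c(0, 0)), 0)
  set.seed(5)
  ctl <- runif(1000, 0, 50)
  expect_equal(compute_threshold(ctl), sum(ctl) / length(ctl) / 2)
  expect_error(compute_threshold(numeric(0)), class = "nanokymo_invalid_argument")
})

test_that("thresholding keeps exactly the high-confidence kymographs", {
  est <- tibble::tibble(mw_kDa = c(1, 2), rs_nm = c(1, 2), p_total = c(5, 15))
  out <- apply_threshold(est, 10)
  expect_equal(out$accepted, c(FALSE, TRUE))
  expect_true(all(apply_threshold(est, 0)$accepted))

  set.seed(6)
  est <- tibble::tibble(mw_kDa = runif(50), rs_nm = runif(50),
                        p_total = runif(50, 0, 100))
  th <- 40
  out <- apply_threshold(est, th)
  expect_equal(out$accepted, est$p_total >= th)
  # monotone: raising the threshold never increases the accepted count
  counts <- vapply(seq(0, 100, by = 5),
                   function(t) sum(apply_threshold(est, t)$accepted),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("3-sigma pruning uses a single moment-matched Gaussian fit", {
  same <- prune_outliers(rep(5, 8))
  expect_equal(same$sigma, 0)
  expect_length(same$removed, 0)

  v <- c(rep(5, 10), 100)
  mu <- mean(v); sig <- sd(v)
  expect_true(abs(100 - mu) > 3 * sig)      # the stated estimator flags it
  pruned <- prune_outliers(v)
  expect_equal(pruned$removed, 11L)
  expect_equal(pruned$values, rep(5, 10))
  expect_equal(pruned$mu, mu)
  expect_equal(pruned$sigma, sig)

  expect_error(prune_outliers(5), class = "nanokymo_invalid_argument")
})

test_that("pruning removes about 0.27% of standard-normal draws", {
  set.seed(7)
  x <- rnorm(1e5)
  frac <- length(prune_outliers(x)$removed) / 1e5
  p <- 2 * pnorm(-3)
  se <- sqrt(p * (1 - p) / 1e5)
  expect_lt(abs(frac - p), 3 * se)
})

test_that("threshold and pruning never increase dispersion", {
  set.seed(8)
  for (r in 1:20) {
    v <- rnorm(50, sd = runif(1, 0.5, 3)) + sample(c(0, 20), 50, TRUE, c(0.9, 0.1))
    out <- prune_outliers(v)
    expect_lte(sd(out$values), sd(v) + 1e-12)
  }
})

test_that("population summaries reflect the surviving estimates", {
  one <- tibble::tibble(mw_kDa = 5.9, rs_nm = 1.5, p_total = 10)
  s1 <- summarize_population(one, thresh = 0)
  expect_equal(s1$mw_mean, 5.9)
  expect_equal(s1$mw_median, 5.9)
  expect_equal(s1$mw_sd, 0)

  pair <- tibble::tibble(mw_kDa = c(4, 6), rs_nm = c(1, 3), p_total = c(5, 5))
  s2 <- summarize_population(pair, thresh = 0)
  expect_equal(s2$mw_mean, 5)
  expect_equal(s2$mw_median, 5)
  expect_equal(s2$rs_mean, 2)

  set.seed(9)
  est <- tibble::tibble(mw_kDa = rnorm(40, 10), rs_nm = rnorm(40, 2, 0.2),
                        p_total = runif(40, 5, 10))
  s3 <- summarize_population(est, thresh = 0, prune = FALSE)
  expect_equal(s3$mw_mean, mean(est$mw_kDa))
  expect_equal(s3$mw_sd, sd(est$mw_kDa))
  expect_equal(s3$rs_median, median(est$rs_nm))

  expect_error(summarize_population(est, thresh = 1e9),
               class = "nanokymo_empty_population")
})

test_that("summaries tidy into long statistic tables", {
  est <- tibble::tibble(mw_kDa = c(4, 6), rs_nm = c(1, 3), p_total = c(5, 5))
  td <- tidy(summarize_population(est, thresh = 0))
  expect_setequal(unique(td$property), c("mw", "rs"))
  expect_equal(td$value[td$property == "mw" & td$statistic == "mean"], 5)
})
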