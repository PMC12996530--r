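#' Architecture configuration of the hierarchical vision transformer
#'
#' The model ingests a preprocessed kymograph (frames x pixels), standardized
#' by its temporal standard deviation, together with the channel
#' cross-section area as a conditioning scalar. An initial convolution
#' (kernel 7, leaky ReLU) is followed by `n_scales` convolutional blocks
#' with progressively more filters, each downsampling by 2x2 max pooling and
#' emitting per-scale scalar property predictions. At the final scale the
#' feature-map cells are encoded as patches (linear patch encoder with
#' learned positional embeddings, plus the area conditioning) and passed
#' through transformer blocks (multi-head attention + MLP). Two heads
#' produce a per-bin probability map (sigmoid) on the coarse
#' `(frames / 2^n_scales) x (pixels / 2^n_scales)` grid, and a per-bin
#' property map (MW, Rs, N; softplus, in units of the `*_scale` fields).
#' The final scalar estimate is the probability-weighted average of the
#' property map.
#'
#' @param input_shape `c(frames, pixels)`; both divisible by `2^n_scales`.
#' @param n_scales Number of downsampling scales.
#' @param initial_kernel Kernel size of the first convolution.
#' @param filters Integer vector of per-scale filter counts
#'   (length `n_scales`); defaults to `8 * 2^(0:(n_scales-1))` capped at 64.
#' @param embed_dim Token embedding dimension (divisible by `n_heads`).
#' @param n_heads Attention heads.
#' @param mlp_dim Hidden width of the transformer MLP (default
#'   `2 * embed_dim`).
#' @param n_transformer_blocks Number of transformer blocks.
#' @param leaky_slope Negative slope of the leaky-ReLU activation.
#' @param patch_size Cells per patch at the final scale (1 = one token per
#'   coarse bin).
#' @param mw_scale,rs_scale,n_scale Property normalization scales (kDa, nm,
#'   trajectory points); heads regress properties in these units so all loss
#'   terms are O(1). `n_scale` defaults to the frame count.
#' @param area_ref_nm2 Reference cross-section area for the conditioning
#'   scalar (the area enters as `area / area_ref - 1`).
#' @return An object of class `hvit_config`.
#' @export
hvit_config <- function(input_shape = c(512L, 512L), n_scales = 4L,
                        initial_kernel = 7L, filters = NULL,
                        embed_dim = 64L, n_heads = 4L, mlp_dim = NULL,
                        n_transformer_blocks = 2L, leaky_slope = 0.1,
                        patch_size = 1L, mw_scale = 30, rs_scale = 3,
                        n_scale = NULL, area_ref_nm2 = 1890) {
  n_scales <- assert_count(n_scales, "n_scales")
  if (any(input_shape %% 2L^n_scales != 0L)) {
    rlang::abort("`input_shape` must be divisible by 2^n_scales.",
                 class = "nanokymo_shape_error")
  }
  filters <- filters %||% pmin(8L * 2L^(seq_len(n_scales) - 1L), 64L)
  if (length(filters) != n_scales) {
    rlang::abort("`filters` must have one entry per scale.",
                 class = "nanokymo_invalid_argument")
  }
  mlp_dim <- mlp_dim %||% (2L * embed_dim)
  if (embed_dim %% n_heads != 0L) {
    rlang::abort("`embed_dim` must be divisible by `n_heads`.",
                 class = "nanokymo_invalid_argument")
  }
  structure(
    list(input_shape = as.integer(input_shape), n_scales = n_scales,
         initial_kernel = as.integer(initial_kernel),
         filters = as.integer(filters), embed_dim = as.integer(embed_dim),
         n_heads = as.integer(n_heads), mlp_dim = as.integer(mlp_dim),
         n_transformer_blocks = as.integer(n_transformer_blocks),
         leaky_slope = leaky_slope, patch_size = as.integer(patch_size),
         mw_scale = mw_scale, rs_scale = rs_scale,
         n_scale = n_scale %||% input_shape[1],
         area_ref_nm2 = area_ref_nm2,
         map_shape = as.integer(input_shape / 2L^n_scales)),
    class = "hvit_config"
  )
}

#' Build an (untrained) hierarchical vision transformer
#'
#' Initializes all parameters (He initialization for convolutions, Xavier
#' for dense layers) and precomputes the convolution index plans for the
#' configured input shape.
#'
#' @param config An [hvit_config()].
#' @param seed Optional seed for the parameter initialization.
#' @return An object of class `nsm_hvit` with elements `config`, `params`
#'   (flat named list of arrays) and `plans`.
#' @export
build_hvit <- function(config, seed = NULL) {
  stopifnot(inherits(config, "hvit_config"))
  with_seed(seed, {
    cfg <- config
    p <- list()
    he <- function(nr, nc, fan_in) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
    xav <- function(nr, nc) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / (nr + nc))), nr, nc)

    k0 <- cfg$initial_kernel
    p[["conv0.W"]] <- he(cfg$filters[1], k0 * k0, k0 * k0)
    p[["conv0.b"]] <- numeric(cfg$filters[1])
    plans <- list(conv0 = conv_plan(cfg$input_shape[1], cfg$input_shape[2], k0, k0))

    H <- cfg$input_shape[1]; W <- cfg$input_shape[2]
    cin <- cfg$filters[1]
    for (i in seq_len(cfg$n_scales)) {
      cout <- cfg$filters[i]
      p[[sprintf("scale%d.W", i)]] <- he(cout, 9L * cin, 9L * cin)
      p[[sprintf("scale%d.b", i)]] <- numeric(cout)
      plans[[sprintf("scale%d", i)]] <- conv_plan(H, W, 3L, 3L)
      H <- H %/% 2L; W <- W %/% 2L
      p[[sprintf("shead%d.W", i)]] <- xav(cout, 2L)
      p[[sprintf("shead%d.b", i)]] <- numeric(2L)
      cin <- cout
    }

    d <- cfg$embed_dim
    n_tok <- prod(cfg$map_shape)
    p[["enc.W"]] <- xav(cfg$filters[cfg$n_scales], d)
    p[["enc.b"]] <- numeric(d)
    p[["enc.pos"]] <- matrix(stats::rnorm(n_tok * d, 0, 0.02), n_tok, d)
    p[["enc.area"]] <- stats::rnorm(d, 0, 0.02)

    for (l in seq_len(cfg$n_transformer_blocks)) {
      pre <- sprintf("blk%d.", l)
      for (w in c("Wq", "Wk", "Wv", "Wo")) p[[paste0(pre, w)]] <- xav(d, d)
      for (b in c("bq", "bk", "bv", "bo")) p[[paste0(pre, b)]] <- numeric(d)
      p[[paste0(pre, "ln1.g")]] <- rep(1, d); p[[paste0(pre, "ln1.b")]] <- numeric(d)
      p[[paste0(pre, "ln2.g")]] <- rep(1, d); p[[paste0(pre, "ln2.b")]] <- numeric(d)
      p[[paste0(pre, "mlp.W1")]] <- xav(d, cfg$mlp_dim)
      p[[paste0(pre, "mlp.b1")]] <- numeric(cfg$mlp_dim)
      p[[paste0(pre, "mlp.W2")]] <- xav(cfg$mlp_dim, d)
      p[[paste0(pre, "mlp.b2")]] <- numeric(d)
    }
    # trajectories occupy a small fraction of the space-time bins, so the
    # probability head starts at a low-occupancy prior
    p[["headp.W"]] <- xav(d, 1L); p[["headp.b"]] <- -2
    p[["headp.b"]] <- as.numeric(p[["headp.b"]])
    p[["headprop.W"]] <- xav(d, 3L); p[["headprop.b"]] <- numeric(3L)
    # the property head also sees the concatenated per-scale GAP features
    # (the multi-scale outputs are folded into the final prediction stage)
    p[["headprop.G"]] <- xav(sum(cfg$filters), 3L)

    structure(list(config = cfg, params = p, plans = plans),
              class = "nsm_hvit")
  })
}

#' @export
print.nsm_hvit <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf(
    "<nsm_hvit> input %d x %d, %d scales, embed %d, %d transformer block(s), %d parameters\n",
    x$config$input_shape[1], x$config$input_shape[2], x$config$n_scales,
    x$config$embed_dim, x$config$n_transformer_blocks, np))
  invisible(x)
}

#' Standardize a kymograph for the model input
#'
#' Subtracts the per-pixel temporal mean and divides by one scalar per
#' kymograph: the lower quartile of the per-pixel temporal standard
#' deviations. The lower quartile is a robust estimate of the background
#' noise floor — a diffusing molecule and the tails of its Gaussian
#' response can touch well over half of the pixels, inflating the mean and
#' even the median per-pixel deviation, whereas the quietest quarter of
#' pixels is essentially always signal-free. Scaling by the noise floor
#' keeps the standardized amplitude of a contrast dip proportional to its
#' physical contrast instead of self-normalizing it away on bright
#' kymographs. An all-constant input maps to all zeros.
#'
#' @param values Kymograph matrix (frames x pixels).
#' @return Standardized matrix of the same shape.
#' @export
standardize_kymograph <- function(values) {
  z <- sweep(values, 2L, colMeans(values), "-")
  sbar <- stats::quantile(sqrt(colMeans(z^2)), 0.25, names = FALSE)
  if (!is.finite(sbar) || sbar <= 0) return(z * 0)
  z / sbar
}

# Full forward pass. Returns predictions and, optionally, every cache needed
# for the analytic backward pass.
forward_hvit <- function(model, values, area_nm2, want_cache = FALSE) {
  cfg <- model$config; p <- model$params
  if (!all(dim(values) == cfg$input_shape)) {
    rlang::abort(sprintf("Input is %d x %d but the model expects %d x %d.",
                         nrow(values), ncol(values),
                         cfg$input_shape[1], cfg$input_shape[2]),
                 class = "nanokymo_shape_error")
  }
  x_std <- standardize_kymograph(values)
  caches <- list()

  f0 <- conv2d_forward(array(x_std, c(dim(x_std), 1L)), p[["conv0.W"]],
                       p[["conv0.b"]], model$plans$conv0)
  a0 <- leaky_forward(f0$y, cfg$leaky_slope)
  caches$conv0 <- f0$cache; caches$act0 <- a0$cache
  h <- a0$y

  scale_raw <- matrix(0, cfg$n_scales, 2L)
  for (i in seq_len(cfg$n_scales)) {
    ci <- conv2d_forward(h, p[[sprintf("scale%d.W", i)]],
                         p[[sprintf("scale%d.b", i)]],
                         model$plans[[sprintf("scale%d", i)]])
    ai <- leaky_forward(ci$y, cfg$leaky_slope)
    pi_ <- maxpool2_forward(ai$y)
    h <- pi_$y
    gap <- apply(h, 3L, mean)
    raw <- drop(gap %*% p[[sprintf("shead%d.W", i)]]) + p[[sprintf("shead%d.b", i)]]
    scale_raw[i, ] <- raw
    caches[[sprintf("conv%d", i)]] <- ci$cache
    caches[[sprintf("act%d", i)]] <- ai$cache
    caches[[sprintf("pool%d", i)]] <- pi_$cache
    caches[[sprintf("gap%d", i)]] <- list(gap = gap, dims = dim(h))
  }
  scale_preds <- softplus_fwd(scale_raw)

  hs <- cfg$map_shape[1]; ws <- cfg$map_shape[2]
  n_tok <- hs * ws
  tokens <- matrix(h, n_tok, dim(h)[3])
  area_z <- area_nm2 / cfg$area_ref_nm2 - 1
  E <- sweep(tokens %*% p[["enc.W"]], 2L, p[["enc.b"]], "+") +
    p[["enc.pos"]] +
    area_z * matrix(p[["enc.area"]], n_tok, cfg$embed_dim, byrow = TRUE)
  caches$enc <- list(tokens = tokens, area_z = area_z, h_dims = dim(h))

  X <- E
  for (l in seq_len(cfg$n_transformer_blocks)) {
    pre <- sprintf("blk%d.", l)
    ln1 <- layernorm_forward(X, p[[paste0(pre, "ln1.g")]], p[[paste0(pre, "ln1.b")]])
    att <- mha_forward(ln1$y, list(Wq = p[[paste0(pre, "Wq")]], bq = p[[paste0(pre, "bq")]],
                                   Wk = p[[paste0(pre, "Wk")]], bk = p[[paste0(pre, "bk")]],
                                   Wv = p[[paste0(pre, "Wv")]], bv = p[[paste0(pre, "bv")]],
                                   Wo = p[[paste0(pre, "Wo")]], bo = p[[paste0(pre, "bo")]]),
                       cfg$n_heads)
    A <- X + att$y
    ln2 <- layernorm_forward(A, p[[paste0(pre, "ln2.g")]], p[[paste0(pre, "ln2.b")]])
    m1 <- linear_forward(ln2$y, p[[paste0(pre, "mlp.W1")]], p[[paste0(pre, "mlp.b1")]])
    ma <- leaky_forward(m1$y, cfg$leaky_slope)
    m2 <- linear_forward(ma$y, p[[paste0(pre, "mlp.W2")]], p[[paste0(pre, "mlp.b2")]])
    Y <- A + m2$y
    caches[[sprintf("blk%d", l)]] <- list(ln1 = ln1$cache, att = att$cache,
                                          ln2 = ln2$cache, m1 = m1$cache,
                                          ma = ma$cache, m2 = m2$cache)
    X <- Y
  }

  z_p <- drop(X %*% p[["headp.W"]]) + p[["headp.b"]]
  P <- sigmoid(z_p)
  gvec <- unlist(lapply(seq_len(cfg$n_scales),
                        function(i) caches[[sprintf("gap%d", i)]]$gap))
  U <- sweep(X %*% p[["headprop.W"]], 2L, p[["headprop.b"]], "+") +
    matrix(drop(gvec %*% p[["headprop.G"]]), n_tok, 3L, byrow = TRUE)
  caches$gvec <- gvec
  prop <- softplus_fwd(U)
  p_total <- sum(P)
  est_norm <- colSums(P * prop) / p_total

  out <- list(
    prob_logits = z_p, prob = P,
    prob_map = matrix(P, hs, ws),
    prop = prop, prop_raw = U,
    scale_preds = scale_preds, scale_raw = scale_raw,
    est_norm = est_norm, p_total = p_total,
    X = X
  )
  if (want_cache) out$caches <- caches
  out
}

# Loss and analytic gradients for a single training example.
# occupancy: binary matrix on the coarse map grid; targets: list with
# normalized mw, rs, n (same units as the heads). Returns list(loss, grads).
hvit_loss_grads <- function(model, values, area_nm2, occupancy, targets,
                            lambda = 1, detach_prob = TRUE, pos_weight = 1) {
  cfg <- model$config; p <- model$params
  fw <- forward_hvit(model, values, area_nm2, want_cache = TRUE)
  caches <- fw$caches
  y <- as.vector(occupancy)
  n_tok <- length(y)
  if (length(fw$prob) != n_tok) {
    rlang::abort("Occupancy shape does not match the probability map.",
                 class = "nanokymo_shape_error")
  }

  # --- loss ---------------------------------------------------------------
  # occupied bins are a small minority; pos_weight > 1 rebalances the
  # cross-entropy so the detection gradient is not drowned by background
  z <- fw$prob_logits
  l_bce <- mean(pos_weight * y * (softplus_fwd(z) - z) +
                  (1 - y) * softplus_fwd(z))
  tvec <- c(targets$mw, targets$rs)
  l_scale <- sum(abs(sweep(fw$scale_preds, 2L, tvec, "-")))
  tfin <- c(targets$mw, targets$rs, targets$n)
  l_final <- sum(abs(fw$est_norm - tfin))
  loss <- l_bce + lambda * (l_scale + l_final)

  g <- list()
  # --- heads ----------------------------------------------------------------
  # final weighted readout: est_j = sum(P * prop_j) / sum(P)
  # With detach_prob the probability map is treated as a constant weight in
  # the readout (stop-gradient): it is trained by the cross-entropy alone,
  # the property map by the L1 terms alone, which keeps the two objectives
  # from destabilizing each other. detach_prob = FALSE gives the exact
  # gradient of the full loss.
  gfin <- lambda * sign(fw$est_norm - tfin)               # dL/d est_j
  dprop <- (fw$prob %o% gfin) / fw$p_total                # [n_tok, 3]
  dz <- (pos_weight * y * (fw$prob - 1) + (1 - y) * fw$prob) / n_tok
  if (!detach_prob) {
    dP_read <- sweep(fw$prop, 2L, fw$est_norm, "-") %*% gfin / fw$p_total
    dz <- dz + as.vector(dP_read) * fw$prob * (1 - fw$prob)
  }
  dU <- dprop * sigmoid(fw$prop_raw)

  g[["headp.W"]] <- t(fw$X) %*% matrix(dz, ncol = 1L)
  g[["headp.b"]] <- sum(dz)
  g[["headprop.W"]] <- t(fw$X) %*% dU
  g[["headprop.b"]] <- colSums(dU)
  du_tot <- colSums(dU)
  g[["headprop.G"]] <- caches$gvec %o% du_tot
  dgvec <- drop(p[["headprop.G"]] %*% du_tot)
  dX <- matrix(dz, ncol = 1L) %*% t(p[["headp.W"]]) + dU %*% t(p[["headprop.W"]])

  # --- transformer blocks, reversed ----------------------------------------
  for (l in rev(seq_len(cfg$n_transformer_blocks))) {
    pre <- sprintf("blk%d.", l)
    cb <- caches[[sprintf("blk%d", l)]]
    # Y = A + m2(ma(m1(ln2(A))))
    b2 <- linear_backward(dX, p[[paste0(pre, "mlp.W2")]], cb$m2)
    g[[paste0(pre, "mlp.W2")]] <- b2$dW; g[[paste0(pre, "mlp.b2")]] <- b2$db
    dma <- leaky_backward(b2$dx, cb$ma, cfg$leaky_slope)
    b1 <- linear_backward(dma, p[[paste0(pre, "mlp.W1")]], cb$m1)
    g[[paste0(pre, "mlp.W1")]] <- b1$dW; g[[paste0(pre, "mlp.b1")]] <- b1$db
    ln2b <- layernorm_backward(b1$dx, cb$ln2)
    g[[paste0(pre, "ln2.g")]] <- ln2b$dg; g[[paste0(pre, "ln2.b")]] <- ln2b$db
    dA <- dX + ln2b$dx
    # A = X + mha(ln1(X))
    attb <- mha_backward(dA, list(Wq = p[[paste0(pre, "Wq")]], Wk = p[[paste0(pre, "Wk")]],
                                  Wv = p[[paste0(pre, "Wv")]], Wo = p[[paste0(pre, "Wo")]]),
                         cb$att)
    for (w in c("Wq", "bq", "Wk", "bk", "Wv", "bv", "Wo", "bo")) {
      g[[paste0(pre, w)]] <- attb[[paste0("d", w)]]
    }
    ln1b <- layernorm_backward(attb$dx, cb$ln1)
    g[[paste0(pre, "ln1.g")]] <- ln1b$dg; g[[paste0(pre, "ln1.b")]] <- ln1b$db
    dX <- dA + ln1b$dx
  }

  # --- patch encoder --------------------------------------------------------
  enc <- caches$enc
  g[["enc.pos"]] <- dX
  g[["enc.area"]] <- colSums(dX) * enc$area_z
  g[["enc.W"]] <- t(enc$tokens) %*% dX
  g[["enc.b"]] <- colSums(dX)
  dtok <- dX %*% t(p[["enc.W"]])
  dh <- array(dtok, enc$h_dims)

  # --- scale blocks, reversed ----------------------------------------------
  for (i in rev(seq_len(cfg$n_scales))) {
    gi <- caches[[sprintf("gap%d", i)]]
    # per-scale scalar head on the GAP of the pooled map
    draw <- lambda * sign(fw$scale_preds[i, ] - tvec) * sigmoid(fw$scale_raw[i, ])
    g[[sprintf("shead%d.W", i)]] <- gi$gap %o% draw
    g[[sprintf("shead%d.b", i)]] <- draw
    seg <- (sum(cfg$filters[seq_len(i - 1L)]) + 1L):sum(cfg$filters[seq_len(i)])
    dgap <- drop(p[[sprintf("shead%d.W", i)]] %*% draw) + dgvec[seg]
    n_cell <- prod(gi$dims[1:2])
    dh <- dh + array(rep(dgap / n_cell, each = n_cell), gi$dims)
    dpool <- maxpool2_backward(dh, caches[[sprintf("pool%d", i)]])
    dact <- leaky_backward(dpool, caches[[sprintf("act%d", i)]], cfg$leaky_slope)
    cvb <- conv2d_backward(dact, p[[sprintf("scale%d.W", i)]],
                           caches[[sprintf("conv%d", i)]])
    g[[sprintf("scale%d.W", i)]] <- cvb$dW
    g[[sprintf("scale%d.b", i)]] <- cvb$db
    dh <- cvb$dx
  }

  dact0 <- leaky_backward(dh, caches$act0, cfg$leaky_slope)
  cv0 <- conv2d_backward(dact0, p[["conv0.W"]], caches$conv0)
  g[["conv0.W"]] <- cv0$dW
  g[["conv0.b"]] <- cv0$db

  list(loss = loss, grads = g,
       parts = c(bce = l_bce, scale = l_scale, final = l_final))
}

#' Rasterize ground-truth trajectories onto the coarse map grid
#'
#' Training target for the probability-map head: a bin is 1 if any molecule
#' is inside the bin's space-time cell (in-view frames only), else 0.
#'
#' @param ground_truth List of per-molecule records (each with a
#'   `trajectory` element), as stored in a simulated [kymograph()]. `NULL`
#'   or empty gives an all-zero map.
#' @param map_shape `c(time_bins, space_bins)`.
#' @param geometry The [channel_geometry()] of the kymograph.
#' @param n_frames Number of frames of the kymograph.
#' @return Binary matrix `time_bins x space_bins`.
#' @export
rasterize_ground_truth <- function(ground_truth, map_shape, geometry,
                                   n_frames) {
  occ <- matrix(0, map_shape[1], map_shape[2])
  if (is.null(ground_truth) || length(ground_truth) == 0L) return(occ)
  L <- view_length_nm(geometry)
  fpb <- n_frames / map_shape[1]
  for (rec in ground_truth) {
    pos <- rec$trajectory$positions
    f <- seq_along(pos)
    inview <- pos >= 0 & pos <= L
    if (!any(inview)) next
    tb <- ceiling(f[inview] / fpb)
    pb <- pmin(floor(pos[inview] / L * map_shape[2]) + 1L, map_shape[2])
    occ[cbind(tb, pb)] <- 1
  }
  occ
}

#' Probability-weighted scalar estimate from probability and property maps
#'
#' `estimate_j = sum(P * theta_j) / sum(P)` over all bins; with a uniform
#' probability map this is the unweighted mean of the property map, and with
#' all mass in one bin it is that bin's value. If the total probability mass
#' is zero the estimates are returned as `NA` with `undefined = TRUE` rather
#' than `NaN`.
#'
#' @param prob_map Matrix of per-bin probabilities.
#' @param property_map Matrix (one property) or 3-D array
#'   (`time_bins x space_bins x n_properties`).
#' @return List with `estimates` (named if the array has dimnames),
#'   `p_total`, and `undefined`.
#' @export
weighted_estimate <- function(prob_map, property_map) {
  if (is.matrix(property_map)) {
    property_map <- array(property_map, c(dim(property_map), 1L))
  }
  if (!all(dim(prob_map) == dim(property_map)[1:2])) {
    rlang::abort("Probability and property maps disagree in shape.",
                 class = "nanokymo_shape_error")
  }
  p_total <- sum(prob_map)
  k <- dim(property_map)[3]
  if (p_total == 0) {
    return(list(estimates = rep(NA_real_, k), p_total = 0, undefined = TRUE))
  }
  est <- vapply(seq_len(k),
                function(j) sum(prob_map * property_map[, , j]) / p_total,
                numeric(1))
  list(estimates = est, p_total = p_total, undefined = FALSE)
}

#' Predict molecular properties from a kymograph
#'
#' Runs the model on a (preprocessed) kymograph and returns the probability
#' map, the property map in physical units, and the probability-weighted
#' molecule estimate. Raw kymographs are preprocessed with default windows
#' first; standardization happens internally. The channel cross-section
#' area is a required input of the prediction (it conditions the
#' contrast-to-mass conversion) and defaults to the kymograph's geometry.
#'
#' @param model A trained (or untrained) `nsm_hvit`.
#' @param kymo An [kymograph()] or plain matrix.
#' @param area_nm2 Channel cross-section area, nm^2.
#' @return An object of class `nsm_prediction`: list with `probability_map`
#'   (`nsm_probability_map`), `property_map` (array, kDa / nm / points),
#'   `scale_preds`, and `estimate` (one-row tibble with `mw_kDa`, `rs_nm`,
#'   `n_points`, `p_total`, `undefined`).
#' @export
predict_hvit <- function(model, kymo, area_nm2 = NULL) {
  stopifnot(inherits(model, "nsm_hvit"))
  if (inherits(kymo, "nsm_kymograph")) {
    area_nm2 <- area_nm2 %||% kymo$geometry$area_nm2
    if (is.null(kymo$preprocessing)) kymo <- preprocess_kymograph(kymo)
    values <- kymo$values
  } else {
    values <- kymo
  }
  if (is.null(area_nm2)) {
    rlang::abort("`area_nm2` is required (or use a kymograph with geometry).",
                 class = "nanokymo_invalid_argument")
  }
  cfg <- model$config
  fw <- forward_hvit(model, values, area_nm2)
  hs <- cfg$map_shape[1]; ws <- cfg$map_shape[2]
  prop_phys <- array(0, c(hs, ws, 3L))
  scales <- c(cfg$mw_scale, cfg$rs_scale, cfg$n_scale)
  for (j in 1:3) prop_phys[, , j] <- matrix(fw$prop[, j], hs, ws) * scales[j]
  we <- weighted_estimate(fw$prob_map, prop_phys)
  est <- tibble::tibble(
    mw_kDa = we$estimates[1], rs_nm = we$estimates[2],
    n_points = we$estimates[3], p_total = we$p_total,
    undefined = we$undefined
  )
  pm <- fw$prob_map
  class(pm) <- c("nsm_probability_map", class(pm))
  structure(list(probability_map = pm, property_map = prop_phys,
                 scale_preds = sweep(fw$scale_preds, 2L,
                                     c(cfg$mw_scale, cfg$rs_scale), "*"),
                 estimate = est),
            class = "nsm_prediction")
}

#' @export
print.nsm_prediction <- function(x, ...) {
  e <- x$estimate
  cat(sprintf("<nsm_prediction> MW = %.3g kDa, Rs = %.3g nm, N = %.3g, P_total = %.3g\n",
              e$mw_kDa, e$rs_nm, e$n_points, e$p_total))
  invisible(x)
}

#' Predict a population of kymographs into one estimate table
#'
#' @param model A trained `nsm_hvit`.
#' @param kymos List of kymographs (or matrices).
#' @param area_nm2 Channel area, nm^2 (default from each kymograph).
#' @param ids Optional identifiers (defaults to names or indices).
#' @return Tibble with one row per kymograph: `id`, `mw_kDa`, `rs_nm`,
#'   `n_points`, `p_total`, `undefined`.
#' @export
predict_population <- function(model, kymos, area_nm2 = NULL, ids = NULL) {
  ids <- ids %||% (names(kymos) %||% as.character(seq_along(kymos)))
  rows <- purrr::map2(kymos, ids, function(k, id) {
    est <- predict_hvit(model, k, area_nm2)$estimate
    dplyr::bind_cols(tibble::tibble(id = id), est)
  })
  dplyr::bind_rows(rows)
}

#' Training loss of the probability and property outputs
#'
#' The total loss is the (optionally positive-weighted) binary cross-entropy
#' between the probability map and the occupancy target, plus `lambda` times
#' the L1 error of the property predictions: the per-scale scalar
#' predictions and the final probability-weighted estimates, all in
#' normalized units. This pure function states the contract; the training
#' path computes the same quantity together with its analytic gradients.
#'
#' @param prob_map Matrix (or vector) of per-bin probabilities in `[0, 1]`.
#' @param occupancy Binary matrix/vector of the same shape.
#' @param scale_preds Matrix (n_scales x 2) of per-scale (MW, Rs)
#'   predictions, normalized units; may be `NULL`.
#' @param est Numeric vector of final estimates (normalized units); may be
#'   `NULL`.
#' @param targets List with `mw`, `rs`, `n` (normalized units).
#' @param lambda Weight of the property L1 terms.
#' @param pos_weight Weight of occupied bins in the cross-entropy.
#' @return Scalar loss.
#' @export
hvit_loss <- function(prob_map, occupancy, scale_preds = NULL, est = NULL,
                      targets, lambda = 1, pos_weight = 1) {
  p <- as.vector(prob_map); y <- as.vector(occupancy)
  if (length(p) != length(y)) {
    rlang::abort("Probability map and occupancy shapes disagree.",
                 class = "nanokymo_shape_error")
  }
  pc <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  bce <- -mean(pos_weight * y * log(pc) + (1 - y) * log(1 - pc))
  l1 <- 0
  tvec <- c(targets$mw, targets$rs)
  if (!is.null(scale_preds)) {
    l1 <- l1 + sum(abs(sweep(scale_preds, 2L, tvec, "-")))
  }
  if (!is.null(est)) {
    l1 <- l1 + sum(abs(est - c(targets$mw, targets$rs, targets$n)))
  }
  bce + lambda * l1
}
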