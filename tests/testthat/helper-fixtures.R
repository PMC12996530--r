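# shared test fixtures, all generated in code

tiny_geometry <- function(n_pixels = 32L) {
  channel_geometry(63, 30, n_pixels = n_pixels)
}

# fully deterministic noise model: plain Gaussian envelope, nothing else
frozen_noise <- function(x0_bg, lambda_bg) {
  noise_params(x0_bg = x0_bg, lambda_bg = lambda_bg, amp_A = 0, d_x = 0,
               n_theta = 0, dirt_amp = 0)
}

# quiet shot-noise-only background used for high-SNR learning fixtures
quiet_noise <- function(n_theta = 4e-4) {
  noise_params(d_x = 0, amp_A = 0, n_theta = n_theta)
}

# the desk-scale model configuration exercised in learning tests
desk_config <- function() {
  hvit_config(input_shape = c(64L, 128L), n_scales = 3L,
              filters = c(8L, 12L, 16L), embed_dim = 24L, n_heads = 4L,
              n_transformer_blocks = 1L, mw_scale = 30, rs_scale = 3)
}

# micro configuration for gradient and shape checks
micro_config <- function(mw_scale = 1, rs_scale = 1, n_scale = 1) {
  hvit_config(input_shape = c(8L, 16L), n_scales = 1L, initial_kernel = 3L,
              filters = 4L, embed_dim = 8L, n_heads = 2L, mlp_dim = 12L,
              n_transformer_blocks = 1L, mw_scale = mw_scale,
              rs_scale = rs_scale, n_scale = n_scale)
}

# brute-force truncated-window moving average (independent oracle)
brute_running_mean <- function(v, w) {
  n <- length(v)
  left <- floor((w - 1) / 2); right <- w - 1 - left
  vapply(seq_len(n), function(i) {
    mean(v[max(1, i - left):min(n, i + right)])
  }, numeric(1))
}
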