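# internal helpers shared across modules

# Evaluate `code` under a temporary RNG seed, restoring global RNG state after.
# seed = NULL leaves the RNG stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

assert_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    rlang::abort(sprintf("`%s` must be a single positive finite number.", name),
                 class = "nanokymo_invalid_argument")
  }
  invisible(x)
}

assert_nonneg_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0) {
    rlang::abort(sprintf("`%s` must be a single non-negative finite number.", name),
                 class = "nanokymo_invalid_argument")
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != as.integer(x)) {
    rlang::abort(sprintf("`%s` must be an integer >= %d.", name, min),
                 class = "nanokymo_invalid_argument")
  }
  invisible(as.integer(x))
}

# Centered moving average with truncated, renormalized windows at the edges.
# The window always sums to one over the samples it actually covers.
running_mean <- function(v, width) {
  n <- length(v)
  width <- assert_count(width, "width")
  cs <- c(0, cumsum(v))
  left <- floor((width - 1L) / 2L)
  right <- width - 1L - left
  idx <- seq_len(n)
  i1 <- pmax(1L, idx - left)
  i2 <- pmin(n, idx + right)
  (cs[i2 + 1L] - cs[i1]) / (i2 - i1 + 1L)
}
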