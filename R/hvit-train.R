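#' Training configuration
#'
#' Training follows the published recipe at configurable scale: Adam with
#' learning rate 1e-4 by default, kymographs re-generated on the fly every
#' step (no example is ever seen twice), optional curriculum stages that
#' progressively widen the simulated MW/Rs ranges once the loss plateaus,
#' and periodic validation against a held-out set of simulated kymographs.
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size Kymographs per optimization step.
#' @param n_steps Total optimization steps.
#' @param mw_range,rs_range Property ranges (kDa, nm) simulated during
#'   training when no curriculum is given.
#' @param curriculum Optional list of stages, each a list with `mw_range`
#'   and `rs_range`; training advances to the next stage when the loss
#'   plateaus (see [plateau_reached()]).
#' @param plateau_tol Relative improvement below which the loss is
#'   considered converged (default 1%).
#' @param patience Window length (steps) over which the plateau rule is
#'   evaluated.
#' @param validation_every Validate every this many steps.
#' @param n_validation Number of held-out validation kymographs.
#' @param lambda_prop Weight of the property L1 loss relative to the
#'   probability-map cross-entropy.
#' @param pos_weight Weight of occupied bins in the cross-entropy (> 1
#'   rebalances the sparse detection targets).
#' @param warmup_steps Linear learning-rate warmup over this many initial
#'   steps (0 disables); stabilizes the early transient of short runs.
#' @param seed Seed for data generation and initialization.
#' @return An object of class `hvit_train_config`.
#' @export
hvit_train_config <- function(learning_rate = 1e-4, batch_size = 8L,
                              n_steps = 2000L, mw_range = c(0, 30),
                              rs_range = c(0.7, 3), curriculum = NULL,
                              plateau_tol = 0.01, patience = 50L,
                              validation_every = 400L, n_validation = 150L,
                              lambda_prop = 1, pos_weight = 1,
                              warmup_steps = 0L, seed = NULL) {
  assert_positive_scalar(learning_rate, "learning_rate")
  stopifnot(mw_range[1] <= mw_range[2], rs_range[1] <= rs_range[2])
  structure(
    list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
         n_steps = as.integer(n_steps), mw_range = mw_range,
         rs_range = rs_range, curriculum = curriculum,
         plateau_tol = plateau_tol, patience = as.integer(patience),
         validation_every = as.integer(validation_every),
         n_validation = as.integer(n_validation),
         lambda_prop = lambda_prop, pos_weight = pos_weight,
         warmup_steps = as.integer(warmup_steps), seed = seed),
    class = "hvit_train_config"
  )
}

#' Curriculum convergence rule
#'
#' The loss is considered plateaued when the mean loss over the most recent
#' `patience` steps improves by less than `tol` (relative) over the mean of
#' the `patience` steps before them. Requires at least `2 * patience`
#' recorded losses.
#'
#' @param losses Numeric vector of per-step training losses.
#' @param patience Window length.
#' @param tol Relative improvement threshold.
#' @return `TRUE` if the plateau rule fires.
#' @export
plateau_reached <- function(losses, patience = 50L, tol = 0.01) {
  n <- length(losses)
  if (n < 2L * patience) return(FALSE)
  recent <- mean(losses[(n - patience + 1L):n])
  previous <- mean(losses[(n - 2L * patience + 1L):(n - patience)])
  if (previous == 0) return(TRUE)
  (previous - recent) / abs(previous) < tol
}

#' Simulation-backed training data generator
#'
#' Returns a closure `function(n, mw_range, rs_range)` producing `n`
#' freshly simulated, preprocessed training examples: kymograph values,
#' coarse-grid occupancy target, normalized property targets, and the
#' channel area. Molecular weight is drawn uniformly from `mw_range`
#' (truncated below at `mw_min`) and Rs from `rs_range`; diffusivity
#' follows from Rs through Stokes-Einstein unless `d_um2_s` pins it (a
#' deliberately decoupled regime for small-scale experiments where slow,
#' in-view trajectories are wanted).
#'
#' @param config The [hvit_config()] of the model to be trained (fixes the
#'   input and map shapes).
#' @param geometry A [channel_geometry()] (pixel count must match the model
#'   input).
#' @param noise A [noise_params()].
#' @param s_nm Gaussian response width, nm.
#' @param d_um2_s Optional fixed diffusivity override, um^2/s.
#' @param n_molecules Molecules per kymograph.
#' @param dt Frame interval, s.
#' @param constants A [conversion_constants()].
#' @param hindrance A [hindrance_model()].
#' @param mw_min Smallest simulated MW (kDa) when ranges start at 0.
#' @param mw_values Optional discrete MW grid (kDa); when given, MW is
#'   sampled uniformly from these values instead of the continuous range
#'   (used for small-scale rank-order experiments).
#' @param p_empty Probability that a training kymograph contains no molecule
#'   (pure background); its occupancy and property targets are all zero, the
#'   regime that teaches the probability head to reject buffer-only
#'   controls.
#' @param window_time,window_space Preprocessing windows.
#' @return A generator closure for [train_hvit()].
#' @export
hvit_training_generator <- function(config, geometry, noise = noise_params(),
                                    s_nm = 100, d_um2_s = NULL,
                                    n_molecules = 1L, dt = 0.005,
                                    constants = conversion_constants(),
                                    hindrance = hindrance_model("none"),
                                    mw_min = 0.5, mw_values = NULL,
                                    p_empty = 0,
                                    window_time = 200L, window_space = 200L) {
  stopifnot(inherits(config, "hvit_config"))
  if (geometry$n_pixels != config$input_shape[2]) {
    rlang::abort("Geometry pixel count must match the model input width.",
                 class = "nanokymo_shape_error")
  }
  n_frames <- config$input_shape[1]
  function(n, mw_range, rs_range) {
    purrr::map(seq_len(n), function(i) {
      empty <- p_empty > 0 && stats::runif(1) < p_empty
      mw <- if (!is.null(mw_values)) {
        mw_values[sample.int(length(mw_values), 1L)]
      } else {
        stats::runif(1, max(mw_range[1], mw_min), mw_range[2])
      }
      rs <- stats::runif(1, rs_range[1], rs_range[2])
      if (empty) mw <- 0
      kym <- simulate_kymograph(
        mw_kDa = if (empty) NULL else mw, rs_nm = rs, d_um2_s = d_um2_s,
        n_molecules = if (empty) 0L else n_molecules,
        n_frames = n_frames, s_nm = s_nm,
        geometry = geometry, noise = noise, constants = constants,
        hindrance = hindrance, dt = dt
      )
      if (empty) rs <- 0
      pre <- preprocess_kymograph(kym, window_time, window_space)
      occ <- rasterize_ground_truth(kym$ground_truth, config$map_shape,
                                    geometry, n_frames)
      n_pts <- sum(vapply(kym$ground_truth %||% list(),
                          function(r) r$trajectory$n_in_view, numeric(1)))
      list(values = pre$values, area = geometry$area_nm2, occupancy = occ,
           targets = list(mw = mw / config$mw_scale,
                          rs = rs / config$rs_scale,
                          n = n_pts / config$n_scale))
    })
  }
}

# One Adam update; state holds first/second moments per parameter array.
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    gnm <- grads[[nm]]
    if (is.null(gnm)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gnm
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gnm^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Train a hierarchical vision transformer on simulated kymographs
#'
#' Runs the optimization loop: every step a fresh batch is simulated with
#' the generator at the current curriculum stage, gradients are averaged
#' over the batch, and Adam updates the parameters. The held-out validation
#' set is generated once up front; validation loss is recorded every
#' `validation_every` steps and the best-validation parameters are kept. A
#' non-finite loss aborts with a diagnostic.
#'
#' @param model An `nsm_hvit` from [build_hvit()].
#' @param generator A generator closure, e.g. from
#'   [hvit_training_generator()].
#' @param config An [hvit_train_config()].
#' @return An object of class `nsm_hvit_fit`: list with `model` (best
#'   validation parameters if validation ran, else final), `final_model`,
#'   `history` (tibble: step, stage, loss, bce, val_loss), and `config`.
#' @export
train_hvit <- function(model, generator, config = hvit_train_config()) {
  stopifnot(inherits(model, "nsm_hvit"),
            inherits(config, "hvit_train_config"))
  with_seed(config$seed, {
    stages <- config$curriculum %||%
      list(list(mw_range = config$mw_range, rs_range = config$rs_range))
    stage <- 1L
    params <- model$params
    state <- list(t = 0L,
                  m = purrr::map(params, function(x) x * 0),
                  v = purrr::map(params, function(x) x * 0))
    val_set <- if (config$n_validation > 0L) {
      generator(config$n_validation, stages[[length(stages)]]$mw_range,
                stages[[length(stages)]]$rs_range)
    }
    val_loss_of <- function(m) {
      mean(vapply(val_set, function(s) {
        hvit_loss_grads(m, s$values, s$area, s$occupancy, s$targets,
                        lambda = config$lambda_prop,
                        pos_weight = config$pos_weight)$loss
      }, numeric(1)))
    }

    history <- vector("list", config$n_steps)
    stage_losses <- numeric(0)
    best_val <- Inf
    best_params <- NULL
    for (step in seq_len(config$n_steps)) {
      batch <- generator(config$batch_size, stages[[stage]]$mw_range,
                         stages[[stage]]$rs_range)
      loss_acc <- 0; bce_acc <- 0; grad_acc <- NULL
      for (s in batch) {
        lg <- hvit_loss_grads(model, s$values, s$area, s$occupancy,
                              s$targets, lambda = config$lambda_prop,
                              pos_weight = config$pos_weight)
        loss_acc <- loss_acc + lg$loss
        bce_acc <- bce_acc + lg$parts[["bce"]]
        grad_acc <- if (is.null(grad_acc)) lg$grads
                    else purrr::map2(grad_acc, lg$grads[names(grad_acc)], `+`)
      }
      loss <- loss_acc / length(batch)
      if (!is.finite(loss)) {
        rlang::abort(sprintf("Training diverged at step %d (loss = %g).",
                             step, loss),
                     class = "nanokymo_divergence")
      }
      grads <- purrr::map(grad_acc, function(gx) gx / length(batch))
      lr_t <- config$learning_rate *
        if (config$warmup_steps > 0L) min(1, step / config$warmup_steps) else 1
      upd <- adam_step(params, grads, state, lr_t)
      params <- upd$params; state <- upd$state
      model$params <- params

      vl <- NA_real_
      if (!is.null(val_set) && step %% config$validation_every == 0L) {
        vl <- val_loss_of(model)
        if (vl < best_val) {
          best_val <- vl
          best_params <- params
        }
      }
      stage_losses <- c(stage_losses, loss)
      history[[step]] <- tibble::tibble(step = step, stage = stage,
                                        loss = loss,
                                        bce = bce_acc / length(batch),
                                        val_loss = vl)
      if (stage < length(stages) &&
          plateau_reached(stage_losses, config$patience, config$plateau_tol)) {
        stage <- stage + 1L
        stage_losses <- numeric(0)
      }
    }
    final_model <- model
    best_model <- model
    if (!is.null(best_params)) best_model$params <- best_params
    structure(
      list(model = best_model, final_model = final_model,
           history = dplyr::bind_rows(history), config = config,
           best_val_loss = if (is.finite(best_val)) best_val else NA_real_),
      class = "nsm_hvit_fit"
    )
  })
}

#' @export
print.nsm_hvit_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf(
    "<nsm_hvit_fit> %d steps, %d stage(s); loss %.4g -> %.4g%s\n",
    nrow(h), max(h$stage), h$loss[1], h$loss[nrow(h)],
    if (is.finite(x$best_val_loss %||% NA))
      sprintf(", best val %.4g", x$best_val_loss) else ""))
  invisible(x)
}
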