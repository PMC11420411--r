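#' Discretized noise-scale schedule
#'
#' The EDM polynomial schedule:
#' `t_i = (sigma_max^(1/rho) + i/(T-1) (sigma_min^(1/rho) - sigma_max^(1/rho)))^rho`
#' for `i = 0..T-1`, with `t_T = 0` appended; `T = 1` degenerates to
#' `{sigma_max, 0}`.  With `sigma(t) = t` these are both the times and the
#' noise scales of the sampling ODE.
#'
#' @param T Number of steps, >= 1.
#' @param sigma_min,sigma_max Schedule endpoints, `0 < sigma_min < sigma_max`.
#' @param rho Schedule exponent (7 concentrates steps near sigma_min).
#' @return An object of class `noise_schedule` with the length `T + 1`
#'   vector `t`.
#' @export
make_schedule <- function(T, sigma_min = 0.002, sigma_max = 80, rho = 7) {
  stopifnot(T >= 1)
  if (!(sigma_min > 0 && sigma_min < sigma_max))
    stop("need 0 < sigma_min < sigma_max")
  if (T == 1L) {
    t <- c(sigma_max, 0)
  } else {
    i <- 0:(T - 1)
    t <- (sigma_max^(1 / rho) +
            i / (T - 1) * (sigma_min^(1 / rho) - sigma_max^(1 / rho)))^rho
    t <- c(t, 0)
  }
  if (any(diff(t) >= 0)) stop("schedule is not strictly decreasing")
  structure(list(T = as.integer(T), sigma_min = sigma_min,
                 sigma_max = sigma_max, rho = rho, t = t),
            class = "noise_schedule")
}

#' Sampler configuration
#'
#' Controls the two modifications of the deterministic Heun sampler that turn
#' an unconditional generator into a denoiser: hijacking (start at step `tau`
#' by injecting the condition image, unscaled and un-noised) and
#' regularization (after every solver step, mix `x <- w x + (1 - w) c`;
#' `w = 1` disables the mixing, `w = 0` returns the condition unchanged).
#' With `tau = T - 1` the single remaining step has `t_next = 0`, so only one
#' network evaluation is spent (NFE = 1).
#'
#' @param schedule A [make_schedule()].
#' @param tau Hijack index in `0..T-1`.
#' @param w Mixing weight in [0, 1].
#' @param geom A [geom_config()].
#' @param mode One of "posterior" (hijack + regularize), "unconditional",
#'   "hijack_only" (no mixing), "regularize_only" (prior start + mixing).
#' @return An object of class `sampler_config`.  `r_max` is
#'   `sigma_max * sqrt(D)` for finite D, else `sigma_max`.
#' @export
sampler_config <- function(schedule = make_schedule(8), tau = schedule$T - 1L,
                           w = 0.5, geom = geom_config(64, 128),
                           mode = c("posterior", "unconditional",
                                    "hijack_only", "regularize_only")) {
  mode <- match.arg(mode)
  stopifnot(inherits(schedule, "noise_schedule"), inherits(geom, "pfct_geom"),
            tau >= 0, tau < schedule$T, w >= 0, w <= 1)
  r_max <- if (is_diffusion_limit(geom)) schedule$sigma_max else
    sigma_to_r(schedule$sigma_max, geom)
  structure(list(schedule = schedule, tau = as.integer(tau), w = w,
                 geom = geom, mode = mode, r_max = r_max),
            class = "sampler_config")
}

#' One deterministic solver step
#'
#' An Euler step with drift `d = (x - D(x; t_cur)) / t_cur`; when
#' `t_next > 0` a second-order (trapezoidal) correction re-evaluates the
#' drift at the predicted point (2 network evaluations), otherwise the Euler
#' step stands alone (1 evaluation) - which is what makes NFE = 1 possible at
#' the final step.
#'
#' @param model A `pfct_denoiser`.
#' @param x Current iterate (normalized units).
#' @param t_cur Current noise scale, > 0.
#' @param t_next Next noise scale, >= 0.
#' @param geom A [geom_config()].
#' @return List with the stepped image `x` and `nfe_increment`.
#' @export
heun_step <- function(model, x, t_cur, t_next, geom = model$geom) {
  stopifnot(t_cur > 0)
  d <- (x - denoise_estimate(model, x, t_cur)) / t_cur
  x_pred <- x + (t_next - t_cur) * d
  if (t_next > 0) {
    d2 <- (x_pred - denoise_estimate(model, x_pred, t_next)) / t_next
    list(x = x + (t_next - t_cur) * (d + d2) / 2, nfe_increment = 2L)
  } else {
    list(x = x_pred, nfe_increment = 1L)
  }
}

#' Closed-form count of network evaluations
#'
#' Sums over the solver steps actually taken (from the start index to
#' `T - 1`): 2 per interior Heun step, 1 for the final Euler step onto
#' `t = 0`.  `tau = T - 1` gives exactly 1.
#'
#' @param cfg A [sampler_config()].
#' @return Integer NFE.
#' @export
count_nfe <- function(cfg) {
  stopifnot(inherits(cfg, "sampler_config"))
  start <- if (cfg$mode %in% c("posterior", "hijack_only")) cfg$tau else 0L
  t <- cfg$schedule$t
  sum(vapply(seq.int(start, cfg$schedule$T - 1L), function(i)
    if (t[i + 2L] > 0) 2L else 1L, integer(1)))
}

new_sampling_result <- function(output, nfe, trajectory = NULL) {
  structure(list(output = output, nfe = nfe, trajectory = trajectory),
            class = "sampling_result")
}

#' @export
print.sampling_result <- function(x, ...) {
  cat(sprintf("<sampling_result> %d x %d image, nfe = %d\n",
              nrow(x$output), ncol(x$output), x$nfe))
  invisible(x)
}

# Integrate steps start_i .. T-1 of the schedule, optionally mixing with the
# condition after each step; records (t, x) states when keep_trajectory.
integrate_steps <- function(model, x, cfg, start_i, c_norm = NULL,
                            mix = FALSE, keep_trajectory = FALSE) {
  t <- cfg$schedule$t
  nfe <- 0L
  traj <- if (keep_trajectory) list(list(t = t[start_i + 1L], x = x)) else NULL
  for (i in seq.int(start_i, cfg$schedule$T - 1L)) {
    st <- heun_step(model, x, t[i + 1L], t[i + 2L], cfg$geom)
    x <- st$x
    nfe <- nfe + st$nfe_increment
    if (mix) x <- cfg$w * x + (1 - cfg$w) * c_norm
    if (keep_trajectory)
      traj[[length(traj) + 1L]] <- list(t = t[i + 2L], x = x)
  }
  list(x = x, nfe = nfe, trajectory = traj)
}

#' Unconditional generation
#'
#' Integrates the full reverse ODE from a prior sample on the
#' `r = r_max` hyper-cylinder (Gaussian at `sigma_max` for `D = Inf`),
#' spending `2T - 1` network evaluations.
#'
#' @param model A `pfct_denoiser`.
#' @param cfg A [sampler_config()] with `mode = "unconditional"`.
#' @param seed Optional integer seed for the prior draw.
#' @param keep_trajectory Record per-step states.
#' @return A `sampling_result`; `output` is in HU.
#' @export
sample_unconditional <- function(model, cfg, seed = NULL,
                                 keep_trajectory = FALSE) {
  stopifnot(inherits(cfg, "sampler_config"))
  if (cfg$mode != "unconditional")
    stop("cfg$mode must be \"unconditional\"")
  shape <- model$patch_shape
  x0 <- with_seed(seed, sample_prior(cfg$r_max, shape, cfg$geom))
  nfe_reset(model)
  res <- integrate_steps(model, x0, cfg, 0L,
                         keep_trajectory = keep_trajectory)
  new_sampling_result(unit_to_hu(res$x, model$normalization), res$nfe,
                      res$trajectory)
}

#' Posterior denoising by hijacking and regularization
#'
#' In "posterior" and "hijack_only" modes the reverse process is hijacked at
#' step `tau`: the condition image is injected as the iterate, unscaled and
#' with no added noise, and the remaining `T - tau` steps are integrated.  In
#' "posterior" (and "regularize_only") mode, after every solver step the
#' iterate is mixed with the condition, `x <- w x + (1 - w) c` - the identity
#' data-consistency map, sufficient for denoising.  "regularize_only" starts
#' from a prior sample instead of hijacking (requires `seed` for the draw).
#' Posterior and hijack modes are fully deterministic.
#'
#' @param model A `pfct_denoiser`.
#' @param c_img The noisy condition image, in HU.
#' @param cfg A [sampler_config()] with a posterior-family mode.
#' @param seed Seed for the prior draw in "regularize_only" mode.
#' @param keep_trajectory Record per-step states.
#' @return A `sampling_result`; `output` is in HU, `nfe` counts actual
#'   network evaluations and equals [count_nfe()].
#' @export
denoise_posterior <- function(model, c_img, cfg, seed = NULL,
                              keep_trajectory = FALSE) {
  stopifnot(inherits(cfg, "sampler_config"))
  if (!cfg$mode %in% c("posterior", "hijack_only", "regularize_only"))
    stop("cfg$mode must be posterior, hijack_only or regularize_only")
  if (!identical(as.integer(dim(c_img)), model$patch_shape) &&
      !inherits(model, "mlp_denoiser"))
    stop("condition image shape incompatible with the model")
  c_norm <- hu_to_unit(c_img, model$normalization)
  nfe_reset(model)
  if (cfg$mode == "regularize_only") {
    x0 <- with_seed(seed, sample_prior(cfg$r_max, dim(c_img), cfg$geom))
    res <- integrate_steps(model, x0, cfg, 0L, c_norm, mix = TRUE,
                           keep_trajectory = keep_trajectory)
  } else {
    mix <- cfg$mode == "posterior"
    res <- integrate_steps(model, c_norm, cfg, cfg$tau, c_norm, mix = mix,
                           keep_trajectory = keep_trajectory)
  }
  new_sampling_result(unit_to_hu(res$x, model$normalization), res$nfe,
                      res$trajectory)
}
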