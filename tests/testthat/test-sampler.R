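test_that("the noise schedule matches its closed form", {
  s <- make_schedule(8, 0.002, 80, 7)
  expect_equal(s$t[1], 80)
  expect_equal(s$t[8], 0.002)
  expect_equal(s$t[9], 0)
  # independent re-evaluation through the log form
  i <- 0:7
  expected <- exp(7 * log(exp(log(80) / 7) +
                            i / 7 * (exp(log(0.002) / 7) - exp(log(80) / 7))))
  expect_equal(s$t[1:8], expected, tolerance = 1e-14)

  expect_equal(make_schedule(1)$t, c(80, 0))
  expect_error(make_schedule(4, 80, 0.002), "sigma_min < sigma_max")
  s32 <- make_schedule(32, 0.002, 80, 7)
  expect_equal(s32$t[1], 80)
  expect_equal(s32$t[32], 0.002)
  expect_true(all(diff(s32$t) < 0))
})

test_that("solver steps are exact on linear fields", {
  g <- geom_config(4, 16)
  norm <- hu_normalization()
  y_hu <- matrix(c(0, 40, -100, 300), 2, 2)
  orc <- oracle_denoiser(list(y_hu), g, norm)
  y <- hu_to_unit(y_hu, norm)

  # zero step
  x <- y + 0.4 * matrix(c(1, -1, 1, -1), 2, 2)
  st <- heun_step(orc, x, 0.5, 0.5)
  expect_equal(st$x, x)

  # single charge: the final Euler step to t = 0 lands exactly on the charge
  st2 <- heun_step(orc, x, 0.8, 0)
  expect_equal(st2$x, y, tolerance = 1e-12)
  expect_identical(st2$nfe_increment, 1L)

  # multi-step integration along the exact linear trajectory stays exact
  sched <- make_schedule(6, 0.01, 2)
  xi <- y + sched$t[1] * matrix(c(0.3, -0.2, 0.1, 0.5), 2, 2)
  for (i in 1:6) xi <- heun_step(orc, xi, sched$t[i], sched$t[i + 1])$x
  expect_equal(xi, y, tolerance = 1e-9)

  # drift linear in t (independent of x): trapezoid integrates it exactly
  a <- matrix(0.3, 1, 1); b <- matrix(-0.2, 1, 1)
  toy <- toy_linear_field_model(a, b, c(1, 1))
  x0 <- matrix(2, 1, 1)
  got <- heun_step(toy, x0, 1.5, 0.4)$x
  analytic <- x0 + a * (0.4 - 1.5) + b * (0.4^2 - 1.5^2) / 2
  expect_equal(got, analytic, tolerance = 1e-14)
})

test_that("NFE bookkeeping matches the closed form on a (T, tau) grid", {
  g <- geom_config(16, 64)
  ds <- list(matrix(runif(16, -1000, 400), 4, 4),
             matrix(runif(16, -1000, 400), 4, 4))
  orc <- oracle_denoiser(ds, g)
  c_img <- ds[[1]] + 30
  for (T in c(1L, 2L, 4L, 8L)) {
    sched <- make_schedule(T)
    for (tau in unique(c(0L, T %/% 2L, T - 1L))) {
      cfg <- sampler_config(sched, tau = tau, w = 0.5, geom = g)
      res <- denoise_posterior(orc, c_img, cfg)
      expect_identical(res$nfe, count_nfe(cfg))
    }
  }
  expect_identical(count_nfe(sampler_config(make_schedule(8), tau = 7L, geom = g)), 1L)
  expect_identical(count_nfe(sampler_config(make_schedule(8), tau = 0L, geom = g)), 15L)
  ucfg <- sampler_config(make_schedule(1), geom = g, mode = "unconditional")
  expect_identical(count_nfe(ucfg), 1L)
  res1 <- sample_unconditional(orc, ucfg, seed = 1)
  expect_identical(res1$nfe, 1L)
  u8 <- sampler_config(make_schedule(8), geom = g, mode = "unconditional")
  expect_identical(sample_unconditional(orc, u8, seed = 1)$nfe, 15L)
})

test_that("posterior denoising follows the single-charge closed form", {
  g <- geom_config(16, 64)
  norm <- hu_normalization()
  y_hu <- matrix(runif(16, -1000, 400), 4, 4)
  orc <- oracle_denoiser(list(y_hu), g, norm)
  set.seed(40)
  c_img <- y_hu + matrix(rnorm(16, sd = 50), 4, 4)
  sched <- make_schedule(8)

  # w = 0: the mixing degenerates to the identity, output = condition
  out0 <- denoise_posterior(orc, c_img, sampler_config(sched, 7L, 0, g))$output
  expect_equal(out0, c_img, tolerance = 1e-12)

  # tau = T-1: single Euler step; closed form w y + (1 - w) c for one charge
  for (w in c(0.3, 0.5, 1)) {
    out <- denoise_posterior(orc, c_img, sampler_config(sched, 7L, w, g))$output
    expect_equal(out, w * y_hu + (1 - w) * c_img, tolerance = 1e-8)
  }

  # tau = T-1, w = 1 equals the raw one-step Euler denoise of c at t_{T-1}
  cn <- hu_to_unit(c_img, norm)
  t7 <- sched$t[8]
  euler <- cn + (0 - t7) * (cn - denoise_estimate(orc, cn, t7)) / t7
  out1 <- denoise_posterior(orc, c_img, sampler_config(sched, 7L, 1, g))$output
  expect_equal(out1, unit_to_hu(euler, norm), tolerance = 1e-10)

  # determinism: posterior mode is a pure function of (model, c, cfg)
  cfg <- sampler_config(sched, 7L, 0.5, g)
  expect_identical(denoise_posterior(orc, c_img, cfg)$output,
                   denoise_posterior(orc, c_img, cfg)$output)
})

test_that("the diffusion special case reduces exactly in the sampler", {
  # the sigma-time ODE given one fixed denoiser is D-independent: posterior
  # trajectories with D = Inf and D = 1e6 agree (hyperparameter translation)
  set.seed(41)
  model <- mlp_denoiser(c(4, 4), geom_config(16, 128))
  c_img <- matrix(runif(16, -1000, 400), 4, 4)
  sched <- make_schedule(8)
  tr <- function(geom) {
    cfg <- sampler_config(sched, tau = 0L, w = 0.5, geom = geom)
    res <- denoise_posterior(model, c_img, cfg, keep_trajectory = TRUE)
    do.call(rbind, lapply(res$trajectory, function(s) as.vector(s$x)))
  }
  t_inf <- tr(geom_config(16, Inf))
  t_fin <- tr(geom_config(16, 1e6))
  expect_lt(sqrt(sum((t_inf - t_fin)^2) / sum(t_inf^2)), 1e-4)
})

test_that("hijacking and regularization reproduce the ablation contract", {
  spec <- default_phantom_spec(32)
  pairs <- make_paired_eval_set(3, spec, degradation_config(50), seed = 50)
  g <- geom_config(1024, 128)
  orc <- oracle_denoiser(pairs$clean, g)
  sched <- make_schedule(8)
  dr <- max(sapply(pairs$clean, max)) - min(sapply(pairs$clean, min))
  # locate a flat ROI (constant in the clean image)
  roi <- NULL
  for (r0 in seq(2, 26, by = 2)) for (c0 in seq(2, 26, by = 2)) {
    cand <- c(r0, r0 + 5, c0, c0 + 5)
    if (roi_noise_sd(pairs$clean[[1]], cand) == 0) { roi <- cand; break }
  }
  expect_false(is.null(roi))

  post <- denoise_posterior(orc, pairs$noisy[[1]],
                            sampler_config(sched, 7L, 0.5, g))$output
  hij <- denoise_posterior(orc, pairs$noisy[[1]],
                           sampler_config(sched, 7L, 1, g,
                                          mode = "hijack_only"))$output
  reg <- denoise_posterior(orc, pairs$noisy[[1]],
                           sampler_config(sched, 0L, 0.5, g,
                                          mode = "regularize_only"),
                           seed = 51)$output

  # posterior output is closer to the clean image than the condition is
  expect_gt(psnr(post, pairs$clean[[1]], dr),
            psnr(pairs$noisy[[1]], pairs$clean[[1]], dr))
  # hijack-only (w = 1) denoises more aggressively than posterior (w = 0.5)
  expect_lt(roi_noise_sd(hij, roi), roi_noise_sd(post, roi))
  # regularize-only stays close to the condition, not to the prior sample
  set.seed(51)
  prior0 <- unit_to_hu(sample_prior(sampler_config(sched, 0L, 0.5, g)$r_max,
                                    dim(pairs$noisy[[1]]), g),
                       hu_normalization())
  expect_gt(cor(as.vector(reg), as.vector(pairs$noisy[[1]])),
            cor(as.vector(reg), as.vector(prior0)))
})
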