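# Independent oracles used to check the implementation.  Everything here is
# deliberately written from the defining formulas (numeric integration,
# direct summation), not by calling the code paths under test.

# CDF of the perturbation-kernel radius R = ||x - y|| for finite (N, D):
# p(R) \propto R^(N-1) / (R^2 + r^2)^((N+D)/2), integrated numerically on a
# theta grid through the substitution R = r tan(theta).
radial_cdf_numeric <- function(N, D, r, n_grid = 200001L) {
  th <- seq(1e-9, pi / 2 - 1e-9, length.out = n_grid)
  R <- r * tan(th)
  logf <- (N - 1) * log(R) - ((N + D) / 2) * log(R^2 + r^2) +
    log(r) - 2 * log(cos(th))
  f <- exp(logf - max(logf))
  cum <- cumsum((f[-1] + f[-length(f)]) / 2 * diff(th))
  cdf <- c(0, cum / cum[length(cum)])
  stats::approxfun(R, cdf, yleft = 0, yright = 1, rule = 2)
}

# Gaussian posterior-mean score drift (x - E[y | x]) / sigma for a discrete
# dataset, computed directly (no log-sum-exp).
gauss_posterior_drift <- function(x, sigma, dataset) {
  sq <- vapply(dataset, function(y) sum((x - y)^2), numeric(1))
  w <- exp(-(sq - min(sq)) / (2 * sigma^2))
  w <- w / sum(w)
  post_mean <- Reduce(`+`, Map(`*`, dataset, as.list(w)))
  (x - post_mean) / sigma
}

# Naive high-precision evaluation of the field ratio
# f* = sqrt(D) * sum_j w_j (x - y_j) / (r * sum_j w_j),
# w_j = (||x-y_j||^2 + r^2)^(-(N+D)/2), summed directly (valid at small N+D).
naive_field_direction <- function(x, r, dataset, D) {
  N <- length(x)
  w <- vapply(dataset, function(y) (sum((x - y)^2) + r^2)^(-(N + D) / 2),
              numeric(1))
  num <- Reduce(`+`, Map(function(y, wj) wj * (x - y), dataset, as.list(w)))
  sqrt(D) * num / (r * sum(w))
}

# Radii ||x - y|| of n perturbation draws around y = 0.
draw_radii <- function(n, N, D, r) {
  geom <- geom_config(N, D)
  y <- numeric(N)
  vapply(seq_len(n), function(i) sqrt(sum(perturb(y, r, geom)$x^2)), numeric(1))
}

# Two fixed 8x8 phantoms used as the toy training dataset.
toy_dataset_8x8 <- function() {
  s1 <- phantom_spec(list(phantom_ellipse(c(-0.2, 0), c(0.5, 0.4), 0, 60),
                          phantom_ellipse(c(0.3, 0.2), c(0.2, 0.2), 0, -100)),
                     background_hu = -1000, image_size = 8)
  s2 <- phantom_spec(list(phantom_ellipse(c(0.1, -0.1), c(0.6, 0.5), 30, 40),
                          phantom_ellipse(c(-0.3, 0.3), c(0.15, 0.25), 0, 300)),
                     background_hu = -1000, image_size = 8)
  list(generate_phantom(s1), generate_phantom(s2))
}

# A custom model whose drift is linear in t (independent of x), for exactness
# tests of the trapezoidal step: D(x; sigma) = x - sigma * (a + b * sigma).
toy_linear_field_model <- function(a, b, shape) {
  m <- structure(list(kind = "toy", patch_shape = as.integer(shape),
                      geom = geom_config(prod(shape), Inf),
                      normalization = hu_normalization(0, 1),
                      a = a, b = b,
                      nfe = new.env(parent = emptyenv())),
                 class = c("toy_linear_field", "pfct_denoiser"))
  m
}

denoise_estimate.toy_linear_field <- function(model, x, sigma, use_ema = TRUE) {
  x - sigma * (model$a + model$b * sigma)
}
registerS3method("denoise_estimate", "toy_linear_field",
                 denoise_estimate.toy_linear_field,
                 envir = asNamespace("pfct"))
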