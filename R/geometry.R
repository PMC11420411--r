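#' Augmented-space geometry configuration
#'
#' PFGM++ treats N-dimensional data (an image patch with N = n x n pixels) as
#' electric charges on the r = 0 hyperplane of an (N + D)-dimensional space.
#' By rotational symmetry only the norm r of the D augmented coordinates needs
#' to be tracked.  `aug_dim = Inf` selects the diffusion (EDM) special case in
#' which all radial quantities are interpreted directly as Gaussian noise
#' scales sigma.
#'
#' @param data_dim N, the number of data dimensions (pixels per patch).
#' @param aug_dim D, a positive number of augmented dimensions, or `Inf` for
#'   the diffusion limit.
#' @return An object of class `pfct_geom` with fields `N` and `D`.
#' @export
#' @examples
#' geom_config(64, 128)
#' geom_config(64, Inf)
geom_config <- function(data_dim, aug_dim) {
  if (!is.numeric(data_dim) || length(data_dim) != 1L || data_dim < 1)
    stop("`data_dim` must be a single number >= 1")
  if (!is.numeric(aug_dim) || length(aug_dim) != 1L ||
      (!is.infinite(aug_dim) && aug_dim < 1))
    stop("`aug_dim` must be a positive number or Inf")
  structure(list(N = as.numeric(data_dim), D = as.numeric(aug_dim)),
            class = "pfct_geom")
}

#' @export
print.pfct_geom <- function(x, ...) {
  cat(sprintf("<pfct_geom> N = %g, D = %s\n", x$N,
              if (is.infinite(x$D)) "Inf (diffusion limit)" else format(x$D)))
  invisible(x)
}

is_diffusion_limit <- function(geom) is.infinite(geom$D)

#' Translate a diffusion noise scale to an augmented radius (and back)
#'
#' The hyperparameter translation `r = sigma * sqrt(D)` aligns the PFGM++
#' radial coordinate with the EDM noise scale, so the EDM training and
#' sampling machinery can be reused unchanged for finite D.
#'
#' @param sigma Noise scale(s), >= 0.
#' @param r Augmented radius(es), >= 0.
#' @param geom A [geom_config()] with finite `D`.
#' @return The translated scale(s).
#' @export
sigma_to_r <- function(sigma, geom) {
  if (is_diffusion_limit(geom))
    stop("D = Inf: work directly in sigma; no radius translation exists")
  stopifnot(all(sigma >= 0))
  sigma * sqrt(geom$D)
}

#' @rdname sigma_to_r
#' @export
r_to_sigma <- function(r, geom) {
  if (is_diffusion_limit(geom))
    stop("D = Inf: work directly in sigma; no radius translation exists")
  stopifnot(all(r >= 0))
  r / sqrt(geom$D)
}

#' Training distribution of noise scales
#'
#' Noise scales are drawn log-normally, `ln(sigma) ~ N(P_mean, P_std^2)`, and
#' translated to radii via `r = sigma * sqrt(D)` when D is finite.  The
#' defaults follow the EDM training recipe.
#'
#' @param P_mean Mean of log sigma.
#' @param P_std Standard deviation of log sigma, > 0.
#' @return An object of class `noise_scale_dist`.
#' @export
noise_scale_dist <- function(P_mean = -1.2, P_std = 1.2) {
  stopifnot(is.numeric(P_mean), is.numeric(P_std), P_std > 0)
  structure(list(P_mean = P_mean, P_std = P_std), class = "noise_scale_dist")
}

#' Draw training noise scales
#'
#' @param dist A [noise_scale_dist()].
#' @param geom A [geom_config()].
#' @param n Number of draws.
#' @return For finite D, radii `r = sigma * sqrt(D)`; for `D = Inf`, the
#'   sigmas themselves.  Uses the current RNG stream.
#' @export
sample_training_scale <- function(dist, geom, n = 1L) {
  stopifnot(inherits(dist, "noise_scale_dist"), inherits(geom, "pfct_geom"))
  sigma <- exp(stats::rnorm(n, dist$P_mean, dist$P_std))
  if (is_diffusion_limit(geom)) sigma else sigma * sqrt(geom$D)
}

#' Construct an augmented state
#'
#' @param x Image-shaped numeric array (matrix or vector).
#' @param r Nonnegative scalar radius; `r = 0` is the data hyperplane.
#' @return An object of class `augmented_state` with fields `x` and `r`.
#' @export
augmented_state <- function(x, r) {
  stopifnot(is.numeric(x), is.numeric(r), length(r) == 1L, r >= 0)
  structure(list(x = x, r = r), class = "augmented_state")
}

# Uniform direction on the unit (N-1)-sphere, shaped like `template`.
runif_sphere <- function(template) {
  v <- stats::rnorm(length(template))
  v <- v / sqrt(sum(v^2))
  if (!is.null(dim(template))) dim(v) <- dim(template)
  v
}

# Radial factor sqrt(u / (1 - u)) with u ~ Beta(N/2, D/2): the perturbation
# kernel p_r(x|y) \propto 1 / (||x - y||^2 + r^2)^((N+D)/2) restricted to the
# radius R = ||x - y|| has density p(R) \propto R^(N-1) / (R^2 + r^2)^((N+D)/2),
# and u = R^2 / (R^2 + r^2) is Beta(N/2, D/2) distributed (verified against
# numeric integration of the density in the test-suite oracle).
rradial_factor <- function(n, N, D) {
  u <- stats::rbeta(n, N / 2, D / 2)
  sqrt(u / (1 - u))
}

#' Perturb a clean image with the PFGM++ kernel
#'
#' For finite D, samples from the heavy-tailed perturbation kernel
#' `p_r(x | y) \propto 1 / (||x - y||^2 + r^2)^((N+D)/2)` via the Beta
#' radial construction: `R = r * sqrt(u / (1 - u))` with
#' `u ~ Beta(N/2, D/2)` and a uniform direction on the N-sphere.  For
#' `D = Inf`, `r` is interpreted as sigma and the Gaussian kernel
#' `x = y + sigma * eps` is used.
#'
#' @param y Clean image (matrix or vector, any scale).
#' @param r Radius (finite D) or sigma (`D = Inf`); must be > 0.
#' @param geom A [geom_config()].
#' @return An [augmented_state()] at radius `r`.
#' @export
perturb <- function(y, r, geom) {
  stopifnot(inherits(geom, "pfct_geom"), is.numeric(r), length(r) == 1L)
  if (r <= 0) stop("`r` must be > 0")
  N <- length(y)
  if (is_diffusion_limit(geom)) {
    eps <- stats::rnorm(N)
    if (!is.null(dim(y))) dim(eps) <- dim(y)
    return(augmented_state(y + r * eps, r))
  }
  R <- r * rradial_factor(1L, N, geom$D)
  augmented_state(y + R * runif_sphere(y), r)
}

#' Sample from the prior noise distribution
#'
#' The reverse ODE starts on the `r = r_max` hyper-cylinder.  Treating the
#' whole dataset as a point charge at the origin (valid when `r_max` greatly
#' exceeds the data norms), the prior is the perturbation kernel about zero:
#' radius `r_max * sqrt(u / (1 - u))`, uniform direction.  For `D = Inf` the
#' prior is Gaussian with scale `sigma_max = r_max`.
#'
#' @param r_max Prior radius (finite D) or sigma_max (`D = Inf`), > 0.
#' @param shape Integer vector giving the image shape, e.g. `c(16, 16)`.
#' @param geom A [geom_config()].
#' @return An image-shaped array drawn from the prior.
#' @export
sample_prior <- function(r_max, shape, geom) {
  stopifnot(r_max > 0, inherits(geom, "pfct_geom"))
  template <- array(0, dim = shape)
  N <- length(template)
  if (is_diffusion_limit(geom)) {
    x <- r_max * stats::rnorm(N)
    dim(x) <- shape
    return(x)
  }
  R <- r_max * rradial_factor(1L, N, geom$D)
  R * runif_sphere(template)
}

#' Regression target of the perturbation objective
#'
#' The unconditional network is trained to regress
#' `(x - y) / (r / sqrt(D))` (finite D) or `(x - y) / sigma` (`D = Inf`);
#' its minimizer is the scaled Poisson field direction
#' `f*(x~) = sqrt(D) E(x~)_x / E(x~)_r`.
#'
#' @param x Perturbed image.
#' @param y Clean image, same shape.
#' @param r Radius (finite D) or sigma (`D = Inf`), > 0.
#' @param geom A [geom_config()].
#' @return Image-shaped target array.
#' @export
training_target <- function(x, y, r, geom) {
  stopifnot(inherits(geom, "pfct_geom"))
  if (r <= 0) stop("`r` must be > 0")
  sigma <- if (is_diffusion_limit(geom)) r else r / sqrt(geom$D)
  (x - y) / sigma
}

#' Exact Poisson field for a discrete dataset (test oracle)
#'
#' For the empirical distribution placing equal charge on each dataset image
#' y_j, the high-dimensional electric field components are sums over charges
#' weighted by `||(x - y_j, r)||^-(N+D)`; the surface-area constant of the
#' unit sphere cancels in the ratio and is never computed.  The returned
#' `direction` is the sigma-time ODE drift
#' `f*(x~) = sqrt(D) * sum_j lambda_j (x - y_j) / r`
#' with normalized weights `lambda_j`, computed in the log domain
#' (log-sum-exp) so it stays finite for N + D up to 1e6 and beyond.  For
#' `D = Inf` the Gaussian posterior weights
#' `lambda_j \propto exp(-||x - y_j||^2 / (2 sigma^2))` are used and the
#' drift is `sum_j lambda_j (x - y_j) / sigma`.
#'
#' @param x Probe image.
#' @param r Radius (finite D) or sigma (`D = Inf`), > 0.
#' @param dataset Nonempty list of images, all the same shape as `x`.
#' @param geom A [geom_config()].
#' @return An object of class `field_evaluation` with fields `direction`
#'   (image-shaped drift) and `log_weights` (per-charge log lambda_j).
#' @export
oracle_field <- function(x, r, dataset, geom) {
  stopifnot(inherits(geom, "pfct_geom"), length(dataset) >= 1L)
  if (r <= 0) stop("`r` must be > 0")
  if (!all(is.finite(x))) stop("non-finite probe")
  N <- length(x)
  diffs <- lapply(dataset, function(y) {
    if (length(y) != N) stop("dataset image shape mismatch")
    if (!all(is.finite(y))) stop("non-finite dataset image")
    x - y
  })
  sq <- vapply(diffs, function(d) sum(d^2), numeric(1))
  if (is_diffusion_limit(geom)) {
    sigma <- r
    logw <- -sq / (2 * sigma^2)
  } else {
    sigma <- r / sqrt(geom$D)
    logw <- -((N + geom$D) / 2) * log(sq + r^2)
  }
  logw <- logw - logsumexp(logw)
  lam <- exp(logw)
  direction <- Reduce(`+`, Map(function(d, l) l * d, diffs, as.list(lam)))
  direction <- direction / sigma
  structure(list(direction = direction, log_weights = logw),
            class = "field_evaluation")
}

logsumexp <- function(v) {
  m <- max(v)
  m + log(sum(exp(v - m)))
}
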