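#' Peak signal-to-noise ratio
#'
#' `10 log10(data_range^2 / MSE)`; identical images give `Inf`.
#'
#' @param a,b Images of identical shape.
#' @param data_range Dynamic range L of the data, > 0 (same units as the
#'   images; for HU images typically the clean set's max - min).
#' @return PSNR in dB.
#' @export
psnr <- function(a, b, data_range) {
  if (!identical(dim(a), dim(b))) stop("shape mismatch")
  stopifnot(data_range > 0)
  mse <- mean((a - b)^2)
  if (mse == 0) return(Inf)
  10 * log10(data_range^2 / mse)
}

# Banded matrix performing a valid 1-D correlation with kernel `k` on
# signals of length n (output length n - length(k) + 1).
valid_filter_matrix <- function(n, k) {
  L <- length(k)
  m <- n - L + 1L
  if (m < 1L) stop(sprintf("image side %d smaller than the %d-pixel window", n, L))
  K <- matrix(0, m, n)
  for (i in seq_len(m)) K[i, i:(i + L - 1L)] <- k
  K
}

gaussian_window_1d <- function(sd = 1.5, truncate = 3.5) {
  r <- as.integer(truncate * sd + 0.5)
  w <- exp(-0.5 * ((-r):r / sd)^2)
  w / sum(w)
}

#' Structural similarity index
#'
#' Mean local SSIM with an 11 x 11 Gaussian window (SD 1.5) and the standard
#' stabilizers `C1 = (k1 L)^2`, `C2 = (k2 L)^2`.  Local means, variances and
#' covariance are Gaussian-weighted, and the SSIM map is averaged over the
#' region where the window fits entirely inside the image (equivalent to the
#' common reference implementation, which crops half a window from each
#' side).
#'
#' @param a,b Images of identical shape, each side at least the window size.
#' @param data_range Dynamic range L, > 0.
#' @param window_sd Gaussian window SD in pixels.
#' @param k1,k2 Stabilizer constants.
#' @return SSIM in [-1, 1]; exactly 1 for identical images.
#' @export
ssim <- function(a, b, data_range, window_sd = 1.5, k1 = 0.01, k2 = 0.03) {
  if (!identical(dim(a), dim(b))) stop("shape mismatch")
  stopifnot(data_range > 0)
  k <- gaussian_window_1d(window_sd)
  Kr <- valid_filter_matrix(nrow(a), k)
  Kc <- t(valid_filter_matrix(ncol(a), k))
  f <- function(m) Kr %*% m %*% Kc
  mu_a <- f(a); mu_b <- f(b)
  va <- f(a * a) - mu_a^2
  vb <- f(b * b) - mu_b^2
  cab <- f(a * b) - mu_a * mu_b
  C1 <- (k1 * data_range)^2
  C2 <- (k2 * data_range)^2
  S <- ((2 * mu_a * mu_b + C1) * (2 * cab + C2)) /
    ((mu_a^2 + mu_b^2 + C1) * (va + vb + C2))
  mean(S)
}

#' Noise level in a flat region of interest
#'
#' @param image HU image.
#' @param roi Integer vector `c(row0, row1, col0, col1)` (inclusive), inside
#'   the image.
#' @return Sample standard deviation of the ROI pixels, in HU.
#' @export
roi_noise_sd <- function(image, roi) {
  stopifnot(length(roi) == 4L)
  if (roi[1] < 1 || roi[2] > nrow(image) || roi[3] < 1 || roi[4] > ncol(image)
      || roi[2] < roi[1] || roi[4] < roi[3])
    stop("roi outside image or empty")
  stats::sd(image[roi[1]:roi[2], roi[3]:roi[4]])
}

#' Grid-search specification
#'
#' @param T_grid Integer vector of step counts.
#' @param w_grid Mixing weights in [0, 1].
#' @param criterion "psnr" or "ssim" (both maximized), or "lpips" (minimized;
#'   requires an external hook).
#' @return An object of class `grid_search_spec`.
#' @export
grid_search_spec <- function(T_grid = c(4L, 8L, 16L, 32L, 64L),
                             w_grid = seq(0.5, 1.0, by = 0.1),
                             criterion = c("psnr", "ssim", "lpips")) {
  criterion <- match.arg(criterion)
  stopifnot(length(T_grid) >= 1, length(w_grid) >= 1,
            all(w_grid >= 0), all(w_grid <= 1))
  structure(list(T_grid = as.integer(T_grid), w_grid = w_grid,
                 criterion = criterion,
                 maximize = criterion %in% c("psnr", "ssim")),
            class = "grid_search_spec")
}

#' Select sampler hyperparameters by grid search
#'
#' Evaluates [denoise_posterior()] with `tau = T - 1` for every `(T, w)` on
#' a paired evaluation set and returns the best configuration under the
#' criterion with a deterministic tie-break (smaller T, then smaller w),
#' together with the full score table.
#'
#' @param model A `pfct_denoiser`.
#' @param pairs List with parallel `clean` and `noisy` lists of HU images
#'   (see [make_paired_eval_set()]).
#' @param spec A [grid_search_spec()].
#' @param sigma_min,sigma_max,rho Schedule parameters shared by every T.
#' @param data_range Dynamic range for the metrics; default the clean set's
#'   max - min.
#' @param lpips_fn Optional hook `function(a, b, data_range)` implementing a
#'   perceptual metric; required when `criterion = "lpips"`.
#' @return A list with `best` (a [sampler_config()]) and `table` (a data
#'   frame with columns T, w, mean, sd of the criterion).
#' @export
grid_search <- function(model, pairs, spec = grid_search_spec(),
                        sigma_min = 0.002, sigma_max = 80, rho = 7,
                        data_range = NULL, lpips_fn = NULL) {
  stopifnot(inherits(spec, "grid_search_spec"), length(pairs$clean) >= 1)
  if (spec$criterion == "lpips" && is.null(lpips_fn))
    stop("criterion \"lpips\" needs an external `lpips_fn` hook; ",
         "fallback criteria: \"psnr\", \"ssim\"")
  if (is.null(data_range))
    data_range <- max(vapply(pairs$clean, max, numeric(1))) -
      min(vapply(pairs$clean, min, numeric(1)))
  metric <- switch(spec$criterion,
                   psnr = function(a, b) psnr(a, b, data_range),
                   ssim = function(a, b) ssim(a, b, data_range),
                   lpips = function(a, b) lpips_fn(a, b, data_range))
  rows <- list()
  for (T in spec$T_grid) {
    sched <- make_schedule(T, sigma_min, sigma_max, rho)
    for (w in spec$w_grid) {
      cfg <- sampler_config(sched, tau = T - 1L, w = w, geom = model$geom,
                            mode = "posterior")
      scores <- vapply(seq_along(pairs$clean), function(i) {
        out <- denoise_posterior(model, pairs$noisy[[i]], cfg)$output
        metric(out, pairs$clean[[i]])
      }, numeric(1))
      rows[[length(rows) + 1L]] <-
        data.frame(T = T, w = w, mean = mean(scores), sd = stats::sd(scores))
    }
  }
  tab <- do.call(rbind, rows)
  score <- if (spec$maximize) tab$mean else -tab$mean
  best_i <- order(-score, tab$T, tab$w)[1L]
  best <- sampler_config(make_schedule(tab$T[best_i], sigma_min, sigma_max, rho),
                         tau = tab$T[best_i] - 1L, w = tab$w[best_i],
                         geom = model$geom, mode = "posterior")
  list(best = best, table = tab)
}
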