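#' Describe an ellipse for a CT phantom
#'
#' Geometry lives in field-of-view coordinates: the image spans [-1, 1] in
#' both axes, pixel centers sit at half-integer grid positions, and semi-axes
#' are fractions of the half field of view.
#'
#' @param center Numeric length-2, ellipse center in [-1, 1] FOV coordinates.
#' @param semi_axes Numeric length-2, strictly positive semi-axes (FOV
#'   fractions).
#' @param rotation Rotation in degrees, counter-clockwise.
#' @param hu Attenuation value of the ellipse interior, in HU.
#' @return A list describing the ellipse.
#' @export
phantom_ellipse <- function(center, semi_axes, rotation = 0, hu = 0) {
  stopifnot(length(center) == 2L, length(semi_axes) == 2L,
            all(semi_axes > 0), all(abs(center) <= 1))
  list(center = as.numeric(center), semi_axes = as.numeric(semi_axes),
       rotation = as.numeric(rotation), hu = as.numeric(hu))
}

#' Specify a piecewise-constant ellipse phantom
#'
#' @param ellipses List of [phantom_ellipse()] objects, painted in order:
#'   later ellipses overwrite earlier ones.
#' @param background_hu Background attenuation (default air, -1000 HU).
#' @param image_size Pixels per side (n; the image is n x n), >= 8.
#' @param jitter Optional list with `center_sd` (FOV units) and `hu_sd` (HU)
#'   giving per-phantom random variation when [generate_phantom()] is called
#'   with a seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(ellipses = list(), background_hu = -1000,
                         image_size = 64L, jitter = NULL) {
  stopifnot(image_size >= 8)
  for (e in ellipses)
    stopifnot(all(e$semi_axes > 0), all(abs(e$center) <= 1))
  if (!is.null(jitter))
    stopifnot(jitter$center_sd >= 0, jitter$hu_sd >= 0)
  structure(list(ellipses = ellipses, background_hu = background_hu,
                 image_size = as.integer(image_size), jitter = jitter),
            class = "phantom_spec")
}

#' A body-like default phantom
#'
#' An abdomen-like section: an elliptical soft-tissue body (40 HU) on an air
#' background, containing organ-scale inserts of fat (-100 HU), blood-like
#' (60 HU) and calcified (300 HU) contrast, spanning the HU contrasts a
#' denoiser must preserve.  Mild default jitter makes repeated draws emulate
#' anatomical variation across slices.
#'
#' @param image_size Pixels per side.
#' @param jitter Jitter spec passed to [phantom_spec()]; default gives
#'   0.03-FOV center and 10-HU value variation.
#' @return A `phantom_spec`.
#' @export
default_phantom_spec <- function(image_size = 64L,
                                 jitter = list(center_sd = 0.03, hu_sd = 10)) {
  phantom_spec(
    ellipses = list(
      phantom_ellipse(c(0, 0), c(0.85, 0.65), 0, 40),
      phantom_ellipse(c(-0.35, 0.1), c(0.3, 0.22), 20, -100),
      phantom_ellipse(c(0.35, -0.05), c(0.25, 0.3), -15, 60),
      phantom_ellipse(c(0.05, -0.3), c(0.12, 0.1), 0, 0),
      phantom_ellipse(c(0, 0.35), c(0.07, 0.07), 0, 300)),
    background_hu = -1000, image_size = image_size, jitter = jitter)
}

#' Render a phantom to an HU image
#'
#' Pixels whose centers fall inside an ellipse take its HU value, later
#' ellipses overwriting earlier ones (painter's order); all other pixels take
#' the background value.  With a seed and a jitter spec, ellipse centers and
#' HU values receive Gaussian perturbations; a jittered center that leaves
#' the [-1, 1] field of view is clipped back with a warning.
#'
#' @param spec A [phantom_spec()].
#' @param seed Optional integer seed driving the jitter; the render itself is
#'   deterministic given `(spec, seed)`.
#' @return An `image_size` x `image_size` numeric matrix in HU.
#' @export
generate_phantom <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$image_size
  # pixel-center coordinates in [-1, 1]; u varies along columns, v along rows
  cc <- 2 * (seq_len(n) - 0.5) / n - 1
  u <- matrix(cc, n, n, byrow = TRUE)
  v <- matrix(cc, n, n)
  img <- matrix(spec$background_hu, n, n)
  ellipses <- spec$ellipses
  if (!is.null(spec$jitter) && !is.null(seed)) {
    ellipses <- with_seed(seed, lapply(ellipses, function(e) {
      e$center <- e$center + stats::rnorm(2, sd = spec$jitter$center_sd)
      e$hu <- e$hu + stats::rnorm(1, sd = spec$jitter$hu_sd)
      e
    }))
    clipped <- FALSE
    ellipses <- lapply(ellipses, function(e) {
      if (any(abs(e$center) > 1)) {
        e$center <- pmin(1, pmax(-1, e$center))
        clipped <<- TRUE
      }
      e
    })
    if (clipped) warning("jittered ellipse center left the field of view; clipped")
  }
  for (e in ellipses) {
    th <- e$rotation * pi / 180
    du <- u - e$center[1L]; dv <- v - e$center[2L]
    up <- cos(th) * du + sin(th) * dv
    vp <- -sin(th) * du + cos(th) * dv
    inside <- (up / e$semi_axes[1L])^2 + (vp / e$semi_axes[2L])^2 <= 1
    img[inside] <- e$hu
  }
  img
}

#' Configuration of the stochastic degradation operator
#'
#' The degradation is a stationary correlated Gaussian field: white noise
#' convolved (circularly) with an isotropic Gaussian kernel of standard
#' deviation `correlation_length` pixels, renormalized so a flat region has
#' sample SD `noise_sd`.  `correlation_length = 0` gives white noise.  This
#' is a deliberately generic stand-in for the mixture of quantum and
#' electronic noise in reconstructed CT slices.
#'
#' @param noise_sd Noise standard deviation in HU, >= 0.
#' @param correlation_length Gaussian kernel SD in pixels, >= 0.
#' @param seed Integer seed; the operator is deterministic given it.
#' @return An object of class `degradation_config`.
#' @export
degradation_config <- function(noise_sd = 50, correlation_length = 0,
                               seed = 1L) {
  stopifnot(noise_sd >= 0, correlation_length >= 0)
  structure(list(noise_sd = noise_sd,
                 correlation_length = correlation_length,
                 seed = as.integer(seed)),
            class = "degradation_config")
}

# Correlated unit-variance stationary Gaussian field via circular FFT
# convolution; exact variance normalization through the kernel's l2 norm.
correlated_noise_field <- function(nr, nc, correlation_length) {
  white <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (correlation_length == 0) return(white)
  k1r <- gauss_kernel_circ(nr, correlation_length)
  k1c <- gauss_kernel_circ(nc, correlation_length)
  ker <- outer(k1r, k1c)
  ker <- ker / sqrt(sum(ker^2))
  Re(stats::fft(stats::fft(white) * stats::fft(ker), inverse = TRUE)) / (nr * nc)
}

gauss_kernel_circ <- function(n, sd) {
  d <- pmin(0:(n - 1), n - (0:(n - 1)))
  k <- exp(-0.5 * (d / sd)^2)
  k / sum(k)
}

#' Apply the degradation operator
#'
#' @param image HU image matrix with finite entries.
#' @param config A [degradation_config()].
#' @return `image` plus a correlated zero-mean Gaussian field of SD
#'   `noise_sd`; deterministic given `config$seed`, and exactly equal to the
#'   input when `noise_sd = 0`.
#' @export
degrade <- function(image, config) {
  stopifnot(inherits(config, "degradation_config"), all(is.finite(image)))
  if (config$noise_sd == 0) return(image)
  field <- with_seed(config$seed,
                     correlated_noise_field(nrow(image), ncol(image),
                                            config$correlation_length))
  image + config$noise_sd * field
}

#' Randomly extract square patches from images
#'
#' Patches are drawn with uniformly random source image and top-left corner
#' (uniform over all valid corners).
#'
#' @param images List of HU image matrices.
#' @param patch_size Side of the square patches; must not exceed any image
#'   side.
#' @param count Number of patches (0 gives an empty set).
#' @param seed Integer seed.
#' @return An object of class `patch_set`: `patches` (list of matrices),
#'   `patch_size`, `source_ids`, `seed`.
#' @export
extract_patches <- function(images, patch_size, count, seed = 1L) {
  stopifnot(length(images) >= 1L, patch_size >= 1, count >= 0)
  for (i in seq_along(images)) {
    if (min(dim(images[[i]])) < patch_size)
      stop(sprintf("patch_size %d exceeds image %d (%d x %d)", patch_size, i,
                   nrow(images[[i]]), ncol(images[[i]])))
  }
  res <- with_seed(seed, {
    ids <- if (count > 0) sample.int(length(images), count, replace = TRUE) else integer(0)
    patches <- lapply(ids, function(i) {
      img <- images[[i]]
      r0 <- sample.int(nrow(img) - patch_size + 1L, 1L)
      c0 <- sample.int(ncol(img) - patch_size + 1L, 1L)
      img[r0:(r0 + patch_size - 1L), c0:(c0 + patch_size - 1L), drop = FALSE]
    })
    list(ids = ids, patches = patches)
  })
  structure(list(patches = res$patches, patch_size = as.integer(patch_size),
                 source_ids = res$ids, seed = as.integer(seed)),
            class = "patch_set")
}

#' Generate a paired clean/noisy evaluation set
#'
#' Training never sees pairs; this exists for evaluation only.  Each clean
#' image is a (jittered) render of the template spec, and its noisy partner
#' differs from it exactly by one draw of the degradation operator.
#'
#' @param n_images Number of pairs, >= 1.
#' @param spec_template A [phantom_spec()].
#' @param degradation A [degradation_config()]; its seed field is ignored in
#'   favor of per-image seeds derived from `seed`.
#' @param seed Integer seed.
#' @return A list with elements `clean` and `noisy`, parallel lists of HU
#'   matrices.
#' @export
make_paired_eval_set <- function(n_images, spec_template, degradation,
                                 seed = 1L) {
  stopifnot(n_images >= 1)
  clean <- lapply(seq_len(n_images), function(i)
    generate_phantom(spec_template, seed = derive_seed(seed, paste0("phantom", i))))
  noisy <- lapply(seq_len(n_images), function(i) {
    cfg <- degradation
    cfg$seed <- derive_seed(seed, paste0("degrade", i))
    degrade(clean[[i]], cfg)
  })
  list(clean = clean, noisy = noisy)
}
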