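#' Affine HU normalization
#'
#' Images are stored in Hounsfield units but the network operates on a
#' roughly unit scale; the affine map `(hu - offset) / scale` is stored with
#' every model so training and inference use the same convention.  The
#' default maps [-1000, 0] HU (air to water) onto [-1, 1].
#'
#' @param offset HU value mapped to 0.
#' @param scale HU half-range mapped to 1.
#' @return An object of class `hu_normalization`.
#' @export
hu_normalization <- function(offset = -500, scale = 500) {
  stopifnot(scale > 0)
  structure(list(offset = offset, scale = scale), class = "hu_normalization")
}

#' @rdname hu_normalization
#' @param x Image in HU (`hu_to_unit`) or normalized units (`unit_to_hu`).
#' @param norm A [hu_normalization()].
#' @export
hu_to_unit <- function(x, norm) (x - norm$offset) / norm$scale

#' @rdname hu_normalization
#' @export
unit_to_hu <- function(x, norm) x * norm$scale + norm$offset

#' EDM preconditioning coefficients
#'
#' The raw backbone F_theta is wrapped as
#' `D(x; sigma) = c_skip(sigma) x + c_out(sigma) F(c_in(sigma) x, c_noise(sigma))`
#' with
#' `c_skip = sigma_d^2 / (sigma^2 + sigma_d^2)`,
#' `c_out  = sigma sigma_d / sqrt(sigma^2 + sigma_d^2)`,
#' `c_in   = 1 / sqrt(sigma^2 + sigma_d^2)`,
#' `c_noise = log(sigma) / 4`.
#' As sigma -> 0, c_skip -> 1 and c_out -> 0, so the identity dominates; the
#' loss weighting `lambda(sigma) = (sigma^2 + sigma_d^2) / (sigma sigma_d)^2`
#' makes the effective regression target unit-scale at every sigma.
#'
#' @param sigma Noise scale(s), > 0.
#' @param sigma_data Assumed data standard deviation in normalized units.
#' @return A list of vectors `c_skip`, `c_out`, `c_in`, `c_noise`.
#' @export
precond_coefficients <- function(sigma, sigma_data = 0.5) {
  stopifnot(all(sigma > 0), sigma_data > 0)
  s2 <- sigma^2 + sigma_data^2
  list(c_skip = sigma_data^2 / s2,
       c_out = sigma * sigma_data / sqrt(s2),
       c_in = 1 / sqrt(s2),
       c_noise = log(sigma) / 4)
}

#' Loss weighting lambda(sigma)
#' @param sigma Noise scale(s), > 0.
#' @param sigma_data Data standard deviation in normalized units.
#' @return `(sigma^2 + sigma_data^2) / (sigma * sigma_data)^2`.
#' @export
loss_weight <- function(sigma, sigma_data = 0.5) {
  (sigma^2 + sigma_data^2) / (sigma * sigma_data)^2
}

#' Backbone configuration
#'
#' Describes the trainable network.  At paper scale this would be a U-Net
#' (base 128 channels, multipliers `c(1,1,2,2,2,2,2)`, self-attention at
#' resolutions 16/8/4); at desk scale the implementation is a fully-connected
#' network whose hidden widths are `base_channels * channel_multipliers`,
#' conditioned on the noise level through sinusoidal features of
#' `c_noise(sigma)`.  `attention_resolutions` is retained so paper-scale
#' configurations round-trip through config files, but must be empty for the
#' built-in backbone.
#'
#' @param base_channels Base hidden width.
#' @param channel_multipliers Integer vector, one entry per hidden layer.
#' @param attention_resolutions Must be `integer(0)` for the built-in MLP.
#' @param dropout_prob Dropout probability in [0, 1), applied to hidden
#'   activations during training only.
#' @param n_freqs Number of sinusoidal noise-embedding frequencies
#'   (embedding dimension is `2 * n_freqs`).
#' @return An object of class `backbone_config`.
#' @export
backbone_config <- function(base_channels = 64,
                            channel_multipliers = c(2, 2),
                            attention_resolutions = integer(0),
                            dropout_prob = 0,
                            n_freqs = 6L) {
  stopifnot(base_channels >= 1, length(channel_multipliers) >= 1,
            dropout_prob >= 0, dropout_prob < 1, n_freqs >= 1)
  if (length(attention_resolutions) > 0)
    stop("the built-in fully-connected backbone has no attention layers; ",
         "attention_resolutions must be empty")
  structure(list(base_channels = base_channels,
                 channel_multipliers = channel_multipliers,
                 attention_resolutions = attention_resolutions,
                 dropout_prob = dropout_prob,
                 n_freqs = as.integer(n_freqs)),
            class = "backbone_config")
}

# Sinusoidal embedding of c_noise values: rows = samples, cols = 2*n_freqs.
noise_embedding <- function(c_noise, n_freqs) {
  f <- 2^(seq_len(n_freqs) - 1)
  ang <- outer(c_noise, f)
  cbind(sin(ang), cos(ang))
}

silu <- function(z) z * stats::plogis(z)
silu_grad <- function(z) {
  s <- stats::plogis(z)
  s * (1 + z * (1 - s))
}

# Initialize MLP weights.  Hidden layers use He-style scaling; the output
# layer starts at zero so D(x; sigma) = c_skip * x at initialization.
init_mlp_weights <- function(n_in, hidden, n_out) {
  sizes <- c(n_in, hidden, n_out)
  L <- length(sizes) - 1L
  W <- vector("list", L)
  b <- vector("list", L)
  for (l in seq_len(L)) {
    fan_in <- sizes[l]
    sd <- if (l == L) 0 else sqrt(2 / fan_in)
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1], sd = sd),
                     nrow = sizes[l])
    b[[l]] <- numeric(sizes[l + 1])
  }
  list(W = W, b = b)
}

# Forward pass.  X: batch x N (already c_in-scaled), emb: batch x (2 n_freqs).
# Returns the raw output F (batch x N) and, if cache = TRUE, pre-activations
# and activations for backprop.  Dropout masks (inverted dropout) are applied
# only when `dropout_prob > 0` and training = TRUE.
mlp_forward <- function(weights, X, emb, dropout_prob = 0, training = FALSE,
                        cache = FALSE) {
  A <- cbind(X, emb)
  L <- length(weights$W)
  Zs <- vector("list", L); As <- vector("list", L + 1L); Ms <- vector("list", L)
  As[[1L]] <- A
  for (l in seq_len(L)) {
    Z <- A %*% weights$W[[l]]
    Z <- sweep(Z, 2L, weights$b[[l]], `+`)
    if (l < L) {
      A <- silu(Z)
      if (training && dropout_prob > 0) {
        m <- matrix(stats::rbinom(length(A), 1L, 1 - dropout_prob) /
                      (1 - dropout_prob), nrow = nrow(A))
        A <- A * m
        Ms[[l]] <- m
      }
    } else A <- Z
    Zs[[l]] <- Z
    As[[l + 1L]] <- A
  }
  if (cache) list(out = A, Zs = Zs, As = As, Ms = Ms) else A
}

# Backward pass: dOut is dLoss/dF (batch x N); returns gradients shaped like
# weights.  `fw` is the cache from mlp_forward(cache = TRUE).
mlp_backward <- function(weights, fw, dOut) {
  L <- length(weights$W)
  gW <- vector("list", L); gb <- vector("list", L)
  delta <- dOut
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(fw$As[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- delta %*% t(weights$W[[l]])
      if (!is.null(fw$Ms[[l - 1L]])) delta <- delta * fw$Ms[[l - 1L]]
      delta <- delta * silu_grad(fw$Zs[[l - 1L]])
    }
  }
  list(W = gW, b = gb)
}

#' Construct a trainable fully-connected denoiser
#'
#' @param patch_shape Integer vector `c(n, n)` the backbone is trained on.
#' @param geom A [geom_config()].
#' @param backbone A [backbone_config()].
#' @param normalization A [hu_normalization()].
#' @param sigma_data Assumed data SD in normalized units.
#' @return A `pfct_denoiser` of subclass `mlp_denoiser`.  Weights are
#'   initialized from the current RNG stream.
#' @export
mlp_denoiser <- function(patch_shape, geom,
                         backbone = backbone_config(),
                         normalization = hu_normalization(),
                         sigma_data = 0.5) {
  stopifnot(length(patch_shape) == 2L, inherits(geom, "pfct_geom"),
            inherits(backbone, "backbone_config"))
  N <- prod(patch_shape)
  if (N != geom$N)
    stop("patch_shape is inconsistent with geom$N")
  hidden <- backbone$base_channels * backbone$channel_multipliers
  weights <- init_mlp_weights(N + 2L * backbone$n_freqs, hidden, N)
  structure(list(kind = "mlp", patch_shape = as.integer(patch_shape),
                 geom = geom, backbone = backbone,
                 normalization = normalization, sigma_data = sigma_data,
                 weights = weights, ema_weights = weights,
                 nfe = new.env(parent = emptyenv())),
            class = c("mlp_denoiser", "pfct_denoiser"))
}

#' Construct the analytic-field oracle denoiser
#'
#' Wraps [oracle_field()] for a discrete dataset as a denoiser:
#' `D(x; sigma) = x - sigma * f(x, sigma)`, the exact posterior-mean denoiser
#' of the empirical distribution.  It is backbone-free and used as the
#' independent reference that trained models are compared against, and as a
#' drop-in model for sampler tests.
#'
#' @param dataset Nonempty list of clean images in HU, all the same shape.
#' @param geom A [geom_config()].
#' @param normalization A [hu_normalization()].
#' @return A `pfct_denoiser` of subclass `oracle_denoiser`.
#' @export
oracle_denoiser <- function(dataset, geom,
                            normalization = hu_normalization()) {
  stopifnot(length(dataset) >= 1L, inherits(geom, "pfct_geom"))
  shp <- dim(dataset[[1L]])
  dataset_n <- lapply(dataset, hu_to_unit, norm = normalization)
  structure(list(kind = "oracle", patch_shape = as.integer(shp),
                 geom = geom, normalization = normalization,
                 sigma_data = 0.5, dataset = dataset_n,
                 nfe = new.env(parent = emptyenv())),
            class = c("oracle_denoiser", "pfct_denoiser"))
}

nfe_reset <- function(model) assign("count", 0L, envir = model$nfe)
nfe_bump <- function(model) {
  cur <- if (exists("count", envir = model$nfe)) get("count", envir = model$nfe) else 0L
  assign("count", cur + 1L, envir = model$nfe)
}
nfe_count <- function(model) {
  if (exists("count", envir = model$nfe)) get("count", envir = model$nfe) else 0L
}

#' Evaluate the denoiser D(x; sigma)
#'
#' Operates in normalized units.  `x` must either match the model's trained
#' patch shape or, for the fully-connected backbone, be larger, in which case
#' the model is applied to overlapping tiles (stride = half the patch side)
#' and overlaps are averaged; a tiled evaluation still counts as a single
#' function evaluation (NFE) of the denoiser.
#'
#' @param model A `pfct_denoiser`.
#' @param x Image in normalized units.
#' @param sigma Noise scale, > 0 (normalized units).
#' @param use_ema Use the EMA weights (default) rather than the current ones.
#' @return The denoised estimate of the clean image (normalized units),
#'   approximating `E[y | x at scale sigma]`.
#' @export
denoise_estimate <- function(model, x, sigma, use_ema = TRUE) {
  if (sigma <= 0) stop("`sigma` must be > 0")
  UseMethod("denoise_estimate")
}

#' @export
denoise_estimate.oracle_denoiser <- function(model, x, sigma, use_ema = TRUE) {
  nfe_bump(model)
  geom <- model$geom
  r <- if (is_diffusion_limit(geom)) sigma else sigma_to_r(sigma, geom)
  fe <- oracle_field(x, r, model$dataset, geom)
  x - sigma * fe$direction
}

#' @export
denoise_estimate.mlp_denoiser <- function(model, x, sigma, use_ema = TRUE) {
  nfe_bump(model)
  shp <- dim(x)
  ps <- model$patch_shape
  if (is.null(shp)) shp <- c(length(x), 1L)
  if (identical(as.integer(shp), ps)) {
    return(mlp_apply(model, x, sigma, use_ema))
  }
  if (any(shp < ps))
    stop("input smaller than the trained patch shape")
  tiled_apply(model, x, sigma, use_ema)
}

# Single-patch application of the preconditioned MLP.
mlp_apply <- function(model, x, sigma, use_ema = TRUE, weights = NULL) {
  if (is.null(weights))
    weights <- if (use_ema) model$ema_weights else model$weights
  cf <- precond_coefficients(sigma, model$sigma_data)
  X <- matrix(as.vector(x) * cf$c_in, nrow = 1L)
  emb <- noise_embedding(cf$c_noise, model$backbone$n_freqs)
  Fout <- mlp_forward(weights, X, emb)
  out <- cf$c_skip * as.vector(x) + cf$c_out * as.vector(Fout)
  dim(out) <- dim(x)
  out
}

# Overlapping-tile application for inputs larger than the trained patch.
tiled_apply <- function(model, x, sigma, use_ema = TRUE) {
  ps <- model$patch_shape
  stride <- pmax(1L, ps %/% 2L)
  shp <- dim(x)
  starts1 <- tile_starts(shp[1L], ps[1L], stride[1L])
  starts2 <- tile_starts(shp[2L], ps[2L], stride[2L])
  acc <- matrix(0, shp[1L], shp[2L])
  cnt <- matrix(0, shp[1L], shp[2L])
  for (i in starts1) for (j in starts2) {
    ri <- i:(i + ps[1L] - 1L); cj <- j:(j + ps[2L] - 1L)
    acc[ri, cj] <- acc[ri, cj] + mlp_apply(model, x[ri, cj, drop = FALSE],
                                           sigma, use_ema)
    cnt[ri, cj] <- cnt[ri, cj] + 1
  }
  acc / cnt
}

tile_starts <- function(total, size, stride) {
  s <- seq.int(1L, max(1L, total - size + 1L), by = stride)
  if (s[length(s)] + size - 1L < total) s <- c(s, total - size + 1L)
  s
}

#' Field (ODE drift) implied by a denoiser
#'
#' The sigma-time ODE drift is `(x - D(x; sigma)) / sigma`, the exact
#' algebraic inverse of the denoiser contract; for finite D it equals
#' `f*(x~) / sqrt(D)` expressed in `t = sigma` time via `r = sigma sqrt(D)`.
#'
#' @param model A `pfct_denoiser`.
#' @param state An [augmented_state()] in normalized units (for `D = Inf`
#'   the `r` slot holds sigma).
#' @param geom A [geom_config()]; defaults to the model's.
#' @return Image-shaped drift array.
#' @export
field_from_denoiser <- function(model, state, geom = model$geom) {
  stopifnot(inherits(state, "augmented_state"))
  if (state$r <= 0) stop("`r` must be > 0")
  sigma <- if (is_diffusion_limit(geom)) state$r else r_to_sigma(state$r, geom)
  (state$x - denoise_estimate(model, state$x, sigma)) / sigma
}

#' Save / load a denoiser checkpoint
#'
#' Checkpoints are plain JSON holding the backbone configuration, geometry,
#' normalization constants, and both current and EMA weights (version tag
#' "pfct-checkpoint-1").  The oracle denoiser stores its dataset.
#'
#' @param model A `pfct_denoiser`.
#' @param path File path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the reconstructed model.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "pfct_denoiser"))
  obj <- list(format = "pfct-checkpoint-1", kind = model$kind,
              patch_shape = model$patch_shape,
              geom = list(N = model$geom$N,
                          D = if (is.infinite(model$geom$D)) "Inf" else model$geom$D),
              normalization = unclass(model$normalization),
              sigma_data = model$sigma_data)
  if (model$kind == "mlp") {
    obj$backbone <- unclass(model$backbone)
    obj$weights <- serialize_weights(model$weights)
    obj$ema_weights <- serialize_weights(model$ema_weights)
  } else {
    obj$dataset <- lapply(model$dataset, function(m)
      list(dim = dim(m), data = as.vector(m)))
  }
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

serialize_weights <- function(w) {
  list(W = lapply(w$W, function(m) list(dim = dim(m), data = as.vector(m))),
       b = w$b)
}

deserialize_weights <- function(s) {
  list(W = lapply(s$W, function(m) {
    v <- as.numeric(unlist(m$data)); dim(v) <- as.integer(unlist(m$dim)); v
  }),
  b = lapply(s$b, as.numeric))
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "pfct-checkpoint-1"))
    stop("unrecognized checkpoint format")
  D <- if (identical(obj$geom$D, "Inf")) Inf else as.numeric(obj$geom$D)
  geom <- geom_config(as.numeric(obj$geom$N), D)
  norm <- hu_normalization(obj$normalization$offset, obj$normalization$scale)
  if (identical(obj$kind, "mlp")) {
    bb <- backbone_config(obj$backbone$base_channels,
                          unlist(obj$backbone$channel_multipliers),
                          integer(0),
                          obj$backbone$dropout_prob,
                          obj$backbone$n_freqs)
    model <- mlp_denoiser(as.integer(unlist(obj$patch_shape)), geom, bb, norm,
                          obj$sigma_data)
    model$weights <- deserialize_weights(obj$weights)
    model$ema_weights <- deserialize_weights(obj$ema_weights)
    model
  } else {
    dataset <- lapply(obj$dataset, function(m) {
      v <- as.numeric(unlist(m$data)); dim(v) <- as.integer(unlist(m$dim)); v
    })
    dataset_hu <- lapply(dataset, unit_to_hu, norm = norm)
    oracle_denoiser(dataset_hu, geom, norm)
  }
}
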