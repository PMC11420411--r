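#' Training configuration
#'
#' Defaults are desk scale.  The paper-scale recipe (batch 32, learning rate
#' 2e-4, 1e5 iterations, 256 x 256 patches, 15% augmentation, 10% dropout)
#' is expressible with the same fields and round-trips through config files.
#'
#' @param batch_size Patches per optimization step, >= 1.
#' @param learning_rate Adam step size, > 0.
#' @param n_iterations Number of optimization steps.
#' @param ema_halflife EMA half-life in images-seen units.
#' @param augment_prob Probability of applying a random flip / 90-degree
#'   rotation to a training patch, in [0, 1].
#' @param dropout_prob Dropout probability on hidden activations during
#'   training, in [0, 1).
#' @param patch_size Side of the square training patches.
#' @param scale_dist A [noise_scale_dist()].
#' @param geom A [geom_config()].
#' @param seed Integer seed; training is a pure function of (dataset, cfg).
#' @return An object of class `training_config`.
#' @export
training_config <- function(batch_size = 32L, learning_rate = 2e-4,
                            n_iterations = 2000L, ema_halflife = 5e3,
                            augment_prob = 0.15, dropout_prob = 0,
                            patch_size = 8L,
                            scale_dist = noise_scale_dist(),
                            geom = geom_config(patch_size^2, 128),
                            seed = 1L) {
  stopifnot(batch_size >= 1, learning_rate > 0, n_iterations >= 1,
            augment_prob >= 0, augment_prob <= 1,
            dropout_prob >= 0, dropout_prob < 1,
            inherits(scale_dist, "noise_scale_dist"),
            inherits(geom, "pfct_geom"))
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 n_iterations = as.integer(n_iterations),
                 ema_halflife = ema_halflife,
                 augment_prob = augment_prob, dropout_prob = dropout_prob,
                 patch_size = as.integer(patch_size),
                 scale_dist = scale_dist, geom = geom,
                 seed = as.integer(seed)),
            class = "training_config")
}

# One of the 8 dihedral transforms of a square matrix.
dihedral_transform <- function(m, k_rot, flip) {
  if (flip) m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
  for (i in seq_len(k_rot %% 4L)) m <- t(m[rev(seq_len(nrow(m))), , drop = FALSE])
  m
}

# Vectorized perturbation of a batch: Y is B x N (normalized units),
# sigma a length-B vector.  Returns B x N perturbed batch.
perturb_batch <- function(Y, sigma, geom) {
  B <- nrow(Y); N <- ncol(Y)
  E <- matrix(stats::rnorm(B * N), B, N)
  if (is_diffusion_limit(geom)) return(Y + sigma * E)
  u <- stats::rbeta(B, N / 2, geom$D / 2)
  Rrad <- sigma * sqrt(geom$D) * sqrt(u / (1 - u))
  V <- E / sqrt(rowSums(E^2))
  Y + Rrad * V
}

# Loss (and optionally gradients) of the preconditioned perturbation
# objective on a prepared batch.  Y: B x N normalized patches; sigma: per
# sample.  The per-sample weight lambda(sigma) * c_out(sigma)^2 = 1, so the
# effective regression target of the raw backbone is unit-scale at every
# noise level.
batch_objective <- function(model, Y, sigma, weights, dropout_prob = 0,
                            want_grads = FALSE, X = NULL) {
  geom <- model$geom
  if (is.null(X)) X <- perturb_batch(Y, sigma, geom)
  cf <- precond_coefficients(sigma, model$sigma_data)
  Xin <- X * cf$c_in
  emb <- noise_embedding(cf$c_noise, model$backbone$n_freqs)
  fw <- mlp_forward(weights, Xin, emb, dropout_prob = dropout_prob,
                    training = want_grads, cache = want_grads)
  Fout <- if (want_grads) fw$out else fw
  Dhat <- X * cf$c_skip + Fout * cf$c_out
  resid <- Dhat - Y
  lam <- loss_weight(sigma, model$sigma_data)
  B <- nrow(Y); N <- ncol(Y)
  loss <- mean(lam * rowMeans(resid^2))
  if (!want_grads) return(list(loss = loss))
  dF <- resid * (2 * lam * cf$c_out / (B * N))
  grads_core <- mlp_backward(weights, fw, dF)
  # strip the embedding columns' contribution is unnecessary: the first-layer
  # weight matrix covers [pixels, embedding] jointly
  list(loss = loss, grads = grads_core)
}

#' Perturbation-objective loss on a batch of clean patches
#'
#' Draws one noise scale per patch from the training distribution, perturbs
#' each patch with the PFGM++ kernel (Gaussian for `D = Inf`), and returns
#' the weighted denoising loss
#' `mean_i lambda(sigma_i) * mean_px (D(x_i; sigma_i) - y_i)^2`, the
#' preconditioned equivalent of the field-space objective.
#'
#' @param model An `mlp_denoiser`.
#' @param patches A [extract_patches()] `patch_set`, or a list of matrices,
#'   in HU; shapes must match the model's patch shape.
#' @param cfg A [training_config()].
#' @param use_ema Evaluate with the EMA weights (default FALSE: current).
#' @param sigma Optional per-patch noise scales; drawn from the training
#'   distribution when NULL.
#' @param perturbed Optional list of pre-perturbed images in HU (parallel to
#'   `patches`; requires `sigma`).  With both given, the loss is a
#'   deterministic, batch-permutation-invariant function of its inputs.
#' @return Scalar loss (uses the current RNG stream for any randomness not
#'   supplied).
#' @export
loss_on_batch <- function(model, patches, cfg, use_ema = FALSE, sigma = NULL,
                          perturbed = NULL) {
  stopifnot(inherits(model, "mlp_denoiser"), inherits(cfg, "training_config"))
  plist <- if (inherits(patches, "patch_set")) patches$patches else patches
  for (p in plist)
    if (!identical(as.integer(dim(p)), model$patch_shape))
      stop("patch shape does not match the model's trained shape")
  Y <- t(vapply(plist, function(p) as.vector(hu_to_unit(p, model$normalization)),
                numeric(prod(model$patch_shape))))
  if (is.null(sigma))
    sigma <- exp(stats::rnorm(nrow(Y), cfg$scale_dist$P_mean, cfg$scale_dist$P_std))
  stopifnot(length(sigma) == nrow(Y))
  X <- NULL
  if (!is.null(perturbed)) {
    stopifnot(length(perturbed) == nrow(Y))
    X <- t(vapply(perturbed,
                  function(p) as.vector(hu_to_unit(p, model$normalization)),
                  numeric(prod(model$patch_shape))))
  }
  w <- if (use_ema) model$ema_weights else model$weights
  batch_objective(model, Y, sigma, w, X = X)$loss
}

#' Exponential-moving-average update of model weights
#'
#' @param ema_weights,current_weights Weight lists of identical shapes.
#' @param halflife Half-life in images-seen units; `halflife = 0` copies the
#'   current weights.
#' @param images_seen Images consumed since the previous update (usually the
#'   batch size), giving per-update decay `0.5^(images_seen / halflife)`.
#' @return Updated EMA weight list.
#' @export
ema_update <- function(ema_weights, current_weights, halflife, images_seen) {
  decay <- if (halflife <= 0) 0 else 0.5^(images_seen / halflife)
  comb <- function(e, c) {
    if (!identical(dim(e), dim(c)) || length(e) != length(c))
      stop("EMA/current weight shape mismatch")
    decay * e + (1 - decay) * c
  }
  list(W = Map(comb, ema_weights$W, current_weights$W),
       b = Map(comb, ema_weights$b, current_weights$b))
}

adam_init <- function(weights) {
  zeros <- function(x) x * 0
  list(m = list(W = lapply(weights$W, zeros), b = lapply(weights$b, zeros)),
       v = list(W = lapply(weights$W, zeros), b = lapply(weights$b, zeros)),
       t = 0L)
}

adam_step <- function(weights, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  upd <- function(w, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^state$t)
    vh <- v / (1 - beta2^state$t)
    list(w = w - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  for (l in seq_along(weights$W)) {
    u <- upd(weights$W[[l]], grads$W[[l]], state$m$W[[l]], state$v$W[[l]])
    weights$W[[l]] <- u$w; state$m$W[[l]] <- u$m; state$v$W[[l]] <- u$v
    u <- upd(weights$b[[l]], grads$b[[l]], state$m$b[[l]], state$v$b[[l]])
    weights$b[[l]] <- u$w; state$m$b[[l]] <- u$m; state$v$b[[l]] <- u$v
  }
  list(weights = weights, state = state)
}

#' Train an unconditional denoiser on clean images (unsupervised)
#'
#' Runs `n_iterations` Adam steps on randomly extracted clean patches with
#' flip / 90-degree-rotation augmentation, maintaining an EMA of the weights
#' that becomes the inference model.  The training pathway consumes clean
#' images only: no noisy counterpart or pair ever enters, which is what makes
#' the method unsupervised.
#'
#' @param dataset Nonempty list of clean HU images.
#' @param cfg A [training_config()].
#' @param backbone A [backbone_config()] (its dropout field is superseded by
#'   `cfg$dropout_prob` during training).
#' @param normalization A [hu_normalization()].
#' @param sigma_data Assumed data SD in normalized units.
#' @param log_file Optional path; per-iteration records are appended as
#'   line-delimited JSON.
#' @return A trained `mlp_denoiser` (EMA weights used for inference); the
#'   loss curve is attached as `model$history`.
#' @export
train_denoiser <- function(dataset, cfg, backbone = backbone_config(),
                           normalization = hu_normalization(),
                           sigma_data = 0.5, log_file = NULL) {
  stopifnot(length(dataset) >= 1L, inherits(cfg, "training_config"))
  for (i in seq_along(dataset))
    if (min(dim(dataset[[i]])) < cfg$patch_size)
      stop(sprintf("patch_size %d exceeds image %d", cfg$patch_size, i))
  ps <- cfg$patch_size
  N <- ps * ps
  if (cfg$geom$N != N) stop("cfg$geom$N must equal patch_size^2")
  with_seed(cfg$seed, {
    model <- mlp_denoiser(c(ps, ps), cfg$geom, backbone, normalization,
                          sigma_data)
    state <- adam_init(model$weights)
    history <- numeric(cfg$n_iterations)
    norm_imgs <- lapply(dataset, hu_to_unit, norm = normalization)
    decay <- if (cfg$ema_halflife <= 0) 0 else
      0.5^(cfg$batch_size / cfg$ema_halflife)
    for (it in seq_len(cfg$n_iterations)) {
      Y <- matrix(0, cfg$batch_size, N)
      for (b in seq_len(cfg$batch_size)) {
        img <- norm_imgs[[sample.int(length(norm_imgs), 1L)]]
        r0 <- sample.int(nrow(img) - ps + 1L, 1L)
        c0 <- sample.int(ncol(img) - ps + 1L, 1L)
        p <- img[r0:(r0 + ps - 1L), c0:(c0 + ps - 1L), drop = FALSE]
        if (stats::runif(1) < cfg$augment_prob)
          p <- dihedral_transform(p, sample.int(4L, 1L) - 1L,
                                  stats::runif(1) < 0.5)
        Y[b, ] <- as.vector(p)
      }
      sigma <- exp(stats::rnorm(cfg$batch_size, cfg$scale_dist$P_mean,
                                cfg$scale_dist$P_std))
      obj <- batch_objective(model, Y, sigma, model$weights,
                             dropout_prob = cfg$dropout_prob,
                             want_grads = TRUE)
      if (!is.finite(obj$loss))
        stop(sprintf("training diverged at iteration %d (loss = %g)",
                     it, obj$loss))
      st <- adam_step(model$weights, obj$grads, state, cfg$learning_rate)
      model$weights <- st$weights
      state <- st$state
      model$ema_weights <- ema_update(model$ema_weights, model$weights,
                                      cfg$ema_halflife, cfg$batch_size)
      history[it] <- obj$loss
      if (!is.null(log_file))
        cat(jsonlite::toJSON(list(iter = it, loss = obj$loss,
                                  lr = cfg$learning_rate, ema_decay = decay),
                             auto_unbox = TRUE, digits = NA),
            "\n", sep = "", file = log_file, append = TRUE)
    }
    model$history <- history
    model
  })
}
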