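#' Plain-text image I/O
#'
#' Float HU matrices are the source of truth and are stored as tab-separated
#' text (no header; rows = image rows), a lossless, portable container.
#' [write_image_pgm()] exports an 8-bit display rendering with a HU window
#' (default [-160, 240] HU, the soft-tissue window used throughout) as ASCII
#' PGM, for visual inspection only.
#'
#' @param image Numeric HU matrix.
#' @param path File path.
#' @return `write_image_hu` / `write_image_pgm` return `path` invisibly;
#'   `read_image_hu` returns the matrix.
#' @export
write_image_hu <- function(image, path) {
  utils::write.table(format(image, digits = 17, trim = TRUE, scientific = TRUE),
                     path, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_image_hu
#' @export
read_image_hu <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE,
                                   colClasses = "numeric"))
  dimnames(m) <- NULL
  m
}

#' @rdname write_image_hu
#' @param window HU display window `c(low, high)`.
#' @export
write_image_pgm <- function(image, path, window = c(-160, 240)) {
  stopifnot(window[2] > window[1])
  g <- round(255 * pmin(1, pmax(0, (image - window[1]) / diff(window))))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(g), nrow(g)), "255"), con)
  utils::write.table(g, con, sep = " ", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write a run configuration
#'
#' Configurations are hierarchical JSON; `D = Inf` is stored as the string
#' "Inf".  [read_run_config()] applies dotted-path overrides of the form
#' `"sampler.w=0.7"` (values parsed as JSON scalars when possible).
#'
#' @param path JSON file path.
#' @param overrides Character vector of `key.path=value` overrides.
#' @return A nested list.
#' @export
read_run_config <- function(path, overrides = character(0)) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (ov in overrides) {
    kv <- strsplit(ov, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) stop("override must look like key.path=value: ", ov)
    keys <- strsplit(kv[1L], ".", fixed = TRUE)[[1L]]
    val <- tryCatch(jsonlite::fromJSON(kv[2L]), error = function(e) kv[2L])
    cfg <- assign_path(cfg, keys, val)
  }
  cfg
}

assign_path <- function(lst, keys, val) {
  if (length(keys) == 1L) {
    lst[[keys]] <- val
    return(lst)
  }
  node <- lst[[keys[1L]]] %||% list()
  lst[[keys[1L]]] <- assign_path(node, keys[-1L], val)
  lst
}

#' @rdname read_run_config
#' @param cfg Configuration list.
#' @export
write_run_config <- function(cfg, path) {
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

cfg_D <- function(x) if (identical(x, "Inf") || is.infinite(x)) Inf else as.numeric(x)

write_manifest <- function(dir, record) {
  record$package_version <- as.character(utils::packageVersion("pfct"))
  jsonlite::write_json(record, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(record)
}

file_checksums <- function(paths) {
  as.list(tools::md5sum(paths))
}

prepare_out_dir <- function(out_dir, force) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !force)
    stop("output directory exists and is not empty (use force = TRUE): ",
         out_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out_dir
}

as_config <- function(config) {
  if (is.character(config)) read_run_config(config) else config
}

#' Generate a dataset on disk
#'
#' Writes `n_train` clean phantom slices (the training set) and, when
#' `n_eval > 0`, a paired clean/noisy evaluation set, plus a manifest
#' recording every seed and checksum so the dataset can be regenerated
#' exactly.
#'
#' @param config Path to a JSON config or an equivalent list with fields
#'   `out_dir`, `seed`, and a `data` block (`n_train`, `n_eval`,
#'   `image_size`, `noise_sd`, `correlation_length`).
#' @param force Overwrite a non-empty output directory.
#' @return The manifest, invisibly.
#' @export
cli_make_data <- function(config, force = FALSE) {
  cfg <- as_config(config)
  out <- prepare_out_dir(cfg$out_dir, force)
  seed <- as.integer(cfg$seed %||% 1L)
  d <- cfg$data %||% list()
  n_train <- d$n_train %||% 8L
  n_eval <- d$n_eval %||% 4L
  size <- d$image_size %||% 64L
  spec <- default_phantom_spec(size)
  dir.create(file.path(out, "train"), showWarnings = FALSE)
  train_paths <- character(n_train)
  train_seeds <- integer(n_train)
  for (i in seq_len(n_train)) {
    train_seeds[i] <- derive_seed(seed, paste0("train", i))
    img <- generate_phantom(spec, seed = train_seeds[i])
    train_paths[i] <- file.path(out, "train", sprintf("clean_%03d.tsv", i))
    write_image_hu(img, train_paths[i])
  }
  eval_paths <- character(0)
  if (n_eval > 0) {
    dir.create(file.path(out, "eval"), showWarnings = FALSE)
    deg <- degradation_config(d$noise_sd %||% 50,
                              d$correlation_length %||% 0)
    pairs <- make_paired_eval_set(n_eval, spec, deg,
                                  seed = derive_seed(seed, "eval"))
    for (i in seq_len(n_eval)) {
      pc <- file.path(out, "eval", sprintf("clean_%03d.tsv", i))
      pn <- file.path(out, "eval", sprintf("noisy_%03d.tsv", i))
      write_image_hu(pairs$clean[[i]], pc)
      write_image_hu(pairs$noisy[[i]], pn)
      eval_paths <- c(eval_paths, pc, pn)
    }
  }
  invisible(write_manifest(out, list(
    subcommand = "make-data", seed = seed, train_seeds = train_seeds,
    eval_seed = if (n_eval > 0) derive_seed(seed, "eval") else NULL,
    config = cfg, checksums = file_checksums(c(train_paths, eval_paths)))))
}

#' Train a denoiser from a config
#'
#' Reads the clean training images (only; the training pathway has no access
#' to noisy data), trains the unconditional denoiser, and writes a JSON
#' checkpoint, a line-delimited loss log, and a manifest.
#'
#' @param config Path or list: `data_dir` (containing `train/clean_*.tsv`),
#'   `out_dir`, `seed`, blocks `geometry` (`D`, possibly "Inf"), `training`
#'   (batch_size, learning_rate, n_iterations, patch_size, ...), `backbone`
#'   and `normalization`.
#' @param force Overwrite a non-empty output directory.
#' @return The manifest, invisibly.
#' @export
cli_train <- function(config, force = FALSE) {
  cfg <- as_config(config)
  out <- prepare_out_dir(cfg$out_dir, force)
  files <- sort(list.files(file.path(cfg$data_dir, "train"),
                           pattern = "^clean_.*\\.tsv$", full.names = TRUE))
  if (length(files) == 0) stop("no clean training images under ", cfg$data_dir)
  dataset <- lapply(files, read_image_hu)
  tr <- cfg$training %||% list()
  ps <- tr$patch_size %||% 8L
  geom <- geom_config(ps^2, cfg_D((cfg$geometry %||% list())$D %||% 128))
  tcfg <- training_config(
    batch_size = tr$batch_size %||% 32L,
    learning_rate = tr$learning_rate %||% 2e-4,
    n_iterations = tr$n_iterations %||% 2000L,
    ema_halflife = tr$ema_halflife %||% 5e3,
    augment_prob = tr$augment_prob %||% 0.15,
    dropout_prob = tr$dropout_prob %||% 0,
    patch_size = ps,
    scale_dist = noise_scale_dist(tr$P_mean %||% -1.2, tr$P_std %||% 1.2),
    geom = geom,
    seed = as.integer(cfg$seed %||% 1L))
  bb <- cfg$backbone %||% list()
  backbone <- backbone_config(bb$base_channels %||% 64,
                              unlist(bb$channel_multipliers %||% c(2, 2)),
                              integer(0), bb$dropout_prob %||% 0,
                              bb$n_freqs %||% 6L)
  nm <- cfg$normalization %||% list()
  normalization <- hu_normalization(nm$offset %||% -500, nm$scale %||% 500)
  log_file <- file.path(out, "loss.ndjson")
  if (file.exists(log_file)) unlink(log_file)
  model <- train_denoiser(dataset, tcfg, backbone, normalization,
                          sigma_data = cfg$sigma_data %||% 0.5,
                          log_file = log_file)
  ckpt <- file.path(out, "checkpoint.json")
  save_checkpoint(model, ckpt)
  invisible(write_manifest(out, list(
    subcommand = "train", seed = tcfg$seed, config = cfg,
    n_images = length(files), final_loss = model$history[length(model$history)],
    checksums = file_checksums(ckpt))))
}

read_sampler_cfg <- function(cfg, geom) {
  s <- cfg$sampler %||% list()
  Tn <- s$T %||% 8L
  sched <- make_schedule(Tn, s$sigma_min %||% 0.002, s$sigma_max %||% 80,
                         s$rho %||% 7)
  sampler_config(sched, tau = s$tau %||% (Tn - 1L), w = s$w %||% 0.5,
                 geom = geom, mode = s$mode %||% "posterior")
}

#' Denoise images from a config
#'
#' Loads a checkpoint, denoises every input image via hijacked, regularized
#' sampling, and writes the outputs plus a manifest recording the per-step
#' sigma (and, for finite D, r) schedule, the NFE, and checksums.  The
#' checkpoint's D must agree with a `geometry.D` given in the config.
#'
#' @param config Path or list: `checkpoint`, `input` (a `.tsv` image or a
#'   directory of `noisy_*.tsv`), `out_dir`, optional `geometry.D`, and a
#'   `sampler` block (T, tau, w, mode, sigma_min, sigma_max, rho).
#' @param force Overwrite a non-empty output directory.
#' @return The manifest, invisibly.
#' @export
cli_denoise <- function(config, force = FALSE) {
  cfg <- as_config(config)
  out <- prepare_out_dir(cfg$out_dir, force)
  model <- load_checkpoint(cfg$checkpoint)
  if (!is.null((cfg$geometry %||% list())$D)) {
    D_cfg <- cfg_D(cfg$geometry$D)
    if (!identical(is.infinite(D_cfg), is.infinite(model$geom$D)) ||
        (is.finite(D_cfg) && D_cfg != model$geom$D))
      stop(sprintf("geometry mismatch: checkpoint D = %s, config D = %s",
                   format(model$geom$D), format(D_cfg)))
  }
  inputs <- if (dir.exists(cfg$input)) {
    sort(list.files(cfg$input, pattern = "^noisy_.*\\.tsv$", full.names = TRUE))
  } else cfg$input
  if (length(inputs) == 0) stop("no input images found at ", cfg$input)
  scfg <- read_sampler_cfg(cfg, model$geom)
  out_paths <- character(length(inputs))
  nfes <- integer(length(inputs))
  for (i in seq_along(inputs)) {
    img <- read_image_hu(inputs[[i]])
    res <- denoise_posterior(model, img, scfg,
                             seed = derive_seed(cfg$seed %||% 1L,
                                                paste0("denoise", i)))
    out_paths[i] <- file.path(out, paste0("denoised_",
                                          sub("^noisy_", "", basename(inputs[[i]]))))
    write_image_hu(res$output, out_paths[i])
    if (isTRUE(cfg$write_pgm))
      write_image_pgm(res$output, sub("\\.tsv$", ".pgm", out_paths[i]),
                      window = unlist(cfg$window %||% c(-160, 240)))
    nfes[i] <- res$nfe
  }
  t <- scfg$schedule$t
  step_log <- data.frame(step = seq_along(t) - 1L, sigma = t,
                         r = if (is_diffusion_limit(scfg$geom)) t else
                           t * sqrt(scfg$geom$D))
  invisible(write_manifest(out, list(
    subcommand = "denoise", config = cfg, nfe = nfes,
    expected_nfe = count_nfe(scfg),
    schedule = step_log, checksums = file_checksums(out_paths))))
}

#' Unconditional sampling from a config
#'
#' @param config Path or list: `checkpoint`, `out_dir`, `seed`, `n_samples`,
#'   and a `sampler` block.
#' @param force Overwrite a non-empty output directory.
#' @return The manifest, invisibly.
#' @export
cli_sample <- function(config, force = FALSE) {
  cfg <- as_config(config)
  out <- prepare_out_dir(cfg$out_dir, force)
  model <- load_checkpoint(cfg$checkpoint)
  cfg$sampler <- cfg$sampler %||% list()
  cfg$sampler$mode <- "unconditional"
  scfg <- read_sampler_cfg(cfg, model$geom)
  n <- cfg$n_samples %||% 1L
  paths <- character(n); nfes <- integer(n)
  for (i in seq_len(n)) {
    res <- sample_unconditional(model, scfg,
                                seed = derive_seed(cfg$seed %||% 1L,
                                                   paste0("sample", i)))
    paths[i] <- file.path(out, sprintf("sample_%03d.tsv", i))
    write_image_hu(res$output, paths[i])
    nfes[i] <- res$nfe
  }
  invisible(write_manifest(out, list(
    subcommand = "sample", config = cfg, nfe = nfes,
    checksums = file_checksums(paths))))
}

#' Evaluate denoised images against clean references
#'
#' @param config Path or list: `clean_dir` (with `clean_*.tsv`),
#'   `denoised_dir` (with `denoised_*.tsv`), `out_dir`, optional
#'   `data_range`.
#' @param force Overwrite a non-empty output directory.
#' @return The manifest (including the aggregate metrics), invisibly.
#' @export
cli_evaluate <- function(config, force = FALSE) {
  cfg <- as_config(config)
  out <- prepare_out_dir(cfg$out_dir, force)
  clean_f <- sort(list.files(cfg$clean_dir, pattern = "^clean_.*\\.tsv$",
                             full.names = TRUE))
  den_f <- sort(list.files(cfg$denoised_dir, pattern = "^denoised_.*\\.tsv$",
                           full.names = TRUE))
  if (length(clean_f) == 0 || length(clean_f) != length(den_f))
    stop("clean/denoised sets are empty or of different sizes")
  clean <- lapply(clean_f, read_image_hu)
  den <- lapply(den_f, read_image_hu)
  dr <- cfg$data_range %||%
    (max(vapply(clean, max, numeric(1))) - min(vapply(clean, min, numeric(1))))
  tab <- data.frame(
    image = basename(den_f),
    psnr = vapply(seq_along(den), function(i) psnr(den[[i]], clean[[i]], dr),
                  numeric(1)),
    ssim = vapply(seq_along(den), function(i) ssim(den[[i]], clean[[i]], dr),
                  numeric(1)))
  utils::write.table(tab, file.path(out, "metrics.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  summary <- list(data_range = dr,
                  psnr_mean = mean(tab$psnr), psnr_sd = stats::sd(tab$psnr),
                  ssim_mean = mean(tab$ssim), ssim_sd = stats::sd(tab$ssim))
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(write_manifest(out, c(list(subcommand = "evaluate", config = cfg),
                                  summary)))
}

#' Grid search from a config
#'
#' @param config Path or list: `checkpoint`, `data_dir` (with an `eval`
#'   subdirectory of pairs), `out_dir`, `gridsearch` block (`T_grid`,
#'   `w_grid`, `criterion`).
#' @param force Overwrite a non-empty output directory.
#' @return The manifest (including the selected T and w), invisibly.
#' @export
cli_gridsearch <- function(config, force = FALSE) {
  cfg <- as_config(config)
  out <- prepare_out_dir(cfg$out_dir, force)
  model <- load_checkpoint(cfg$checkpoint)
  ev <- file.path(cfg$data_dir, "eval")
  clean <- lapply(sort(list.files(ev, pattern = "^clean_.*\\.tsv$",
                                  full.names = TRUE)), read_image_hu)
  noisy <- lapply(sort(list.files(ev, pattern = "^noisy_.*\\.tsv$",
                                  full.names = TRUE)), read_image_hu)
  g <- cfg$gridsearch %||% list()
  spec <- grid_search_spec(unlist(g$T_grid %||% c(4L, 8L)),
                           unlist(g$w_grid %||% c(0.5, 0.8, 1.0)),
                           g$criterion %||% "psnr")
  res <- grid_search(model, list(clean = clean, noisy = noisy), spec)
  utils::write.table(res$table, file.path(out, "grid.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(write_manifest(out, list(
    subcommand = "gridsearch", config = cfg,
    best_T = res$best$schedule$T, best_w = res$best$w,
    criterion = spec$criterion)))
}

#' Command-line entry point
#'
#' Dispatches `pfct_cli(c("<subcommand>", "--config", path, "--set",
#' "key=value", ...))` to the corresponding `cli_*` function; `--force`
#' allows writing into a non-empty output directory.  Subcommands:
#' make-data, train, denoise, sample, evaluate, gridsearch.
#'
#' @param args Character vector of command-line arguments (e.g.
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return The subcommand's manifest, invisibly.
#' @export
pfct_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) < 1L)
    stop("usage: pfct <make-data|train|denoise|sample|evaluate|gridsearch> ",
         "--config <file> [--set key.path=value]... [--force]")
  sub <- args[[1L]]
  rest <- args[-1L]
  config_path <- NULL; overrides <- character(0); force <- FALSE
  i <- 1L
  while (i <= length(rest)) {
    a <- rest[[i]]
    if (a == "--config") { config_path <- rest[[i + 1L]]; i <- i + 2L }
    else if (a == "--set") { overrides <- c(overrides, rest[[i + 1L]]); i <- i + 2L }
    else if (a == "--force") { force <- TRUE; i <- i + 1L }
    else stop("unknown argument: ", a)
  }
  if (is.null(config_path)) stop("--config is required")
  cfg <- read_run_config(config_path, overrides)
  fn <- switch(sub,
               "make-data" = cli_make_data, "train" = cli_train,
               "denoise" = cli_denoise, "sample" = cli_sample,
               "evaluate" = cli_evaluate, "gridsearch" = cli_gridsearch,
               stop("unknown subcommand: ", sub))
  fn(cfg, force = force)
}
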