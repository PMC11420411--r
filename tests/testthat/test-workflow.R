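make_base_config <- function(root) {
  list(
    seed = 123,
    out_dir = file.path(root, "data"),
    data = list(n_train = 3L, n_eval = 2L, image_size = 16L,
                noise_sd = 50, correlation_length = 0))
}

test_that("the full make-data / train / denoise / evaluate chain runs", {
  root <- withr::local_tempdir()
  dcfg <- make_base_config(root)
  man1 <- cli_make_data(dcfg)
  expect_true(file.exists(file.path(root, "data", "manifest.json")))
  expect_length(list.files(file.path(root, "data", "train")), 3L)
  expect_length(list.files(file.path(root, "data", "eval")), 4L)
  expect_error(cli_make_data(dcfg), "force")

  # identical config reruns reproduce the dataset bit for bit (checksums)
  dcfg2 <- dcfg; dcfg2$out_dir <- file.path(root, "data2")
  man2 <- cli_make_data(dcfg2)
  expect_identical(unname(unlist(man1$checksums)),
                   unname(unlist(man2$checksums)))
  # and the manifest alone suffices to regenerate it
  mcfg <- jsonlite::read_json(file.path(root, "data", "manifest.json"),
                              simplifyVector = TRUE)$config
  mcfg$out_dir <- file.path(root, "data3")
  man3 <- cli_make_data(mcfg)
  expect_identical(unname(unlist(man1$checksums)),
                   unname(unlist(man3$checksums)))

  tcfg <- list(
    seed = 7, data_dir = file.path(root, "data"),
    out_dir = file.path(root, "run"),
    geometry = list(D = 64),
    training = list(batch_size = 8L, learning_rate = 1e-3,
                    n_iterations = 120L, patch_size = 8L),
    backbone = list(base_channels = 16, channel_multipliers = c(1, 1)))
  cli_train(tcfg)
  ckpt <- file.path(root, "run", "checkpoint.json")
  expect_true(file.exists(ckpt))
  expect_true(file.exists(file.path(root, "run", "loss.ndjson")))
  log1 <- readLines(file.path(root, "run", "loss.ndjson"))
  expect_length(log1, 120L)
  expect_true(is.finite(jsonlite::fromJSON(log1[[120]])$loss))

  ncfg <- list(
    seed = 7, checkpoint = ckpt, input = file.path(root, "data", "eval"),
    out_dir = file.path(root, "den"), geometry = list(D = 64),
    sampler = list(T = 4L, tau = 3L, w = 0.5), write_pgm = TRUE)
  man <- cli_denoise(ncfg)
  expect_identical(unname(man$nfe), c(1L, 1L))
  expect_identical(man$expected_nfe, 1L)
  expect_length(list.files(file.path(root, "den"), pattern = "denoised_.*tsv"), 2L)
  pgm <- readLines(list.files(file.path(root, "den"), pattern = "\\.pgm$",
                              full.names = TRUE)[1])
  expect_identical(pgm[1], "P2")
  # per-step sigma/r log allows post-hoc schedule verification
  sched <- jsonlite::read_json(file.path(root, "den", "manifest.json"),
                               simplifyVector = TRUE)$schedule
  expect_equal(sched$sigma, make_schedule(4)$t)
  expect_equal(sched$r, sched$sigma * sqrt(64))

  # checkpoint/geometry mismatch is a hard error
  bad <- ncfg; bad$geometry$D <- 128; bad$out_dir <- file.path(root, "den_bad")
  expect_error(cli_denoise(bad), "geometry mismatch")

  ecfg <- list(clean_dir = file.path(root, "data", "eval"),
               denoised_dir = file.path(root, "den"),
               out_dir = file.path(root, "metrics"))
  eman <- cli_evaluate(ecfg)
  expect_true(is.finite(eman$psnr_mean))
  expect_true(eman$ssim_mean > -1 && eman$ssim_mean <= 1)
  tab <- read.delim(file.path(root, "metrics", "metrics.tsv"))
  expect_identical(nrow(tab), 2L)
})

test_that("denoising with w = 0 reproduces the input after the HU round trip", {
  root <- withr::local_tempdir()
  dcfg <- make_base_config(root)
  cli_make_data(dcfg)
  # an oracle checkpoint is enough to exercise the identity path
  clean <- lapply(sort(list.files(file.path(root, "data", "eval"),
                                  pattern = "^clean_", full.names = TRUE)),
                  read_image_hu)
  orc <- oracle_denoiser(clean, geom_config(256, 128))
  ckpt <- file.path(root, "oracle.json")
  save_checkpoint(orc, ckpt)
  ncfg <- list(checkpoint = ckpt, input = file.path(root, "data", "eval"),
               out_dir = file.path(root, "den0"),
               sampler = list(T = 4L, tau = 3L, w = 0))
  cli_denoise(ncfg)
  noisy_f <- sort(list.files(file.path(root, "data", "eval"),
                             pattern = "^noisy_", full.names = TRUE))
  den_f <- sort(list.files(file.path(root, "den0"), pattern = "^denoised_",
                           full.names = TRUE))
  for (i in seq_along(noisy_f))
    expect_equal(read_image_hu(den_f[i]), read_image_hu(noisy_f[i]),
                 tolerance = 1e-12)
})

test_that("gridsearch CLI writes the full (T, w) table", {
  root <- withr::local_tempdir()
  dcfg <- make_base_config(root)
  cli_make_data(dcfg)
  clean <- lapply(sort(list.files(file.path(root, "data", "eval"),
                                  pattern = "^clean_", full.names = TRUE)),
                  read_image_hu)
  ckpt <- file.path(root, "oracle.json")
  save_checkpoint(oracle_denoiser(clean, geom_config(256, 128)), ckpt)
  gcfg <- list(checkpoint = ckpt, data_dir = file.path(root, "data"),
               out_dir = file.path(root, "grid"),
               gridsearch = list(T_grid = c(2L, 4L), w_grid = c(0.5, 1.0),
                                 criterion = "psnr"))
  man <- cli_gridsearch(gcfg)
  tab <- read.delim(file.path(root, "grid", "grid.tsv"))
  expect_identical(nrow(tab), 4L)
  expect_true(man$best_T %in% c(2L, 4L))
  expect_true(man$best_w %in% c(0.5, 1.0))
})

test_that("the CLI dispatcher parses configs, overrides, and --force", {
  root <- withr::local_tempdir()
  cfg_path <- file.path(root, "cfg.json")
  write_run_config(make_base_config(root), cfg_path)
  pfct_cli(c("make-data", "--config", cfg_path))
  expect_length(list.files(file.path(root, "data", "train")), 3L)
  # --set overrides a nested key; --force allows the rewrite
  pfct_cli(c("make-data", "--config", cfg_path, "--force",
             "--set", "data.n_train=5"))
  expect_length(list.files(file.path(root, "data", "train")), 5L)
  expect_error(pfct_cli(c("make-data", "--config", cfg_path)), "force")
  expect_error(pfct_cli(character(0)), "usage")
  expect_error(pfct_cli(c("bogus", "--config", cfg_path)), "subcommand")
  cfg <- read_run_config(cfg_path, "data.noise_sd=25")
  expect_identical(cfg$data$noise_sd, 25L)
})
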