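test_that("phantom rendering follows the stated geometry", {
  empty <- phantom_spec(list(), background_hu = -1000, image_size = 16)
  expect_true(all(generate_phantom(empty) == -1000))

  circ <- phantom_spec(list(phantom_ellipse(c(0, 0), c(0.5, 0.5), 0, 0)),
                       background_hu = -1000, image_size = 64)
  img <- generate_phantom(circ)
  expect_identical(dim(img), c(64L, 64L))
  expect_equal(img[32, 32], 0)
  expect_equal(img[1, 1], -1000)

  # mean HU = background + contrast * disc area fraction, where the fraction
  # is recomputed here by brute-force enumeration of pixel centers
  cc <- 2 * (seq_len(64) - 0.5) / 64 - 1
  frac <- mean(outer(cc, cc, function(v, u) u^2 + v^2 <= 0.25))
  expect_equal(mean(img), -1000 + 1000 * frac)

  # painter's order: a later ellipse overwrites an earlier one
  stack <- phantom_spec(list(phantom_ellipse(c(0, 0), c(0.5, 0.5), 0, 100),
                             phantom_ellipse(c(0, 0), c(0.2, 0.2), 0, -100)),
                        background_hu = 0, image_size = 32)
  expect_equal(generate_phantom(stack)[16, 16], -100)
})

test_that("phantom jitter is seeded, deterministic, and clipped to the FOV", {
  spec <- default_phantom_spec(32)
  a <- generate_phantom(spec, seed = 7)
  b <- generate_phantom(spec, seed = 7)
  c <- generate_phantom(spec, seed = 8)
  expect_identical(a, b)
  expect_false(identical(a, c))
  wild <- phantom_spec(list(phantom_ellipse(c(0.99, 0), c(0.1, 0.1), 0, 50)),
                       image_size = 16, jitter = list(center_sd = 3, hu_sd = 0))
  expect_warning(generate_phantom(wild, seed = 41), "clipped")
})

test_that("degradation is calibrated, correlated, and seeded", {
  img <- matrix(0, 256, 256)
  expect_identical(degrade(img, degradation_config(noise_sd = 0)), img)

  for (cl in c(0, 2, 4)) {
    cfg <- degradation_config(noise_sd = 50, correlation_length = cl,
                              seed = 100 + cl)
    noisy <- degrade(img, cfg)
    expect_equal(sd(noisy), 50, tolerance = 0.05)
    expect_identical(noisy, degrade(img, cfg))
  }

  # correlation: lag-1 autocorrelation grows with the kernel width
  n0 <- degrade(img, degradation_config(50, 0, seed = 1))
  n4 <- degrade(img, degradation_config(50, 4, seed = 1))
  lag1 <- function(m) cor(as.vector(m[-1, ]), as.vector(m[-nrow(m), ]))
  expect_lt(abs(lag1(n0)), 0.05)
  expect_gt(lag1(n4), 0.5)
})

test_that("patch extraction is uniform over corners and reproducible", {
  imgs <- list(matrix(seq_len(64 * 64), 64, 64))
  full <- extract_patches(imgs, 64, 3, seed = 1)
  expect_true(all(vapply(full$patches, identical, logical(1), imgs[[1]])))

  none <- extract_patches(imgs, 8, 0, seed = 1)
  expect_length(none$patches, 0)

  expect_error(extract_patches(imgs, 65, 1), "exceeds image 1")

  ps <- extract_patches(imgs, 32, 1000, seed = 42)
  expect_identical(ps$patches, extract_patches(imgs, 32, 1000, seed = 42)$patches)
  # corner (r0, c0) recoverable from the stored sequence values
  corners <- vapply(ps$patches, function(p) p[1, 1], numeric(1))
  cell <- factor(corners, levels = as.vector(outer(1:33, 0:32 * 64, `+`)))
  ct <- suppressWarnings(
    chisq.test(table(cell), simulate.p.value = TRUE, B = 1999))
  expect_gt(ct$p.value, 0.01)
})

test_that("paired evaluation sets pair correctly and degrade with noise_sd", {
  spec <- default_phantom_spec(32)
  clean_only <- make_paired_eval_set(3, spec, degradation_config(0), seed = 9)
  expect_identical(clean_only$clean, clean_only$noisy)

  p1 <- make_paired_eval_set(3, spec, degradation_config(50), seed = 9)
  p2 <- make_paired_eval_set(3, spec, degradation_config(50), seed = 9)
  expect_identical(p1, p2)
  expect_identical(p1$clean, clean_only$clean)

  p_double <- make_paired_eval_set(3, spec, degradation_config(100), seed = 9)
  dr <- max(sapply(p1$clean, max)) - min(sapply(p1$clean, min))
  for (i in 1:3) {
    expect_lt(psnr(p_double$noisy[[i]], p_double$clean[[i]], dr),
              psnr(p1$noisy[[i]], p1$clean[[i]], dr))
  }
})

test_that("the training interface cannot receive noisy images or pairs", {
  # unsupervised contract: the training entry point accepts a clean dataset
  # and configuration only - there is no argument through which noisy
  # counterparts could enter
  args <- names(formals(train_denoiser))
  expect_false(any(grepl("nois|pair|condition", args, ignore.case = TRUE)))
  expect_identical(args[1:2], c("dataset", "cfg"))
})
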