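Package: pfct
Title: Unsupervised Poisson Flow Denoising for Photon-Counting CT
Version: 0.1.0
Authors@R:
    person("pfct", "maintainers", email = "pfct@example.org", role = c("aut", "cre"))
Description: Tools for unsupervised denoising of CT and photon-counting CT
    image slices with Poisson flow generative models (PFGM++), which contain
    score-based diffusion (EDM) as the D -> infinity special case. The package
    trains an unconditional denoiser on clean image patches only, then denoises
    a noisy slice by hijacking a deterministic Heun ODE sampler at the last
    step and mixing the iterate with the condition image, giving a single
    network evaluation (NFE = 1) per image. Includes a CT ellipse-phantom
    generator with a correlated-noise degradation operator, an exact analytic
    Poisson field oracle for discrete datasets, PSNR/SSIM image-quality
    metrics with a T/w grid-search selector, and a command-line workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
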