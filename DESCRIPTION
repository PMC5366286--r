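Package: cardiffusion
Title: Non-Gaussian Diffusion Modelling and Model Selection for Cardiac
    Diffusion MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits seven models of diffusion-weighted signal attenuation
    (diffusion tensor, stretched exponential, diffusion kurtosis,
    biexponential, truncated Gaussian, gamma and beta diffusivity
    distributions) to cardiac diffusion MRI data in the eigenframe of the
    diffusion tensor, and ranks them by the corrected Akaike information
    criterion over a maximum-b-value sweep. Includes phase-based Rician
    noise mitigation, helix/transverse/sheetlet angle maps in a local wall
    coordinate system, q-space propagator utilities, a synthetic phantom
    generator emulating ex-vivo rat heart acquisitions, and group
    comparison of kurtosis and skewness by exact Mann-Whitney U tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
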