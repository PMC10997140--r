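Package: csvtracts
Title: Mapping Tractography Streamlines Near the Cingulate Sulcus Visual Area onto Major White Matter Tracts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for relating a functionally defined cortical seed region
    (the cingulate sulcus visual area, CSv) to the major white matter tracts
    that pass near it, using diffusion-MRI tractography. Provides readers and
    writers for streamline files (TCK/TRK) and NIfTI volumes, a synthetic
    diffusion phantom generator with known ground truth, diffusion tensor
    fitting with principal-diffusion-direction colour maps, a linear fascicle
    evaluation (LiFE) style non-negative least-squares streamline filter,
    endpoint-proximity selection of seed-adjacent streamlines, waypoint-ROI
    tract classification, and one-sample t-test group statistics on tract
    proportions with Bonferroni correction, together with a reproducible
    end-to-end pipeline driven by a single configuration file.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    RNifti,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
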