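Package: tractstats
Title: Along-Tract Diffusion MRI Statistics with Permutation Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Statistical toolkit for tractometry: reads AFQ-style tract
    profiles (diffusion metrics sampled at equidistant nodes along white
    matter tracts), computes hemispheric lateralization indices, runs
    tract-wise and point-wise group comparisons with covariate adjustment,
    permutation-based family-wise error correction (Freedman-Lane residual
    permutation and max-statistic correction) and a consecutive-node
    cluster-extent criterion, and fits brain-behavior association models
    with partial-correlation effect sizes. Includes a synthetic
    tract-profile generator with node-autocorrelated noise, hemispheric
    asymmetry, localized group effects and behavior coupling, so the whole
    pipeline is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
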