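Package: dotsens
Title: Depth Sensitivity Profiling for Diffuse Optical Tomography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxel-based Monte Carlo simulation of near-infrared photon
    transport through segmented head volumes, virtual 10-10/10-5 optode
    placement from cranial fiducials, source-detector channel sensitivity
    (photon measurement density function) volumes, and depth-binned
    sensitivity profiles with half-width-half-maximum summaries as a
    function of source-detector separation distance. Includes synthetic
    layered head phantoms (slabs and spheres) with age-parameterised
    extracerebral layer thicknesses, a closed-form diffusion oracle for
    validating the transport kernel, and a config-driven experiment runner
    with per-optode fluence caching.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
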