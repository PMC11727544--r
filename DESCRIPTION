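Package: bundlescope
Title: Virtual Dissection of White-Matter Bundles: ROI Recipes versus
    Streamline Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for segmenting white-matter bundles from diffusion-MRI
    tractograms by two families of methods and comparing the results
    quantitatively. Provides a lightweight streamline/tractogram data model
    with TRK (TrackVis) and TCK (MRtrix) readers and writers, a synthetic
    phantom generator that emulates four association bundles (arcuate
    fasciculus, its indirect anterior and posterior segments, and the
    inferior fronto-occipital fasciculus) together with the recurrent
    artefact streamline populations seen in clinical virtual dissection,
    an ROI waypoint/exclusion recipe engine with 'Any Part'/'No Part'
    operators and midline slice filtering, a minimum-average-direct-flip
    (MDF) clustering engine with medoid prototypes and a template-guided
    selection policy, voxel-based bundle shape measures culminating in the
    irregularity (compactness) index, and paired statistical comparison of
    the two segmentation approaches across a cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
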