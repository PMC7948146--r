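Package: cerebparc
Title: Individual-Specific Cerebro-Cerebellar Functional Network Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for mapping the functional network organization of the
    human cerebellum within single individuals from resting-state fMRI.
    Implements run-level quality control, nuisance regression, band-pass
    filtering, seed-based correlation maps with Fisher z averaging,
    connectivity-profile construction with top-fraction binarization,
    spherical clustering of cortical vertices into discrete networks,
    top-k winner-take-all assignment of cerebellar voxels to cortical
    networks, split-half reliability and overlap metrics, seed-back
    validation of cerebellar zones against cortical network boundaries,
    cortex-cerebellum proportionality analysis, and majority-vote
    projection of volumetric labels onto a flatmap surface. A synthetic
    scene generator produces ground-truth subjects with contralateral
    cerebro-cerebellar coupling, mirrored multi-representation cerebellar
    topography, and somatomotor body-part subdivisions, so that every
    stage of the pipeline can be validated by label recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
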