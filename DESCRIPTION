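Package: reinstatr
Title: Multivoxel Reinstatement and Gist Indices with PLSC Brain-Behavior
    Analysis for Memory-Consolidation Studies
Version: 0.1.0
Authors@R: person("Memory", "Lab", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computes corrected scene-specific reinstatement and gist-like
    representation indices from trial-wise multivoxel beta patterns,
    provides sign-flip permutation tests, mixed-effects condition models
    with Satterthwaite degrees of freedom, effect sizes and multiplicity
    corrections, and a partial least squares correlation (PLSC) procedure
    linking ROI metric profiles to behavior with permutation and bootstrap
    inference. Ships a synthetic-cohort generator that emulates an
    object-location association consolidation design (adaptive learning to
    criterion, recent/remote retrieval over three delays, planted
    reinstatement and gist effects) so the full pipeline is testable
    without any imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    data.table,
    lme4
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
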