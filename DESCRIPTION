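Package: mrjet
Title: Direct Mitral Regurgitation Quantification from 4D Flow CMR by Jet Tracking
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for direct quantification of mitral regurgitation (MR)
    from time-resolved three-dimensional phase-contrast cardiovascular
    magnetic resonance (4D flow CMR). Implements regurgitant jet detection
    and frame-to-frame tracking, peak-velocity multiplanar-reformat plane
    placement perpendicular to the jet, through-plane flow-rate computation,
    and spline-integrated regurgitant volume, together with the conventional
    indirect volumetric method (left-ventricular stroke volume minus aortic
    forward flow), MR severity grading, and the agreement-statistics battery
    (intraclass correlation, Bland-Altman limits of agreement, Cohen's
    kappa, Wilcoxon signed-rank). Includes a digital 4D flow jet phantom
    with known ground truth for validation, velocity-aliasing unwrapping,
    and eddy-current background offset correction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, tools, RNifti, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
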