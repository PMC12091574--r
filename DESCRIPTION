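Package: hydroshell
Title: Hydration-Shell Water Entropy, Structure and Dynamics from MD Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-water rotational and translational entropy estimation from
    molecular dynamics trajectories via permutation-reduced orientational
    histograms, together with the surrounding hydration-shell analyses used to
    characterize water near the ice-binding surfaces of antifreeze and
    ice-nucleating proteins: geometric hydrogen-bond detection, O-O-O angle
    distributions and the conditional tetrahedral order parameter, mean square
    displacement, stable-state-picture residence-time kinetics with
    bi-exponential fitting, and protein-side ice-binding-surface geometry
    metrics (threonine side-chain orientation angles, side-chain RMSD, ladder
    spacings, tyrosine stacking and Ser-Gly hydrogen-bond distances). Includes
    synthetic trajectory generators with analytic ground truth so every
    pipeline stage is testable without running MD.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    bio3d,
    minpack.lm,
    jsonlite,
    stats,
    graphics,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
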