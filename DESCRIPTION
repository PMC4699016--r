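Package: DomainOrient
Title: Rigid Local Axes and Relative Orientation of Deformable Domains in
    Molecular Dynamics Trajectories
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies relative movements of quasi-rigid domains in large
    biomolecules over a molecular dynamics trajectory. For each domain a
    body-fixed orthonormal triad is derived once, by principal component
    analysis of the C-alpha coordinates at the domain's most central frame
    (the frame minimising the summed superposition RMSD to all other
    frames), orientation-disambiguated against user-chosen atom pairs, and
    then transported to every frame with the rotation from a Kabsch
    least-squares fit. This avoids the sign-flip and axis-swap artifacts of
    per-frame PCA. From the transported triads the package computes
    inter-domain centre distances, directional cosines, x-convention Euler
    angles, autocorrelation functions, and Pearson correlations with
    Fisher-z confidence intervals. Includes a grafting tool to assemble a
    composite complex by superposition on a shared domain, and a synthetic
    trajectory generator of noisy rigid-body helix motions with exact
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, bio3d, Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse, jsonlite, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'AllClasses.R'
    'geometry.R'
    'structure-io.R'
    'domain-table.R'
    'orientation.R'
    'timeseries-stats.R'
    'complex-builder.R'
    'synthetic.R'
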