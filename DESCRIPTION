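Package: dacnc
Title: Core-Shell Dialcohol Cellulose Nanocrystal Models and Shear Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds atomistic cellulose I-beta nanocrystal models with graded
    C2-C3 dialcohol (periodate-oxidized/reduced) core-shell modification and
    analyses their structure and shear mechanics. Structural observables
    include interchain radial distribution functions and the derived
    structure factor S(q), geometric hydrogen-bond counts, glycosidic
    torsion distributions, solvent-accessible surface area, and hydration
    shells. Steered-shear force-displacement traces are post-processed into
    engineering stress curves, maximum shear stress, interfacial stiffness,
    stick-slip events, and force-curve interaction energies. A synthetic-data
    module generates thermally jittered crystals, hydration shells, and
    parameterized stick-slip traces with known ground truth so that every
    analysis stage is testable without molecular dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    optparse,
    pracma,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
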