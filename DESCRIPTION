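Package: vitdfree
Title: Steady-State Modeling of Free Vitamin D Metabolites and Monocyte
    Cathelicidin Induction
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "maintainer@example.org", role = c("aut", "cre"))
Description: Coupled steady-state models of vitamin D metabolite handling.
    An extracellular equilibrium model estimates free 25-hydroxyvitamin D
    (25OHD) and 1,25-dihydroxyvitamin D from total serum levels, vitamin D
    binding protein (DBP/GC) genotype and albumin, by solving the two-ligand
    multi-binder competitive binding system. An intracellular model couples
    membrane permeation, CYP27B1-mediated conversion of 25OHD to
    1,25-dihydroxyvitamin D (Michaelis-Menten), cooperative vitamin D
    receptor occupancy and VDRE transactivation to predict induction of the
    cathelicidin antimicrobial peptide (CAMP) gene in monocytes. Includes
    genotype calibration from published free-25OHD reference values, staged
    weighted least-squares fitting of the intracellular parameters to
    dose-response data, a synthetic dose-response generator, and a
    mass-action kinetic oracle used to validate both steady-state solvers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
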