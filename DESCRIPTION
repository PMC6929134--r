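Package: mpsdyn
Title: Coarse-Grained Langevin Dynamics of Magnetosensitive Polymersomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds and simulates a coarse-grained model of a magnetosensitive
    polymersome: two nested triangulated elastic shells confining a quasi-2D
    monolayer of dipolar magnetic nanoparticles, evolved by translational and
    rotational Langevin dynamics under a uniform external magnetic field.
    Provides mesh construction, all force and torque kernels (shell stretching,
    triangle-area restoring, intershell bonds, Weeks-Chandler-Andersen
    repulsion, dipole-dipole coupling, Zeeman torque), equilibration and
    field-response protocols with replica averaging, and observables for the
    field-induced elongation, inner-cavity volume defect, magnetization and
    nanoparticle chain structure, together with dimensional-to-reduced
    parameter conversions for ferrite nanoparticles.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
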