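Package: hydrosas
Title: Explicit-Solvent Small-Angle Scattering and Hydration-Shell Observables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes small-angle X-ray and neutron scattering (SAXS/SANS)
    curves from atomistic solute-in-solvent configurations by explicit-solvent
    buffer subtraction inside a spatial envelope, and derives hydration-shell
    observables from them: Guinier and P(r)-based radii of gyration, the
    hydration-shell increments DeltaRg = Rg(SAS) - Rg(protein) and
    DeltaRg(SAS) = Rg(SAXS) - Rg(SANS), block-averaged standard errors, and
    solvent density profiles versus distance from the solute Van-der-Waals
    surface. Includes a seeded synthetic-system generator (lattice solutes,
    pseudo-water solvent with a controllable hydration-shell excess, matched
    buffer boxes) that stands in for molecular-dynamics trajectories, an
    icosphere-based star-shaped envelope geometry, neutron H/D exchange with
    fractional backbone-amide deuteration, and readers/writers for multi-model
    PDB, extended XYZ, and three-column scattering curve files.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    tools,
    utils,
    yaml,
    jsonlite,
    rlang,
    bio3d
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
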