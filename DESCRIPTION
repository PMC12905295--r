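Package: fieldcat
Title: Internal Electric Fields and Free-Energy Profiles in Enzymatic PET Depolymerization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis machinery for studying how active-site electric fields
    shape enzymatic polyester hydrolysis. Computes internal electric fields
    from point-charge environments projected onto reaction axes (Coulomb sum
    at the axis midpoint, MV/cm), reconstructs one-dimensional free-energy
    profiles from harmonically biased umbrella-sampling windows by
    self-consistent WHAM with bootstrap uncertainties and overlap and
    convergence diagnostics, converts barriers to rate constants via Eyring
    transition-state theory, fits per-state Stark models to field-energy
    scans and decomposes field-induced barrier shifts into static and
    dynamic parts, and validates putative transition states by committor
    analysis with Langevin dynamics on model potentials. Ships seeded
    synthetic-data generators with analytically known ground truth so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
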