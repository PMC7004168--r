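Package: cucolumn
Title: Copper Biogeochemical Cycling in an Idealized Ocean Water Column
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Desk-scale simulator of dissolved copper cycling in a one-
    dimensional ocean water column. Implements one-ligand Cu speciation
    (inorganic Cu' versus ligand-bound CuL at conditional equilibrium),
    reversible scavenging onto sinking organic particles, quota-regulated
    phytoplankton uptake with an evolving Cu:P ratio, zooplankton recycling
    and excretion, bacterial remineralization, aerosol and river surface
    sources, implicit vertical mixing and particle sinking, and a scenario
    harness with budget, residence-time, profile-linearity and cellular-quota
    diagnostics. Ecosystem drivers (biomass, particulate organic carbon,
    grazing, mixing) are prescribed from a deterministic synthetic forcing
    generator, so every experiment runs with no external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
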