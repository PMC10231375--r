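Package: mepflux
Title: MEP Pathway Flux from Isotope Labeling and HDR Enzyme Kinetics
Version: 0.1.0
Authors@R: person("mepflux", "maintainers", email = "mepflux@example.org",
    role = c("aut", "cre"))
Description: Estimates methylerythritol 4-phosphate (MEP) pathway flux from
    13CO2 to isoprene labeling time courses using the closed-form
    fractional-labeling curve of a four-pool linear chain (DXP, MEcDP,
    HMBDP, IDP+DMADP), with an independent adaptive ODE oracle. Estimates
    plastidial pool sizes from total pools and final labeling fractions
    referenced to isoprene. Analyses HDR ((E)-4-hydroxy-3-methylbut-2-enyl
    diphosphate reductase) progress-curve assays: initial velocities from
    exponential (Box-Lucas) fits, Michaelis-Menten and Lineweaver-Burk
    parameter estimation, kcat and catalytic efficiency, and DMADP:IDP
    product ratios. Includes a stoichiometric calculator for DMADP/IDP
    demand of prenyl diphosphate product profiles, seeded synthetic-data
    generators emulating PTR-MS and LC-MS/MS inputs, CSV readers/writers
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
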