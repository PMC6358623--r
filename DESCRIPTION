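Package: roadzone
Title: Road-Effect Zones and Structural Equation Models for Wildlife Sign Densities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates road-effect zones from georeferenced wildlife sign
    records by comparing sign densities in distance ring buffers around a
    road network against rigid-motion (shift-and-rotate) randomized copies
    of the same buffer sections, using paired Wilcoxon signed-rank tests
    per ring. Decomposes direct and indirect road effects on sign density
    with a covariance-based structural equation model containing a latent
    land-cover factor, including maximum-likelihood estimation, chi-square
    and RMSEA fit indices, standardized solutions, and a stepwise
    indicator-removal procedure. A seeded synthetic-landscape generator
    (classed road networks, smooth elevation fields, road-dependent land
    cover, and inhomogeneous Poisson sign points with a known suppression
    zone) provides ground-truthed inputs for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
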