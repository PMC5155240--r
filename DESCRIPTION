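Package: nsatcn
Title: Nitrogen Saturation in a Coupled Carbon-Nitrogen Ecosystem Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A point-scale coupled carbon-nitrogen terrestrial ecosystem
    simulator with an explicit nitrogen-saturation mechanism. Soil mineral
    nitrogen controls plant production, nitrogen immobilization and soil
    organic matter mineralization through three multiplicative modifiers
    that decline once mineral nitrogen exceeds a site-specific saturation
    threshold derived from empirical nitrogen critical loads. The package
    provides a seeded synthetic forcing generator (monthly climate, annual
    CO2 and nitrogen-deposition trajectories), a vegetation-type by region
    critical-load table with fill rules and saturation classification, a
    three-stage spin-up/transient simulation protocol, and a six-scenario
    factorial experiment design for attributing NPP and NEP responses to
    climate, CO2 and nitrogen-deposition drivers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
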