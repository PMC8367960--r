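Package: bugyal
Title: Evaluation Toolkit for Eco-Restoration of Himalayan Alpine Meadows
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative evaluation of eco-restoration interventions in
    high-altitude alpine and subalpine pastures (bugyals). Implements quadrat
    vegetation analytics (density, frequency, abundance, dominant communities),
    rangeland forage yield and grazing capacity in cow units, physical and real
    tourist carrying capacity with weather-derived correction factors,
    check-dam sediment retention accounting from core bulk densities, and a
    multi-criteria restoration success scorecard over direct management,
    environmental desirability and socio-economic feasibility variables.
    Includes a seeded synthetic-data generator emulating the statistical
    structure of field surveys so every stage of the pipeline is testable
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
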