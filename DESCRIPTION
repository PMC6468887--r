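Package: sugarsim
Title: Health Impact Simulation of Population Sugar Reduction Programmes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the health impact of a population-level sugar reduction
    programme applied to individual-level diet-diary records. Applies three
    reduction mechanisms (reformulation, portion size reduction, sales
    weighting) to food items by category, converts the resulting calorie
    changes into weight and body mass index changes for children (trial-based
    sugar coefficient) and adults (Christiansen-Garby energy balance model),
    and propagates adult BMI changes through a proportional multistate
    lifetable to estimate disease cases averted, quality-adjusted life years,
    and healthcare costs with Monte Carlo uncertainty intervals. Includes a
    synthetic diet-survey generator so the full pipeline runs without access
    to restricted survey microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, knitr, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
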