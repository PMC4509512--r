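Package: soilngas
Title: Daily Simulation of Soil Nitrification, Denitrification and
    Nitrogenous Gas Emissions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A standalone daily-time-step simulator of microbial nitrogen
    transformation and nitrogenous gas (NO, N2O, N2) emission from a layered
    soil profile. Autotrophic nitrifier and heterotrophic denitrifier
    populations are modelled with explicit growth, death and maintenance
    kinetics; the four-step denitrification reduction chain
    (NO3- -> NO2- -> NO -> N2O -> N2) uses competitive Michaelis-Menten
    electron-acceptor kinetics inside an anaerobic soil fraction controlled
    by water-filled pore space. Includes environmental response functions
    (Q10 temperature, moisture, substrate, pH), a management-event engine
    for fertiliser and slurry applications, an exact nitrogen mass-balance
    ledger, a seven-statistic model-evaluation suite with a differential
    evolution calibration harness, and a reproducible synthetic forcing
    generator emulating a temperate grassland.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
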