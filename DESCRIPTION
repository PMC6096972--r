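Package: mpsorb
Title: pH-Dependent Sorption of Ionizable Pollutants to Microplastics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Model-based analysis of pH-dependent equilibrium sorption of
    ionizable organic pollutants (pharmaceuticals, pesticides, personal-care
    compounds) to microplastic particles such as polyethylene and polystyrene.
    Computes acid/base speciation from the Henderson-Hasselbalch equation,
    derives overall distribution coefficients from batch mass balance,
    estimates species-specific partition coefficients by non-negative linear
    least squares, screens estimates against an analytical-uncertainty error
    model tied to the liquid-to-solid ratio, and maps equilibrium dissolved
    fractions in multi-sorbent (organic carbon plus plastic) water bodies.
    Includes a seeded synthetic batch-experiment generator so the full
    pipeline is testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
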