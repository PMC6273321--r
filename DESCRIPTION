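Package: lipoannot
Title: Accurate-Mass Annotation of Aconitane Lipo-Alkaloids from LC-MS/MS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identification engine for lipo-alkaloids, the fatty-acid esters of
    C19-norditerpenoid (aconitane) alkaloids found in Aconitum species.
    Builds a combinatorial accurate-mass compound database by composing
    aconitane skeletons with an enumerated fatty-acid side-chain space,
    predicts diagnostic MS/MS fragment ions from a rule-based neutral-loss
    grammar (methanol, water, carbon monoxide, benzoic and acetic acid
    losses driven by skeleton substitution flags), matches MS1 features and
    MS/MS spectra against the database to classify the skeleton and infer
    the side chain, and assigns hydroxyl positions of oxygenated fatty
    acids from negative-mode spectra. Includes a seeded synthetic-spectrum
    generator and MGF input/output so the whole pipeline can be exercised
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
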