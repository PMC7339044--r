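Package: prioplan
Title: Wish-List Driven Lexicographic Radiotherapy Planning and
    Coverage-Toxicity Trade-Off Exploration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Automated generation of prostate radiotherapy treatment plans
    by prioritized (lexicographic) constrained convex optimization of
    beamlet weights against a declarative wish-list of hard constraints
    and goal-valued objectives. Includes a seeded synthetic pelvic phantom
    generator with a simplified beamlet dose-influence model, planning
    structure derivation (PTV margins, rectum PRV, conformality shells),
    dose-volume and gEUD/EQD2/LTCP dosimetry, a logistic NTCP model for
    grade >= 2 late gastro-intestinal toxicity with diabetes as a
    non-dosimetric predictor, and a per-patient seven-plan workflow that
    maps the trade-off between low-dose target coverage and predicted
    toxicity.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
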