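Package: ageflow
Title: Rule-Based Forensic Age-of-Majority Assessment and Cohort Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements a step-wise, rule-based model for deciding whether a
    young person without identity documents has reached 18 years of age,
    combining Tanner staging of secondary sexual characteristics, root
    maturation of the seven left mandibular teeth, Cameriere's third molar
    maturity index (I3M) with its 0.08 and 0.15 cut-offs, and Schmeling
    staging of the medial clavicular epiphysis, emitting the branch-specific
    adult probabilities (99.9, 96, 60 and 16 percent) together with a full
    audit trail of the decision path. Also provides exact polygon-union
    geometry for the carpal Bo/Ca skeletal maturity ratio, a seeded synthetic
    maturation-cohort simulator honouring the published population constraints
    (hand maturity complete by 16, seven-teeth maturity by 17, clavicle fusion
    never before 19), Monte-Carlo calibration of the simulator against the
    published conditional probabilities, Wilson-interval branch-probability
    estimation, misclassification accounting, and CSV/JSON readers, writers
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
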