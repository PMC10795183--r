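Package: medequip
Title: Multi-Criteria Replacement Prioritization for Large Medical Equipment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deciding which items of large medical equipment
    (MRI scanners and similar capital devices) a hospital should replace
    first.  Computes a nine-indicator usage/benefit profile (operating
    saturation, utilization, work intensity, patient waiting and
    inter-exam intervals, life index, failure count, cost-benefit ratio,
    payback period) from operational logs; derives indicator weights from
    expert panels via the combined ordered weighted averaging (COWA)
    operator, from the data via principal component analysis, and fuses
    the two by game-theoretic combination weighting; ranks equipment with
    a gray relational analysis / TOPSIS fusion score, with plain GRA,
    plain TOPSIS and VIKOR comparators and a Kendall-W concordance check
    across methods.  Includes a synthetic workload generator with known
    ground truth and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
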