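Package: admixscan
Title: Ancestry Enrichment Scans for Admixture-Enabled Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects admixture-enabled selection in recently admixed
    populations from local-ancestry haplotype calls. Computes gene-level
    ancestry fractions and enrichment z-scores per population, combines
    evidence across populations with Fisher's combined probability test,
    builds admixture null distributions by gene-wise multinomial draws and
    by Wright-Fisher forward simulation with recombination, tests polygenic
    ancestry enrichment against size-matched permutation nulls, and infers
    selection coefficients with a tri-allelic recursive selection model.
    Includes a synthetic local-ancestry cohort generator with known ground
    truth so the full screen can be validated without external data.
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
    jsonlite,
    withr
Config/testthat/edition: 3
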