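Package: prioritize
Title: Crowd-Sourced Priority Setting with Weighted-Vote Scoring and
    Expert Agreement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements the scoring and ranking stage of CHNRI-style
    crowd-sourced priority setting for patient safety: collated problem
    and solution statements are scored by a panel of clinicians against
    weighted-vote criteria (Yes = 1, No = 0, Unsure = 0.5, blank =
    Unaware), aggregated into per-criterion intermediate scores and
    composite priority scores on a 0-100 scale, and ranked.  Scorer
    consensus is quantified per suggestion with the Average Expert
    Agreement (AEA), the mean across criteria of the fraction of scorers
    giving the modal response.  Includes validated readers and writers
    for scoring-sheet, catalogue and criterion-set artifacts, ranked
    report rendering, and a synthetic-respondent generator with
    closed-form expectations for testing scoring pipelines when raw
    sheets are unavailable.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
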