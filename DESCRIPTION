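Package: collocr
Title: Windowed Collocation and Concordance Analysis for Text Corpora
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds positional indexes over collections of full-text articles
    (JATS/NLM XML or plain text), extracts windowed collocates of a target
    term scored with the Dunning log-likelihood (G2) association statistic,
    and produces keyword-in-context concordances, exact phrase frequencies,
    and modifier profiles. Includes a synthetic-corpus generator with a
    Zipfian background vocabulary and planted collocations at controlled
    association strengths, so every stage of the pipeline can be exercised
    and calibrated without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
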