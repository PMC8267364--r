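Package: ltcdiscovery
Title: ABC Literature-Based Discovery with Linking Term Count Ranking
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An open-discovery literature-based discovery (LBD) pipeline over
    concept-annotated document streams. Builds a symmetric windowed
    co-occurrence matrix of UMLS-style concept identifiers (CUIs), links a
    start (A) term to a restricted set of linking (B) terms, expands to
    candidate target (C) terms, filters candidates by co-occurrence count and
    semantic type, and ranks them by Linking Term Count (LTC): the number of
    unique B terms shared with A. Includes a synthetic corpus generator that
    plants prescribed pairwise co-occurrence counts, packaged fixtures
    encoding a published metabolite/cardiac-arrest worked example, and
    reporting in the ranked-list, histogram, and threshold-listing formats
    used in that study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    yaml,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
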