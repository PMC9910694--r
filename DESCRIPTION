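Package: amrcode
Title: Classification and Coding of Human-Disease Animal-Model Resource Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A registry, codec and retrieval toolkit for hierarchical
    classification codes of human-disease animal-model resources. Holds the
    controlled vocabularies of the three trunk dimensions (system disease,
    animal species, modeling method) and the essential-attribute branch
    (cooperation, sharing, preservation); encodes model records to canonical
    CSTR09 code strings and decodes and validates them; parses national
    science-and-technology resource identifiers; searches coded catalogs by
    per-digit wildcard patterns and by the keyword field-AND baseline; and
    generates seeded synthetic catalogs with skewed cell occupancy so the
    retrieval-efficiency gain of code-based search over keyword search can be
    benchmarked without access to the live national database.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
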