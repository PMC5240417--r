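Package: hybridmode
Title: Expression Inheritance Classification for F1 Hybrid Transcriptome Trios
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing the transcriptome of an F1 hybrid with those of
    its two parents from de novo assemblies. Provides unigene selection from
    transcript clusters (FPKM and ortholog-evidence retention with
    longest-isoform representatives), three-species ortholog-group integration
    with singleton zero-filling, negative-binomial differential-expression
    testing (exact conditional and Wald tests with a dual-test consensus rule),
    classification of differentially expressed genes into additive, dominant,
    incomplete-dominant and transgressive inheritance modes relative to the
    mid-parent value, summary tables, and a seeded negative-binomial simulator
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
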