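Package: litlevels
Title: Mapping Target-Disease Literature Evidence onto Biological Levels of Study
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for triaging literature evidence fragments that link therapeutic
    targets to diseases, and for mapping each fragment onto the biological level at
    which the association was studied (DNA/RNA, protein, or metabolite). Provides
    annotation-based filtering of candidate fragments, dictionary-term screening with
    whole-word exceptions and match highlighting, diversity-maximising review-sample
    selection by a fixed-size-subset genetic algorithm over cosine similarities,
    three-question manual-review bookkeeping with term-answer association tables,
    per-category Bernoulli naive Bayes classifiers evaluated by stratified
    cross-validated balanced accuracy, and summary reporting. A seeded synthetic-corpus
    generator with known ground truth makes every pipeline stage testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
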