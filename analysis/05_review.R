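#!/usr/bin/env Rscript
# Stage 5: manual review (simulated) and term-answer associations.
#
# On synthetic data the planted ground truth plays the role of the reviewer
# consensus: question 3 (is the level of study mentioned?) follows the
# planted validity and decides validation. Per-category validation
# percentages and term-answer association tables (with the ten most
# positively and ten most negatively associated terms) are written.

suppressPackageStartupMessages(library(litlevels))

truth <- read.delim("scratch/truth.tsv", stringsAsFactors = FALSE)
hits <- read.delim("scratch/screen_hits.tsv", stringsAsFactors = FALSE)

reviews <- do.call(rbind, lapply(level_categories(), function(cat) {
  ids <- readLines(sprintf("results/review_sample_%s.tsv", cat))[-1]
  reviews_from_truth(truth, ids, cat)
}))
write_reviews(reviews, "results/review_records.csv")

s <- summarize_reviews(reviews)
write.table(s, "results/review_summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
for (i in seq_len(nrow(s))) {
  message(sprintf("%-10s reviewed %d: %.1f%% validated, %.1f%% false positives",
                  s$category[i], s$n_reviewed[i], s$pct_validated[i],
                  s$pct_invalidated[i]))
}

assoc <- term_associations(reviews, hits)
write.table(assoc, "results/term_associations.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
for (cat in level_categories()) {
  a <- assoc[assoc$category == cat, , drop = FALSE]
  if (!nrow(a)) next
  rk <- rank_terms(a, 10)
  message(cat, ": most positively associated terms: ",
          paste(utils::head(rk$top_positive$term, 5), collapse = ", "), " ...")
}
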