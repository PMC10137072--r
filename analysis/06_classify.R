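#!/usr/bin/env Rscript
# Stage 6: automated review.
#
# One Bernoulli naive Bayes classifier per category is trained on the
# manual-review labels (validated = positive, others negative, within the
# category's review sample), assessed by stratified 5-fold cross-validated
# balanced accuracy, and applied to every screened fragment of its category.

suppressPackageStartupMessages(library(litlevels))

seed <- 1L
candidates <- read_evidence("scratch/candidates.jsonl")
hits <- read.delim("scratch/screen_hits.tsv", stringsAsFactors = FALSE)
reviews <- read_reviews("results/review_records.csv")

token_sets <- tokenize_distinct(candidates$text)
names(token_sets) <- candidates$fragment_id
screened <- lapply(stats::setNames(nm = level_categories()), function(cat) {
  unique(hits$fragment_id[hits$category == cat])
})

models <- list()
cv_rows <- list()
for (cat in level_categories()) {
  r <- reviews[reviews$screened_category == cat, ]
  cv <- nb_cross_validate(token_sets[r$fragment_id], r$validated,
                          folds = 5, seed = seed)
  cv_rows[[cat]] <- data.frame(category = cat,
                               mean_balanced_accuracy = cv$mean_balanced_accuracy)
  message(sprintf("%-10s 5-fold CV balanced accuracy %.3f", cat,
                  cv$mean_balanced_accuracy))
  models[[cat]] <- nb_fit(token_sets[r$fragment_id], r$validated)
  nb_to_json(models[[cat]], sprintf("scratch/nb_model_%s.json", cat))
}
write.table(do.call(rbind, cv_rows), "results/cv_report.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cls <- classify_corpus(models, screened, candidates)
write.table(cls$summary, "results/classification_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(cls$predictions, "scratch/predictions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
for (i in seq_len(nrow(cls$summary))) {
  message(sprintf("%-10s confirmed %d / %d screened (%.1f%% unrelated)",
                  cls$summary$category[i], cls$summary$confirmed_count[i],
                  cls$summary$n_screened[i],
                  100 * cls$summary$unrelated_count[i] /
                    cls$summary$n_screened[i]))
}
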