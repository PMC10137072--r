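#!/usr/bin/env Rscript
# Stage 4: pick the manual-review sample.
#
# For each screened category, 200 fragments are chosen to maximize their
# diversity: a fixed-size-subset genetic algorithm minimizes the summed
# pairwise cosine similarity of whole-fragment texts plus matched-term
# profiles. Review forms (bracket-highlighted text + the three questions)
# are exported for each category.

suppressPackageStartupMessages(library(litlevels))

seed <- 1L
candidates <- read_evidence("scratch/candidates.jsonl")
hits <- read.delim("scratch/screen_hits.tsv", stringsAsFactors = FALSE)
dtm <- build_dtm(candidates$text, candidates$fragment_id)

selected_all <- character(0)
for (cat in level_categories()) {
  ids <- unique(hits$fragment_id[hits$category == cat])
  h <- hits[hits$category == cat, , drop = FALSE]
  term_dtm <- build_dtm(lapply(ids, function(id) h$term[h$fragment_id == id]),
                        ids)
  res <- select_diverse(ids, cosine_matrix(dtm[ids, , drop = FALSE]),
                        cosine_matrix(term_dtm),
                        selection_config(k = 200, seed = seed,
                                         generations = 50))
  write_selection(res, sprintf("results/review_sample_%s.tsv", cat),
                  sprintf("scratch/ga_trace_%s.tsv", cat))
  sel_frags <- candidates[match(res$selected, candidates$fragment_id), ]
  export_review_forms(sel_frags, h[h$fragment_id %in% res$selected, ],
                      sprintf("scratch/review_forms_%s.txt", cat))
  message(sprintf("%-10s selected %d/%d fragments, objective %.2f", cat,
                  length(res$selected), length(ids), res$objective))
  selected_all <- c(selected_all, res$selected)
}
message("review sample: ", length(selected_all), " fragments total")
writeLines(selected_all, "scratch/review_sample_ids.txt")
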