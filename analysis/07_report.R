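#!/usr/bin/env Rscript
# Stage 7: final summary.
#
# Combines screening counts (raw and dictionary-size-adjusted), the manual
# review summary and the automated-review partition into the run's summary
# report, and checks recovered quantities against the generator's planted
# ground truth.

suppressPackageStartupMessages(library(litlevels))

dict <- default_dictionary()
screen <- read_report("results/screen_counts.tsv")
cls <- read.delim("results/classification_summary.tsv", stringsAsFactors = FALSE)
revs <- read.delim("results/review_summary.tsv", stringsAsFactors = FALSE)
truth <- read.delim("scratch/truth.tsv", stringsAsFactors = FALSE)

counts <- stats::setNames(screen$raw_count, screen$category)
report <- category_report(counts, dict, cls)
render_reports(report, "results/final_report.tsv", "results/final_report.txt",
               review_summary = revs)
message(paste(readLines("results/final_report.txt"), collapse = "\n"))

planted_fp <- mean(!truth$planted_valid[truth$category != "none" &
                                          !truth$is_duplicate])
message(sprintf(
  "\nplanted false-positive rate %.1f%%; review estimate %.1f%%; %s",
  100 * planted_fp, mean(revs$pct_invalidated),
  sprintf("automated review flags %.1f%% unrelated",
          100 * sum(cls$unrelated_count) / sum(cls$n_screened))))
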