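#!/usr/bin/env Rscript
# Stage 2: identify candidate fragments.
#
# Reads the evidence stream, removes duplicate records, filters the
# annotation records by the ten selection criteria, and keeps only the
# fragments whose (target gene, PMID) pair is backed by a surviving
# high-quality annotation.

suppressPackageStartupMessages(library(litlevels))

fragments <- read_evidence("scratch/corpus.jsonl")
message("read ", nrow(fragments), " fragments (",
        attr(fragments, "skipped"), " malformed lines skipped)")

unique_frags <- deduplicate_fragments(fragments)
message("deduplication removed ", attr(unique_frags, "n_removed"),
        " records; retained ",
        round(100 * nrow(unique_frags) / nrow(fragments), 1), "%")

annotations <- read_annotations("scratch/annotations.tsv")
accepted <- filter_annotations(annotations)
excl <- attr(accepted, "exclusions")
message("accepted ", nrow(accepted), " (gene, PMID) pairs; exclusions by criterion:")
for (nm in names(excl)) message(sprintf("  %-28s %d", nm, excl[[nm]]))
write_accepted_pairs(accepted, "scratch/accepted_pairs.tsv")

candidates <- join_candidates(unique_frags, accepted)
write_evidence(candidates, "scratch/candidates.jsonl")
message(nrow(candidates), " candidate fragments retained for screening")
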