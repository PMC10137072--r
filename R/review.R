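#' Assemble manual-review records
#'
#' One record per reviewed fragment: the category it was screened into and
#' the answers to the three review questions — (1) does the fragment allow
#' judging the category of the experimental method, (2) are the highlighted
#' terms sufficient to judge it, (3) is the specific level of study mentioned
#' in the fragment. The consensus validity of the screened category
#' (`validated`) is judged from question 3, so `validated` implies `q3`.
#'
#' @param fragment_id,screened_category,q1,q2,q3 Parallel vectors.
#' @param validated Consensus decision; defaults to `q3`.
#' @return data.frame of review records.
#' @export
review_records <- function(fragment_id, screened_category, q1, q2, q3,
                           validated = q3) {
  if (any(validated & !q3)) {
    stop("a fragment cannot be validated when question 3 is answered 'no'")
  }
  data.frame(fragment_id = as.character(fragment_id),
             screened_category = as.character(screened_category),
             q1_method_category_judgeable = as.logical(q1),
             q2_terms_sufficient = as.logical(q2),
             q3_level_mentioned = as.logical(q3),
             validated = as.logical(validated),
             stringsAsFactors = FALSE)
}

#' Summarize manual-review outcomes per category
#'
#' @param records Review-record data.frame from [review_records()].
#' @return data.frame with one row per category present in the records:
#'   `category`, `n_reviewed`, `n_validated`, `n_invalidated`,
#'   `pct_validated`, `pct_invalidated` (percentages sum to 100 per row).
#' @export
summarize_reviews <- function(records) {
  cats <- intersect(level_categories(), unique(records$screened_category))
  out <- do.call(rbind, lapply(cats, function(cat) {
    r <- records[records$screened_category == cat, , drop = FALSE]
    n_val <- sum(r$validated)
    data.frame(category = cat,
               n_reviewed = nrow(r),
               n_validated = n_val,
               n_invalidated = nrow(r) - n_val,
               pct_validated = 100 * n_val / nrow(r),
               pct_invalidated = 100 * (nrow(r) - n_val) / nrow(r),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Tabulate term-answer associations from reviewed fragments
#'
#' For every dictionary term matched in a reviewed fragment (within the
#' fragment's screened category), counts how many reviews answered
#' positively versus negatively. The default "positive answer" is the
#' conjunction of questions 1 and 2 (the fragment is judgeable AND the
#' highlighted terms suffice); per-question counts are also emitted so
#' either single-question reading stays recoverable.
#'
#' @param records Review-record data.frame.
#' @param hits Screening-hit data.frame (from [screen_corpus()]), covering
#'   at least the reviewed fragments.
#' @return data.frame: `term`, `category`, `positive_count`,
#'   `negative_count`, `q1_positive`, `q2_positive`, `total`. Terms never
#'   matched in a reviewed fragment are absent.
#' @export
term_associations <- function(records, hits) {
  key <- paste(hits$fragment_id, hits$category, sep = "\r")
  rkey <- paste(records$fragment_id, records$screened_category, sep = "\r")
  h <- hits[key %in% rkey, , drop = FALSE]
  # a term counts once per fragment it matched in
  h <- h[!duplicated(h[, c("fragment_id", "category", "term")]), , drop = FALSE]
  if (!nrow(h)) {
    return(data.frame(term = character(0), category = character(0),
                      positive_count = integer(0), negative_count = integer(0),
                      q1_positive = integer(0), q2_positive = integer(0),
                      total = integer(0)))
  }
  ridx <- match(paste(h$fragment_id, h$category, sep = "\r"), rkey)
  pos <- records$q1_method_category_judgeable[ridx] &
    records$q2_terms_sufficient[ridx]
  agg <- stats::aggregate(
    cbind(positive_count = as.integer(pos),
          negative_count = as.integer(!pos),
          q1_positive = as.integer(records$q1_method_category_judgeable[ridx]),
          q2_positive = as.integer(records$q2_terms_sufficient[ridx]),
          total = 1L),
    by = list(term = h$term, category = h$category), FUN = sum)
  agg <- agg[order(agg$category, agg$term), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Rank terms by prevalence of positive and negative review answers
#'
#' Returns the top-`n` terms by positive-answer prevalence and the top-`n`
#' by negative-answer prevalence (prevalence = count / total). Ties are
#' broken by larger total count, then lexicographically by term. With few
#' terms the two lists may be forced to overlap.
#'
#' @param assocs Association data.frame from [term_associations()] (one
#'   category at a time is the usual call).
#' @param n Number of terms per list.
#' @return List with data.frames `top_positive` and `top_negative`.
#' @export
rank_terms <- function(assocs, n) {
  stopifnot(n >= 1)
  rank_by <- function(count) {
    prev <- count / assocs$total
    ord <- order(-prev, -assocs$total, assocs$term)
    out <- assocs[ord[seq_len(min(n, nrow(assocs)))], , drop = FALSE]
    out$prevalence <- prev[ord[seq_len(nrow(out))]]
    rownames(out) <- NULL
    out
  }
  list(top_positive = rank_by(assocs$positive_count),
       top_negative = rank_by(assocs$negative_count))
}

#' Write review records to CSV / read them back
#' @param records Review-record data.frame.
#' @param path File path.
#' @export
write_reviews <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_reviews
#' @export
read_reviews <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("q1_method_category_judgeable", "q2_terms_sufficient",
                "q3_level_mentioned", "validated")) {
    df[[col]] <- as.logical(df[[col]])
  }
  df
}

#' Export review forms for an external labeling tool
#'
#' Writes, for each fragment to review, the bracket-highlighted text followed
#' by the three review questions, as plain text blocks separated by blank
#' lines — the content a labeling web form would present.
#'
#' @param fragments Evidence fragments to review.
#' @param hits Screening hits covering them.
#' @param path Output text file.
#' @export
export_review_forms <- function(fragments, hits, path) {
  questions <- c(
    "1. Does the text fragment allow us to judge the category of the experimental method?",
    "2. Are highlighted terms sufficient to judge the category of experimental method?",
    "3. Is the specific level of the study mentioned in the text fragment?")
  blocks <- vapply(seq_len(nrow(fragments)), function(i) {
    h <- hits[hits$fragment_id == fragments$fragment_id[i], , drop = FALSE]
    paste(c(paste0("## ", fragments$fragment_id[i]),
            highlight_fragment(fragments$text[i], h, fragments$target_name[i]),
            questions), collapse = "\n")
  }, character(1))
  writeLines(paste(blocks, collapse = "\n\n"), path, useBytes = TRUE)
  invisible(path)
}
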