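#' Adjust raw category counts by dictionary size
#'
#' Dividing each category's raw fragment count by the number of terms in the
#' corresponding dictionary category makes categories with dictionaries of
#' different sizes comparable.
#'
#' @param raw Named numeric vector of raw counts per category.
#' @param dict A `level_dictionary` (or a named vector of term counts).
#' @return Named numeric vector `raw / term_count`, over `names(raw)`.
#' @export
adjust_counts <- function(raw, dict) {
  term_counts <- if (inherits(dict, "level_dictionary")) {
    dict$term_count_by_category
  } else {
    dict
  }
  if (any(term_counts[names(raw)] <= 0) || any(is.na(term_counts[names(raw)]))) {
    stop("every category needs a positive dictionary term count")
  }
  raw / term_counts[names(raw)]
}

#' Assemble the per-category summary report
#'
#' @param screen_counts Named integer vector of screened fragment counts.
#' @param dict A `level_dictionary`.
#' @param classification Optional `summary` data.frame from
#'   [classify_corpus()] (adds confirmed/unrelated counts).
#' @return data.frame: `category`, `raw_count`, `term_count`,
#'   `adjusted_count`, and when available `confirmed_count`,
#'   `unrelated_count`.
#' @export
category_report <- function(screen_counts, dict, classification = NULL) {
  cats <- names(screen_counts)
  out <- data.frame(
    category = cats,
    raw_count = as.integer(screen_counts),
    term_count = as.integer(dict$term_count_by_category[cats]),
    adjusted_count = as.numeric(adjust_counts(screen_counts, dict)),
    stringsAsFactors = FALSE
  )
  if (!is.null(classification)) {
    idx <- match(out$category, classification$category)
    out$confirmed_count <- classification$confirmed_count[idx]
    out$unrelated_count <- classification$unrelated_count[idx]
  }
  rownames(out) <- NULL
  out
}

#' Render reports deterministically to TSV and a plain-text summary
#'
#' The TSV keeps full numeric precision and round-trips byte-identically
#' through [read_report()]; the text summary prints adjusted counts to two
#' decimals. Same inputs always produce byte-identical files.
#'
#' @param report data.frame from [category_report()].
#' @param tsv_path,txt_path Output paths (either may be NULL to skip).
#' @param review_summary Optional data.frame from [summarize_reviews()],
#'   folded into the text summary.
#' @return The report, invisibly.
#' @export
render_reports <- function(report, tsv_path = NULL, txt_path = NULL,
                           review_summary = NULL) {
  if (!is.null(tsv_path)) {
    fmt <- report
    fmt$adjusted_count <- sprintf("%.17g", fmt$adjusted_count)
    utils::write.table(fmt, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(txt_path)) {
    lines <- c("Level-of-study screening summary",
               "================================")
    for (i in seq_len(nrow(report))) {
      lines <- c(lines, sprintf(
        "%-10s raw=%d terms=%d adjusted=%.2f%s",
        report$category[i], report$raw_count[i], report$term_count[i],
        report$adjusted_count[i],
        if (!is.null(report$confirmed_count) &&
            !is.na(report$confirmed_count[i])) {
          sprintf(" confirmed=%d unrelated=%d", report$confirmed_count[i],
                  report$unrelated_count[i])
        } else ""))
    }
    if (!is.null(review_summary)) {
      lines <- c(lines, "", "Manual review", "-------------")
      for (i in seq_len(nrow(review_summary))) {
        lines <- c(lines, sprintf(
          "%-10s reviewed=%d validated=%.1f%% invalidated=%.1f%%",
          review_summary$category[i], review_summary$n_reviewed[i],
          review_summary$pct_validated[i], review_summary$pct_invalidated[i]))
      }
    }
    writeLines(lines, txt_path, useBytes = TRUE)
  }
  invisible(report)
}

#' Read back a report TSV written by [render_reports()]
#' @param path TSV path.
#' @return The report data.frame.
#' @export
read_report <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$adjusted_count <- as.numeric(df$adjusted_count)
  df
}
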