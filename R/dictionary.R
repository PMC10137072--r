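#' Load a method-term dictionary from TSV
#'
#' The dictionary assigns method terms to one of three levels of study:
#' `DNA_RNA`, `PROTEIN` or `METABOLITE`. Columns: `term` (matched
#' case-insensitively), `category`, `whole_word_only` (logical; TRUE for
#' short terms that would otherwise fire inside longer unrelated words, e.g.
#' "ria", "gag") and optionally `source_group` (the terminology grouping the
#' term came from).
#'
#' Duplicate (term, category) rows are collapsed with a warning; an unknown
#' category label is fatal and reports the offending row number.
#'
#' @param path Path to the dictionary TSV.
#' @return An object of class `level_dictionary`: list with `terms` (data
#'   frame) and `term_count_by_category` (named integer vector).
#' @export
load_dictionary <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("term", "category", "whole_word_only") %in% names(df)))
  bad <- which(!df$category %in% level_categories())
  if (length(bad)) {
    stop("unknown category label '", df$category[bad[1]], "' in dictionary row ",
         bad[1])
  }
  df$term <- tolower(trimws(df$term))
  if (any(!nzchar(df$term))) stop("empty dictionary term")
  df$whole_word_only <- as.logical(df$whole_word_only)
  if (!"source_group" %in% names(df)) df$source_group <- NA_character_
  dup <- duplicated(df[, c("term", "category")])
  if (any(dup)) {
    warning(sum(dup), " duplicate (term, category) dictionary row(s) collapsed")
    df <- df[!dup, , drop = FALSE]
  }
  rownames(df) <- NULL
  counts <- table(factor(df$category, levels = level_categories()))
  structure(
    list(terms = df,
         term_count_by_category = stats::setNames(as.integer(counts),
                                                  names(counts))),
    class = "level_dictionary"
  )
}

#' The three biological levels of study
#' @return Character vector `c("DNA_RNA", "PROTEIN", "METABOLITE")`.
#' @export
level_categories <- function() c("DNA_RNA", "PROTEIN", "METABOLITE")

#' The packaged default dictionary
#'
#' A curated dictionary built from the IUPAC bioanalytical-chemistry method
#' terminology groupings (Enzymatic / Immunoanalytical methods and Proteomics
#' map to `PROTEIN`; Genomics and Nucleic Acid Analysis to `DNA_RNA`;
#' Metabolomics, Glycomics and Lipidomics to `METABOLITE`), with short
#' ambiguous terms ("ria", "gag", "rna", "dna", ...) restricted to whole-word
#' matches.
#'
#' @return A `level_dictionary`.
#' @export
default_dictionary <- function() {
  load_dictionary(system.file("extdata", "method_terms.tsv",
                              package = "litlevels", mustWork = TRUE))
}

#' @export
print.level_dictionary <- function(x, ...) {
  cat("Method-term dictionary:", nrow(x$terms), "terms\n")
  print(x$term_count_by_category)
  invisible(x)
}

.word_boundary_pattern <- function(term) {
  # word characters are letters, digits and underscore, on case-folded text
  paste0("(?<![[:alnum:]_])",
         gsub("([^[:alnum:]_ ])", "\\\\\\1", term),
         "(?![[:alnum:]_])")
}

#' Screen a corpus of fragments against a dictionary
#'
#' A fragment belongs to a category when at least one of the category's terms
#' occurs in its text. Matching is case-insensitive; ordinary terms may occur
#' inside longer words, whole-word-only terms must be flanked by word
#' boundaries (transition between `[[:alnum:]_]` and anything else, or a
#' string edge). Membership is multi-label: a fragment may hit 0-3
#' categories.
#'
#' @param fragments Evidence fragment data.frame (`fragment_id`, `text`).
#' @param dict A `level_dictionary`.
#' @return List with `hits` (data.frame `fragment_id`, `category`, `term`,
#'   `start`, `end`; 0-based half-open character spans on the original text),
#'   `by_category` (named list of unique fragment-id vectors, input order)
#'   and `counts` (named integer vector of list lengths).
#' @export
screen_corpus <- function(fragments, dict) {
  text_low <- tolower(fragments$text)
  acc <- vector("list", nrow(dict$terms))
  for (i in seq_len(nrow(dict$terms))) {
    term <- dict$terms$term[i]
    m <- if (dict$terms$whole_word_only[i]) {
      gregexpr(.word_boundary_pattern(term), text_low, perl = TRUE)
    } else {
      gregexpr(term, text_low, fixed = TRUE)
    }
    hit_rows <- which(vapply(m, function(x) x[1] != -1L, logical(1)))
    if (!length(hit_rows)) next
    starts <- lapply(m[hit_rows], as.integer)
    lens <- lapply(m[hit_rows], function(x) attr(x, "match.length"))
    acc[[i]] <- data.frame(
      fragment_id = rep(fragments$fragment_id[hit_rows], lengths(starts)),
      category = dict$terms$category[i],
      term = term,
      start = unlist(starts) - 1L,
      end = unlist(starts) - 1L + unlist(lens),
      stringsAsFactors = FALSE
    )
  }
  hits <- do.call(rbind, acc)
  if (is.null(hits)) {
    hits <- data.frame(fragment_id = character(0), category = character(0),
                       term = character(0), start = integer(0), end = integer(0))
  }
  # stable order: by fragment (input order), then span start
  ord <- order(match(hits$fragment_id, fragments$fragment_id), hits$start, hits$end)
  hits <- hits[ord, , drop = FALSE]
  rownames(hits) <- NULL

  by_category <- lapply(stats::setNames(nm = level_categories()), function(cat) {
    ids <- unique(hits$fragment_id[hits$category == cat])
    ids[order(match(ids, fragments$fragment_id))]
  })
  list(hits = hits,
       by_category = by_category,
       counts = vapply(by_category, length, integer(1)))
}

#' Screen a single fragment
#'
#' @param fragment One-row evidence fragment data.frame, or a list with
#'   `fragment_id` and `text`.
#' @inheritParams screen_corpus
#' @return The hit data.frame for this fragment (possibly zero rows).
#' @export
screen_fragment <- function(fragment, dict) {
  df <- data.frame(fragment_id = as.character(fragment$fragment_id),
                   text = as.character(fragment$text),
                   stringsAsFactors = FALSE)
  screen_corpus(df, dict)$hits
}

.merge_spans <- function(start, end) {
  # left-greedy merge of possibly overlapping spans; inputs sorted by start
  if (!length(start)) return(list(start = integer(0), end = integer(0)))
  ms <- start[1]; me <- end[1]
  out_s <- integer(0); out_e <- integer(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] < me) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  list(start = c(out_s, ms), end = c(out_e, me))
}

#' Mark up a fragment for manual review
#'
#' Wraps every occurrence of the biological entity's name in square brackets
#' and every matched dictionary-term span in curly brackets, e.g.
#' `"... an anti-acetyl lysine {antibody}, we identified [Aurora B] as an
#' acetylated {protein} ..."`. Overlapping term spans are merged
#' left-greedily; a term span overlapping an entity occurrence is dropped
#' (the entity wins). Stripping all bracket characters recovers the original
#' text whenever the text itself contains none.
#'
#' @param text Fragment text.
#' @param hits Hit data.frame for this fragment (from [screen_fragment()]).
#' @param target_name Entity name as written in the text (matched
#'   case-insensitively).
#' @return The annotated text.
#' @export
highlight_fragment <- function(text, hits, target_name) {
  low <- tolower(text)
  ent <- list(start = integer(0), end = integer(0))
  if (!is.null(target_name) && nzchar(target_name)) {
    m <- gregexpr(tolower(target_name), low, fixed = TRUE)[[1]]
    if (m[1] != -1L) {
      ent <- .merge_spans(as.integer(m) - 1L,
                          as.integer(m) - 1L + attr(m, "match.length"))
    }
  }
  trm <- list(start = integer(0), end = integer(0))
  if (nrow(hits)) {
    ord <- order(hits$start, hits$end)
    trm <- .merge_spans(hits$start[ord], hits$end[ord])
    keep <- vapply(seq_along(trm$start), function(i) {
      !any(trm$start[i] < ent$end & ent$start < trm$end[i])
    }, logical(1))
    trm <- list(start = trm$start[keep], end = trm$end[keep])
  }
  spans <- data.frame(
    start = c(ent$start, trm$start),
    end = c(ent$end, trm$end),
    open = c(rep("[", length(ent$start)), rep("{", length(trm$start))),
    close = c(rep("]", length(ent$start)), rep("}", length(trm$start))),
    stringsAsFactors = FALSE
  )
  if (!nrow(spans)) return(text)
  spans <- spans[order(spans$start), , drop = FALSE]
  out <- character(0)
  pos <- 0L # 0-based cursor
  for (i in seq_len(nrow(spans))) {
    out <- c(out,
             substr(text, pos + 1L, spans$start[i]),
             spans$open[i],
             substr(text, spans$start[i] + 1L, spans$end[i]),
             spans$close[i])
    pos <- spans$end[i]
  }
  paste0(paste(out, collapse = ""), substr(text, pos + 1L, nchar(text)))
}

#' Remove highlight markup
#' @param text Annotated text from [highlight_fragment()].
#' @return Text with all `[]{}` characters removed.
#' @export
strip_highlight <- function(text) gsub("[][{}]", "", text)

#' Write screening hits as TSV
#' @param hits Hit data.frame from [screen_corpus()].
#' @param path Output file path.
#' @export
write_hits <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
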