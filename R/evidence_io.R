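#' Default key names for Open-Targets-style evidence JSON Lines
#'
#' Maps the internal field names of an evidence fragment to the JSON keys
#' used in the input stream. Defaults follow the shape of Open Targets
#' `europepmc` literature evidence (one JSON object per line, carrying the
#' target's Ensembl gene ID, the target name as written in the text, the
#' disease identifier, the PubMed ID and the sentence itself).
#'
#' @return Named character vector mapping internal field -> JSON key.
#' @export
evidence_keys <- function(fragment_id = "id",
                          target_ensembl_id = "targetId",
                          target_name = "targetName",
                          disease_id = "diseaseId",
                          pmid = "pmid",
                          text = "text") {
  c(fragment_id = fragment_id,
    target_ensembl_id = target_ensembl_id,
    target_name = target_name,
    disease_id = disease_id,
    pmid = pmid,
    text = text)
}

#' Read literature evidence fragments from a JSON Lines stream
#'
#' Each line must be a standalone JSON object carrying a target gene ID, the
#' target name as written in the fragment, a disease ID, a PubMed ID and the
#' fragment text. Key names are configurable via [evidence_keys()]. Lines are
#' processed in chunks so arbitrarily large files can be streamed.
#'
#' Malformed lines (unparseable JSON, missing keys, empty text after
#' whitespace trimming) are skipped with a warning naming the line number;
#' the number of skipped lines is attached as attribute `"skipped"`.
#'
#' @param path Path to a JSON Lines file, or a connection.
#' @param keys Named character vector from [evidence_keys()].
#' @param chunk_size Number of lines read per chunk.
#' @return A data.frame of evidence fragments (columns `fragment_id`,
#'   `target_ensembl_id`, `target_name`, `disease_id`, `pmid`, `text`), input
#'   order preserved, with attribute `skipped` (integer count).
#' @export
read_evidence <- function(path, keys = evidence_keys(), chunk_size = 5000L) {
  con <- if (inherits(path, "connection")) path else {
    if (!file.exists(path)) stop("cannot read evidence stream: ", path)
    file(path, open = "r", encoding = "UTF-8")
  }
  if (!isOpen(con)) open(con, "r")
  on.exit(close(con), add = TRUE)

  fields <- names(evidence_keys())
  rows <- list()
  skipped <- 0L
  line_no <- 0L
  repeat {
    lines <- readLines(con, n = chunk_size, warn = FALSE)
    if (length(lines) == 0L) break
    for (ln in lines) {
      line_no <- line_no + 1L
      if (!nzchar(trimws(ln))) next
      rec <- tryCatch(jsonlite::fromJSON(ln), error = function(e) NULL)
      if (is.null(rec) || !is.list(rec)) {
        warning("skipping malformed JSON on line ", line_no, call. = FALSE)
        skipped <- skipped + 1L
        next
      }
      vals <- lapply(keys, function(k) rec[[k]])
      names(vals) <- fields
      bad <- vapply(vals, function(v) {
        is.null(v) || length(v) != 1L || is.na(v)
      }, logical(1))
      if (any(bad) || !nzchar(trimws(as.character(vals$text)))) {
        warning("skipping line ", line_no, ": missing or empty field(s): ",
                paste(fields[bad], collapse = ", "), call. = FALSE)
        skipped <- skipped + 1L
        next
      }
      rows[[length(rows) + 1L]] <- vapply(vals, as.character, character(1))
    }
  }
  out <- if (length(rows)) {
    as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  } else {
    as.data.frame(stats::setNames(rep(list(character(0)), length(fields)), fields))
  }
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Write evidence fragments as JSON Lines
#'
#' Inverse of [read_evidence()]; used by the synthetic-corpus generator to
#' emit corpora in the same dialect the pipeline consumes.
#'
#' @param fragments Evidence fragment data.frame.
#' @param path Output file path.
#' @param keys Named character vector from [evidence_keys()].
#' @export
write_evidence <- function(fragments, path, keys = evidence_keys()) {
  lines <- vapply(seq_len(nrow(fragments)), function(i) {
    rec <- as.list(fragments[i, names(keys), drop = FALSE])
    names(rec) <- unname(keys)
    jsonlite::toJSON(rec, auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

.dedup_key <- function(fragments) {
  norm_text <- gsub("[[:space:]]+", " ", trimws(tolower(fragments$text)))
  paste(norm_text, fragments$target_ensembl_id, fragments$disease_id, sep = "\r")
}

#' Remove duplicate evidence fragments
#'
#' Two fragments are duplicates when they agree on the case-folded,
#' whitespace-collapsed text, the target Ensembl gene ID and the disease ID.
#' The first occurrence is retained; order is otherwise preserved. The
#' operation is idempotent.
#'
#' @param fragments Evidence fragment data.frame.
#' @return The retained fragments, with attribute `n_removed`.
#' @export
deduplicate_fragments <- function(fragments) {
  keep <- !duplicated(.dedup_key(fragments))
  out <- fragments[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Selection criteria for protein-annotation records
#'
#' Encodes the record-selection rules used to restrict the evidence corpus to
#' articles cited as high-quality evidence for high-quality protein
#' annotations: protein-level existence, an allowed annotation hierarchy
#' group, GOLD annotation quality, no membership in cautionary categories, no
#' negative evidence, GOLD evidence quality, evidence type "publication", an
#' allowed evidence descriptor (ECO term), a present PubMed ID and a
#' one-to-one protein-to-Ensembl-gene mapping.
#'
#' @return A list of class `filter_criteria`.
#' @export
default_filter_criteria <- function() {
  structure(list(
    allowed_groups = c(
      "general-annotation; generic-function",
      "general-annotation",
      "general-annotation; generic-interaction",
      "general-annotation; medical"
    ),
    forbidden_categories = c("caution", "domain-info", "sequence-caution",
                             "variant-info"),
    allowed_eco_terms = c(
      "physical interaction evidence used in manual assertion",
      "experimental evidence used in manual assertion",
      "direct assay evidence used in manual assertion",
      "experimental evidence"
    ),
    required_annotation_quality = "GOLD",
    required_evidence_quality = "GOLD",
    required_evidence_type = "publication"
  ), class = "filter_criteria")
}

#' Names of the individual record-selection criteria, in printed order
#' @return Character vector of criterion identifiers, as used in the
#'   `exclusions` attribute of [filter_annotations()].
#' @export
filter_criterion_names <- function() {
  c("protein_level_existence", "allowed_group", "annotation_quality_gold",
    "forbidden_category", "no_negative_evidence", "evidence_quality_gold",
    "evidence_type_publication", "allowed_eco_term", "pmid_present",
    "single_ensembl_gene")
}

#' Filter protein-annotation records and emit accepted (gene, PMID) pairs
#'
#' A record passes only if every selection criterion holds; passing records
#' contribute their (Ensembl gene ID, PubMed ID) pair. Records carrying zero
#' or multiple Ensembl gene IDs are excluded outright (the one-to-one mapping
#' rule), never expanded. Per-criterion exclusion tallies are attached as
#' attribute `exclusions`: for each failing record every violated criterion
#' is tallied.
#'
#' @param records Annotation record data.frame as returned by
#'   [read_annotations()] or [generate_annotation_fixture()]: columns
#'   `protein_accession`, `ensembl_gene_ids` (list column or `;`-separated
#'   string), `protein_existence_level`, `annotation_group`,
#'   `annotation_category`, `annotation_quality`, `has_negative_evidence`,
#'   `evidence_quality`, `evidence_type`, `eco_terms` (list column or
#'   `;`-separated string), `pmid` (NA when absent).
#' @param criteria A `filter_criteria` list, see [default_filter_criteria()].
#' @return data.frame with columns `ensembl_gene_id`, `pmid` (unique pairs),
#'   with attribute `exclusions` (named integer vector over criteria).
#' @export
filter_annotations <- function(records, criteria = default_filter_criteria()) {
  genes <- .as_set_column(records$ensembl_gene_ids)
  ecos <- .as_set_column(records$eco_terms)
  pmid_chr <- as.character(records$pmid)

  ok <- cbind(
    protein_level_existence = records$protein_existence_level == "protein_level",
    allowed_group = records$annotation_group %in% criteria$allowed_groups,
    annotation_quality_gold =
      records$annotation_quality == criteria$required_annotation_quality,
    forbidden_category =
      !(records$annotation_category %in% criteria$forbidden_categories),
    no_negative_evidence = !records$has_negative_evidence,
    evidence_quality_gold =
      records$evidence_quality == criteria$required_evidence_quality,
    evidence_type_publication =
      records$evidence_type == criteria$required_evidence_type,
    allowed_eco_term = vapply(ecos, function(e) {
      length(e) > 0L && all(e %in% criteria$allowed_eco_terms)
    }, logical(1)),
    pmid_present = !is.na(pmid_chr) & nzchar(pmid_chr),
    single_ensembl_gene = lengths(genes) == 1L
  )
  ok[is.na(ok)] <- FALSE
  pass <- rowSums(ok) == ncol(ok)

  exclusions <- colSums(!ok[!pass, , drop = FALSE])
  pairs <- if (any(pass)) {
    unique(data.frame(
      ensembl_gene_id = vapply(genes[pass], `[`, character(1), 1L),
      pmid = pmid_chr[pass],
      stringsAsFactors = FALSE
    ))
  } else {
    data.frame(ensembl_gene_id = character(0), pmid = character(0))
  }
  rownames(pairs) <- NULL
  attr(pairs, "exclusions") <- exclusions
  pairs
}

.as_set_column <- function(x) {
  if (is.list(x)) {
    lapply(x, function(v) {
      v <- as.character(v)
      v[!is.na(v) & nzchar(v)]
    })
  } else {
    lapply(strsplit(ifelse(is.na(x), "", as.character(x)), ";", fixed = TRUE),
           function(v) {
             v <- trimws(v)
             v[nzchar(v)]
           })
  }
}

#' Read annotation records from JSON Lines or TSV
#'
#' TSV input carries the set-valued fields (`ensembl_gene_ids`, `eco_terms`)
#' as `;`-separated strings; JSON Lines input carries them as arrays.
#'
#' @param path Input file path.
#' @param format `"jsonl"` or `"tsv"`; guessed from the extension by default.
#' @return Annotation record data.frame with list columns for sets.
#' @export
read_annotations <- function(path, format = c("auto", "jsonl", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "tsv" else "jsonl"
  }
  if (format == "tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  } else {
    recs <- lapply(readLines(path, warn = FALSE), jsonlite::fromJSON)
    df <- do.call(rbind, lapply(recs, function(r) {
      data.frame(
        protein_accession = r$protein_accession,
        ensembl_gene_ids = paste(r$ensembl_gene_ids, collapse = ";"),
        protein_existence_level = r$protein_existence_level,
        annotation_group = r$annotation_group,
        annotation_category = r$annotation_category,
        annotation_quality = r$annotation_quality,
        has_negative_evidence = isTRUE(r$has_negative_evidence),
        evidence_quality = r$evidence_quality,
        evidence_type = r$evidence_type,
        eco_terms = paste(r$eco_terms, collapse = ";"),
        pmid = if (is.null(r$pmid)) NA_character_ else as.character(r$pmid),
        stringsAsFactors = FALSE
      )
    }))
  }
  df$ensembl_gene_ids <- .as_set_column(df$ensembl_gene_ids)
  df$eco_terms <- .as_set_column(df$eco_terms)
  df$has_negative_evidence <- as.logical(df$has_negative_evidence)
  df
}

#' Write accepted (gene, PMID) pairs as a two-column TSV
#' @param pairs data.frame from [filter_annotations()].
#' @param path Output file path.
#' @export
write_accepted_pairs <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Keep only fragments backed by an accepted (gene, PMID) pair
#'
#' Pools the evidence corpus with the annotation-derived whitelist: a
#' fragment is kept iff its (target Ensembl gene ID, PubMed ID) pair appears
#' among the accepted pairs. Output order follows input order; no fragment is
#' duplicated.
#'
#' @param fragments Evidence fragment data.frame.
#' @param accepted_pairs data.frame with columns `ensembl_gene_id`, `pmid`.
#' @return The retained fragments.
#' @export
join_candidates <- function(fragments, accepted_pairs) {
  wanted <- paste(accepted_pairs$ensembl_gene_id, accepted_pairs$pmid, sep = "\r")
  key <- paste(fragments$target_ensembl_id, fragments$pmid, sep = "\r")
  out <- fragments[key %in% wanted, , drop = FALSE]
  rownames(out) <- NULL
  out
}
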