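#' Configuration for the synthetic evidence-corpus generator
#'
#' The generator emulates the structural properties of a screened literature
#' corpus with fully known ground truth: fragments composed of background
#' vocabulary tokens; injected method terms that place a fragment in a
#' dictionary category; homograph traps (whole-word-only terms embedded
#' strictly inside longer words, which must never fire); planted review
#' validity with class-conditional context cues whose separability fixes the
#' Bayes-optimal balanced accuracy in closed form; and duplicated records.
#'
#' @param seed Integer seed; corpora are byte-reproducible given it.
#' @param n_per_category Fragments generated per dictionary category.
#' @param background_vocab_size Size of the synthetic background vocabulary.
#' @param term_injection_rate Probability that a category fragment actually
#'   receives a term of its category (fragments without one screen nowhere
#'   and carry truth category `"none"`).
#' @param homograph_rate Probability that a fragment additionally embeds a
#'   whole-word-only dictionary term inside a longer word.
#' @param false_positive_rate Probability that a term-carrying fragment is
#'   planted invalid (the term is used in a non-method sense).
#' @param duplicate_rate Expected fraction of the emitted corpus that are
#'   duplicate copies; implemented as per-fragment Bernoulli duplication
#'   with odds `d / (1 - d)`. Must be < 0.5.
#' @param separability Probability that a fragment carries a
#'   class-conditional context cue token (a "positive-context" token when
#'   valid, "negative-context" when invalid); cue-free fragments are
#'   distributed identically in both classes, so the Bayes-optimal balanced
#'   accuracy is exactly `(1 + separability) / 2` (see
#'   [bayes_optimal_ba()]).
#' @param fragment_length Integer `c(min, max)` background words per
#'   fragment.
#' @param n_cue_tokens Distinct cue tokens per context block.
#' @param n_genes,n_diseases Pool sizes for target genes and diseases.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L, n_per_category = 200L,
                             background_vocab_size = 150L,
                             term_injection_rate = 1,
                             homograph_rate = 0,
                             false_positive_rate = 0.4,
                             duplicate_rate = 0,
                             separability = 0.44,
                             fragment_length = c(8L, 15L),
                             n_cue_tokens = 4L,
                             n_genes = NULL, n_diseases = 20L) {
  probs <- c(term_injection_rate, homograph_rate, false_positive_rate,
             duplicate_rate, separability)
  stopifnot(all(probs >= 0), all(probs <= 1), duplicate_rate < 0.5,
            length(fragment_length) == 2,
            fragment_length[1] <= fragment_length[2],
            fragment_length[1] >= 1,
            background_vocab_size >= fragment_length[2],
            n_per_category >= 1)
  if (is.null(n_genes)) n_genes <- max(20L, as.integer(n_per_category / 5))
  structure(list(seed = as.integer(seed),
                 n_per_category = as.integer(n_per_category),
                 background_vocab_size = as.integer(background_vocab_size),
                 term_injection_rate = term_injection_rate,
                 homograph_rate = homograph_rate,
                 false_positive_rate = false_positive_rate,
                 duplicate_rate = duplicate_rate,
                 separability = separability,
                 fragment_length = as.integer(fragment_length),
                 n_cue_tokens = as.integer(n_cue_tokens),
                 n_genes = as.integer(n_genes),
                 n_diseases = as.integer(n_diseases)),
            class = "synthetic_config")
}

#' Bayes-optimal balanced accuracy planted by a generator configuration
#'
#' Valid fragments carry a positive-context cue with probability
#' `separability`, invalid ones a negative-context cue with the same
#' probability; cue-free fragments are identically distributed in both
#' classes. The optimal rule classifies by the cue when present, and no rule
#' can do better or worse in balanced accuracy on cue-free fragments (any
#' assignment of them shifts sensitivity and specificity by equal and
#' opposite amounts), so the optimum is `(1 + separability) / 2` — a
#' monotone function of the separation.
#'
#' @param cfg A `synthetic_config`.
#' @return Scalar balanced accuracy in `[0.5, 1]`.
#' @export
bayes_optimal_ba <- function(cfg) (1 + cfg$separability) / 2

.cue_tokens <- function(cfg) {
  list(pos = sprintf("cuepos%02d", seq_len(cfg$n_cue_tokens)),
       neg = sprintf("cueneg%02d", seq_len(cfg$n_cue_tokens)))
}

#' Generate a synthetic evidence corpus with known ground truth
#'
#' @param cfg A [synthetic_config()].
#' @param dict Dictionary whose terms are injected; defaults to the
#'   packaged one.
#' @return List with `fragments` (evidence data.frame, originals first,
#'   duplicate copies appended) and `truth` (data.frame `fragment_id`,
#'   `category` — `"none"` when no term was injected — `planted_valid`,
#'   `is_duplicate`).
#' @export
generate_corpus <- function(cfg, dict = default_dictionary()) {
  if (cfg$background_vocab_size < cfg$fragment_length[2]) {
    stop("background vocabulary smaller than the maximum fragment length")
  }
  bg <- sprintf("bkg%05d", seq_len(cfg$background_vocab_size))
  cues <- .cue_tokens(cfg)
  ww_terms <- dict$terms$term[dict$terms$whole_word_only]
  if (!length(ww_terms)) ww_terms <- "ria"
  genes <- sprintf("ENSG%011d", seq_len(cfg$n_genes))
  diseases <- sprintf("EFO_%07d", seq_len(cfg$n_diseases))

  withr::with_seed(cfg$seed, {
    n <- cfg$n_per_category
    cats <- rep(level_categories(), each = n)
    total <- length(cats)
    lens <- sample(seq(cfg$fragment_length[1], cfg$fragment_length[2]),
                   total, replace = TRUE)
    gene_i <- sample.int(cfg$n_genes, total, replace = TRUE)
    injected <- stats::runif(total) < cfg$term_injection_rate
    homo <- stats::runif(total) < cfg$homograph_rate
    valid <- injected & stats::runif(total) >= cfg$false_positive_rate
    cued <- stats::runif(total) < cfg$separability
    terms_by_cat <- lapply(stats::setNames(nm = level_categories()),
                           function(cat) dict$terms$term[dict$terms$category == cat])
    texts <- vapply(seq_len(total), function(i) {
      toks <- bg[sample.int(cfg$background_vocab_size, lens[i], replace = TRUE)]
      extras <- sprintf("TGT%04d", gene_i[i])
      if (injected[i]) {
        ct <- terms_by_cat[[cats[i]]]
        extras <- c(extras, ct[sample.int(length(ct), 1L)])
      }
      if (homo[i]) {
        extras <- c(extras, paste0("xx", ww_terms[sample.int(length(ww_terms), 1L)],
                                   "xx"))
      }
      if (cued[i]) {
        block <- if (valid[i]) cues$pos else cues$neg
        extras <- c(extras, block[sample.int(length(block), 1L)])
      }
      for (e in extras) {
        toks <- append(toks, e, after = sample.int(length(toks) + 1L, 1L) - 1L)
      }
      paste(toks, collapse = " ")
    }, character(1))
    fragments <- data.frame(
      fragment_id = sprintf("F%06d", seq_len(total)),
      target_ensembl_id = genes[gene_i],
      target_name = sprintf("TGT%04d", gene_i),
      disease_id = diseases[sample.int(cfg$n_diseases, total, replace = TRUE)],
      pmid = as.character(10000000L + sample.int(899999L, total, replace = TRUE)),
      text = texts,
      stringsAsFactors = FALSE)
    truth <- data.frame(
      fragment_id = fragments$fragment_id,
      category = ifelse(injected, cats, "none"),
      planted_valid = valid,
      is_duplicate = FALSE,
      stringsAsFactors = FALSE)

    if (cfg$duplicate_rate > 0) {
      p_dup <- cfg$duplicate_rate / (1 - cfg$duplicate_rate)
      dup_of <- which(stats::runif(nrow(fragments)) < p_dup)
      if (length(dup_of)) {
        copies <- fragments[dup_of, , drop = FALSE]
        copies$fragment_id <- paste0(copies$fragment_id, "d")
        fragments <- rbind(fragments, copies)
        tcopies <- truth[dup_of, , drop = FALSE]
        tcopies$fragment_id <- paste0(tcopies$fragment_id, "d")
        tcopies$is_duplicate <- TRUE
        truth <- rbind(truth, tcopies)
      }
    }
    rownames(fragments) <- rownames(truth) <- NULL
    list(fragments = fragments, truth = truth)
  })
}

#' Generate an annotation-record fixture exercising every filter criterion
#'
#' Emits one passing record per accepted (gene, PMID) pair plus, for each of
#' the selection criteria, exactly one record violating only that criterion
#' (its `protein_accession` is `VIOLATES_<criterion>`). Violators carry
#' gene/PMID values outside the passing set so they can never rescue a
#' fragment.
#'
#' @param pairs data.frame with columns `ensembl_gene_id`, `pmid`: the pairs
#'   the passing records must cover (e.g. unique pairs of a generated
#'   corpus).
#' @return Annotation-record data.frame (list columns for the set-valued
#'   fields) ready for [filter_annotations()].
#' @export
generate_annotation_fixture <- function(pairs) {
  pairs <- unique(pairs[, c("ensembl_gene_id", "pmid")])
  base <- function(accession, gene, pmid) {
    list(protein_accession = accession,
         ensembl_gene_ids = list(gene),
         protein_existence_level = "protein_level",
         annotation_group = "general-annotation; generic-function",
         annotation_category = "function",
         annotation_quality = "GOLD",
         has_negative_evidence = FALSE,
         evidence_quality = "GOLD",
         evidence_type = "publication",
         eco_terms = list("experimental evidence"),
         pmid = pmid)
  }
  passing <- lapply(seq_len(nrow(pairs)), function(i) {
    base(sprintf("NX_P%05d", i), pairs$ensembl_gene_id[i], pairs$pmid[i])
  })
  vgene <- "ENSG99999999999"
  vpmid <- "99999999"
  mutate <- function(field, value) {
    rec <- base("x", vgene, vpmid)
    rec[[field]] <- value
    rec
  }
  violators <- list(
    protein_level_existence = mutate("protein_existence_level", "other"),
    allowed_group = mutate("annotation_group", "sequence; topology"),
    annotation_quality_gold = mutate("annotation_quality", "SILVER"),
    forbidden_category = mutate("annotation_category", "caution"),
    no_negative_evidence = mutate("has_negative_evidence", TRUE),
    evidence_quality_gold = mutate("evidence_quality", "SILVER"),
    evidence_type_publication = mutate("evidence_type", "database"),
    allowed_eco_term = mutate(
      "eco_terms", list("sequence similarity evidence used in automatic assertion")),
    pmid_present = mutate("pmid", NA_character_),
    single_ensembl_gene = mutate("ensembl_gene_ids",
                                 list(c(vgene, "ENSG88888888888")))
  )
  stopifnot(identical(names(violators), filter_criterion_names()))
  for (nm in names(violators)) {
    violators[[nm]]$protein_accession <- paste0("VIOLATES_", nm)
  }
  recs <- c(passing, unname(violators))
  out <- data.frame(
    protein_accession = vapply(recs, `[[`, character(1), "protein_accession"),
    protein_existence_level = vapply(recs, `[[`, character(1),
                                     "protein_existence_level"),
    annotation_group = vapply(recs, `[[`, character(1), "annotation_group"),
    annotation_category = vapply(recs, `[[`, character(1), "annotation_category"),
    annotation_quality = vapply(recs, `[[`, character(1), "annotation_quality"),
    has_negative_evidence = vapply(recs, `[[`, logical(1),
                                   "has_negative_evidence"),
    evidence_quality = vapply(recs, `[[`, character(1), "evidence_quality"),
    evidence_type = vapply(recs, `[[`, character(1), "evidence_type"),
    pmid = vapply(recs, `[[`, character(1), "pmid"),
    stringsAsFactors = FALSE)
  out$ensembl_gene_ids <- lapply(recs, function(r) r$ensembl_gene_ids[[1]])
  out$eco_terms <- lapply(recs, function(r) r$eco_terms[[1]])
  out
}

#' Build review records from a truth table
#'
#' Plays the role of the consensus manual review on synthetic data: the
#' planted validity answers question 3 (is the level of study mentioned) and
#' determines the consensus; the fragment is always judgeable (question 1)
#' and the highlighted terms suffice exactly when the planted category is
#' genuine (question 2).
#'
#' @param truth Truth table from [generate_corpus()].
#' @param ids Fragment ids to review (e.g. a diversity selection).
#' @param category The screened category the review pertains to.
#' @return Review-record data.frame (see [review_records()]).
#' @export
reviews_from_truth <- function(truth, ids, category) {
  t <- truth[match(ids, truth$fragment_id), , drop = FALSE]
  review_records(fragment_id = t$fragment_id,
                 screened_category = category,
                 q1 = TRUE,
                 q2 = t$planted_valid,
                 q3 = t$planted_valid)
}

#' Write a generator configuration as a key-value text file, with its hash
#'
#' The file is `key = value` per line; the run log line includes the seed
#' and an FNV-1a hash of the canonical serialization, so any two runs with
#' identical configuration are identifiable.
#'
#' @param cfg A `synthetic_config`.
#' @param path Output path.
#' @return The configuration hash string, invisibly.
#' @export
write_config <- function(cfg, path) {
  vals <- vapply(cfg, function(v) paste(format(v, digits = 17), collapse = ","),
                 character(1))
  lines <- paste(names(cfg), "=", vals)
  h <- config_hash(cfg)
  writeLines(c(lines, paste("config_hash =", h)), path, useBytes = TRUE)
  invisible(h)
}

#' FNV-1a hash of a configuration's canonical serialization
#' @param cfg A `synthetic_config`.
#' @return Hex string.
#' @export
config_hash <- function(cfg) {
  s <- paste(names(cfg),
             vapply(cfg, function(v) paste(format(v, digits = 17), collapse = ","),
                    character(1)),
             sep = "=", collapse = ";")
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b)) # fold into 31 bits
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
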