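# Shared fixtures and independent oracles, built in code at test time.

make_fragments <- function(texts, ids = sprintf("f%02d", seq_along(texts)),
                           gene = "ENSG00000000001", disease = "EFO_0000001",
                           pmid = "12345678", target_name = "GENEX") {
  data.frame(fragment_id = ids,
             target_ensembl_id = rep_len(gene, length(texts)),
             target_name = rep_len(target_name, length(texts)),
             disease_id = rep_len(disease, length(texts)),
             pmid = rep_len(pmid, length(texts)),
             text = texts,
             stringsAsFactors = FALSE)
}

write_jsonl <- function(lines, path = tempfile(fileext = ".jsonl")) {
  writeLines(lines, path)
  path
}

evidence_line <- function(id, text, gene = "ENSG00000000001",
                          name = "GENEX", disease = "EFO_0000001",
                          pmid = "12345678") {
  sprintf(paste0('{"id":"%s","targetId":"%s","targetName":"%s",',
                 '"diseaseId":"%s","pmid":"%s","text":"%s"}'),
          id, gene, name, disease, pmid, text)
}

mini_dictionary <- function(rows) {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  load_dictionary(path)
}

# One all-passing annotation record, optionally perturbed.
annotation_record <- function(...) {
  rec <- data.frame(protein_accession = "NX_P00001",
                    protein_existence_level = "protein_level",
                    annotation_group = "general-annotation; generic-function",
                    annotation_category = "function",
                    annotation_quality = "GOLD",
                    has_negative_evidence = FALSE,
                    evidence_quality = "GOLD",
                    evidence_type = "publication",
                    pmid = "12345678",
                    stringsAsFactors = FALSE)
  rec$ensembl_gene_ids <- list("ENSG00000000001")
  rec$eco_terms <- list("experimental evidence")
  mods <- list(...)
  for (nm in names(mods)) rec[[nm]] <- mods[[nm]]
  rec
}

# Independent naive Bayes oracle: explicit Bayes-rule evaluation by plain
# counting and full products over the vocabulary (no logs, no shared code
# with nb_fit/nb_predict).
nb_oracle_posterior <- function(token_sets, labels, alpha, test_tokens) {
  vocab <- sort(unique(unlist(token_sets)))
  joint <- function(cls) {
    docs <- token_sets[labels == cls]
    prior <- length(docs) / length(token_sets)
    p <- prior
    for (t in vocab) {
      n_t <- sum(vapply(docs, function(d) t %in% d, logical(1)))
      p_t <- (n_t + alpha) / (length(docs) + 2 * alpha)
      p <- p * (if (t %in% test_tokens) p_t else 1 - p_t)
    }
    p
  }
  jp <- joint(TRUE); jn <- joint(FALSE)
  jp / (jp + jn)
}

# Random small labeled corpus over a tiny vocabulary.
random_toy_corpus <- function(n_docs = 8, vocab_size = 5) {
  vocab <- letters[seq_len(vocab_size)]
  repeat {
    sets <- lapply(seq_len(n_docs), function(i) {
      sample(vocab, sample.int(vocab_size, 1))
    })
    labels <- sample(c(TRUE, FALSE), n_docs, replace = TRUE)
    if (any(labels) && !all(labels)) return(list(sets = sets, labels = labels))
  }
}

random_similarity <- function(n) {
  m <- matrix(runif(n * 12), nrow = n)
  rownames(m) <- sprintf("d%02d", seq_len(n))
  cosine_matrix(m)
}
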