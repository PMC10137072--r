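test_that("dictionary TSV loads with validation and duplicate collapsing", {
  rows <- data.frame(term = c("pcr", "antibody", "lipidome"),
                     category = c("DNA_RNA", "PROTEIN", "METABOLITE"),
                     whole_word_only = FALSE)
  d <- mini_dictionary(rows)
  expect_equal(unname(d$term_count_by_category), c(1L, 1L, 1L))

  expect_warning(d2 <- mini_dictionary(rows[c(1, 1, 2, 3), ]), "duplicate")
  expect_equal(d2$term_count_by_category, d$term_count_by_category)

  bad <- rows; bad$category[2] <- "LIPID"
  expect_error(mini_dictionary(bad), "row 2")
})

test_that("the packaged dictionary has terms in all three categories", {
  d <- default_dictionary()
  expect_true(all(d$term_count_by_category > 0))
  expect_true(all(c("replication", "gene") %in%
                    d$terms$term[d$terms$category == "DNA_RNA"]))
  expect_true(all(c("lipidome", "metabolome", "metabolomics", "lipids",
                    "carbohydrate", "lipid droplets") %in%
                    d$terms$term[d$terms$category == "METABOLITE"]))
  ww <- d$terms[d$terms$term %in% c("ria", "gag"), ]
  expect_true(all(ww$whole_word_only))
})

test_that("substring terms match inside words, whole-word terms never do", {
  d <- default_dictionary()
  gwas_text <- "A genome-wide association study identifies IL23R as an inflammatory bowel disease gene."
  hits <- screen_fragment(list(fragment_id = "x", text = gwas_text), d)
  expect_true("DNA_RNA" %in% hits$category)
  expect_true(all(c("genome-wide association", "gene") %in% hits$term))

  # "gag" only between word boundaries
  h2 <- screen_fragment(list(fragment_id = "y",
                             text = "engagement of the receptor"), d)
  expect_false("gag" %in% h2$term)
  h3 <- screen_fragment(list(fragment_id = "z",
                             text = "the viral gag polyprotein"), d)
  expect_true("gag" %in% h3$term)

  expect_equal(nrow(screen_fragment(list(fragment_id = "w",
                                         text = "the quick brown fox"), d)), 0L)
})

test_that("match spans use 0-based half-open offsets into the original text", {
  d <- mini_dictionary(data.frame(term = "pcr", category = "DNA_RNA",
                                  whole_word_only = FALSE))
  hits <- screen_fragment(list(fragment_id = "x", text = "qPCR assay"), d)
  expect_equal(hits$start, 1L)
  expect_equal(hits$end, 4L)
  expect_equal(tolower(substr("qPCR assay", hits$start + 1, hits$end)), "pcr")
})

test_that("screening is invariant to the case of the input text", {
  d <- default_dictionary()
  t1 <- "Western blot and PCR confirmed the finding"
  h1 <- screen_fragment(list(fragment_id = "a", text = t1), d)
  h2 <- screen_fragment(list(fragment_id = "a", text = toupper(t1)), d)
  h3 <- screen_fragment(list(fragment_id = "a", text = tolower(t1)), d)
  expect_equal(h1[c("category", "term", "start", "end")],
               h2[c("category", "term", "start", "end")])
  expect_equal(h1[c("category", "term", "start", "end")],
               h3[c("category", "term", "start", "end")])
})

test_that("whole-word matching agrees with a brute-force regex oracle", {
  set.seed(7)
  term <- "ria"
  d <- mini_dictionary(data.frame(term = term, category = "PROTEIN",
                                  whole_word_only = TRUE))
  flanks <- c("", " ", "x", "9", "_", "-", ".", "(")
  for (i in 1:200) {
    pre <- sample(flanks, 1); post <- sample(flanks, 1)
    text <- paste0("lead ", pre, term, post, " tail")
    hits <- screen_fragment(list(fragment_id = "x", text = text), d)
    # oracle: tokenize on non-word characters and look for the exact token
    oracle <- term %in% unlist(strsplit(tolower(text), "[^a-z0-9_]+"))
    expect_equal(nrow(hits) > 0, oracle, info = text)
  }
})

test_that("corpus screening is multi-label and counts equal list lengths", {
  d <- default_dictionary()
  frags <- make_fragments(c(
    "Western blot and PCR were performed",   # PROTEIN + DNA_RNA
    "the metabolome was profiled",           # METABOLITE
    "nothing relevant here"),
    ids = c("f1", "f2", "f3"))
  sc <- screen_corpus(frags, d)
  expect_true("f1" %in% sc$by_category$PROTEIN)
  expect_true("f1" %in% sc$by_category$DNA_RNA)
  expect_equal(sc$by_category$METABOLITE, "f2")
  expect_equal(unname(sc$counts),
               unname(vapply(sc$by_category, length, integer(1))))
  expect_false("f3" %in% unlist(sc$by_category))
})

test_that("screening recovers planted categories exactly at full injection", {
  cfg <- synthetic_config(seed = 11L, n_per_category = 200L,
                          term_injection_rate = 1)
  corpus <- generate_corpus(cfg)
  sc <- screen_corpus(corpus$fragments, default_dictionary())
  for (cat in level_categories()) {
    planted <- corpus$truth$fragment_id[corpus$truth$category == cat]
    expect_setequal(sc$by_category[[cat]], planted)
  }
})

test_that("homograph-only corpora produce zero hits", {
  cfg <- synthetic_config(seed = 12L, n_per_category = 50L,
                          term_injection_rate = 0, homograph_rate = 1)
  corpus <- generate_corpus(cfg)
  sc <- screen_corpus(corpus$fragments, default_dictionary())
  expect_equal(unname(sc$counts), c(0L, 0L, 0L))
})

test_that("adding a dictionary term never removes existing hits", {
  base_rows <- data.frame(term = c("pcr", "antibody"),
                          category = c("DNA_RNA", "PROTEIN"),
                          whole_word_only = FALSE)
  frags <- make_fragments(c("PCR and antibody staining", "a gene was sequenced",
                            "plain text"))
  h_base <- screen_corpus(frags, mini_dictionary(base_rows))$hits
  bigger <- rbind(base_rows, data.frame(term = "gene", category = "DNA_RNA",
                                        whole_word_only = FALSE))
  h_big <- screen_corpus(frags, mini_dictionary(bigger))$hits
  key <- function(h) paste(h$fragment_id, h$category, h$term, h$start)
  expect_true(all(key(h_base) %in% key(h_big)))
})

test_that("highlighting brackets entities and terms as in the review form", {
  text <- paste0("Using IP with an anti-acetyl lysine antibody, we identified ",
                 "Aurora B as an acetylated protein in PC3 prostate cancer cells. ",
                 "Aurora B is regulated by acetylation/deacetylation during ",
                 "mitosis in prostate cancer cells")
  hits <- screen_fragment(list(fragment_id = "x", text = text),
                          default_dictionary())
  out <- highlight_fragment(text, hits, "Aurora B")
  expect_equal(out, paste0(
    "Using IP with an anti-acetyl lysine {antibody}, we identified ",
    "[Aurora B] as an acetylated {protein} in PC3 prostate cancer cells. ",
    "[Aurora B] is regulated by acetylation/deacetylation during ",
    "mitosis in prostate cancer cells"))
  expect_equal(strip_highlight(out), text)
})

test_that("stripping markup recovers the original text on random fragments", {
  cfg <- synthetic_config(seed = 3L, n_per_category = 20L)
  corpus <- generate_corpus(cfg)
  d <- default_dictionary()
  for (i in sample(nrow(corpus$fragments), 25)) {
    f <- corpus$fragments[i, ]
    hits <- screen_fragment(f, d)
    marked <- highlight_fragment(f$text, hits, f$target_name)
    expect_equal(strip_highlight(marked), f$text)
  }
})

test_that("overlapping term spans are merged left-greedily", {
  d <- mini_dictionary(data.frame(
    term = c("genome-wide association", "genome-wide"),
    category = "DNA_RNA", whole_word_only = FALSE))
  text <- "a genome-wide association study"
  hits <- screen_fragment(list(fragment_id = "x", text = text), d)
  out <- highlight_fragment(text, hits, "")
  expect_equal(out, "a {genome-wide association} study")
})
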