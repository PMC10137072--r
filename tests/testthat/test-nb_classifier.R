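test_that("distinct-word tokenization has set semantics", {
  expect_equal(tokenize_distinct("Gene gene GENE"), "gene")
  expect_equal(tokenize_distinct(""), character(0))
  aurora <- paste0("Using IP with an anti-acetyl lysine antibody, we ",
                   "identified Aurora B as an acetylated protein in PC3 ",
                   "prostate cancer cells.")
  expect_setequal(tokenize_distinct(aurora),
                  c("using", "ip", "with", "an", "anti", "acetyl", "lysine",
                    "antibody", "we", "identified", "aurora", "b", "as",
                    "acetylated", "protein", "in", "pc3", "prostate",
                    "cancer", "cells"))
})

test_that("two-document fit matches the closed-form smoothed estimates", {
  m <- nb_fit(list("a", "b"), c(TRUE, FALSE), alpha = 1)
  expect_equal(exp(m$conditionals$pos["a", "log_present"]), 2 / 3)
  expect_equal(exp(m$conditionals$neg["a", "log_present"]), 1 / 3)
  expect_equal(exp(unname(m$log_prior)), c(0.5, 0.5))
  expect_equal(sum(exp(m$log_prior)), 1)
  # Bernoulli conditionals are proper per token and class
  expect_equal(exp(m$conditionals$pos[, "log_present"]) +
                 exp(m$conditionals$pos[, "log_absent"]),
               c(a = 1, b = 1))
  # the posterior for {a} follows by hand: 2/9 vs 1/18 -> 0.8
  expect_equal(nb_predict(m, "a")$posterior, 0.8)
})

test_that("swapped training labels mirror the parameters", {
  sets <- list(c("a", "b"), "a", c("b", "c"), "c")
  m1 <- nb_fit(sets, c(TRUE, TRUE, FALSE, FALSE))
  m2 <- nb_fit(sets, c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(m1$conditionals$pos, m2$conditionals$neg)
  expect_equal(m1$conditionals$neg, m2$conditionals$pos)
  p1 <- nb_predict(m1, c("a", "c"))$posterior
  p2 <- nb_predict(m2, c("a", "c"))$posterior
  expect_equal(p1, 1 - p2, tolerance = 1e-12)
})

test_that("the four-document toy corpus reproduces the hand-computed table", {
  sets <- list(c("a", "b"), "a", c("b", "c"), "c")
  m <- nb_fit(sets, c(TRUE, TRUE, FALSE, FALSE), alpha = 1)
  expect_equal(exp(m$conditionals$pos[, "log_present"]),
               c(a = 3 / 4, b = 1 / 2, c = 1 / 4))
  expect_equal(exp(m$conditionals$neg[, "log_present"]),
               c(a = 1 / 4, b = 1 / 2, c = 3 / 4))
  # P(+|{a}) = (1/2 * 3/4 * 1/2 * 3/4) / (that + 1/2 * 1/4 * 1/2 * 1/4) = 0.9
  expect_equal(nb_predict(m, "a")$posterior, 0.9)
})

test_that("prediction ignores out-of-vocabulary tokens and duplicate words", {
  sets <- list(c("a", "b"), "a", c("b", "c"), "c")
  m <- nb_fit(sets, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(nb_predict(m, c("a", "zzz"))$posterior,
               nb_predict(m, "a")$posterior)
  raw <- tokenize_distinct("a a a A")
  expect_equal(nb_predict(m, raw)$posterior, nb_predict(m, "a")$posterior)
})

test_that("an uninformative model ties at 0.5 and ties go negative", {
  m <- nb_fit(list("a", "b"), c(TRUE, FALSE))
  p <- nb_predict(m, character(0))
  expect_equal(p$posterior, 0.5)
  expect_false(p$label)
})

test_that("single-class training data is rejected", {
  expect_error(nb_fit(list("a", "b"), c(TRUE, TRUE)), "both classes")
})

test_that("fit/predict agree with explicit Bayes-rule enumeration", {
  set.seed(61)
  for (rep in 1:25) {
    corpus <- random_toy_corpus(n_docs = sample(6:10, 1),
                                vocab_size = sample(3:6, 1))
    alpha <- sample(c(0.5, 1, 2), 1)
    m <- nb_fit(corpus$sets, corpus$labels, alpha = alpha)
    test_doc <- sample(letters[1:6], sample.int(4, 1))
    want <- nb_oracle_posterior(corpus$sets, corpus$labels, alpha,
                                intersect(test_doc, m$vocabulary))
    got <- nb_predict(m, test_doc)$posterior
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("fit/predict agree with an independent reference implementation", {
  skip_if_not_installed("e1071")
  set.seed(62)
  corpus <- random_toy_corpus(n_docs = 20, vocab_size = 6)
  vocab <- sort(unique(unlist(corpus$sets)))
  X <- as.data.frame(lapply(vocab, function(t) {
    factor(vapply(corpus$sets, function(d) t %in% d, logical(1)),
           levels = c(FALSE, TRUE))
  }), col.names = vocab)
  ref <- e1071::naiveBayes(X, factor(corpus$labels, levels = c(FALSE, TRUE)),
                           laplace = 1)
  m <- nb_fit(corpus$sets, corpus$labels, alpha = 1)
  for (i in 1:5) {
    doc <- sample(vocab, sample.int(5, 1))
    newX <- as.data.frame(lapply(vocab, function(t) {
      factor(t %in% doc, levels = c(FALSE, TRUE))
    }), col.names = vocab)
    want <- unname(predict(ref, newX, type = "raw")[1, "TRUE"])
    expect_equal(nb_predict(m, doc)$posterior, want, tolerance = 1e-8)
  }
})

test_that("balanced accuracy of any constant classifier is exactly 0.5", {
  truth <- c(rep(TRUE, 37), rep(FALSE, 3))
  expect_equal(balanced_accuracy(truth, rep(TRUE, 40))$balanced_accuracy, 0.5)
  expect_equal(balanced_accuracy(truth, rep(FALSE, 40))$balanced_accuracy, 0.5)
})

test_that("cross-validation folds are stratified, seeded and reproducible", {
  set.seed(63)
  sets <- lapply(1:50, function(i) sample(letters[1:8], 3))
  labels <- rep(c(TRUE, FALSE), c(30, 20))
  cv1 <- nb_cross_validate(sets, labels, folds = 5, seed = 7)
  cv2 <- nb_cross_validate(sets, labels, folds = 5, seed = 7)
  expect_identical(cv1, cv2)

  fold <- cv1$fold_assignments
  for (cls in c(TRUE, FALSE)) {
    per_fold <- table(fold[labels == cls])
    expect_lte(max(per_fold) - min(per_fold), 1)
  }
  expect_error(nb_cross_validate(sets[1:6], c(TRUE, rep(FALSE, 5)), folds = 5),
               "at least")
})

test_that("a perfectly separable corpus cross-validates at 1.0", {
  sets <- c(lapply(1:20, function(i) c("marker", sample(letters[1:5], 2))),
            lapply(1:20, function(i) c("other", sample(letters[1:5], 2))))
  labels <- rep(c(TRUE, FALSE), each = 20)
  cv <- nb_cross_validate(sets, labels, folds = 5, seed = 1)
  expect_equal(cv$mean_balanced_accuracy, 1.0)
})

test_that("labels shuffled independently of features score near 0.5", {
  set.seed(64)
  bas <- vapply(1:50, function(rep) {
    sets <- lapply(1:60, function(i) sample(letters[1:10], 4))
    labels <- sample(rep(c(TRUE, FALSE), each = 30))
    nb_cross_validate(sets, labels, folds = 5, seed = rep)$mean_balanced_accuracy
  }, numeric(1))
  expect_equal(mean(bas), 0.5, tolerance = 0.04)
})

test_that("corpus classification partitions each screened category", {
  cfg <- synthetic_config(seed = 65L, n_per_category = 150L,
                          false_positive_rate = 0.3, separability = 0.9)
  corpus <- generate_corpus(cfg)
  sc <- screen_corpus(corpus$fragments, default_dictionary())
  token_sets <- tokenize_distinct(corpus$fragments$text)
  names(token_sets) <- corpus$fragments$fragment_id
  models <- lapply(stats::setNames(nm = level_categories()), function(cat) {
    ids <- sc$by_category[[cat]]
    labels <- corpus$truth$planted_valid[match(ids, corpus$truth$fragment_id)]
    nb_fit(token_sets[ids], labels)
  })
  res <- classify_corpus(models, sc$by_category, corpus$fragments)
  expect_equal(res$summary$confirmed_count + res$summary$unrelated_count,
               res$summary$n_screened)
  # high separability: unrelated fraction tracks the planted 30% rate
  expect_equal(sum(res$summary$unrelated_count) / sum(res$summary$n_screened),
               0.3, tolerance = 0.2)
})

test_that("a model that confirms everything yields zero unrelated counts", {
  sets <- list(c("yes", "a"), c("yes", "b"), "no")
  m <- nb_fit(sets, c(TRUE, TRUE, FALSE))
  frags <- make_fragments(c("yes a thing", "yes b thing"), ids = c("x", "y"))
  res <- classify_corpus(list(PROTEIN = m), list(PROTEIN = c("x", "y")), frags)
  expect_equal(res$summary$unrelated_count, 0L)
  expect_equal(res$summary$confirmed_count, 2L)
})

test_that("models survive JSON serialization byte-for-byte in behavior", {
  sets <- list(c("a", "b"), "a", c("b", "c"), "c")
  m <- nb_fit(sets, c(TRUE, TRUE, FALSE, FALSE))
  path <- tempfile(fileext = ".json")
  nb_to_json(m, path)
  m2 <- nb_from_json(path)
  docs <- list("a", c("a", "c"), "b", character(0))
  expect_equal(nb_predict(m2, docs), nb_predict(m, docs), tolerance = 1e-15)
})
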