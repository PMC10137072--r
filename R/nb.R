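#' Tokenize a text into its set of distinct lowercase words
#'
#' Set semantics: repeated words contribute once. A word is a maximal run of
#' word characters (letters, digits, underscore) on the case-folded text.
#'
#' @param text Character scalar or vector.
#' @return For a scalar, a character vector of distinct tokens; for a
#'   vector, a list of such sets.
#' @export
tokenize_distinct <- function(text) {
  sets <- lapply(tokenize_words(text), unique)
  if (length(text) == 1L) sets[[1]] else sets
}

#' Fit a binary naive Bayes classifier on token sets
#'
#' Bernoulli event model over the training vocabulary with Laplace
#' smoothing: for token t and class c,
#' `P(t present | c) = (n_ct + alpha) / (n_c + 2 alpha)` where `n_ct` is the
#' number of class-c documents containing t and `n_c` the class-c document
#' count. Class priors are the class frequencies. A multinomial event model
#' (`P(t|c)` proportional to smoothed token occurrence counts) is available
#' behind `event_model = "multinomial"`; the Bernoulli model is the default
#' because documents are reduced to distinct-word sets.
#'
#' @param token_sets List of character vectors (distinct tokens per
#'   document, e.g. from [tokenize_distinct()]).
#' @param labels Logical vector; `TRUE` = positive (validated) examples.
#' @param alpha Smoothing constant, > 0.
#' @param event_model `"bernoulli"` (default) or `"multinomial"`.
#' @return Object of class `nb_model`: log priors, per-token conditional
#'   log-probabilities for both classes, vocabulary, `alpha`, event model.
#' @export
nb_fit <- function(token_sets, labels, alpha = 1,
                   event_model = c("bernoulli", "multinomial")) {
  event_model <- match.arg(event_model)
  labels <- as.logical(labels)
  stopifnot(length(token_sets) == length(labels), alpha > 0)
  if (!any(labels) || all(labels)) {
    stop("both classes must be present in the training data")
  }
  vocab <- sort(unique(unlist(token_sets)))
  contains <- function(cls) {
    tab <- table(factor(unlist(lapply(token_sets[labels == cls], unique)),
                        levels = vocab))
    as.numeric(tab)
  }
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (event_model == "bernoulli") {
    p_pos <- (contains(TRUE) + alpha) / (n_pos + 2 * alpha)
    p_neg <- (contains(FALSE) + alpha) / (n_neg + 2 * alpha)
    cond <- list(
      pos = cbind(log_present = log(p_pos), log_absent = log1p(-p_pos)),
      neg = cbind(log_present = log(p_neg), log_absent = log1p(-p_neg)))
  } else {
    cnt <- function(cls) {
      tab <- table(factor(unlist(token_sets[labels == cls]), levels = vocab))
      as.numeric(tab)
    }
    c_pos <- cnt(TRUE); c_neg <- cnt(FALSE)
    cond <- list(
      pos = cbind(log_present = log((c_pos + alpha) /
                                      (sum(c_pos) + alpha * length(vocab))),
                  log_absent = 0),
      neg = cbind(log_present = log((c_neg + alpha) /
                                      (sum(c_neg) + alpha * length(vocab))),
                  log_absent = 0))
  }
  rownames(cond$pos) <- rownames(cond$neg) <- vocab
  structure(list(
    vocabulary = vocab,
    log_prior = c(pos = log(n_pos) - log(n_pos + n_neg),
                  neg = log(n_neg) - log(n_pos + n_neg)),
    conditionals = cond,
    alpha = alpha,
    event_model = event_model), class = "nb_model")
}

#' Predict the class of a token set
#'
#' Bernoulli likelihood over the full model vocabulary: present tokens
#' contribute `P(t|c)`, absent ones `1 - P(t|c)`; tokens outside the
#' vocabulary are ignored. The label is positive iff the positive posterior
#' exceeds 0.5; an exact tie goes negative (favouring "unrelated").
#'
#' @param model An `nb_model`.
#' @param tokens Character vector (one document's distinct tokens), or a
#'   list of such vectors.
#' @return data.frame with columns `posterior` (positive-class probability)
#'   and `label` (logical).
#' @export
nb_predict <- function(model, tokens) {
  if (!is.list(tokens)) tokens <- list(tokens)
  bernoulli <- model$event_model == "bernoulli"
  cd_pos <- model$conditionals$pos
  cd_neg <- model$conditionals$neg
  base_pos <- if (bernoulli) sum(cd_pos[, "log_absent"]) else 0
  base_neg <- if (bernoulli) sum(cd_neg[, "log_absent"]) else 0
  post <- vapply(tokens, function(tk) {
    present <- match(unique(tk), model$vocabulary)
    present <- present[!is.na(present)]
    lp <- model$log_prior["pos"] + base_pos +
      sum(cd_pos[present, "log_present"]) -
      (if (bernoulli) sum(cd_pos[present, "log_absent"]) else 0)
    ln <- model$log_prior["neg"] + base_neg +
      sum(cd_neg[present, "log_present"]) -
      (if (bernoulli) sum(cd_neg[present, "log_absent"]) else 0)
    m <- max(lp, ln)
    exp(lp - m) / (exp(lp - m) + exp(ln - m))
  }, numeric(1))
  data.frame(posterior = post, label = post > 0.5)
}

#' Balanced accuracy of predicted versus true labels
#'
#' Mean of sensitivity (true-positive rate) and specificity (true-negative
#' rate); equals 0.5 for any constant classifier regardless of class
#' imbalance.
#'
#' @param truth,predicted Logical vectors.
#' @return List with `sensitivity`, `specificity`, `balanced_accuracy`.
#' @export
balanced_accuracy <- function(truth, predicted) {
  truth <- as.logical(truth); predicted <- as.logical(predicted)
  sens <- mean(predicted[truth])
  spec <- mean(!predicted[!truth])
  list(sensitivity = sens, specificity = spec,
       balanced_accuracy = (sens + spec) / 2)
}

#' Stratified k-fold cross-validation of the naive Bayes classifier
#'
#' Folds are assigned by a seeded shuffle within each class followed by
#' cyclic assignment, so per-fold class counts differ by at most one and
#' every fold contains both classes (given at least `folds` examples per
#' class). Reports per-fold sensitivity, specificity and balanced accuracy
#' and their mean.
#'
#' @param token_sets,labels,alpha,event_model As in [nb_fit()].
#' @param folds Number of folds (default 5).
#' @param seed Integer seed for the shuffle.
#' @param ids Optional fragment ids for the fold-assignment map.
#' @return List of class `cv_report`: `fold_assignments` (named integer
#'   vector), `per_fold` (data.frame), `mean_balanced_accuracy`.
#' @export
nb_cross_validate <- function(token_sets, labels, folds = 5L, seed = 1L,
                              alpha = 1, event_model = "bernoulli",
                              ids = NULL) {
  labels <- as.logical(labels)
  if (min(sum(labels), sum(!labels)) < folds) {
    stop("each class needs at least ", folds, " examples for ", folds,
         "-fold cross-validation")
  }
  n <- length(labels)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  fold <- integer(n)
  withr::with_seed(seed, {
    for (cls in c(TRUE, FALSE)) {
      idx <- which(labels == cls)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  per_fold <- do.call(rbind, lapply(seq_len(folds), function(f) {
    test <- fold == f
    model <- nb_fit(token_sets[!test], labels[!test], alpha = alpha,
                    event_model = event_model)
    pred <- nb_predict(model, token_sets[test])
    ba <- balanced_accuracy(labels[test], pred$label)
    data.frame(fold = f, n_test = sum(test),
               sensitivity = ba$sensitivity, specificity = ba$specificity,
               balanced_accuracy = ba$balanced_accuracy)
  }))
  structure(list(
    fold_assignments = stats::setNames(fold, ids),
    per_fold = per_fold,
    mean_balanced_accuracy = mean(per_fold$balanced_accuracy)),
    class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("Stratified", nrow(x$per_fold), "fold cross-validation\n")
  print(x$per_fold, row.names = FALSE)
  cat("mean balanced accuracy:",
      format(x$mean_balanced_accuracy, digits = 4), "\n")
  invisible(x)
}

#' Classify every screened fragment with its category's model
#'
#' Each fragment in a category's screened list is scored by that category's
#' classifier; fragments predicted positive are counted as confirmed, the
#' rest as unrelated to the dictionary-defined category. Confirmed and
#' unrelated counts partition each category's list.
#'
#' @param models Named list of `nb_model`s, one per category.
#' @param screened Named list of fragment-id vectors per category (the
#'   `by_category` element of [screen_corpus()]).
#' @param fragments Evidence fragment data.frame covering all listed ids.
#' @return List with `summary` (data.frame: `category`, `n_screened`,
#'   `confirmed_count`, `unrelated_count`) and `predictions` (data.frame:
#'   `fragment_id`, `category`, `posterior`, `label`).
#' @export
classify_corpus <- function(models, screened, fragments) {
  stopifnot(all(names(screened) %in% names(models)))
  token_sets <- tokenize_distinct(fragments$text)
  if (!is.list(token_sets)) token_sets <- list(token_sets)
  names(token_sets) <- fragments$fragment_id
  preds <- do.call(rbind, lapply(names(screened), function(cat) {
    ids <- screened[[cat]]
    if (!length(ids)) return(NULL)
    p <- nb_predict(models[[cat]], token_sets[ids])
    data.frame(fragment_id = ids, category = cat,
               posterior = p$posterior, label = p$label,
               stringsAsFactors = FALSE)
  }))
  if (is.null(preds)) {
    preds <- data.frame(fragment_id = character(0), category = character(0),
                        posterior = numeric(0), label = logical(0))
  }
  summary <- do.call(rbind, lapply(names(screened), function(cat) {
    p <- preds[preds$category == cat, , drop = FALSE]
    data.frame(category = cat, n_screened = length(screened[[cat]]),
               confirmed_count = sum(p$label),
               unrelated_count = sum(!p$label),
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  list(summary = summary, predictions = preds)
}

#' Serialize / restore a naive Bayes model as JSON
#' @param model An `nb_model`.
#' @param path JSON file path.
#' @export
nb_to_json <- function(model, path) {
  obj <- list(
    event_model = model$event_model,
    alpha = model$alpha,
    vocabulary = model$vocabulary,
    log_prior = as.list(model$log_prior),
    conditionals = list(
      pos = list(log_present = unname(model$conditionals$pos[, "log_present"]),
                 log_absent = unname(model$conditionals$pos[, "log_absent"])),
      neg = list(log_present = unname(model$conditionals$neg[, "log_present"]),
                 log_absent = unname(model$conditionals$neg[, "log_absent"]))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname nb_to_json
#' @export
nb_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  vocab <- obj$vocabulary
  mk <- function(side) {
    m <- cbind(log_present = side$log_present, log_absent = side$log_absent)
    rownames(m) <- vocab
    m
  }
  structure(list(
    vocabulary = vocab,
    log_prior = c(pos = obj$log_prior$pos, neg = obj$log_prior$neg),
    conditionals = list(pos = mk(obj$conditionals$pos),
                        neg = mk(obj$conditionals$neg)),
    alpha = obj$alpha,
    event_model = obj$event_model), class = "nb_model")
}
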