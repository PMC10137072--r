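#' Tokenize text into lowercase word tokens
#'
#' A word is a maximal run of word characters (letters, digits, underscore)
#' on the case-folded text.
#'
#' @param text Character vector.
#' @return List of character vectors (tokens in text order, repeats kept).
#' @export
tokenize_words <- function(text) {
  lapply(strsplit(tolower(text), "[^[:alnum:]_]+"), function(x) x[nzchar(x)])
}

#' Build a document-term count matrix
#'
#' @param texts Character vector of documents (or a list of pre-tokenized
#'   token vectors).
#' @param ids Row identifiers; defaults to names or sequence.
#' @return Integer matrix: rows = documents (in input order), columns =
#'   vocabulary tokens (sorted); all-zero vocabulary columns cannot occur.
#' @export
build_dtm <- function(texts, ids = NULL) {
  toks <- if (is.list(texts)) lapply(texts, as.character) else tokenize_words(texts)
  if (!length(toks) || all(lengths(toks) == 0L)) {
    stop("cannot build a document-term matrix from empty texts")
  }
  if (is.null(ids)) ids <- if (!is.null(names(texts))) names(texts) else as.character(seq_along(toks))
  vocab <- sort(unique(unlist(toks)))
  m <- matrix(0L, nrow = length(toks), ncol = length(vocab),
              dimnames = list(ids, vocab))
  for (i in seq_along(toks)) {
    if (!length(toks[[i]])) next
    tab <- table(toks[[i]])
    m[i, names(tab)] <- as.integer(tab)
  }
  m
}

#' Pairwise cosine similarity between matrix rows
#'
#' Entries lie in `[0, 1]` for nonnegative counts; the diagonal is 1 for
#' nonzero rows. An all-zero row has similarity 0 to everything, including
#' itself (diagonal 0 by convention).
#'
#' @param m Numeric matrix (documents in rows).
#' @return Symmetric similarity matrix with `m`'s row names.
#' @export
cosine_matrix <- function(m) {
  m <- as.matrix(m)
  norms <- sqrt(rowSums(m^2))
  cross <- tcrossprod(m)
  denom <- outer(norms, norms)
  sim <- ifelse(denom > 0, cross / denom, 0)
  sim[norms == 0, ] <- 0
  sim[, norms == 0] <- 0
  # clamp floating-point overshoot
  sim[sim > 1] <- 1
  dimnames(sim) <- list(rownames(m), rownames(m))
  sim
}

#' Diversity objective: weighted total pairwise similarity of a subset
#'
#' The quantity minimized when picking a maximally heterogeneous review
#' sample: the sum over unordered pairs within the subset of the whole-text
#' cosine similarity plus the matched-term-profile cosine similarity, each
#' weighted.
#'
#' @param subset Indices or row names into the similarity matrices.
#' @param sim_text,sim_terms Symmetric similarity matrices (same ordering).
#' @param weights Length-2 nonnegative numeric `c(text, terms)`.
#' @return Nonnegative scalar; 0 for subsets of size < 2.
#' @export
selection_objective <- function(subset, sim_text, sim_terms = NULL,
                                weights = c(1, 1)) {
  stopifnot(length(weights) == 2, all(weights >= 0), any(weights > 0))
  if (length(subset) < 2) return(0)
  s_t <- sim_text[subset, subset, drop = FALSE]
  total <- weights[1] * (sum(s_t) - sum(diag(s_t))) / 2
  if (!is.null(sim_terms)) {
    s_m <- sim_terms[subset, subset, drop = FALSE]
    total <- total + weights[2] * (sum(s_m) - sum(diag(s_m))) / 2
  }
  total
}

.combined_sim <- function(sim_text, sim_terms, weights) {
  s <- weights[1] * sim_text
  if (!is.null(sim_terms)) s <- s + weights[2] * sim_terms
  s
}

.subset_objective <- function(idx, S, diag_S) {
  (sum(S[idx, idx]) - sum(diag_S[idx])) / 2
}

#' Configuration for diversity-maximising subset selection
#'
#' @param k Subset size (fragments to review per category).
#' @param seed Integer seed; the whole selection is reproducible given it.
#' @param population_size,generations,tournament_size,mutation_probability
#'   Genetic-algorithm hyperparameters (fixed-size-subset encoding,
#'   tournament selection, per-position swap mutation).
#' @param weight_text,weight_terms Objective weights for the whole-text and
#'   matched-term similarity components.
#' @return List of class `selection_config`.
#' @export
selection_config <- function(k, seed = 1L, population_size = 100L,
                             generations = 200L, tournament_size = 2L,
                             mutation_probability = 0.01,
                             weight_text = 1, weight_terms = 1) {
  stopifnot(k >= 1, population_size >= 2, generations >= 1,
            mutation_probability >= 0, mutation_probability <= 1,
            weight_text >= 0, weight_terms >= 0,
            weight_text + weight_terms > 0)
  structure(list(k = as.integer(k), seed = as.integer(seed),
                 population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 tournament_size = as.integer(tournament_size),
                 mutation_probability = mutation_probability,
                 weights = c(weight_text, weight_terms)),
            class = "selection_config")
}

#' Select a maximally diverse fixed-size subset by a genetic algorithm
#'
#' Minimizes [selection_objective()] over size-`k` subsets of the candidates
#' using a fixed-size-subset GA: random initial population (the best of at
#' least 100 seeded random subsets always enters it, so the result is never
#' worse than that baseline), tournament selection, union-resampling
#' crossover, per-position swap mutation and single-survivor elitism. When
#' several subsets in the final population tie on the objective the
#' lexicographically smallest id set is returned, making the result
#' deterministic given the seed.
#'
#' @param candidates Character vector of candidate ids (must match the
#'   similarity matrices' dimnames) or indices.
#' @param sim_text,sim_terms Similarity matrices over the candidates.
#' @param cfg A [selection_config()].
#' @return List of class `selection_result`: `selected` (sorted ids, size
#'   k), `objective`, `trace` (best objective per generation).
#' @export
select_diverse <- function(candidates, sim_text, sim_terms = NULL, cfg) {
  n <- length(candidates)
  if (cfg$k > n) stop("k (", cfg$k, ") exceeds number of candidates (", n, ")")
  idx_all <- seq_len(n)
  S <- .combined_sim(sim_text[candidates, candidates, drop = FALSE],
                     if (is.null(sim_terms)) NULL else
                       sim_terms[candidates, candidates, drop = FALSE],
                     cfg$weights)
  dS <- diag(S)
  obj <- function(idx) .subset_objective(idx, S, dS)

  if (cfg$k == n) {
    return(structure(list(selected = sort(as.character(candidates)),
                          objective = obj(idx_all),
                          trace = obj(idx_all)),
                     class = "selection_result"))
  }

  withr::with_seed(cfg$seed, {
    n_init <- max(cfg$population_size, 100L)
    init <- replicate(n_init, sort(sample(idx_all, cfg$k)), simplify = FALSE)
    fit <- vapply(init, obj, numeric(1))
    keep <- order(fit)[seq_len(cfg$population_size)]
    pop <- init[keep]
    fit <- fit[keep]
    trace <- numeric(cfg$generations)

    for (g in seq_len(cfg$generations)) {
      best_i <- which.min(fit)
      new_pop <- vector("list", cfg$population_size)
      new_pop[[1]] <- pop[[best_i]] # elitism
      for (j in 2:cfg$population_size) {
        pick <- function() {
          cand <- sample.int(cfg$population_size, cfg$tournament_size,
                             replace = TRUE)
          pop[[cand[which.min(fit[cand])]]]
        }
        p1 <- pick(); p2 <- pick()
        pool <- unique(c(p1, p2))
        child <- if (length(pool) == cfg$k) pool else
          pool[sample.int(length(pool), cfg$k)]
        mut <- which(stats::runif(cfg$k) < cfg$mutation_probability)
        if (length(mut)) {
          outside <- setdiff(idx_all, child)
          repl <- outside[sample.int(length(outside),
                                     min(length(mut), length(outside)))]
          child <- c(child[-mut[seq_along(repl)]], repl)
        }
        new_pop[[j]] <- sort(child)
      }
      pop <- new_pop
      fit <- vapply(pop, obj, numeric(1))
      trace[g] <- min(fit)
    }

    best_val <- min(fit)
    tied <- which(fit <= best_val + 1e-12)
    tied_ids <- lapply(pop[tied], function(idx) sort(as.character(candidates[idx])))
    ord <- order(vapply(tied_ids, paste, character(1), collapse = "\r"))
    structure(list(selected = tied_ids[[ord[1]]],
                   objective = obj(pop[[tied[ord[1]]]]),
                   trace = trace),
              class = "selection_result")
  })
}

#' Exact diversity-optimal subset by exhaustive enumeration
#'
#' Test oracle for [select_diverse()]: enumerates all `choose(n, k)` subsets
#' (refusing instances above one million) and returns the optimum, breaking
#' ties by the lexicographically smallest id set.
#'
#' @inheritParams select_diverse
#' @param k Subset size.
#' @param weights Objective weights.
#' @return A `selection_result` (with `trace = objective`).
#' @export
brute_force_select <- function(candidates, sim_text, sim_terms = NULL, k,
                               weights = c(1, 1)) {
  n <- length(candidates)
  if (k > n) stop("k exceeds number of candidates")
  if (choose(n, k) > 1e6) stop("instance too large for enumeration")
  S <- .combined_sim(sim_text[candidates, candidates, drop = FALSE],
                     if (is.null(sim_terms)) NULL else
                       sim_terms[candidates, candidates, drop = FALSE],
                     weights)
  dS <- diag(S)
  combs <- utils::combn(n, k)
  vals <- apply(combs, 2, .subset_objective, S = S, diag_S = dS)
  best <- min(vals)
  tied <- which(vals <= best + 1e-12)
  tied_ids <- lapply(tied, function(j) sort(as.character(candidates[combs[, j]])))
  ord <- order(vapply(tied_ids, paste, character(1), collapse = "\r"))
  structure(list(selected = tied_ids[[ord[1]]], objective = best,
                 trace = best),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("Diversity selection:", length(x$selected), "ids, objective",
      format(x$objective, digits = 6), "\n")
  invisible(x)
}

#' Write a selection result to disk
#'
#' Selected ids as a one-column TSV and the per-generation best-objective
#' trace as a two-column TSV.
#'
#' @param result A `selection_result`.
#' @param ids_path,trace_path Output paths (either may be NULL to skip).
#' @export
write_selection <- function(result, ids_path = NULL, trace_path = NULL) {
  if (!is.null(ids_path)) {
    utils::write.table(data.frame(fragment_id = result$selected), ids_path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(trace_path)) {
    utils::write.table(
      data.frame(generation = seq_along(result$trace), objective = result$trace),
      trace_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(result)
}
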