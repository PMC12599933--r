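#' Uncertainty scores from a class-posterior matrix
#'
#' Given per-sample class posteriors `P(y_c | x; theta)` (rows non-negative,
#' summing to 1), three classic pool-based uncertainty functionals score how
#' much a model would gain from having a sample labeled:
#'
#' * least confidence: `1 - max_c P(y_c | x)`, in `[0, 1 - 1/C]`;
#' * margin: `1 - (P(y1* | x) - P(y2* | x))`, one minus the gap between the
#'   top two classes, in `[0, 1]`;
#' * entropy: `-sum_c P(y_c | x) log P(y_c | x)` (natural log, `0 log 0 = 0`),
#'   maximized by the uniform row.
#'
#' Higher scores mean more uncertainty in all three.
#'
#' @param posteriors Numeric matrix, one row per unlabeled sample, one
#'   column per class.
#' @return Numeric score vector, one per row.
#' @export
#' @examples
#' P <- rbind(c(0.6, 0.3, 0.1), c(1, 0, 0))
#' least_confidence_scores(P)
#' margin_scores(P)
#' entropy_scores(P)
least_confidence_scores <- function(posteriors) {
  P <- check_posteriors(posteriors)
  1 - apply(P, 1, max)
}

#' @rdname least_confidence_scores
#' @export
margin_scores <- function(posteriors) {
  P <- check_posteriors(posteriors)
  if (ncol(P) < 2L) {
    stop_vteal("validation", "margin requires at least 2 classes")
  }
  top2 <- t(apply(P, 1, function(p) sort(p, decreasing = TRUE)[1:2]))
  1 - (top2[, 1] - top2[, 2])
}

#' @rdname least_confidence_scores
#' @export
entropy_scores <- function(posteriors) {
  P <- check_posteriors(posteriors)
  apply(P, 1, function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  })
}

check_posteriors <- function(posteriors) {
  P <- as.matrix(posteriors)
  if (!nrow(P) || !ncol(P)) stop_vteal("validation", "empty posterior matrix")
  if (any(P < -1e-9)) stop_vteal("validation", "negative class probabilities")
  if (any(abs(rowSums(P) - 1) > 1e-6)) {
    stop_vteal("validation", "posterior rows must sum to 1")
  }
  P
}

#' Query context: the substrate every query strategy reads
#'
#' @param labeled_ids Ids of already-labeled samples.
#' @param labels Their labels (same order).
#' @param unlabeled_ids Ids of the candidate pool (disjoint from
#'   `labeled_ids`).
#' @param posteriors Optional matrix of class posteriors for the unlabeled
#'   pool (rows in `unlabeled_ids` order), required by the uncertainty
#'   strategies.
#' @param vectors Optional document-vector matrix with rownames covering all
#'   labeled and unlabeled ids, required by the similarity strategies.
#' @param texts Optional named character vector of texts (for Length-Words).
#' @param rng Optional [rng_stream()] used by the random strategy and random
#'   tie-breaking.
#' @return A `vte_query_context`.
#' @export
query_context <- function(labeled_ids, labels, unlabeled_ids,
                          posteriors = NULL, vectors = NULL, texts = NULL,
                          rng = NULL) {
  labeled_ids <- as.character(labeled_ids)
  unlabeled_ids <- as.character(unlabeled_ids)
  if (length(labeled_ids) != length(labels)) {
    stop_vteal("validation", "labeled_ids and labels differ in length")
  }
  if (length(intersect(labeled_ids, unlabeled_ids))) {
    stop_vteal("validation", "labeled and unlabeled pools overlap")
  }
  if (!is.null(posteriors)) {
    posteriors <- as.matrix(posteriors)
    if (nrow(posteriors) != length(unlabeled_ids)) {
      stop_vteal("validation", "posteriors must have one row per unlabeled id")
    }
    rownames(posteriors) <- unlabeled_ids
  }
  structure(list(labeled_ids = labeled_ids, labels = as.character(labels),
                 unlabeled_ids = unlabeled_ids, posteriors = posteriors,
                 vectors = vectors, texts = texts, rng = rng),
            class = "vte_query_context")
}

#' Query-strategy specification
#'
#' @param name One of `random`, `least_confidence`, `margin`, `entropy`,
#'   `length_words`, `word_similarity`, `tfidf_similarity`,
#'   `wordsim_least_confidence`, `wordsim_margin`, `wordsim_entropy`.
#' @param tie_break `"lowest_index"` (default, reproducible) or `"random"`
#'   (drawn from the context rng).
#' @param similarity_aggregate How similarity-novelty aggregates over the
#'   labeled set: `"mean"` (default; stable to outlier labeled points) or
#'   `"min"`.
#' @return A `vte_strategy_spec`.
#' @export
strategy_spec <- function(name, tie_break = c("lowest_index", "random"),
                          similarity_aggregate = c("mean", "min")) {
  valid <- c("random", "least_confidence", "margin", "entropy",
             "length_words", "word_similarity", "tfidf_similarity",
             "wordsim_least_confidence", "wordsim_margin", "wordsim_entropy")
  if (!is.character(name) || length(name) != 1L || !(name %in% valid)) {
    stop_vteal("config", "unknown strategy name '", paste(name), "'; valid: ",
               paste(valid, collapse = ", "))
  }
  structure(list(name = name, tie_break = match.arg(tie_break),
                 similarity_aggregate = match.arg(similarity_aggregate)),
            class = "vte_strategy_spec")
}

# argmax with configurable tie handling; the winner's score travels along
# as an attribute for the selection audit trail.
pick_best <- function(ids, scores, tie_break = "lowest_index", rng = NULL) {
  best <- which(scores == max(scores))
  if (length(best) > 1L && tie_break == "random") {
    best <- if (is.null(rng)) best[sample.int(length(best), 1L)]
            else rng_draw(rng, best[sample.int(length(best), 1L)])
  } else {
    best <- best[1L]
  }
  structure(ids[best], score = scores[best])
}

#' Length-Words selection
#'
#' Selects the unlabeled report with the greatest token count, on the
#' premise that longer reports potentially carry more information.
#'
#' @param context A [query_context()] with `texts`.
#' @param tie_break See [strategy_spec()].
#' @return The selected unlabeled id.
#' @export
length_words_select <- function(context, tie_break = "lowest_index") {
  stopifnot(inherits(context, "vte_query_context"))
  if (is.null(context$texts)) stop_vteal("config", "length_words needs texts")
  txt <- context$texts[context$unlabeled_ids]
  if (anyNA(txt)) stop_vteal("config", "texts missing for some unlabeled ids")
  n_tokens <- lengths(tokenize(txt))
  pick_best(context$unlabeled_ids, n_tokens, tie_break, context$rng)
}

# similarity of each unlabeled candidate to the labeled set
novelty_scores <- function(context, aggregate = "mean") {
  if (is.null(context$vectors)) {
    stop_vteal("config", "similarity strategies need document vectors")
  }
  if (!length(context$labeled_ids)) {
    stop_vteal("validation", "similarity strategies need a labeled set")
  }
  need <- c(context$labeled_ids, context$unlabeled_ids)
  if (!all(need %in% rownames(context$vectors))) {
    stop_vteal("config", "vectors missing for some ids")
  }
  S <- cosine_rows(context$vectors[context$unlabeled_ids, , drop = FALSE],
                   context$vectors[context$labeled_ids, , drop = FALSE])
  if (aggregate == "mean") rowMeans(S) else apply(S, 1, min)
}

#' Minimum-similarity (novelty) selection
#'
#' For each unlabeled candidate the novelty score is its mean (or minimum)
#' cosine similarity to the already-labeled samples; the candidate with the
#' lowest score is the "most novel" and is selected.  Used with dense word
#' vectors (word similarity) or TF-IDF vectors (TF-IDF similarity).
#'
#' @inheritParams length_words_select
#' @param aggregate `"mean"` (default) or `"min"` over labeled samples.
#' @return The selected unlabeled id.
#' @export
min_similarity_select <- function(context, aggregate = c("mean", "min"),
                                  tie_break = "lowest_index") {
  stopifnot(inherits(context, "vte_query_context"))
  aggregate <- match.arg(aggregate)
  s <- novelty_scores(context, aggregate)
  pick_best(context$unlabeled_ids, -s, tie_break, context$rng)
}

#' Per-class average similarity of a candidate
#'
#' For candidate `u`, component `c` is the mean cosine similarity between
#' `u` and the labeled members of class `c`
#' (`1/|L_c| * sum_{x in L_c} sim(x, u)`); classes with no labeled members
#' are omitted.
#'
#' @param context A [query_context()] with `vectors`.
#' @param u An unlabeled id.
#' @return Named numeric vector over the classes with labeled members.
#' @export
class_average_similarity <- function(context, u) {
  stopifnot(inherits(context, "vte_query_context"))
  if (!length(context$labeled_ids)) {
    stop_vteal("validation", "no labeled data")
  }
  if (is.null(context$vectors) ||
      !all(c(u, context$labeled_ids) %in% rownames(context$vectors))) {
    stop_vteal("config", "vectors missing for some ids")
  }
  sims <- drop(cosine_rows(
    context$vectors[u, , drop = FALSE],
    context$vectors[context$labeled_ids, , drop = FALSE]))
  tapply(sims, context$labels, mean)
}

#' Word-similarity uncertainty selection
#'
#' Combines per-class average similarity with an uncertainty functional:
#' each candidate's class-average-similarity vector is shifted to be
#' non-negative (subtracting its minimum) and L1-normalized into a
#' pseudo-posterior, the chosen uncertainty score (least confidence, margin
#' or entropy) is applied, and the most uncertain candidate is selected.
#' A candidate equally similar to every class is therefore maximally
#' queried.  With a single labeled class the pseudo-posterior is degenerate,
#' so the strategy falls back to [min_similarity_select()] with a warning.
#'
#' @inheritParams length_words_select
#' @param mode `"least_confidence"`, `"margin"` or `"entropy"`.
#' @return The selected unlabeled id.
#' @export
similarity_uncertainty_select <- function(context,
                                          mode = c("least_confidence",
                                                   "margin", "entropy"),
                                          tie_break = "lowest_index") {
  stopifnot(inherits(context, "vte_query_context"))
  mode <- match.arg(mode)
  classes <- unique(context$labels)
  if (length(classes) < 2L) {
    warning("single labeled class; falling back to min-similarity novelty",
            call. = FALSE)
    return(min_similarity_select(context, tie_break = tie_break))
  }
  pseudo <- t(vapply(context$unlabeled_ids, function(u) {
    class_sim_to_pseudo_posterior(class_average_similarity(context, u))
  }, numeric(length(classes))))
  scorer <- switch(mode,
                   least_confidence = least_confidence_scores,
                   margin = margin_scores,
                   entropy = entropy_scores)
  pick_best(context$unlabeled_ids, scorer(pseudo), tie_break, context$rng)
}

# Shift-to-non-negative then L1-normalize; an all-equal vector maps to the
# uniform distribution (maximal uncertainty under every functional).
class_sim_to_pseudo_posterior <- function(sims) {
  shifted <- sims - min(sims)
  if (sum(shifted) == 0) rep(1 / length(sims), length(sims))
  else shifted / sum(shifted)
}

#' Select the next sample to label
#'
#' Dispatches to the named query strategy: `random` draws uniformly from the
#' pool via the context rng; the uncertainty strategies return the
#' argmax-score candidate from the posterior matrix; `length_words` the
#' longest text; the similarity strategies the argmin-novelty candidate; and
#' the `wordsim_*` strategies the combined word-similarity uncertainty
#' selection.  A missing required input raises a configuration error naming
#' it.
#'
#' @param spec A [strategy_spec()].
#' @param context A [query_context()].
#' @return The selected unlabeled id.
#' @export
select_query <- function(spec, context) {
  stopifnot(inherits(spec, "vte_strategy_spec"),
            inherits(context, "vte_query_context"))
  if (!length(context$unlabeled_ids)) {
    stop_vteal("validation", "unlabeled pool is empty")
  }
  need_posteriors <- function() {
    if (is.null(context$posteriors)) {
      stop_vteal("config", "strategy '", spec$name,
                 "' requires posteriors, which are absent from the context")
    }
    context$posteriors
  }
  switch(spec$name,
    random = {
      if (is.null(context$rng)) {
        stop_vteal("config", "random strategy requires a context rng")
      }
      rng_draw(context$rng, {
        structure(
          context$unlabeled_ids[sample.int(length(context$unlabeled_ids), 1L)],
          score = NA_real_)
      })
    },
    least_confidence = pick_best(context$unlabeled_ids,
                                 least_confidence_scores(need_posteriors()),
                                 spec$tie_break, context$rng),
    margin = pick_best(context$unlabeled_ids,
                       margin_scores(need_posteriors()),
                       spec$tie_break, context$rng),
    entropy = pick_best(context$unlabeled_ids,
                        entropy_scores(need_posteriors()),
                        spec$tie_break, context$rng),
    length_words = length_words_select(context, spec$tie_break),
    word_similarity = min_similarity_select(
      context, aggregate = spec$similarity_aggregate,
      tie_break = spec$tie_break),
    tfidf_similarity = min_similarity_select(
      context, aggregate = spec$similarity_aggregate,
      tie_break = spec$tie_break),
    wordsim_least_confidence = similarity_uncertainty_select(
      context, "least_confidence", spec$tie_break),
    wordsim_margin = similarity_uncertainty_select(
      context, "margin", spec$tie_break),
    wordsim_entropy = similarity_uncertainty_select(
      context, "entropy", spec$tie_break)
  )
}
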