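#' Active-learning experiment configuration
#'
#' The epoch protocol: a model is seeded with `seed_size` labeled samples
#' drawn uniformly at random from the training pool, then at every query
#' iteration one sample is selected by the query strategy, labeled, added to
#' the training set, and the model is retrained from scratch; test-set F1 is
#' recorded after the seed fit and after every query.  An epoch ends when
#' the labeled count reaches the budget, and the whole process is repeated
#' for `epochs` independent epochs whose F1 trajectories are averaged per
#' iteration.
#'
#' @param seed_size Initial labeled-set size (default 8).  Classes may be
#'   missing from the seed: models are fit on the classes present, absent
#'   classes get probability 0, and the zero-division convention keeps F1
#'   defined.
#' @param budget Labeling budget: a fraction of the training pool if `< 1`
#'   (default 0.5), otherwise an absolute labeled-set size.
#' @param epochs Number of independent active-learning epochs (default 50).
#' @param strategy A [strategy_spec()].
#' @param classifier A [classifier_spec()].
#' @param embedding Feature space: `"tf"`, `"tfidf"`, `"word_average"`, or
#'   `"document"`.
#' @param embedding_dim Dimension of the dense spaces (default 100).
#' @param f1_average F1 averaging scheme recorded on the learning curve.
#' @param master_seed Seed of the whole experiment; epoch e uses
#'   `master_seed + e`.
#' @return A `vte_al_config`.
#' @export
al_config <- function(seed_size = 8L, budget = 0.5, epochs = 50L,
                      strategy = strategy_spec("random"),
                      classifier = classifier_spec("random_forest"),
                      embedding = c("tf", "tfidf", "word_average",
                                    "document"),
                      embedding_dim = 100L, f1_average = "macro",
                      master_seed = 1L) {
  embedding <- match.arg(embedding)
  stopifnot(inherits(strategy, "vte_strategy_spec"),
            inherits(classifier, "vte_classifier_spec"))
  seed_size <- as.integer(seed_size)
  if (seed_size < 1L) stop_vteal("config", "seed_size must be >= 1")
  if (budget >= 1 && budget <= seed_size) {
    stop_vteal("config", "absolute budget must exceed seed_size")
  }
  structure(list(seed_size = seed_size, budget = budget,
                 epochs = as.integer(epochs), strategy = strategy,
                 classifier = classifier, embedding = embedding,
                 embedding_dim = as.integer(embedding_dim),
                 f1_average = f1_average,
                 master_seed = as.integer(master_seed)),
            class = "vte_al_config")
}

strategy_needs <- function(name) {
  list(
    posteriors = name %in% c("least_confidence", "margin", "entropy"),
    vectors = name %in% c("word_similarity", "tfidf_similarity",
                          "wordsim_least_confidence", "wordsim_margin",
                          "wordsim_entropy"),
    texts = name == "length_words"
  )
}

resolve_budget <- function(budget, n_pool) {
  n <- if (budget < 1) round(budget * n_pool) else min(budget, n_pool)
  as.integer(n)
}

# posterior matrix over the full label set, zero for classes the model has
# not seen
expand_posteriors <- function(P, labels) {
  out <- matrix(0, nrow(P), length(labels),
                dimnames = list(rownames(P), labels))
  out[, colnames(P)] <- P
  out
}

#' Run one active-learning epoch
#'
#' @param config A [al_config()].
#' @param train_pool List with `X` (feature matrix), `y` (labels), and
#'   optionally `ids`, `texts` (named by id), `vectors` (document-vector
#'   matrix with rownames, for similarity strategies).
#' @param test_set List with `X` and `y`.
#' @param epoch_seed Integer seed of this epoch (seed draw, tie-breaks,
#'   random strategy, and classifier fits all derive from it).
#' @return Numeric F1 trajectory of length `1 + queries`, with the selected
#'   ids in attribute `"selections"`.
#' @export
run_epoch <- function(config, train_pool, test_set, epoch_seed = 1L) {
  stopifnot(inherits(config, "vte_al_config"))
  X <- as.matrix(train_pool$X)
  y <- as.character(train_pool$y)
  n <- nrow(X)
  ids <- if (!is.null(train_pool$ids)) as.character(train_pool$ids)
         else sprintf("d%d", seq_len(n))
  budget_n <- resolve_budget(config$budget, n)
  if (budget_n <= config$seed_size) {
    stop_vteal("config", "budget leaves no room for queries")
  }
  if (budget_n > n) stop_vteal("config", "budget exceeds the training pool")
  needs <- strategy_needs(config$strategy$name)
  if (needs$vectors && is.null(train_pool$vectors)) {
    stop_vteal("config", "strategy '", config$strategy$name,
               "' requires train_pool$vectors")
  }
  if (needs$texts && is.null(train_pool$texts)) {
    stop_vteal("config", "strategy '", config$strategy$name,
               "' requires train_pool$texts")
  }
  scheme_labels <- sort(unique(c(y, as.character(test_set$y))))
  Xtest <- as.matrix(test_set$X)
  ytest <- as.character(test_set$y)

  rng <- rng_stream(epoch_seed)
  labeled <- rng_draw(rng, sample.int(n, config$seed_size))
  unlabeled <- setdiff(seq_len(n), labeled)

  eval_f1 <- function() {
    model <- fit_classifier(config$classifier, X[labeled, , drop = FALSE],
                            y[labeled], seed = epoch_seed)
    pred <- predict_label(model, Xtest)
    list(f1 = score_f1(ytest, pred, average = config$f1_average),
         model = model)
  }
  state <- eval_f1()
  f1s <- state$f1
  selections <- character(0)

  while (length(labeled) < budget_n) {
    posteriors <- NULL
    if (needs$posteriors) {
      P <- predict_prob(state$model, X[unlabeled, , drop = FALSE])
      posteriors <- expand_posteriors(P, scheme_labels)
    }
    ctx <- query_context(
      labeled_ids = ids[labeled], labels = y[labeled],
      unlabeled_ids = ids[unlabeled], posteriors = posteriors,
      vectors = train_pool$vectors, texts = train_pool$texts, rng = rng)
    chosen <- as.character(select_query(config$strategy, ctx))
    j <- match(chosen, ids)
    labeled <- c(labeled, j)
    unlabeled <- setdiff(unlabeled, j)
    selections <- c(selections, chosen)
    state <- eval_f1()
    f1s <- c(f1s, state$f1)
  }
  structure(f1s, selections = selections)
}

#' Run a full active-learning experiment
#'
#' Splits the corpus once (8:2, stratified), fits the feature space on the
#' training pool only, and runs [run_epoch()] for every epoch with seeds
#' `master_seed + 1 .. master_seed + epochs`; the per-iteration mean and
#' standard deviation of the F1 trajectories form the learning curve.
#'
#' @param config A [al_config()].
#' @param corpus A `vte_corpus`.
#' @return A `vte_learning_curve` (see [curve_aggregate()]) with attributes
#'   `config` and `selections` (per-epoch id sequences).
#' @export
run_experiment <- function(config, corpus) {
  stopifnot(inherits(config, "vte_al_config"), is_corpus(corpus))
  parts <- split_corpus(corpus, split_spec(0.8, seed = config$master_seed,
                                           stratified = TRUE))
  feats <- build_feature_space(config, parts$train, parts$test)
  train_pool <- list(X = feats$X_train, y = parts$train$label,
                     ids = parts$train$id,
                     texts = stats::setNames(parts$train$text,
                                             parts$train$id),
                     vectors = feats$vectors)
  test_set <- list(X = feats$X_test, y = parts$test$label)
  trajectories <- lapply(seq_len(config$epochs), function(e) {
    run_epoch(config, train_pool, test_set,
              epoch_seed = config$master_seed + e)
  })
  curve <- curve_aggregate(lapply(trajectories, as.numeric))
  attr(curve, "config") <- config
  attr(curve, "selections") <- lapply(trajectories, attr, "selections")
  curve
}

# Fit the configured embedding on the training pool and transform both
# partitions; also supplies the vector space read by similarity strategies.
build_feature_space <- function(config, train, test) {
  vocab <- build_vocabulary(train)
  if (config$embedding %in% c("tf", "tfidf")) {
    Xtr <- tf_vectorize(train, vocab)
    Xte <- tf_vectorize(test, vocab)
    if (config$embedding == "tfidf") {
      Xtr <- tfidf_weight(Xtr, vocab)
      Xte <- tfidf_weight(Xte, vocab)
    }
    Xtr <- as.matrix(Xtr); Xte <- as.matrix(Xte)
  } else {
    mode <- if (config$embedding == "word_average") "word-average"
            else "document"
    model <- train_dense_embeddings(train, mode = mode,
                                    dim = config$embedding_dim)
    Xtr <- model$vectors
    Xte <- embed_documents(model, test)
  }
  rownames(Xtr) <- train$id
  rownames(Xte) <- test$id
  vectors <- if (config$strategy$name == "tfidf_similarity" &&
                 config$embedding != "tfidf") {
    V <- as.matrix(tfidf_weight(tf_vectorize(train, vocab), vocab))
    rownames(V) <- train$id
    V
  } else Xtr
  list(X_train = Xtr, X_test = Xte, vectors = vectors, vocab = vocab)
}

#' Write a learning curve as TSV
#'
#' Columns `iteration`, `mean_f1`, `sd_f1`, plus one `epoch_<e>` column per
#' epoch when `per_epoch = TRUE`.
#'
#' @param curve A `vte_learning_curve`.
#' @param path Output file.
#' @param per_epoch Include per-epoch trajectories.
#' @return `path`, invisibly.
#' @export
write_curve_tsv <- function(curve, path, per_epoch = TRUE) {
  stopifnot(inherits(curve, "vte_learning_curve"))
  df <- data.frame(iteration = curve$iteration, mean_f1 = curve$mean,
                   sd_f1 = curve$sd)
  if (per_epoch) {
    m <- t(curve$trajectories)
    colnames(m) <- sprintf("epoch_%d", seq_len(ncol(m)))
    df <- cbind(df, m)
  }
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
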