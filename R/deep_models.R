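#' Tokenizer specification for the sequence models
#'
#' Every document is encoded to exactly `max_length` token indices: shorter
#' documents are right-padded with the pad index (0), longer ones keep their
#' first `max_length` tokens (excess truncated from the end).
#'
#' @param max_length Encoded length in tokens (default 256).
#' @return A `vte_tokenizer_spec`.
#' @export
tokenizer_spec <- function(max_length = 256L) {
  max_length <- as.integer(max_length)
  if (is.na(max_length) || max_length < 1L) {
    stop_vteal("config", "max_length must be a positive integer")
  }
  structure(list(max_length = max_length, pad_index = 0L,
                 truncation = "end"),
            class = "vte_tokenizer_spec")
}

#' Encode texts to fixed-length index matrices
#'
#' Tokens are mapped to the indices of a vocabulary fitted on the training
#' folds only; out-of-vocabulary tokens are dropped.
#'
#' @param texts Character vector.
#' @param spec A [tokenizer_spec()].
#' @param vocab A [build_vocabulary()].
#' @return Integer matrix `(length(texts), max_length)`; 0 is padding.
#' @export
encode_batch <- function(texts, spec, vocab) {
  stopifnot(inherits(spec, "vte_tokenizer_spec"),
            inherits(vocab, "vte_vocabulary"))
  toks <- as_token_list(texts)
  L <- spec$max_length
  out <- t(vapply(toks, function(t) {
    j <- match(t, vocab$tokens)
    j <- j[!is.na(j)]
    if (length(j) > L) j <- j[seq_len(L)]
    c(j, rep(0L, L - length(j)))
  }, integer(L)))
  out
}

#' Early-stopping rule
#'
#' Training halts when the validation metric has failed to improve on its
#' running best by at least `min_delta` for `patience` consecutive epochs.
#'
#' @param history Validation-accuracy sequence, one value per completed
#'   epoch (oldest first).
#' @param min_delta Minimum improvement that counts (default 1e-4).
#' @param patience Number of consecutive sub-threshold epochs that triggers
#'   the stop (default 2).
#' @return `TRUE` if training should stop after the last epoch in `history`.
#' @export
#' @examples
#' early_stop_check(c(0.80, 0.80005, 0.80009))  # TRUE
#' early_stop_check(c(0.80, 0.85, 0.851))       # FALSE
early_stop_check <- function(history, min_delta = 1e-4, patience = 2L) {
  if (!length(history)) stop_vteal("validation", "empty history")
  if (length(history) < patience + 1L) return(FALSE)
  improvement <- vapply(seq_along(history)[-1L], function(i) {
    history[i] - max(history[seq_len(i - 1L)])
  }, numeric(1))
  all(utils::tail(improvement, patience) < min_delta)
}

#' Deep-learning configuration
#'
#' @param architecture `"lstm"`, `"cnn1d"` (single kernel of width 3),
#'   `"multikernel_cnn1d"` (kernel widths 3/4/5, max-over-time pooled and
#'   concatenated), or `"multikernel_cnn1d_pretrained"` (the same network
#'   with the embedding table initialized from word vectors; by default
#'   these are trained on the training fold itself so no download is
#'   needed, or supply a GloVe-format text file via `pretrained_path`).
#' @param kernel_sizes Kernel widths for the multi-kernel variants.
#' @param embedding_dim,hidden_dim,filters Capacities (defaults 64/64/32,
#'   sized for desk-scale CPU training).
#' @param max_epochs Training epochs cap (default 50).
#' @param min_delta,patience Early-stopping rule parameters (defaults
#'   1e-4 / 2 on validation accuracy); set `early_stopping = FALSE` to
#'   always train `max_epochs`.
#' @param folds Cross-validation folds (default 5).
#' @param batch_size,learning_rate ADAM minibatch training parameters.
#' @param max_length See [tokenizer_spec()].
#' @param val_fraction Stratified share of each fold's training portion
#'   held out to monitor validation accuracy (default 0.1).
#' @param pretrained_path Optional word-vector text file
#'   (`token v1 ... vD` per line) for the pretrained variant.
#' @param seed Integer seed; deterministic mode.
#' @return A `vte_dl_config`.
#' @export
dl_config <- function(architecture = c("lstm", "cnn1d", "multikernel_cnn1d",
                                       "multikernel_cnn1d_pretrained"),
                      kernel_sizes = c(3L, 4L, 5L), embedding_dim = 64L,
                      hidden_dim = 64L, filters = 32L, max_epochs = 50L,
                      min_delta = 1e-4, patience = 2L,
                      early_stopping = TRUE, folds = 5L, batch_size = 32L,
                      learning_rate = 0.01, max_length = 256L,
                      val_fraction = 0.1, pretrained_path = NULL,
                      seed = 1L) {
  architecture <- match.arg(architecture)
  if (folds < 2L) stop_vteal("config", "folds must be >= 2")
  if (min_delta <= 0) stop_vteal("config", "min_delta must be > 0")
  kernels <- if (architecture == "cnn1d") 3L else as.integer(kernel_sizes)
  structure(list(architecture = architecture, kernels = kernels,
                 embedding_dim = as.integer(embedding_dim),
                 hidden_dim = as.integer(hidden_dim),
                 filters = as.integer(filters),
                 max_epochs = as.integer(max_epochs),
                 min_delta = min_delta, patience = as.integer(patience),
                 early_stopping = isTRUE(early_stopping),
                 folds = as.integer(folds),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 max_length = as.integer(max_length),
                 val_fraction = val_fraction,
                 pretrained_path = pretrained_path,
                 seed = as.integer(seed)),
            class = "vte_dl_config")
}

#' Read a word-vector table in GloVe text format
#'
#' One `token v1 v2 ... vD` record per line, whitespace-separated.
#'
#' @param path Text file.
#' @return Numeric matrix with tokens as rownames.
#' @export
read_word_vectors <- function(path) {
  if (!file.exists(path)) stop_vteal("io", "word-vector file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\\s+")
  toks <- vapply(parts, `[[`, character(1), 1L)
  vals <- lapply(parts, function(p) as.numeric(p[-1L]))
  if (length(unique(lengths(vals))) != 1L) {
    stop_vteal("schema", "inconsistent vector dimensions in ", path)
  }
  m <- do.call(rbind, vals)
  rownames(m) <- toks
  m
}

# Pretrained embedding rows aligned to `vocab` (zero for uncovered tokens).
align_pretrained <- function(vocab, dim, pretrained_path, train_texts) {
  wv <- if (!is.null(pretrained_path)) read_word_vectors(pretrained_path)
  else {
    model <- train_dense_embeddings(train_texts, mode = "word-average",
                                    dim = dim)
    model$word_vectors
  }
  if (ncol(wv) != dim) {
    stop_vteal("config", sprintf(
      "pretrained vectors have dim %d, expected %d", ncol(wv), dim))
  }
  E <- matrix(rnorm(length(vocab$tokens) * dim, sd = 0.1),
              length(vocab$tokens), dim)
  hit <- match(vocab$tokens, rownames(wv))
  E[!is.na(hit), ] <- wv[hit[!is.na(hit)], , drop = FALSE]
  E
}

#' Train one sequence classifier
#'
#' Minibatch ADAM training with per-epoch validation accuracy and the
#' [early_stop_check()] rule.  Deterministic given `config$seed`.
#'
#' @param config A [dl_config()].
#' @param texts,labels Training documents.
#' @param val_texts,val_labels Validation set monitored for early stopping;
#'   when omitted, a stratified `val_fraction` of the training data is held
#'   out.
#' @param classes Label set for the output layer (defaults to the labels
#'   observed).
#' @return A `vte_dl_model` with `$history` (validation accuracy per epoch).
#' @export
train_dl <- function(config, texts, labels, val_texts = NULL,
                     val_labels = NULL, classes = NULL) {
  stopifnot(inherits(config, "vte_dl_config"))
  labels <- as.character(labels)
  if (is.null(classes)) classes <- sort(unique(labels))
  with_seed(config$seed, {
    if (is.null(val_texts)) {
      hold <- stratified_holdout(labels, config$val_fraction)
      val_texts <- texts[hold]
      val_labels <- labels[hold]
      texts <- texts[-hold]
      labels <- labels[-hold]
    }
    spec <- tokenizer_spec(config$max_length)
    vocab <- build_vocabulary(texts)
    ids <- encode_batch(texts, spec, vocab)
    ids_val <- encode_batch(val_texts, spec, vocab)
    y <- match(labels, classes)
    y_val <- match(as.character(val_labels), classes)

    arch <- if (config$architecture == "lstm") "lstm" else "cnn"
    pretrained_E <-
      if (config$architecture == "multikernel_cnn1d_pretrained") {
        align_pretrained(vocab, config$embedding_dim,
                         config$pretrained_path, texts)
      }
    params <- nn_init_params(arch, length(vocab$tokens),
                             config$embedding_dim, config$hidden_dim,
                             config$filters, config$kernels,
                             length(classes), pretrained_E)
    state <- adam_init(params)
    n <- nrow(ids)
    history <- numeric(0)
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = config$batch_size)
      for (s in starts) {
        sel <- ord[s:min(s + config$batch_size - 1L, n)]
        out <- nn_pass(params, arch, config$kernels,
                       ids[sel, , drop = FALSE], y[sel])
        upd <- adam_step(params, out$grads, state,
                         lr = config$learning_rate)
        params <- upd$params
        state <- upd$state
      }
      pv <- nn_pass(params, arch, config$kernels, ids_val)$probs
      acc <- mean(max.col(pv, ties.method = "first") == y_val)
      history <- c(history, acc)
      if (config$early_stopping &&
          early_stop_check(history, config$min_delta, config$patience)) {
        break
      }
    }
    structure(list(params = params, arch = arch, kernels = config$kernels,
                   classes = classes, vocab = vocab, spec = spec,
                   config = config, history = history),
              class = "vte_dl_model")
  })
}

stratified_holdout <- function(labels, fraction) {
  idx <- unlist(lapply(unique(labels), function(l) {
    members <- which(labels == l)
    take <- max(1L, round(fraction * length(members)))
    if (take >= length(members)) take <- length(members) - 1L
    if (take < 1L) return(integer(0))
    members[sample.int(length(members), take)]
  }), use.names = FALSE)
  if (!length(idx)) idx <- sample.int(length(labels), 1L)
  sort(idx)
}

#' @export
predict.vte_dl_model <- function(object, texts, type = c("prob", "label"),
                                 ...) {
  type <- match.arg(type)
  ids <- encode_batch(texts, object$spec, object$vocab)
  P <- nn_pass(object$params, object$arch, object$kernels, ids)$probs
  colnames(P) <- object$classes
  if (type == "prob") P
  else object$classes[max.col(P, ties.method = "first")]
}

# Stratified fold assignment (1..k per document), seeded by caller's RNG.
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (l in unique(labels)) {
    members <- which(labels == l)
    if (length(members) < k) {
      warning(sprintf(
        "class '%s' has %d member(s), fewer than %d folds; stratification degrades",
        l, length(members), k), call. = FALSE)
    }
    fold[members] <- ((sample.int(length(members)) - 1L) %% k) + 1L
  }
  fold
}

#' Stratified cross-validation of a sequence classifier
#'
#' Stratified k-fold protocol: per fold, a model is trained on the other
#' folds (with an inner stratified validation split for early stopping) and
#' scored on the held-out fold; per-fold F1 is the macro average over the
#' classes present in the fold's test documents or predictions.
#'
#' @param config A [dl_config()].
#' @param corpus A `vte_corpus`.
#' @param scheme `"7-class"` or `"6-class"` (applied via
#'   [restrict_labels()]).
#' @param f1_average Averaging scheme for the per-fold F1.
#' @return A `vte_cv_result`: list with `folds` (per-fold data frame rows:
#'   fold, n_train, n_test, f1, epochs_run) and `mean_f1`.
#' @export
train_cv <- function(config, corpus, scheme = c("7-class", "6-class"),
                     f1_average = "macro") {
  stopifnot(inherits(config, "vte_dl_config"), is_corpus(corpus))
  scheme <- match.arg(scheme)
  corpus <- restrict_labels(corpus, scheme)
  if (nrow(corpus) == 0L) {
    stop_vteal("validation", "no reports under the ", scheme, " scheme")
  }
  observed <- unique(corpus$label)
  empty <- setdiff(vte_labels(scheme), observed)
  if (length(empty) == length(vte_labels(scheme))) {
    stop_vteal("validation", "no labeled classes under the scheme")
  }
  classes <- intersect(vte_labels(scheme), observed)
  folds <- with_seed(config$seed, stratified_folds(corpus$label,
                                                   config$folds))
  records <- lapply(seq_len(config$folds), function(f) {
    tr <- corpus[folds != f, , drop = FALSE]
    te <- corpus[folds == f, , drop = FALSE]
    fold_cfg <- config
    fold_cfg$seed <- config$seed + f
    model <- train_dl(fold_cfg, tr$text, tr$label, classes = classes)
    pred <- if (nrow(te)) predict(model, te$text, type = "label")
            else character(0)
    f1 <- if (nrow(te)) score_f1(te$label, pred, average = f1_average)
          else NA_real_
    data.frame(fold = f, n_train = nrow(tr), n_test = nrow(te), f1 = f1,
               epochs_run = length(model$history))
  })
  folds_df <- do.call(rbind, records)
  structure(list(folds = folds_df,
                 mean_f1 = mean(folds_df$f1, na.rm = TRUE),
                 scheme = scheme, architecture = config$architecture),
            class = "vte_cv_result")
}

#' @export
print.vte_cv_result <- function(x, ...) {
  cat(sprintf("<vte_cv_result> %s, %s: mean F1 %.4f over %d folds\n",
              x$architecture, x$scheme, x$mean_f1, nrow(x$folds)))
  invisible(x)
}

#' Per-report inference timing
#'
#' Mean wall-clock seconds to process a single report (tokenization +
#' classification, batch size 1) over a test set.  Hardware-dependent by
#' nature; the report records the machine descriptor and asserts no numeric
#' target.
#'
#' @param model A `vte_dl_model` (or any object with a
#'   `predict(model, texts)` method).
#' @param texts Test documents.
#' @param spec Unused for `vte_dl_model` (the model carries its tokenizer);
#'   accepted for interface parity.
#' @return A `vte_timing_report`: list with `mean_seconds`, `n`,
#'   `batch_size` (1), `includes_tokenization` (TRUE), `machine`.
#' @export
measure_inference_time <- function(model, texts, spec = NULL) {
  if (!length(texts)) stop_vteal("validation", "empty test set")
  elapsed <- vapply(texts, function(tx) {
    t0 <- proc.time()[["elapsed"]]
    predict(model, tx, type = "prob")
    proc.time()[["elapsed"]] - t0
  }, numeric(1))
  structure(list(mean_seconds = mean(elapsed), n = length(texts),
                 batch_size = 1L, includes_tokenization = TRUE,
                 machine = paste(Sys.info()[["sysname"]],
                                 Sys.info()[["machine"]], R.version.string)),
            class = "vte_timing_report")
}

#' Plug-in interface for external fine-tunable encoders
#'
#' Runs the identical stratified cross-validation protocol through a
#' caller-supplied encoder/classifier (e.g. a transformer fine-tuned
#' outside this package).  No pretrained weights are shipped or required: a
#' descriptor is either a list of functions or the name of an optional
#' package, and an unresolvable descriptor raises a distinct
#' `vteal_missing_dependency_error`.
#'
#' @param descriptor Either a list with functions
#'   `encode(texts) -> features`, `fit(features, labels) -> model` and
#'   `predict(model, features) -> labels`, or a single package name to be
#'   resolved (the package must export those three functions).
#' @param corpus A `vte_corpus`.
#' @param config A [dl_config()] (folds and seed are honored).
#' @param scheme Label scheme.
#' @return A `vte_cv_result`, as from [train_cv()].
#' @export
plugin_transformer_interface <- function(descriptor, corpus,
                                         config = dl_config(),
                                         scheme = "7-class") {
  if (is.character(descriptor)) {
    if (!requireNamespace(descriptor, quietly = TRUE)) {
      stop_vteal("missing_dependency",
                 "optional dependency missing: package '", descriptor,
                 "' is not installed; supply a descriptor list instead")
    }
    ns <- asNamespace(descriptor)
    descriptor <- list(encode = get("encode", ns), fit = get("fit", ns),
                       predict = get("predict", ns))
  }
  if (!is.list(descriptor) ||
      !all(vapply(descriptor[c("encode", "fit", "predict")], is.function,
                  logical(1)))) {
    stop_vteal("missing_dependency",
               "descriptor must provide encode/fit/predict functions")
  }
  corpus <- restrict_labels(corpus, scheme)
  folds <- with_seed(config$seed, stratified_folds(corpus$label,
                                                   config$folds))
  records <- lapply(seq_len(config$folds), function(f) {
    tr <- corpus[folds != f, , drop = FALSE]
    te <- corpus[folds == f, , drop = FALSE]
    feats_tr <- descriptor$encode(tr$text)
    model <- descriptor$fit(feats_tr, tr$label)
    pred <- descriptor$predict(model, descriptor$encode(te$text))
    data.frame(fold = f, n_train = nrow(tr), n_test = nrow(te),
               f1 = score_f1(te$label, pred), epochs_run = NA_integer_)
  })
  folds_df <- do.call(rbind, records)
  structure(list(folds = folds_df, mean_f1 = mean(folds_df$f1),
                 scheme = scheme, architecture = "plugin"),
            class = "vte_cv_result")
}
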