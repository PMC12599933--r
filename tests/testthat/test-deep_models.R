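# Reduced capacities keep these CPU tests in seconds.
fast_dl <- function(architecture, ...) {
  args <- list(architecture = architecture, embedding_dim = 24L,
               hidden_dim = 24L, filters = 12L, batch_size = 16L,
               max_epochs = 12L, max_length = 48L)
  override <- list(...)
  args[names(override)] <- override
  do.call(dl_config, args)
}

test_that("encode_batch pads, truncates, and keeps shape", {
  vocab <- build_vocabulary(list(letters))
  spec <- tokenizer_spec(256L)
  doc100 <- paste(sample(letters, 100, replace = TRUE), collapse = " ")
  doc300 <- paste(sample(letters, 300, replace = TRUE), collapse = " ")
  m <- encode_batch(c(doc100, doc300, ""), spec, vocab)
  expect_equal(dim(m), c(3L, 256L))
  expect_equal(sum(m[1, ] > 0), 100L)
  expect_equal(m[1, 101:256], rep(0L, 156))
  expect_equal(sum(m[2, ] > 0), 256L)
  # truncation keeps the first 256 tokens
  toks <- tokenize(doc300)[[1]]
  expect_equal(as.integer(m[2, ]), match(toks[1:256], vocab$tokens))
  expect_equal(m[3, ], rep(0L, 256))
})

test_that("early_stop_check implements the min-delta/patience rule", {
  expect_true(early_stop_check(c(0.80, 0.80005, 0.80009), 1e-4, 2))
  expect_false(early_stop_check(c(0.80, 0.85, 0.851), 1e-4, 2))
  # monotone +0.01 history never stops
  for (len in c(3, 10, 25)) {
    expect_false(early_stop_check(0.5 + 0.01 * seq_len(len), 1e-4, 2))
  }
  expect_false(early_stop_check(c(0.8), 1e-4, 2))  # shorter than patience+1
  expect_true(early_stop_check(c(0.9, 0.9, 0.9), 1e-4, 2))
  expect_error(early_stop_check(numeric(0)),
               class = "vteal_validation_error")
})

test_that("train_cv produces one record per fold and is reproducible", {
  corp <- separable_corpus(n = 42, seed = 13, synonym_rate = 0.5)
  cfg <- fast_dl("cnn1d", folds = 2L, seed = 3L)
  res <- suppressWarnings(train_cv(cfg, corp))
  expect_s3_class(res, "vte_cv_result")
  expect_equal(nrow(res$folds), 2L)
  expect_equal(sum(res$folds$n_test), 42L)
  res2 <- suppressWarnings(train_cv(cfg, corp))
  expect_identical(res$folds$f1, res2$folds$f1)
})

test_that("cv folds are disjoint, exhaustive, and stratified", {
  labels <- rep(c("a", "b", "c"), c(20, 10, 5))
  set.seed(3)
  folds <- vteal:::stratified_folds(labels, 5)
  expect_setequal(folds, 1:5)
  for (l in c("a", "b", "c")) {
    per_fold <- table(factor(folds[labels == l], levels = 1:5))
    expect_lte(max(per_fold) - min(per_fold), 1L)
  }
  expect_warning(vteal:::stratified_folds(c("a", "a", "b"), 2),
                 "fewer than 2 folds")
})

test_that("training is deterministic with early stopping disabled", {
  corp <- separable_corpus(n = 35, seed = 17)
  cfg <- fast_dl("lstm", folds = 2L, seed = 5L, early_stopping = FALSE,
                 max_epochs = 3L)
  r1 <- suppressWarnings(train_cv(cfg, corp))
  r2 <- suppressWarnings(train_cv(cfg, corp))
  expect_identical(r1$folds$f1, r2$folds$f1)
  expect_equal(r1$folds$epochs_run, c(3L, 3L))
})

test_that("6-class cv runs on the restrict_labels image of the corpus", {
  corp <- generate_corpus(generator_config(
    n_reports = 120,
    class_counts = stats::setNames(c(40, 16, 16, 16, 16, 0, 16),
                                   vte_labels()),
    distractor_rate = 0, seed = 19))
  cfg <- fast_dl("cnn1d", folds = 2L, seed = 7L, max_epochs = 6L)
  res7 <- suppressWarnings(train_cv(cfg, corp, "7-class"))
  res6 <- suppressWarnings(train_cv(cfg, corp, "6-class"))
  expect_equal(sum(res6$folds$n_test),
               sum(corp$label != vte_negative_label()))
  expect_true(is.finite(res7$mean_f1) && is.finite(res6$mean_f1))

  neg_only <- as_corpus(data.frame(
    id = "x", text = "No evidence of thrombus.", modality = "chest CT",
    label = "No DVT or PE"))
  expect_error(suppressWarnings(train_cv(cfg, neg_only, "6-class")),
               class = "vteal_validation_error")
})

test_that("inference timing reports the contract fields", {
  corp <- separable_corpus(n = 30, seed = 23)
  cfg <- fast_dl("cnn1d", seed = 2L, max_epochs = 2L)
  model <- train_dl(cfg, corp$text, corp$label)
  tm <- measure_inference_time(model, corp$text[1:10])
  expect_s3_class(tm, "vte_timing_report")
  expect_equal(tm$n, 10L)
  expect_equal(tm$batch_size, 1L)
  expect_true(tm$includes_tokenization)
  expect_gt(tm$mean_seconds, 0)
  expect_error(measure_inference_time(model, character(0)),
               class = "vteal_validation_error")
})

test_that("a larger model is slower on the same documents", {
  corp <- separable_corpus(n = 30, seed = 29)
  small <- train_dl(fast_dl("multikernel_cnn1d", seed = 2L, max_epochs = 1L),
                    corp$text, corp$label)
  big_cfg <- dl_config("multikernel_cnn1d", embedding_dim = 240L,
                       hidden_dim = 240L, filters = 120L,
                       max_epochs = 1L, batch_size = 16L,
                       max_length = 480L, seed = 2L)
  big <- train_dl(big_cfg, corp$text, corp$label)
  docs <- rep(corp$text[1:10], 3)
  t_small <- measure_inference_time(small, docs)$mean_seconds
  t_big <- measure_inference_time(big, docs)$mean_seconds
  expect_lt(t_small, t_big)
})

test_that("plug-in interface reuses the cv protocol and fails cleanly", {
  corp <- separable_corpus(n = 42, seed = 31)
  # trivial mock encoder behind the plug-in contract: bag of words + svm
  mock <- local({
    vocab <- NULL
    list(
      encode = function(texts) {
        if (is.null(vocab)) vocab <<- build_vocabulary(texts)
        as.matrix(tf_vectorize(texts, vocab))
      },
      fit = function(X, y) fit_classifier(classifier_spec("svm"), X, y),
      predict = function(model, X) predict_label(model, X)
    )
  })
  cfg <- fast_dl("lstm", folds = 3L, seed = 11L)
  res <- suppressWarnings(plugin_transformer_interface(mock, corp, cfg))
  expect_equal(nrow(res$folds), 3L)
  expect_true(res$mean_f1 > 0)

  err <- expect_error(
    plugin_transformer_interface("surelyNotInstalledPkg", corp, cfg),
    class = "vteal_missing_dependency_error")
  expect_match(conditionMessage(err), "optional dependency missing")
})

test_that("pretrained word vectors load from GloVe-format text", {
  f <- tempfile(fileext = ".txt")
  writeLines(c("thrombus 0.1 0.2 0.3", "vein -0.5 0.4 0.0"), f)
  wv <- read_word_vectors(f)
  expect_equal(dim(wv), c(2L, 3L))
  expect_equal(rownames(wv), c("thrombus", "vein"))
  writeLines(c("a 1 2", "b 1 2 3"), f)
  expect_error(read_word_vectors(f), class = "vteal_schema_error")
})
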