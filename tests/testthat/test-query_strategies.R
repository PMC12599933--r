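test_that("uncertainty scores match their closed forms", {
  P <- rbind(c(1, 0), c(0.5, 0.5))
  expect_equal(least_confidence_scores(P), c(0, 0.5))
  expect_equal(margin_scores(P), c(0, 1))
  expect_equal(entropy_scores(P), c(0, log(2)))

  row3 <- matrix(c(0.6, 0.3, 0.1), 1)
  expect_equal(least_confidence_scores(row3), 0.4)
  expect_equal(margin_scores(row3), 0.7)
  expect_equal(least_confidence_scores(matrix(0.25, 1, 4)), 0.75)

  expect_error(least_confidence_scores(matrix(numeric(0), 0, 3)),
               class = "vteal_validation_error")
  expect_error(margin_scores(matrix(1, 2, 1)),
               class = "vteal_validation_error")
  expect_error(entropy_scores(matrix(c(0.7, 0.7), 1)),
               class = "vteal_validation_error")
})

test_that("uniform rows maximize entropy (property sweep)", {
  set.seed(21)
  for (k in c(3, 7)) {
    u_ent <- entropy_scores(matrix(1 / k, 1, k))
    expect_equal(u_ent, log(k))
    P <- random_posteriors(100, k)
    expect_true(all(entropy_scores(P) < u_ent + 1e-12))
  }
})

test_that("LC, margin, entropy rank-agree on binary posteriors", {
  set.seed(31)
  for (i in 1:100) {
    P <- random_posteriors(20, 2)
    o_lc <- order(least_confidence_scores(P))
    expect_identical(order(margin_scores(P)), o_lc)
    expect_identical(order(entropy_scores(P)), o_lc)
  }
})

test_that("raising the top probability never increases any score", {
  set.seed(41)
  for (i in 1:50) {
    p <- as.numeric(random_posteriors(1, 5))
    top <- which.max(p)
    bump <- runif(1, 0, 1 - p[top])
    q <- p * (1 - (p[top] + bump)) / (1 - p[top])
    q[top] <- p[top] + bump
    for (f in list(least_confidence_scores, margin_scores, entropy_scores)) {
      expect_lte(f(matrix(q, 1)), f(matrix(p, 1)) + 1e-12)
    }
  }
})

test_that("length_words_select picks the longest text", {
  texts <- c(a = "one two three", b = "one two three four five six seven",
             c = "one two three four five")
  ctx <- query_context(character(0), character(0), c("a", "b", "c"),
                       texts = texts)
  expect_equal(as.character(length_words_select(ctx)), "b")

  ties <- query_context(character(0), character(0), c("a", "b"),
                        texts = c(a = "x y", b = "p q"))
  expect_equal(as.character(length_words_select(ties)), "a")
})

test_that("min_similarity_select matches the double-loop oracle", {
  set.seed(51)
  for (trial in 1:20) {
    fx <- random_query_fixture(n = sample(15:50, 1))
    ctx <- query_context(fx$labeled, fx$labels, fx$unlabeled,
                         vectors = fx$vectors)
    expect_equal(as.character(min_similarity_select(ctx)),
                 oracle_min_similarity(fx$vectors, fx$labeled, fx$unlabeled))
  }
  # forced cases
  V <- rbind(l1 = c(1, 0), u1 = c(1, 0), u2 = c(0, 1))
  ctx <- query_context("l1", "c1", c("u1", "u2"), vectors = V)
  expect_equal(as.character(min_similarity_select(ctx)), "u2")
  expect_error(min_similarity_select(
    query_context(character(0), character(0), "u1", vectors = V)),
    class = "vteal_validation_error")
})

test_that("class_average_similarity matches the per-class oracle", {
  V <- rbind(a = c(1, 0), b = c(0.6, 0.8), u = c(1, 0))
  ctx <- query_context(c("a", "b"), c("c1", "c1"), "u", vectors = V)
  got <- class_average_similarity(ctx, "u")
  expect_equal(as.numeric(got), mean(c(1, 0.6)))

  set.seed(61)
  fx <- random_query_fixture(n = 30, n_classes = 3, n_labeled = 12)
  ctx <- query_context(fx$labeled, fx$labels, fx$unlabeled,
                       vectors = fx$vectors)
  for (u in fx$unlabeled[1:5]) {
    expect_equal(
      as.numeric(class_average_similarity(ctx, u)),
      as.numeric(oracle_class_avg_sim(fx$vectors, fx$labeled, fx$labels, u)),
      tolerance = 1e-10)
  }
})

test_that("similarity-uncertainty combination behaves as specified", {
  # equidistant candidate beats a one-sided candidate under every mode
  V <- rbind(l1 = c(1, 0, 0), l2 = c(0, 1, 0),
             mid = c(1, 1, 0) / sqrt(2), side = c(1, 0.1, 0))
  ctx <- query_context(c("l1", "l2"), c("c1", "c2"), c("mid", "side"),
                       vectors = V)
  for (mode in c("least_confidence", "margin", "entropy")) {
    expect_equal(as.character(similarity_uncertainty_select(ctx, mode)),
                 "mid")
  }
  # single labeled class falls back with a warning
  ctx1 <- query_context("l1", "c1", c("mid", "side"), vectors = V)
  expect_warning(got <- similarity_uncertainty_select(ctx1, "margin"),
                 "single labeled class")
})

test_that("similarity-uncertainty matches the brute-force oracle", {
  set.seed(71)
  for (trial in 1:12) {
    fx <- random_query_fixture(n = sample(15:50, 1), n_classes = 3)
    ctx <- query_context(fx$labeled, fx$labels, fx$unlabeled,
                         vectors = fx$vectors)
    for (mode in c("least_confidence", "margin", "entropy")) {
      expect_equal(
        as.character(similarity_uncertainty_select(ctx, mode)),
        oracle_wordsim_uncertainty(fx$vectors, fx$labeled, fx$labels,
                                   fx$unlabeled, mode))
    }
  }
})

test_that("select_query dispatches, validates, and stays in the pool", {
  set.seed(81)
  fx <- random_query_fixture(n = 25)
  P <- random_posteriors(length(fx$unlabeled), 4)
  texts <- stats::setNames(
    vapply(seq_along(fx$ids),
           function(i) paste(rep("w", i), collapse = " "), character(1)),
    fx$ids)
  ctx <- query_context(fx$labeled, fx$labels, fx$unlabeled, posteriors = P,
                       vectors = fx$vectors, texts = texts,
                       rng = rng_stream(5))
  for (nm in c("random", "least_confidence", "margin", "entropy",
               "length_words", "word_similarity", "tfidf_similarity",
               "wordsim_least_confidence", "wordsim_margin",
               "wordsim_entropy")) {
    got <- select_query(strategy_spec(nm), ctx)
    expect_true(as.character(got) %in% fx$unlabeled, label = nm)
  }
  # least_confidence equals a direct sweep
  expect_equal(as.character(select_query(strategy_spec("least_confidence"),
                                         ctx)),
               fx$unlabeled[which.max(oracle_lc(P))])
  # missing posteriors -> configuration error naming the input
  ctx2 <- query_context(fx$labeled, fx$labels, fx$unlabeled,
                        vectors = fx$vectors)
  err <- expect_error(select_query(strategy_spec("margin"), ctx2),
                      class = "vteal_config_error")
  expect_match(conditionMessage(err), "posterior")
  # pool of one is forced
  ctx3 <- query_context(fx$labeled, fx$labels, fx$unlabeled[1],
                        posteriors = P[1, , drop = FALSE])
  expect_equal(as.character(select_query(strategy_spec("entropy"), ctx3)),
               fx$unlabeled[1])
  expect_error(strategy_spec("bogus"), class = "vteal_config_error")
  expect_error(query_context("a", "c1", c("a", "b")),
               class = "vteal_validation_error")
})

test_that("random strategy is seed-reproducible", {
  fx <- random_query_fixture(n = 20)
  pick_seq <- function(seed) {
    ctx <- query_context(fx$labeled, fx$labels, fx$unlabeled,
                         rng = rng_stream(seed))
    replicate(5, as.character(select_query(strategy_spec("random"), ctx)))
  }
  expect_identical(pick_seq(3), pick_seq(3))
  expect_false(identical(pick_seq(3), pick_seq(4)))
})
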