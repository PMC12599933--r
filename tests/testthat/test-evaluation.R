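test_that("confusion tallies match a double-loop recount (oracle)", {
  set.seed(101)
  labels <- letters[1:4]
  truth <- sample(labels, 500, replace = TRUE)
  pred <- sample(labels, 500, replace = TRUE)
  counts <- confusion_from_predictions(truth, pred, labels)
  for (l in labels) {
    tp <- 0; fp <- 0; fn <- 0
    for (i in seq_along(truth)) {
      if (truth[i] == l && pred[i] == l) tp <- tp + 1
      if (truth[i] != l && pred[i] == l) fp <- fp + 1
      if (truth[i] == l && pred[i] != l) fn <- fn + 1
    }
    row <- counts[counts$label == l, ]
    expect_equal(c(row$tp, row$fp, row$fn), c(tp, fp, fn))
    expect_equal(row$support, tp + fn)
  }
  expect_error(confusion_from_predictions(truth, pred[-1]),
               class = "vteal_validation_error")
})

test_that("perfect and degenerate predictions tally as forced", {
  truth <- c("a", "b", "b", "c")
  perfect <- confusion_from_predictions(truth, truth)
  expect_true(all(perfect$fp == 0) && all(perfect$fn == 0))
  allb <- confusion_from_predictions(truth, rep("b", 4))
  expect_equal(allb$fp[allb$label == "b"], 2)
  expect_equal(sum(allb$fp), 2)
})

test_that("precision/recall/F1 follow the closed forms and 0-conventions", {
  counts <- structure(
    data.frame(label = c("x", "y", "z"),
               tp = c(8, 1, 0), fp = c(2, 1, 0), fn = c(4, 0, 5),
               support = c(12, 1, 5)),
    class = c("vte_confusion", "data.frame"))
  rep_ <- precision_recall_f1(counts)
  expect_equal(rep_$precision[1], 0.8)
  expect_equal(rep_$recall[1], 8 / 12)
  expect_equal(rep_$f1[1], 2 * 0.8 * (8 / 12) / (0.8 + 8 / 12))
  # precision 0.5, recall 1.0 -> F1 = 2/3
  expect_equal(rep_$f1[2], 2 * 0.5 * 1 / 1.5)
  # TP=0, FP=0, FN=5 -> all zero under the convention
  expect_equal(unlist(rep_[3, c("precision", "recall", "f1")]),
               c(precision = 0, recall = 0, f1 = 0))
})

test_that("aggregate F1 schemes behave and micro equals accuracy", {
  counts <- confusion_from_predictions(c("a", "a", "b", "b"),
                                       c("a", "b", "b", "b"))
  rep_ <- precision_recall_f1(counts)
  expect_equal(aggregate_f1(rep_, "macro"), mean(rep_$f1))
  expect_error(aggregate_f1(rep_, "bogus"), class = "vteal_config_error")

  set.seed(103)
  for (i in 1:100) {
    k <- sample(2:6, 1)
    n <- sample(10:60, 1)
    truth <- sample(letters[1:k], n, replace = TRUE)
    pred <- sample(letters[1:k], n, replace = TRUE)
    micro <- score_f1(truth, pred, labels = letters[1:k],
                      average = "micro")
    expect_equal(micro, mean(truth == pred), tolerance = 1e-12)
  }
  # single-class scheme: all aggregates equal the class F1
  r1 <- precision_recall_f1(confusion_from_predictions(
    c("a", "a"), c("a", "a"), "a"))
  for (s in c("macro", "micro", "weighted")) {
    expect_equal(aggregate_f1(r1, s), r1$f1[1])
  }
})

test_that("F1 respects the harmonic-geometric-arithmetic mean chain", {
  set.seed(104)
  for (i in 1:200) {
    tp <- sample(0:20, 1); fp <- sample(0:20, 1); fn <- sample(0:20, 1)
    counts <- structure(
      data.frame(label = "x", tp = tp, fp = fp, fn = fn,
                 support = tp + fn),
      class = c("vte_confusion", "data.frame"))
    r <- precision_recall_f1(counts)
    expect_lte(r$f1, sqrt(r$precision * r$recall) + 1e-12)
    expect_lte(sqrt(r$precision * r$recall),
               (r$precision + r$recall) / 2 + 1e-12)
  }
})

test_that("composition summary uses the right denominators", {
  corp <- generate_corpus(generator_config(n_reports = 200, seed = 14))
  comp <- summarize_composition(corp)
  expect_equal(sum(comp$modality$n), 200)
  expect_equal(sum(comp$vte_presence$n), 200)
  expect_equal(sum(comp$vte_classes$n), comp$vte_presence$n[1])
  # percentage groups sum to ~100 within rounding slack
  expect_lt(abs(sum(comp$modality$percent) - 100), 0.3)
  expect_lt(abs(sum(comp$vte_presence$percent) - 100), 0.3)
  expect_lt(abs(sum(comp$vte_classes$percent) - 100), 0.3)

  one <- as_corpus(data.frame(
    id = "x", text = "Occlusive thrombus in the femoral vein.",
    modality = "DVT CT", label = "Proximal DVT"))
  comp1 <- summarize_composition(one)
  expect_equal(comp1$vte_classes$percent[
    comp1$vte_classes$label == "Proximal DVT"], 100.0)
})

test_that("concordance rate rounds half-up to one decimal", {
  expect_equal(concordance_rate(372, 200)$percent_coded, 65.0)
  expect_equal(concordance_rate(0, 10)$percent_coded, 0.0)
  expect_equal(concordance_rate(1, 2)$percent_coded, 33.3)
  expect_error(concordance_rate(0, 0), class = "vteal_validation_error")
  # invariant to scaling both counts
  for (m in c(2, 7, 30)) {
    expect_equal(concordance_rate(372 * m, 200 * m)$percent_coded, 65.0)
  }
})

test_that("curve aggregation matches a direct recomputation", {
  expect_equal(curve_aggregate(list(c(0.2, 0.4), c(0.4, 0.6)))$mean,
               c(0.3, 0.5))
  same <- curve_aggregate(list(c(0.1, 0.2), c(0.1, 0.2)))
  expect_equal(same$sd, c(0, 0))
  expect_error(curve_aggregate(list(c(1, 2), c(1, 2, 3))),
               class = "vteal_validation_error")

  set.seed(105)
  m <- matrix(runif(50 * 100), 50, 100)
  agg <- curve_aggregate(m)
  expect_equal(agg$mean, colMeans(m))
  expect_equal(agg$sd, apply(m, 2, stats::sd))
})
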