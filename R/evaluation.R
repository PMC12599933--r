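#' Per-class confusion counts
#'
#' One-vs-rest tally of true positives, false positives and false negatives
#' per class, the inputs to precision, recall and F1.
#'
#' @param truth,predicted Label vectors of equal length.
#' @param labels Label set to tally over; defaults to the union of labels
#'   observed in `truth` and `predicted` (in [vte_labels()] order when they
#'   are scheme labels).
#' @return A `vte_confusion`: data frame with columns
#'   `label, tp, fp, fn, support`.
#' @export
confusion_from_predictions <- function(truth, predicted, labels = NULL) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) {
    stop_vteal("validation", sprintf(
      "length mismatch: %d true vs %d predicted labels",
      length(truth), length(predicted)))
  }
  if (is.null(labels)) {
    seen <- unique(c(truth, predicted))
    labels <- if (all(seen %in% vte_labels())) {
      intersect(vte_labels(), seen)
    } else sort(seen)
  }
  bad <- setdiff(unique(c(truth, predicted)), labels)
  if (length(bad)) {
    stop_vteal("validation", "label(s) outside the scheme: ",
               paste(bad, collapse = ", "))
  }
  tp <- vapply(labels, function(l) sum(truth == l & predicted == l), 0)
  fp <- vapply(labels, function(l) sum(truth != l & predicted == l), 0)
  fn <- vapply(labels, function(l) sum(truth == l & predicted != l), 0)
  structure(data.frame(label = labels, tp = tp, fp = fp, fn = fn,
                       support = tp + fn, row.names = NULL,
                       stringsAsFactors = FALSE),
            class = c("vte_confusion", "data.frame"))
}

#' Precision, recall and F1 per class
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`, and F1 is their
#' harmonic mean `2 * precision * recall / (precision + recall)`.  Any 0/0
#' quotient yields 0: with an 8-sample labeled seed and 7 classes, early
#' active-learning iterations routinely predict no member of some class, and
#' the 0 convention keeps learning curves defined at every iteration.
#'
#' @param counts A [confusion_from_predictions()] tally.
#' @return A `vte_metric_report`: per-class data frame with columns
#'   `label, support, precision, recall, f1`.
#' @export
precision_recall_f1 <- function(counts) {
  stopifnot(inherits(counts, "vte_confusion"))
  safe_div <- function(num, den) ifelse(den == 0, 0, num / den)
  precision <- safe_div(counts$tp, counts$tp + counts$fp)
  recall <- safe_div(counts$tp, counts$tp + counts$fn)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  structure(data.frame(label = counts$label, support = counts$support,
                       precision = precision, recall = recall, f1 = f1,
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("vte_metric_report", "data.frame"),
            counts = counts)
}

#' Aggregate F1 across classes
#'
#' `macro` is the unweighted mean of per-class F1 (the package default:
#' robust to the severe class imbalance of VTE corpora), `weighted` is the
#' support-weighted mean, and `micro` is the F1 of the pooled confusion
#' counts (equal to accuracy for single-label multiclass prediction).
#'
#' @param report A [precision_recall_f1()] report.
#' @param scheme Averaging scheme.
#' @return Scalar aggregate F1.
#' @export
aggregate_f1 <- function(report, scheme = c("macro", "micro", "weighted")) {
  if (!is.character(scheme) ||
      !all(scheme %in% c("macro", "micro", "weighted"))) {
    stop_vteal("config", "unknown F1 averaging scheme")
  }
  scheme <- match.arg(scheme)
  stopifnot(inherits(report, "vte_metric_report"))
  if (scheme == "macro") return(mean(report$f1))
  if (scheme == "weighted") {
    if (sum(report$support) == 0) return(0)
    return(sum(report$f1 * report$support) / sum(report$support))
  }
  counts <- attr(report, "counts")
  tp <- sum(counts$tp); fp <- sum(counts$fp); fn <- sum(counts$fn)
  p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  if (p + r == 0) 0 else 2 * p * r / (p + r)
}

#' Convenience multiclass F1
#'
#' @inheritParams confusion_from_predictions
#' @param average Averaging scheme, see [aggregate_f1()].
#' @return Scalar F1.
#' @export
score_f1 <- function(truth, predicted, labels = NULL, average = "macro") {
  aggregate_f1(
    precision_recall_f1(confusion_from_predictions(truth, predicted, labels)),
    scheme = average)
}

#' Corpus composition summary
#'
#' Tabulates modality counts and VTE presence over all reports, and VTE
#' subclass counts over VTE-positive reports only, with percentages rounded
#' half-up to one decimal (the denominators used in the emulated corpus's
#' published composition tables).
#'
#' @param corpus A `vte_corpus`.
#' @return A `vte_composition`: list of data frames `modality`,
#'   `vte_presence`, `vte_classes`, each with `n` and `percent`.
#' @export
summarize_composition <- function(corpus) {
  stopifnot(is_corpus(corpus))
  if (nrow(corpus) == 0L) stop_vteal("validation", "corpus is empty")
  n <- nrow(corpus)
  pct <- function(x, den) round_half_up(100 * x / den, 1L)

  mod <- table(factor(corpus$modality, levels = vte_modalities()))
  modality <- data.frame(modality = names(mod), n = as.integer(mod),
                         percent = pct(as.integer(mod), n),
                         stringsAsFactors = FALSE)

  pos <- corpus$label != vte_negative_label()
  vte_presence <- data.frame(
    status = c("VTE Present", "No VTE"),
    n = c(sum(pos), sum(!pos)),
    percent = pct(c(sum(pos), sum(!pos)), n),
    stringsAsFactors = FALSE)

  pos_labels <- vte_labels("6-class")
  cls <- table(factor(corpus$label[pos], levels = pos_labels))
  n_pos <- sum(pos)
  vte_classes <- data.frame(
    label = names(cls), n = as.integer(cls),
    percent = if (n_pos > 0) pct(as.integer(cls), n_pos)
              else rep(0, length(cls)),
    stringsAsFactors = FALSE)

  structure(list(n_reports = n, modality = modality,
                 vte_presence = vte_presence, vte_classes = vte_classes),
            class = "vte_composition")
}

#' @export
print.vte_composition <- function(x, ...) {
  cat(sprintf("Corpus composition (n = %s)\n",
              format(x$n_reports, big.mark = ",")))
  cat("Modality of imaging test\n")
  for (i in seq_len(nrow(x$modality))) {
    cat(sprintf("  %-45s %6s (%.1f%%)\n", x$modality$modality[i],
                format(x$modality$n[i], big.mark = ","),
                x$modality$percent[i]))
  }
  cat("Presence of VTE\n")
  for (i in seq_len(nrow(x$vte_presence))) {
    cat(sprintf("  %-45s %6s (%.1f%%)\n", x$vte_presence$status[i],
                format(x$vte_presence$n[i], big.mark = ","),
                x$vte_presence$percent[i]))
  }
  cat("Classification of VTE (% of VTE-positive)\n")
  for (i in seq_len(nrow(x$vte_classes))) {
    cat(sprintf("  %-45s %6s (%.1f%%)\n", x$vte_classes$label[i],
                format(x$vte_classes$n[i], big.mark = ","),
                x$vte_classes$percent[i]))
  }
  invisible(x)
}

#' ICD-10 concordance rate
#'
#' Fraction of imaging-confirmed VTE-positive reports that carry a
#' VTE-related ICD-10 code, as a percentage rounded half-up to one decimal.
#'
#' @param n_coded,n_uncoded Non-negative counts, not both zero.
#' @return A `vte_concordance`: list with `n_sampled`, `n_coded`,
#'   `n_uncoded`, `percent_coded`.
#' @export
#' @examples
#' concordance_rate(372, 200)$percent_coded  # 65.0
concordance_rate <- function(n_coded, n_uncoded) {
  n_coded <- as.integer(n_coded); n_uncoded <- as.integer(n_uncoded)
  if (is.na(n_coded) || is.na(n_uncoded) || n_coded < 0 || n_uncoded < 0) {
    stop_vteal("validation", "counts must be non-negative integers")
  }
  n <- n_coded + n_uncoded
  if (n == 0L) stop_vteal("validation", "no sampled reports (both counts zero)")
  structure(list(n_sampled = n, n_coded = n_coded, n_uncoded = n_uncoded,
                 percent_coded = round_half_up(100 * n_coded / n, 1L)),
            class = "vte_concordance")
}

#' Aggregate learning-curve trajectories
#'
#' Stacks equal-length per-epoch F1 trajectories and reports the
#' per-iteration mean and standard deviation across epochs.
#'
#' @param trajectories List (or matrix, epochs in rows) of numeric F1
#'   trajectories, one per active-learning epoch, all of equal length.
#' @return A `vte_learning_curve`: list with `iteration` (0-based: 0 is the
#'   seed fit), `mean`, `sd`, and the `epochs x iterations` matrix.
#' @export
curve_aggregate <- function(trajectories) {
  if (is.matrix(trajectories)) {
    trajectories <- lapply(seq_len(nrow(trajectories)),
                           function(i) trajectories[i, ])
  }
  lens <- lengths(trajectories)
  if (!length(lens)) stop_vteal("validation", "no trajectories")
  if (length(unique(lens)) != 1L) {
    bad <- which(lens != lens[1L])[1L]
    stop_vteal("validation", sprintf(
      "ragged trajectories: epoch %d has length %d, expected %d",
      bad, lens[bad], lens[1L]))
  }
  m <- do.call(rbind, trajectories)
  structure(list(
    iteration = seq_len(ncol(m)) - 1L,
    mean = colMeans(m),
    sd = if (nrow(m) == 1L) rep(0, ncol(m)) else apply(m, 2, stats::sd),
    trajectories = m
  ), class = "vte_learning_curve")
}

#' @export
print.vte_learning_curve <- function(x, ...) {
  cat(sprintf("<vte_learning_curve> %d epochs x %d iterations\n",
              nrow(x$trajectories), ncol(x$trajectories)))
  show <- unique(round(seq(1, length(x$mean), length.out = 6)))
  for (i in show) {
    cat(sprintf("  iter %4d  mean F1 %.3f  sd %.3f\n",
                x$iteration[i], x$mean[i],
                ifelse(is.na(x$sd[i]), 0, x$sd[i])))
  }
  invisible(x)
}
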