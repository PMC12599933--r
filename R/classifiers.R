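#' Classifier specification
#'
#' Four probabilistic classifier families are available for the
#' active-learning loop; none of the usual implementations ship with this
#' environment, so all four are implemented in-package:
#'
#' * `random_forest` — bagged CART trees with gini splits and per-node
#'   feature subsampling (compiled); probabilities are tree-averaged leaf
#'   class distributions.
#' * `svm` — one-vs-rest L2-regularized linear SVM (squared hinge) fitted by
#'   full-batch subgradient descent.
#' * `svm_sgd` — the same objective fitted by pegasos-style stochastic
#'   gradient descent over single samples.
#' * `gradient_boosting` — multinomial gradient boosting with shallow
#'   regression trees (compiled) and the standard multinomial leaf update.
#'
#' The SVM families expose class probabilities through a softmax over the
#' decision values: monotone in each decision value with rows summing to 1,
#' as the uncertainty-based query strategies require.
#'
#' @param family One of `random_forest`, `svm`, `svm_sgd`,
#'   `gradient_boosting`.
#' @param ... Family hyperparameters overriding the defaults:
#'   `n_trees` (100), `mtry` (sqrt of feature count), `max_depth` (25 forest
#'   / 3 boosting), `min_node` (1); `lambda` (0.01), `iters` (200 batch /
#'   20 SGD passes); `n_rounds` (50), `shrinkage` (0.1).
#' @return A `vte_classifier_spec`.
#' @export
classifier_spec <- function(family = c("random_forest", "svm", "svm_sgd",
                                       "gradient_boosting"), ...) {
  family <- match.arg(family)
  defaults <- switch(family,
    random_forest = list(n_trees = 100L, mtry = NA, max_depth = 25L,
                         min_node = 1L),
    svm = list(lambda = 0.01, iters = 200L, lr = 0.5),
    svm_sgd = list(lambda = 0.01, iters = 20L),
    gradient_boosting = list(n_rounds = 50L, shrinkage = 0.1,
                             max_depth = 3L, min_node = 5L)
  )
  override <- list(...)
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown)) {
    stop_vteal("config", "unknown hyperparameter(s) for ", family, ": ",
               paste(unknown, collapse = ", "))
  }
  defaults[names(override)] <- override
  structure(list(family = family, hyperparameters = defaults),
            class = "vte_classifier_spec")
}

#' Fit a classifier
#'
#' @param spec A [classifier_spec()].
#' @param X Numeric feature matrix (dense or sparse), one row per document.
#' @param y Label vector (character).  The model is fit on the classes
#'   present in `y`; [predict_prob()] reports probabilities over those
#'   classes.
#' @param seed Integer seed fixing all training randomness.
#' @return A `vte_classifier` with element `classes`.
#' @export
fit_classifier <- function(spec, X, y, seed = 1L) {
  stopifnot(inherits(spec, "vte_classifier_spec"))
  X <- as.matrix(X)
  y <- as.character(y)
  if (nrow(X) != length(y)) {
    stop_vteal("validation", "X rows and y length differ")
  }
  classes <- sort(unique(y))
  yi <- match(y, classes) - 1L
  hp <- spec$hyperparameters
  fit <- with_seed(seed, switch(spec$family,
    random_forest = {
      mtry <- if (is.na(hp$mtry)) max(1L, floor(sqrt(ncol(X)))) else hp$mtry
      cpp_forest_fit(X, yi, length(classes), hp$n_trees, as.integer(mtry),
                     hp$max_depth, hp$min_node)
    },
    svm = fit_linear_svm_batch(X, yi, length(classes), hp$lambda, hp$iters,
                               hp$lr),
    svm_sgd = fit_linear_svm_sgd(X, yi, length(classes), hp$lambda,
                                 hp$iters),
    gradient_boosting = fit_gbm(X, yi, length(classes), hp$n_rounds,
                                hp$shrinkage, hp$max_depth, hp$min_node)
  ))
  structure(list(family = spec$family, fit = fit, classes = classes,
                 hyperparameters = hp),
            class = "vte_classifier")
}

#' Class-probability predictions
#'
#' @param model A fitted [fit_classifier()] model.
#' @param X Feature matrix in the space the model was fit on.
#' @return Matrix (documents x classes) of probabilities, columns named by
#'   `model$classes`; rows sum to 1.
#' @export
predict_prob <- function(model, X) {
  stopifnot(inherits(model, "vte_classifier"))
  X <- as.matrix(X)
  K <- length(model$classes)
  P <- switch(model$family,
    random_forest = cpp_forest_predict(model$fit, X, K),
    svm = ,
    svm_sgd = softmax_rows(cbind(1, X) %*% model$fit$W),
    gradient_boosting = softmax_rows(gbm_scores(model$fit, X, K))
  )
  colnames(P) <- model$classes
  P
}

#' @rdname predict_prob
#' @return For `predict_label()`, the argmax-probability label per row.
#' @export
predict_label <- function(model, X) {
  P <- predict_prob(model, X)
  model$classes[max.col(P, ties.method = "first")]
}

softmax_rows <- function(S) {
  S <- as.matrix(S)
  S <- S - apply(S, 1, max)
  E <- exp(S)
  E / rowSums(E)
}

# One-vs-rest squared-hinge linear SVM, full-batch subgradient descent.
fit_linear_svm_batch <- function(X, yi, K, lambda, iters, lr) {
  Xb <- cbind(1, X)
  n <- nrow(Xb); p <- ncol(Xb)
  W <- matrix(0, p, K)
  Y <- matrix(-1, n, K)
  Y[cbind(seq_len(n), yi + 1L)] <- 1
  for (it in seq_len(iters)) {
    M <- Xb %*% W                      # decision values
    viol <- pmax(0, 1 - Y * M)         # squared-hinge slack
    G <- -2 * crossprod(Xb, Y * viol) / n + lambda * W
    W <- W - (lr / sqrt(it)) * G
  }
  list(W = W)
}

# Pegasos-style stochastic subgradient descent on the hinge loss.
fit_linear_svm_sgd <- function(X, yi, K, lambda, passes) {
  Xb <- cbind(1, X)
  n <- nrow(Xb); p <- ncol(Xb)
  W <- matrix(0, p, K)
  t <- 0L
  for (pass in seq_len(passes)) {
    for (i in sample.int(n)) {
      t <- t + 1L
      eta <- 1 / (lambda * t)
      x <- Xb[i, ]
      m <- drop(crossprod(x, W))       # 1 x K decision values
      ysign <- rep(-1, K); ysign[yi[i] + 1L] <- 1
      active <- ysign * m < 1
      W <- W * (1 - eta * lambda)
      if (any(active)) {
        W[, active] <- W[, active] +
          eta * outer(x, ysign[active]) / max(1, sum(active))
      }
    }
  }
  list(W = W)
}

# Multinomial gradient boosting with shallow regression trees.
fit_gbm <- function(X, yi, K, n_rounds, shrinkage, max_depth, min_node) {
  n <- nrow(X)
  Fmat <- matrix(0, n, K)
  trees <- vector("list", n_rounds)
  for (m in seq_len(n_rounds)) {
    P <- softmax_rows(Fmat)
    round_trees <- vector("list", K)
    for (k in seq_len(K)) {
      r <- as.numeric(yi == (k - 1L)) - P[, k]
      tree <- cpp_reg_tree_fit(X, r, max_depth, min_node, ncol(X))
      # multinomial leaf update: gamma = (K-1)/K * sum(r) / sum(|r|(1-|r|))
      leaf <- tree$train_leaf + 1L
      num <- tapply(r, leaf, sum)
      den <- tapply(abs(r) * (1 - abs(r)), leaf, sum)
      gamma <- rep(0, length(tree$feature))
      gamma[as.integer(names(num))] <-
        (K - 1) / K * num / pmax(den, 1e-10)
      tree$gamma <- gamma
      tree$train_leaf <- NULL
      round_trees[[k]] <- tree
      Fmat[, k] <- Fmat[, k] + shrinkage * gamma[leaf]
    }
    trees[[m]] <- round_trees
  }
  list(trees = trees, shrinkage = shrinkage, n_rounds = n_rounds)
}

gbm_scores <- function(fit, X, K) {
  n <- nrow(X)
  Fmat <- matrix(0, n, K)
  for (round_trees in fit$trees) {
    for (k in seq_len(K)) {
      tree <- round_trees[[k]]
      leaf <- cpp_tree_leaf(tree, X) + 1L
      Fmat[, k] <- Fmat[, k] + fit$shrinkage * tree$gamma[leaf]
    }
  }
  Fmat
}
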