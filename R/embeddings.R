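#' Tokenize report text
#'
#' Deterministic bag-of-words tokenizer: lowercase, strip punctuation,
#' split on whitespace.  Empty text yields an empty token vector.
#'
#' @param texts Character vector of report texts.
#' @param lowercase,strip_punct Casing / punctuation flags.
#' @return List of character token vectors, one per input text.
#' @export
#' @examples
#' tokenize("No evidence of PE.")[[1]]
tokenize <- function(texts, lowercase = TRUE, strip_punct = TRUE) {
  x <- as.character(texts)
  if (lowercase) x <- tolower(x)
  if (strip_punct) x <- gsub("[^a-z0-9A-Z ]", " ", x)
  x <- trimws(gsub("\\s+", " ", x))
  out <- strsplit(x, " ", fixed = TRUE)
  lapply(out, function(t) t[nzchar(t)])
}

#' Build a vocabulary from a training corpus
#'
#' Maps each distinct token (in order of first appearance) to a contiguous
#' index and records per-token document frequencies.  The vocabulary must be
#' fitted on the training pool only; transforming test documents never
#' extends it (out-of-vocabulary tokens are dropped in count spaces).
#'
#' @param x A `vte_corpus`, character vector of texts, or list of token
#'   vectors.
#' @param min_count Drop tokens occurring in fewer than `min_count`
#'   documents.
#' @return A `vte_vocabulary`: list with `tokens` (index = position), `df`
#'   (document frequencies) and `n_docs`.
#' @export
build_vocabulary <- function(x, min_count = 1L) {
  toks <- as_token_list(x)
  uniq <- lapply(toks, unique)
  df <- table(factor(unlist(uniq), levels = unique(unlist(toks))))
  keep <- df >= min_count
  structure(list(
    tokens = names(df)[keep],
    df = as.integer(df[keep]),
    n_docs = length(toks)
  ), class = "vte_vocabulary")
}

as_token_list <- function(x) {
  if (is_corpus(x)) tokenize(x$text)
  else if (is.list(x)) x
  else tokenize(x)
}

corpus_ids <- function(x, n) {
  if (is_corpus(x)) x$id else sprintf("d%d", seq_len(n))
}

#' Term-frequency document-term matrix
#'
#' Entry (d, t) is the count of vocabulary token t in document d;
#' out-of-vocabulary tokens are dropped.
#'
#' @param x Corpus, texts, or token list.
#' @param vocab A [build_vocabulary()] fitted on the training pool.
#' @return Sparse `dgCMatrix` (documents x tokens) with dimnames.
#' @export
tf_vectorize <- function(x, vocab) {
  stopifnot(inherits(vocab, "vte_vocabulary"))
  toks <- as_token_list(x)
  n <- length(toks)
  idx <- lapply(toks, function(t) {
    j <- match(t, vocab$tokens)
    j[!is.na(j)]
  })
  i <- rep(seq_len(n), lengths(idx))
  j <- unlist(idx, use.names = FALSE)
  m <- Matrix::sparseMatrix(
    i = i, j = j, x = 1,
    dims = c(n, length(vocab$tokens)),
    dimnames = list(corpus_ids(x, n), vocab$tokens)
  )
  methods::as(m, "CsparseMatrix")
}

#' Inverse-document-frequency weighting
#'
#' Reweights a term-frequency matrix by the smoothed IDF
#' `idf(t) = ln((1 + N) / (1 + df(t))) + 1`, where N is the number of
#' training documents the vocabulary was fitted on.  Strictly positive, so
#' the sparsity pattern of the TF matrix is preserved; rarer tokens get
#' strictly larger weights.
#'
#' @param tf Matrix from [tf_vectorize()].
#' @param vocab The vocabulary used to build `tf`.
#' @return Weighted matrix of the same shape and sparsity.
#' @export
tfidf_weight <- function(tf, vocab) {
  stopifnot(inherits(vocab, "vte_vocabulary"),
            ncol(tf) == length(vocab$tokens))
  idf <- log((1 + vocab$n_docs) / (1 + vocab$df)) + 1
  out <- tf %*% Matrix::Diagonal(x = idf, names = FALSE)
  dimnames(out) <- dimnames(tf)
  out
}

#' Cosine similarity between two vectors
#'
#' `sim(a, b) = (a . b) / (|a| |b|)`, in `[-1, 1]`.  If either vector has
#' zero norm the similarity is 0 by convention (the quotient is undefined;
#' 0 marks the document as maximally novel, the safe choice for
#' similarity-based querying).
#'
#' @param a,b Numeric vectors of equal dimension.
#' @return Scalar in `[-1, 1]`.
#' @export
#' @examples
#' cosine_similarity(c(1, 2, 3), c(4, 5, 6))
cosine_similarity <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) {
    stop_vteal("validation", sprintf(
      "dimension mismatch: %d vs %d", length(a), length(b)))
  }
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

# Row-wise cosine similarity matrix between A (m x d) and B (n x d);
# zero-norm rows yield similarity 0.
cosine_rows <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  na <- sqrt(rowSums(A^2)); nb <- sqrt(rowSums(B^2))
  s <- A %*% t(B)
  denom <- outer(na, nb)
  out <- ifelse(denom == 0, 0, s / ifelse(denom == 0, 1, denom))
  out
}

# Truncated SVD with a deterministic sign convention (largest-magnitude
# loading of each left singular vector is positive).
svd_trunc <- function(X, k) {
  X <- as.matrix(X)
  k <- min(k, nrow(X), ncol(X))
  s <- svd(X, nu = k, nv = k)
  for (j in seq_len(k)) {
    pivot <- which.max(abs(s$u[, j]))
    if (s$u[pivot, j] < 0) {
      s$u[, j] <- -s$u[, j]
      s$v[, j] <- -s$v[, j]
    }
  }
  list(u = s$u, d = s$d[seq_len(k)], v = s$v)
}

#' Train dense document embeddings
#'
#' Two dense schemes complement the sparse TF/TF-IDF spaces:
#'
#' * `"word-average"` — word vectors are learned from windowed co-occurrence
#'   counts via positive pointwise mutual information (PPMI) followed by
#'   truncated SVD (the count-based equivalent of skip-gram word
#'   embeddings), and a document is the mean of its tokens' vectors
#'   (all-out-of-vocabulary documents map to the zero vector).
#' * `"document"` — latent semantic analysis: truncated SVD of the TF-IDF
#'   document-term matrix gives one vector per document, and unseen
#'   documents are projected onto the same latent basis.
#'
#' Both are deterministic given the fitted corpus (SVD with a fixed sign
#' convention); `seed` and `epochs` are accepted for interface parity with
#' stochastic trainers and do not affect the result.
#'
#' @param corpus Training corpus (vocabulary is fitted on it only).
#' @param mode `"word-average"` or `"document"`.
#' @param dim Embedding dimension (default 100).
#' @param window Symmetric co-occurrence window (word-average mode).
#' @param min_count Minimum document frequency for vocabulary tokens.
#' @param epochs,seed Interface-compatibility knobs (no effect; see above).
#' @return A `vte_embedding_model` with `$vectors` (training-document
#'   matrix, rows named by id) usable directly, and projectable to new
#'   documents via [embed_documents()].
#' @export
train_dense_embeddings <- function(corpus,
                                   mode = c("word-average", "document"),
                                   dim = 100L, window = 5L, min_count = 1L,
                                   epochs = 20L, seed = 1L) {
  mode <- match.arg(mode)
  dim <- as.integer(dim)
  if (is.na(dim) || dim <= 0L) stop_vteal("config", "dim must be positive")
  toks <- as_token_list(corpus)
  if (!length(toks)) stop_vteal("validation", "corpus is empty")
  vocab <- build_vocabulary(toks, min_count = min_count)
  V <- length(vocab$tokens)

  if (mode == "word-average") {
    # windowed co-occurrence counts
    ii <- integer(0); jj <- integer(0)
    pairs <- lapply(toks, function(t) {
      j <- match(t, vocab$tokens)
      j <- j[!is.na(j)]
      L <- length(j)
      if (L < 2L) return(NULL)
      out_i <- integer(0); out_j <- integer(0)
      for (w in seq_len(min(window, L - 1L))) {
        out_i <- c(out_i, j[seq_len(L - w)])
        out_j <- c(out_j, j[seq_len(L - w) + w])
      }
      cbind(out_i, out_j)
    })
    pairs <- do.call(rbind, pairs)
    C <- Matrix::sparseMatrix(i = pairs[, 1], j = pairs[, 2], x = 1,
                              dims = c(V, V))
    C <- C + Matrix::t(C)
    tot <- sum(C)
    rs <- Matrix::rowSums(C)
    # PPMI: max(0, log(p(i,j) / (p(i) p(j))))
    Cd <- as.matrix(C)
    pmi <- log(pmax(Cd, .Machine$double.eps) * tot) -
      log(outer(pmax(rs, 1), pmax(rs, 1)))
    pmi[Cd == 0] <- 0
    pmi[pmi < 0] <- 0
    s <- svd_trunc(pmi, dim)
    k <- length(s$d)
    wv <- s$u %*% diag(sqrt(s$d), k, k)
    if (k < dim) wv <- cbind(wv, matrix(0, V, dim - k))
    rownames(wv) <- vocab$tokens
    model <- structure(list(mode = mode, dim = dim, vocab = vocab,
                            word_vectors = wv),
                       class = "vte_embedding_model")
  } else {
    X <- tfidf_weight(tf_vectorize(toks, vocab), vocab)
    s <- svd_trunc(X, dim)
    k <- length(s$d)
    dv <- s$u %*% diag(s$d, k, k)
    if (k < dim) dv <- cbind(dv, matrix(0, nrow(dv), dim - k))
    proj <- s$v %*% diag(1 / pmax(s$d, .Machine$double.eps), k, k)
    model <- structure(list(mode = mode, dim = dim, vocab = vocab,
                            projection = proj, k = k),
                       class = "vte_embedding_model")
  }
  model$vectors <- embed_documents(model, toks)
  rownames(model$vectors) <- corpus_ids(corpus, length(toks))
  model
}

#' Embed documents in a fitted dense space
#'
#' @param model A [train_dense_embeddings()] model.
#' @param x Corpus, texts, or token list to embed.
#' @return Numeric matrix (documents x `model$dim`).
#' @export
embed_documents <- function(model, x) {
  stopifnot(inherits(model, "vte_embedding_model"))
  toks <- as_token_list(x)
  n <- length(toks)
  if (model$mode == "word-average") {
    out <- t(vapply(toks, function(t) {
      j <- match(t, model$vocab$tokens)
      j <- j[!is.na(j)]
      if (!length(j)) return(numeric(model$dim))
      colMeans(model$word_vectors[j, , drop = FALSE])
    }, numeric(model$dim)))
  } else {
    X <- tfidf_weight(tf_vectorize(toks, model$vocab), model$vocab)
    out <- as.matrix(X %*% model$projection)
    if (model$k < model$dim) {
      out <- cbind(out, matrix(0, n, model$dim - model$k))
    }
  }
  rownames(out) <- corpus_ids(x, n)
  out
}
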