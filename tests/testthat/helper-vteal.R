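# Shared fixtures and independent brute-force oracles.  Oracles are written
# directly from the definitions (double loops, closed forms) and never call
# the package functions they check.

balanced_counts <- function() {
  stats::setNames(rep(1L, 7L), vte_labels())
}

# Small separable corpus: equal class weights, no distractors or synonyms.
separable_corpus <- function(n = 140, seed = 1, synonym_rate = 0) {
  generate_corpus(generator_config(
    n_reports = n, class_counts = balanced_counts(),
    distractor_rate = 0, synonym_rate = synonym_rate, seed = seed))
}

tiny_corpus_df <- function() {
  data.frame(
    id = c("a1", "a2", "a3"),
    text = c("No evidence of thrombus.",
             "Occlusive thrombus in the femoral vein.",
             "Filling defect in the segmental pulmonary artery."),
    modality = c("chest CT", "DVT CT", "pulmonary artery CT angiography"),
    label = c("No DVT or PE", "Proximal DVT", "PE only"),
    icd10_coded = c(FALSE, TRUE, TRUE),
    age = c(70, 61, NA),
    sex = c("male", NA, "female"),
    stringsAsFactors = FALSE
  )
}

# --- independent oracles -------------------------------------------------

oracle_lc <- function(P) apply(P, 1, function(p) 1 - max(p))

oracle_margin <- function(P) {
  apply(P, 1, function(p) {
    s <- sort(p, decreasing = TRUE)
    1 - (s[1] - s[2])
  })
}

oracle_entropy <- function(P) {
  apply(P, 1, function(p) {
    h <- 0
    for (v in p) if (v > 0) h <- h - v * log(v)
    h
  })
}

oracle_cosine <- function(a, b) {
  na <- sqrt(sum(a * a)); nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

# Exhaustive double-loop novelty selection (mean similarity to labeled set).
oracle_min_similarity <- function(vectors, labeled_ids, unlabeled_ids) {
  scores <- sapply(unlabeled_ids, function(u) {
    mean(sapply(labeled_ids, function(l) {
      oracle_cosine(vectors[l, ], vectors[u, ])
    }))
  })
  unlabeled_ids[which.min(scores)]
}

oracle_class_avg_sim <- function(vectors, labeled_ids, labels, u) {
  cls <- sort(unique(labels))
  sapply(cls, function(c) {
    members <- labeled_ids[labels == c]
    mean(sapply(members, function(l) oracle_cosine(vectors[l, ],
                                                   vectors[u, ])))
  })
}

oracle_wordsim_uncertainty <- function(vectors, labeled_ids, labels,
                                       unlabeled_ids, mode) {
  scores <- sapply(unlabeled_ids, function(u) {
    s <- oracle_class_avg_sim(vectors, labeled_ids, labels, u)
    s <- s - min(s)
    p <- if (sum(s) == 0) rep(1 / length(s), length(s)) else s / sum(s)
    switch(mode,
           least_confidence = 1 - max(p),
           margin = {
             ss <- sort(p, decreasing = TRUE)
             1 - (ss[1] - ss[2])
           },
           entropy = oracle_entropy(matrix(p, 1)))
  })
  unlabeled_ids[which.max(scores)]
}

# random posterior matrix with rows on the simplex
random_posteriors <- function(n, k) {
  P <- matrix(stats::rexp(n * k), n, k)
  P / rowSums(P)
}

random_query_fixture <- function(n = 30, dim = 5, n_classes = 3,
                                 n_labeled = 10) {
  ids <- sprintf("s%02d", seq_len(n))
  V <- matrix(rnorm(n * dim), n, dim, dimnames = list(ids, NULL))
  labeled <- ids[seq_len(n_labeled)]
  labels <- sample(sprintf("c%d", seq_len(n_classes)), n_labeled,
                   replace = TRUE)
  while (length(unique(labels)) < 2) {
    labels <- sample(sprintf("c%d", seq_len(n_classes)), n_labeled,
                     replace = TRUE)
  }
  list(ids = ids, vectors = V, labeled = labeled, labels = labels,
       unlabeled = setdiff(ids, labeled))
}
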