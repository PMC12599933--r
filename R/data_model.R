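#' Label and modality schemes for VTE imaging reports
#'
#' Seven anatomical classes are used to annotate venous-thromboembolism (VTE)
#' imaging reports: one negative class and six positive classes covering
#' pulmonary embolism (PE) and the anatomical subtypes of deep vein
#' thrombosis (DVT).  The 6-class scheme drops the dominant negative class
#' ("No DVT or PE") and keeps only VTE-positive reports.
#'
#' @param scheme `"7-class"` (default) or `"6-class"`.
#' @return Character vector of canonical label tokens, in fixed order.
#' @export
#' @examples
#' vte_labels()
#' vte_labels("6-class")
vte_labels <- function(scheme = c("7-class", "6-class")) {
  scheme <- match.arg(scheme)
  labs <- c(
    "No DVT or PE", "PE only", "Proximal DVT", "Distal DVT",
    "Thrombophlebitis", "Other DVT", "DVT and PE"
  )
  if (scheme == "6-class") labs[-1L] else labs
}

#' @rdname vte_labels
#' @return For `vte_modalities()`, the closed set of five imaging modalities.
#' @export
vte_modalities <- function() {
  c(
    "chest CT", "pulmonary artery CT angiography",
    "lower extremity vein CT", "DVT CT",
    "lower extremity vein duplex ultrasonography"
  )
}

#' @rdname vte_labels
#' @export
vte_negative_label <- function() "No DVT or PE"

# Canonical column order of the on-disk corpus formats.
corpus_columns <- function() {
  c("id", "text", "modality", "label", "icd10_coded", "age", "sex")
}

# Case-insensitive, whitespace-normalized matching of a token against a set
# of canonical values.  Returns the canonical value or NA.
canonicalize_token <- function(token, canonical) {
  norm <- function(x) tolower(gsub("\\s+", " ", trimws(x)))
  canonical[match(norm(token), norm(canonical))]
}

#' Construct a corpus of imaging reports
#'
#' A corpus is a data frame with one row per report and columns
#' `id, text, modality, label, icd10_coded, age, sex`, carrying a
#' `label_scheme` attribute (`"7-class"` or `"6-class"`).  Ids must be
#' unique, texts non-empty, and labels/modalities drawn from their closed
#' sets (matched case-insensitively after whitespace normalization).
#'
#' @param reports Data frame with at least `id`, `text`, `modality`, `label`;
#'   `icd10_coded` (logical), `age`, `sex` are optional.
#' @param scheme Label scheme the corpus is annotated under.
#' @return A `vte_corpus` object.
#' @export
as_corpus <- function(reports, scheme = c("7-class", "6-class")) {
  scheme <- match.arg(scheme)
  required <- c("id", "text", "modality", "label")
  missing_cols <- setdiff(required, names(reports))
  if (length(missing_cols)) {
    stop_vteal("schema", "corpus is missing required column(s): ",
               paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(reports, stringsAsFactors = FALSE)
  df$id <- as.character(df$id)
  df$text <- as.character(df$text)
  if (is.null(df$icd10_coded)) df$icd10_coded <- NA
  df$icd10_coded <- as.logical(df$icd10_coded)
  if (is.null(df$age)) df$age <- NA_real_
  df$age <- suppressWarnings(as.numeric(df$age))
  if (is.null(df$sex)) df$sex <- NA_character_
  df$sex <- ifelse(is.na(df$sex) | df$sex == "", NA_character_,
                   canonicalize_token(as.character(df$sex), c("male", "female")))

  labs <- canonicalize_token(df$label, vte_labels(scheme))
  if (anyNA(labs)) {
    bad <- which(is.na(labs))[1L]
    stop_vteal("validation", sprintf(
      "unknown label token '%s' at row %d (scheme %s)",
      df$label[bad], bad, scheme))
  }
  mods <- canonicalize_token(df$modality, vte_modalities())
  if (anyNA(mods)) {
    bad <- which(is.na(mods))[1L]
    stop_vteal("validation", sprintf(
      "unknown modality token '%s' at row %d", df$modality[bad], bad))
  }
  df$label <- labs
  df$modality <- mods
  if (anyDuplicated(df$id)) {
    stop_vteal("validation", "report ids are not unique (first duplicate: '",
               df$id[anyDuplicated(df$id)], "')")
  }
  if (any(!nzchar(df$text) | is.na(df$text))) {
    bad <- which(!nzchar(df$text) | is.na(df$text))[1L]
    stop_vteal("validation", sprintf("empty report text at row %d", bad))
  }
  df <- df[, corpus_columns()]
  rownames(df) <- NULL
  structure(df, label_scheme = scheme,
            class = c("vte_corpus", "data.frame"))
}

#' @rdname as_corpus
#' @param x Object to test or print.
#' @export
is_corpus <- function(x) inherits(x, "vte_corpus")

#' @export
print.vte_corpus <- function(x, ...) {
  cat(sprintf("<vte_corpus> %d reports, %s scheme\n",
              nrow(x), attr(x, "label_scheme")))
  tab <- table(factor(x$label, levels = vte_labels(attr(x, "label_scheme"))))
  for (l in names(tab)) cat(sprintf("  %-18s %d\n", l, tab[[l]]))
  invisible(x)
}

#' @export
label_scheme <- function(corpus) attr(corpus, "label_scheme")

#' Read a report corpus from disk
#'
#' Two symmetric plain-text dialects are supported: UTF-8 CSV with a header
#' row, and JSON-lines (one JSON object per report).  Both carry the fields
#' `id, text, modality, label, icd10_coded, age, sex`.  Record order is
#' preserved; unparseable labels are reported with their row number.
#'
#' @param path File to read.
#' @param format `"auto"` (by extension: `.csv` vs `.jsonl`/`.ndjson`),
#'   `"csv"`, or `"jsonl"`.
#' @param scheme Label scheme to validate against.
#' @return A [as_corpus()] object.
#' @export
load_corpus <- function(path, format = c("auto", "csv", "jsonl"),
                        scheme = c("7-class", "6-class")) {
  format <- match.arg(format)
  scheme <- match.arg(scheme)
  if (!file.exists(path)) stop_vteal("io", "corpus file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(jsonl|ndjson)$", path, ignore.case = TRUE))
      "jsonl" else "csv"
  }
  df <- if (format == "csv") {
    utils::read.csv(path, colClasses = "character", na.strings = "",
                    fileEncoding = "UTF-8", check.names = FALSE)
  } else {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(lines)]
    recs <- lapply(seq_along(lines), function(i) {
      rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                      error = function(e) stop_vteal(
                        "schema", sprintf("malformed JSON at line %d: %s",
                                          i, conditionMessage(e))))
      rec[vapply(rec, is.null, logical(1))] <- NA
      as.data.frame(rec, stringsAsFactors = FALSE)
    })
    cols <- unique(unlist(lapply(recs, names)))
    recs <- lapply(recs, function(r) {
      r[setdiff(cols, names(r))] <- NA
      r[cols]
    })
    do.call(rbind, recs)
  }
  if ("icd10_coded" %in% names(df) && is.character(df$icd10_coded)) {
    df$icd10_coded <- ifelse(is.na(df$icd10_coded), NA,
                             toupper(df$icd10_coded) %in% c("TRUE", "T", "1"))
  }
  as_corpus(df, scheme = scheme)
}

#' Write a report corpus to disk
#'
#' Inverse of [load_corpus()]: `load_corpus(write_corpus(x, f))` reproduces
#' every field of every report, and re-writing a loaded file is
#' byte-identical (the written form is canonical).
#'
#' @param corpus A `vte_corpus`.
#' @param path Output file.
#' @param format `"auto"`, `"csv"` or `"jsonl"` (as in [load_corpus()]).
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path, format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  stopifnot(is_corpus(corpus))
  if (format == "auto") {
    format <- if (grepl("\\.(jsonl|ndjson)$", path, ignore.case = TRUE))
      "jsonl" else "csv"
  }
  df <- as.data.frame(corpus)
  if (format == "csv") {
    con <- file(path, open = "wb")
    on.exit(close(con))
    utils::write.csv(df, con, row.names = FALSE, na = "", quote = TRUE,
                     fileEncoding = "UTF-8", eol = "\n")
  } else {
    lines <- vapply(seq_len(nrow(df)), function(i) {
      rec <- as.list(df[i, , drop = FALSE])
      jsonlite::toJSON(rec, auto_unbox = TRUE, na = "null", digits = NA)
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
  }
  invisible(path)
}

#' Train/test split specification
#'
#' @param train_fraction Proportion of reports assigned to training, in
#'   (0, 1).  The reference protocol uses an 8:2 training:test ratio.
#' @param seed Integer seed; the split is a pure function of
#'   (corpus, spec).
#' @param stratified Preserve per-class proportions (default).  Severe class
#'   imbalance (the smallest class has ~0.2% prevalence) makes unstratified
#'   20% test sets unstable, so stratification is the default even though it
#'   can be switched off to mimic simple randomization.
#' @return A `vte_split_spec`.
#' @export
split_spec <- function(train_fraction = 0.8, seed = 1L, stratified = TRUE) {
  if (!is.numeric(train_fraction) || train_fraction <= 0 ||
      train_fraction >= 1) {
    stop_vteal("config", "train_fraction must lie in (0, 1)")
  }
  structure(list(train_fraction = train_fraction, seed = as.integer(seed),
                 stratified = isTRUE(stratified)),
            class = "vte_split_spec")
}

#' Split a corpus into disjoint train and test partitions
#'
#' Deterministic given the spec's seed.  The stratified variant apportions
#' the training quota across classes by largest remainder so the overall
#' train fraction is met within one report while per-class proportions are
#' preserved within rounding; a class with a single member is assigned to
#' the training partition with a warning.
#'
#' @param corpus A `vte_corpus`.
#' @param spec A [split_spec()].
#' @return List with `train` and `test` corpora (disjoint, exhaustive).
#' @export
split_corpus <- function(corpus, spec = split_spec()) {
  stopifnot(is_corpus(corpus), inherits(spec, "vte_split_spec"))
  n <- nrow(corpus)
  if (n == 0L) stop_vteal("validation", "cannot split an empty corpus")
  n_train <- round(spec$train_fraction * n)
  n_train <- max(1L, min(n - 1L, n_train))
  idx_train <- with_seed(spec$seed, {
    if (!spec$stratified) {
      sample.int(n, n_train)
    } else {
      cls <- factor(corpus$label, levels = vte_labels(label_scheme(corpus)))
      singles <- which(cls %in% names(which(table(cls) == 1L)))
      if (length(singles)) {
        warning("class(es) with a single member assigned to train: ",
                paste(unique(corpus$label[singles]), collapse = ", "),
                call. = FALSE)
      }
      rest <- setdiff(seq_len(n), singles)
      quota_total <- max(0L, n_train - length(singles))
      counts <- table(droplevels(cls[rest]))
      quota <- largest_remainder(as.numeric(counts), quota_total)
      picked <- unlist(lapply(seq_along(counts), function(k) {
        members <- rest[cls[rest] == names(counts)[k]]
        if (quota[k] >= length(members)) members
        else members[sample.int(length(members), quota[k])]
      }), use.names = FALSE)
      c(singles, picked)
    }
  })
  idx_train <- sort(idx_train)
  list(
    train = as_corpus(corpus[idx_train, , drop = FALSE],
                      scheme = label_scheme(corpus)),
    test = as_corpus(corpus[-idx_train, , drop = FALSE],
                     scheme = label_scheme(corpus))
  )
}

#' Restrict a corpus to a label scheme
#'
#' Under the 6-class scheme every "No DVT or PE" report is dropped and the
#' surviving reports are untouched; under the 7-class scheme the corpus is
#' returned unchanged.
#'
#' @inheritParams split_corpus
#' @param scheme Target scheme.
#' @return A `vte_corpus` under `scheme`.
#' @export
restrict_labels <- function(corpus, scheme = c("7-class", "6-class")) {
  scheme <- match.arg(scheme)
  stopifnot(is_corpus(corpus))
  if (scheme == "7-class") return(corpus)
  if (label_scheme(corpus) == "6-class") return(corpus)
  keep <- corpus$label != vte_negative_label()
  if (!any(keep)) {
    warning("no VTE-positive reports; 6-class corpus is empty",
            call. = FALSE)
  }
  df <- as.data.frame(corpus)[keep, , drop = FALSE]
  rownames(df) <- NULL
  structure(df, label_scheme = "6-class",
            class = c("vte_corpus", "data.frame"))
}
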