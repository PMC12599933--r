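#' Default class counts and modality weights of the emulated corpus
#'
#' The synthetic generator emulates a single-institution corpus of 5,839
#' imaging reports in which VTE was detected in 1,088 (18.6%); the default
#' class counts and modality weights reproduce that composition exactly.
#'
#' @return Named integer (counts) or numeric (weights) vector.
#' @export
default_class_counts <- function() {
  c("No DVT or PE" = 4751L, "PE only" = 75L, "Proximal DVT" = 570L,
    "Distal DVT" = 286L, "Thrombophlebitis" = 58L, "Other DVT" = 11L,
    "DVT and PE" = 88L)
}

#' @rdname default_class_counts
#' @export
default_modality_weights <- function() {
  w <- c(2425, 69, 568, 886, 1891)
  names(w) <- vte_modalities()
  w
}

#' Configuration of the synthetic report generator
#'
#' @param n_reports Number of reports to generate (default 5,839, the size
#'   of the emulated corpus).
#' @param class_counts Named non-negative weights over the 7 labels; scaled
#'   to `n_reports` by largest-remainder apportionment, so with the defaults
#'   the per-class counts reproduce the emulated corpus exactly.
#' @param modality_weights Named non-negative weights over the 5 modalities.
#' @param icd10_concordance Probability that a VTE-positive report carries a
#'   VTE-related ICD-10 code (default 0.650, the audited concordance).
#' @param distractor_rate Probability of appending a clinically irrelevant
#'   sentence (and, independently, an incidental negative finding) to a
#'   report.  Set to 0 for a maximally separable corpus.
#' @param synonym_rate Per-slot probability of substituting a synonym for
#'   the default wording of a lexical slot.
#' @param seed Integer seed; generation is fully reproducible.
#' @return A `vte_generator_config`.
#' @export
generator_config <- function(n_reports = 5839L,
                             class_counts = default_class_counts(),
                             modality_weights = default_modality_weights(),
                             icd10_concordance = 0.650,
                             distractor_rate = 0.3,
                             synonym_rate = 0.5,
                             seed = 1L) {
  n_reports <- as.integer(n_reports)
  if (is.na(n_reports) || n_reports < 1L) {
    stop_vteal("config", "n_reports must be a positive integer")
  }
  labs <- vte_labels()
  if (is.null(names(class_counts)) || !all(names(class_counts) %in% labs)) {
    stop_vteal("config", "class_counts must be named with the 7 labels")
  }
  cc <- stats::setNames(numeric(length(labs)), labs)
  cc[names(class_counts)] <- as.numeric(class_counts)
  if (any(cc < 0) || all(cc == 0)) {
    stop_vteal("config", "class_counts must be non-negative, not all zero")
  }
  mods <- vte_modalities()
  if (is.null(names(modality_weights)) ||
      !all(names(modality_weights) %in% mods)) {
    stop_vteal("config", "modality_weights must be named with the 5 modalities")
  }
  mw <- stats::setNames(numeric(length(mods)), mods)
  mw[names(modality_weights)] <- as.numeric(modality_weights)
  for (r in c(icd10_concordance, distractor_rate, synonym_rate)) {
    if (!is.numeric(r) || r < 0 || r > 1) {
      stop_vteal("config", "rates must lie in [0, 1]")
    }
  }
  structure(list(
    n_reports = n_reports, class_counts = cc, modality_weights = mw,
    icd10_concordance = icd10_concordance, distractor_rate = distractor_rate,
    synonym_rate = synonym_rate, seed = as.integer(seed)
  ), class = "vte_generator_config")
}

#' Load a template bank
#'
#' Reads the YAML bank of per-class findings templates, per-modality header
#' phrases, distractor sentences and lexical slot lexicons used by
#' [render_report()].  The bank shipped with the package can be copied and
#' edited; every class must provide at least 3 findings templates.
#'
#' @param path YAML file; `NULL` loads the bank shipped with the package.
#' @return A `vte_template_bank` (named list).
#' @export
template_bank <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "template_bank.yaml", package = "vteal")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop_vteal("io", "template bank not found: ", path)
  }
  bank <- yaml::read_yaml(path)
  for (lab in vte_labels()) {
    cls <- bank$classes[[lab]]
    if (is.null(cls)) stop_vteal("config", "bank lacks class '", lab, "'")
    tpl <- if (lab == "DVT and PE") c(cls$pe_templates, cls$dvt_templates)
           else cls$templates
    if (length(tpl) < 3L) {
      stop_vteal("config", "class '", lab, "' needs >= 3 templates")
    }
  }
  if (!all(vte_modalities() %in% names(bank$headers))) {
    stop_vteal("config", "bank lacks headers for some modalities")
  }
  structure(bank, class = c("vte_template_bank", "list"))
}

#' Apportion report counts across classes
#'
#' Scales the configured class weights to `n_reports` by deterministic
#' largest-remainder apportionment, so the per-class counts of a generated
#' corpus are exact (not sampled).  With the default configuration the
#' allocation reproduces the emulated corpus: 1,088 VTE-positive reports
#' out of 5,839, of which 570 proximal DVT, 286 distal DVT, 88 combined
#' DVT and PE, and so on.
#'
#' @param config A [generator_config()].
#' @return Named integer vector over the 7 labels summing to `n_reports`.
#' @export
allocate_counts <- function(config) {
  stopifnot(inherits(config, "vte_generator_config"))
  n_pos_classes <- sum(config$class_counts > 0)
  if (config$n_reports < n_pos_classes) {
    stop_vteal("config", sprintf(
      "n_reports (%d) is smaller than the number of classes with positive weight (%d)",
      config$n_reports, n_pos_classes))
  }
  counts <- largest_remainder(config$class_counts, config$n_reports)
  stats::setNames(counts, names(config$class_counts))
}

# Fill {slot} placeholders: default (first) wording, or a synonym with
# probability synonym_rate.  Draws come from the supplied stream.
fill_slots <- function(template, slots, synonym_rate, rng) {
  out <- template
  repeat {
    m <- regmatches(out, regexpr("\\{[a-z_]+\\}", out))
    if (!length(m)) break
    key <- substr(m, 2, nchar(m) - 1)
    lex <- slots[[key]]
    if (is.null(lex)) stop_vteal("config", "unknown template slot '", key, "'")
    pick <- rng_draw(rng, {
      if (length(lex) > 1L && runif(1) < synonym_rate) {
        lex[[sample.int(length(lex) - 1L, 1L) + 1L]]
      } else lex[[1L]]
    })
    out <- sub("\\{[a-z_]+\\}", pick, out)
  }
  out
}

#' Render one synthetic report text
#'
#' Composes a modality header, one findings sentence drawn from the class's
#' template bank (for the compound "DVT and PE" class, one pulmonary
#' embolism sentence plus one deep-vein sentence), and optional incidental
#' negative and distractor sentences.  Positive-class text always contains a
#' class-diagnostic anatomical phrase; negative-class text always contains
#' an explicit negation of thrombus/embolism.  The literal label token never
#' appears in the rendered text.
#'
#' @param label One of [vte_labels()].
#' @param modality One of [vte_modalities()].
#' @param bank A [template_bank()].
#' @param rng A [rng_stream()].
#' @param synonym_rate,distractor_rate See [generator_config()].
#' @return Single character string.
#' @export
render_report <- function(label, modality, bank, rng,
                          synonym_rate = 0.5, distractor_rate = 0.3) {
  stopifnot(inherits(bank, "vte_template_bank"))
  cls <- bank$classes[[label]]
  if (is.null(cls)) stop_vteal("config", "label '", label, "' missing from bank")
  headers <- bank$headers[[modality]]
  pick1 <- function(x) rng_draw(rng, x[[sample.int(length(x), 1L)]])
  parts <- pick1(headers)
  if (label == "DVT and PE") {
    parts <- c(parts,
               fill_slots(pick1(cls$pe_templates), bank$slots, synonym_rate, rng),
               fill_slots(pick1(cls$dvt_templates), bank$slots, synonym_rate, rng))
  } else {
    parts <- c(parts,
               fill_slots(pick1(cls$templates), bank$slots, synonym_rate, rng))
  }
  if (length(cls$incidental_negatives) &&
      rng_draw(rng, runif(1)) < distractor_rate) {
    parts <- c(parts, pick1(cls$incidental_negatives))
  }
  if (rng_draw(rng, runif(1)) < distractor_rate) {
    parts <- c(parts, pick1(bank$distractors))
  }
  paste(parts, collapse = " ")
}

#' Generate a synthetic report corpus
#'
#' Produces a corpus whose per-class counts equal [allocate_counts()]
#' exactly; modalities are sampled from the configured weights, VTE-positive
#' reports are flagged as ICD-10-coded by an independent Bernoulli draw with
#' probability `icd10_concordance`, and demographics follow the emulated
#' corpus (50.6% male, age ~ Normal(61.9, 15.1) truncated to 18-100).
#' Fully reproducible from `config$seed`.
#'
#' @param config A [generator_config()].
#' @param bank A [template_bank()].
#' @return A `vte_corpus` of `config$n_reports` reports.
#' @export
#' @examples
#' corp <- generate_corpus(generator_config(n_reports = 60, seed = 1))
#' table(corp$label)
generate_corpus <- function(config = generator_config(),
                            bank = template_bank()) {
  stopifnot(inherits(config, "vte_generator_config"))
  counts <- allocate_counts(config)
  n <- config$n_reports
  rng <- rng_stream(config$seed)

  labels <- rep(names(counts), counts)
  labels <- labels[rng_draw(rng, sample.int(n))]
  modality <- rng_draw(rng, sample(
    vte_modalities(), n, replace = TRUE,
    prob = config$modality_weights / sum(config$modality_weights)))
  texts <- vapply(seq_len(n), function(i) {
    render_report(labels[i], modality[i], bank, rng,
                  synonym_rate = config$synonym_rate,
                  distractor_rate = config$distractor_rate)
  }, character(1))
  positive <- labels != vte_negative_label()
  coded <- logical(n)
  coded[positive] <- rng_draw(
    rng, runif(sum(positive))) < config$icd10_concordance
  age <- rng_draw(rng, pmin(100, pmax(18, round(rnorm(n, 61.9, 15.1)))))
  sex <- rng_draw(rng, ifelse(runif(n) < 0.506, "male", "female"))

  as_corpus(data.frame(
    id = sprintf("R%06d", seq_len(n)),
    text = texts, modality = modality, label = labels,
    icd10_coded = coded, age = age, sex = sex,
    stringsAsFactors = FALSE
  ))
}
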