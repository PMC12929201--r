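#' Annotate abstract records against drug, population, and disease lexicons
#'
#' Scans each record for drug synonyms (over title, abstract, keywords, and
#' MeSH terms), population synonyms (over title, abstract, and MeSH terms),
#' and disease MeSH headings (exact term membership in the taxonomy).
#' Matching is case-insensitive at word boundaries, so "supraspinatus" never
#' hits "aspirin". Study-type labels are not recomputed here: they are
#' inputs (classifier output or ground truth) copied through unchanged,
#' with the PE/CT mutual-exclusion invariant enforced.
#'
#' @param records Tibble of abstract records (`record_id`, `title`,
#'   `abstract`, `mesh_terms` list-column, `keywords` list-column).
#' @param drug_lex Drug lexicon from [build_drug_lexicon()].
#' @param pop_lex Population lexicon, default [default_population_lexicon()].
#' @param disease_tax Disease taxonomy, default [default_disease_taxonomy()].
#' @param study_labels Optional tibble (`record_id`, `study_types`
#'   list-column) of study-type labels to attach.
#' @return A tibble with one row per record: `record_id`, `drugs`,
#'   `populations`, `diseases`, `study_types` (all list-columns of sorted
#'   character vectors).
#' @examples
#' lex <- build_drug_lexicon(list(acetaminophen = "paracetamol"))
#' rec <- tibble::tibble(record_id = "1", title = "Paracetamol dosing",
#'   abstract = "in pregnant women", mesh_terms = list(character()),
#'   keywords = list(character()))
#' annotate_corpus(rec, lex)
#' @export
annotate_corpus <- function(records, drug_lex,
                            pop_lex = default_population_lexicon(),
                            disease_tax = default_disease_taxonomy(),
                            study_labels = NULL) {
  records <- as_tibble(records)
  if (anyDuplicated(records$record_id)) {
    abort("record_id must be unique within a corpus.",
          class = "pharmgap_invariant_error")
  }
  n <- nrow(records)
  mesh_text <- map_chr(records$mesh_terms, paste, collapse = " ; ")
  kw_text <- map_chr(records$keywords, paste, collapse = " ; ")
  drug_scan <- stringr::str_to_lower(
    paste(records$title, records$abstract, kw_text, mesh_text, sep = " \n "))
  pop_scan <- stringr::str_to_lower(
    paste(records$title, records$abstract, mesh_text, sep = " \n "))

  detect_sets <- function(lex, key, text) {
    hits <- rep(list(character()), length(text))
    for (k in unique(lex[[key]])) {
      syns <- lex$synonym[lex[[key]] == k]
      pat <- paste0("\\b(", paste(escape_regex(syns), collapse = "|"), ")\\b")
      found <- stringr::str_detect(text, pat)
      hits[found] <- map(hits[found], ~ c(.x, k))
    }
    map(hits, sort)
  }

  drugs <- detect_sets(rename(drug_lex, key = "canonical"), "key", drug_scan)
  pops <- detect_sets(rename(pop_lex, key = "tag"), "key", pop_scan)
  tax_terms <- stringr::str_to_lower(disease_tax$term)
  diseases <- map(records$mesh_terms, function(m) {
    sort(unique(disease_tax$term[tax_terms %in% stringr::str_to_lower(m)]))
  })

  types <- rep(list(character()), n)
  if (!is.null(study_labels)) {
    study_labels <- as_tibble(study_labels)
    idx <- match(records$record_id, study_labels$record_id)
    types <- map(idx, function(i) {
      if (is.na(i)) character() else sort(unlist(study_labels$study_types[[i]]))
    })
    bad <- map_lgl(types, ~ all(c("PE", "CT") %in% .x))
    if (any(bad)) {
      abort(paste0("PE and CT are mutually exclusive; violated for record(s): ",
                   paste(records$record_id[bad], collapse = ", ")),
            class = "pharmgap_invariant_error")
    }
  }

  tibble(record_id = records$record_id, drugs = drugs, populations = pops,
         diseases = diseases, study_types = types)
}

#' @rdname annotate_corpus
#' @param record A single record (one-row tibble or named list).
#' @export
annotate_record <- function(record, drug_lex,
                            pop_lex = default_population_lexicon(),
                            disease_tax = default_disease_taxonomy(),
                            study_labels = NULL) {
  if (!is.data.frame(record)) {
    record <- tibble(record_id = record$record_id, title = record$title,
                     abstract = record$abstract,
                     mesh_terms = list(record$mesh_terms %||% character()),
                     keywords = list(record$keywords %||% character()))
  }
  annotate_corpus(record, drug_lex, pop_lex, disease_tax, study_labels)
}

#' Count publications per drug, population, and study type
#'
#' Aggregates annotation results into distinct-record counts: a record
#' carrying d drugs, p populations, and s study types contributes one unit
#' to each of the d x p x s cells, and a drug mentioned five times in one
#' abstract still counts once. Records lacking a drug, a population, or a
#' study type contribute to no cell.
#'
#' @param annotations Tibble from [annotate_corpus()].
#' @return A tibble (`drug`, `population`, `study_type`, `paper_count`),
#'   sorted; counts are numbers of distinct record ids.
#' @export
count_publications <- function(annotations) {
  if (anyDuplicated(annotations$record_id)) {
    abort("record_id must be unique.", class = "pharmgap_invariant_error")
  }
  annotations |>
    select("record_id", "drugs", "populations", "study_types") |>
    unnest("drugs") |>
    unnest("populations") |>
    unnest("study_types") |>
    distinct() |>
    count(drug = .data$drugs, population = .data$populations,
          study_type = .data$study_types, name = "paper_count") |>
    arrange(.data$drug, .data$population, .data$study_type)
}
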