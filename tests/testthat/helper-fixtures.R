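# shared fixture builders; everything is generated in code at test time

identity_lexicon <- function(names) {
  build_drug_lexicon(stats::setNames(as.list(names), names))
}

# minimal abstract record
make_record <- function(id = "X1", title = "", abstract = "",
                        mesh = character(), keywords = character(),
                        year = 2020L) {
  tibble::tibble(record_id = id, title = title, abstract = abstract,
                 mesh_terms = list(mesh), keywords = list(keywords),
                 year = year, language = "eng")
}

# random 2x2 contingency tables with positive cells
random_tables <- function(n, seed = 1, max_cell = 2000L) {
  withr::with_seed(seed, {
    tibble::tibble(
      n11 = sample(1:200, n, replace = TRUE),
      n10 = sample(10:max_cell, n, replace = TRUE),
      n01 = sample(10:max_cell, n, replace = TRUE),
      n00 = sample(1000:50000, n, replace = TRUE)
    ) |>
      dplyr::mutate(N = n11 + n10 + n01 + n00,
                    E = (n11 + n10) * (n11 + n01) / N)
  })
}

# claims cohort fragment with hand-placed spans/events
make_claims <- function(persons, enrollment, prescriptions = NULL,
                        diagnoses = NULL, deliveries = NULL) {
  list(
    persons = persons,
    enrollment = enrollment,
    prescriptions = prescriptions %||% tibble::tibble(
      person_id = character(), drug = character(), day = integer()),
    diagnoses = diagnoses %||% tibble::tibble(
      person_id = character(), icd10_code = character(), day = integer()),
    deliveries = deliveries %||% tibble::tibble(
      person_id = character(), day = integer(), code = character())
  )
}

`%||%` <- rlang::`%||%`
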