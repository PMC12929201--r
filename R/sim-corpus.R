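#' Simulate an annotated abstract corpus with known ground truth
#'
#' Generates MEDLINE-like abstract records whose drug mentions, population
#' mentions, study-type labels, and per-drug totals are all known exactly, so
#' the lexicon scanner and publication counter can be validated cell-for-cell.
#' Relevant abstracts draw a primary drug from a Zipf law over the configured
#' drug list (heavy-tailed publication counts), one patient subpopulation,
#' and one of the five admissible study-type label combinations; each
#' assigned drug name is embedded verbatim in exactly one of title, abstract,
#' or MeSH field, chosen uniformly. Study types leave distinct token
#' footprints in the abstract so that a text classifier can separate them
#' from non-relevant records.
#'
#' @param config A [sim_config()].
#' @return A list with components:
#'   * `records`: tibble of [AbstractRecord-like rows] with columns
#'     `record_id`, `title`, `abstract`, `mesh_terms` (list), `keywords`
#'     (list), `year`, `language`.
#'   * `truth`: list with `records` (per-record true annotations: `relevant`,
#'     `drugs`, `population`, `study_types`) and `publication_counts`
#'     (tibble of distinct-record counts per drug, population tag, and study
#'     type).
#' @examples
#' sim <- simulate_corpus(sim_config(seed = 1, n_papers = 50))
#' nrow(sim$records)
#' @export
simulate_corpus <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 101L, generate_corpus_impl(config))
}

generate_corpus_impl <- function(config) {
  n <- config$n_papers
  empty_records <- tibble(
    record_id = character(), title = character(), abstract = character(),
    mesh_terms = list(), keywords = list(), year = integer(),
    language = character()
  )
  empty_truth_records <- tibble(
    record_id = character(), relevant = logical(), drugs = list(),
    population = character(), study_types = list()
  )
  if (n == 0L) {
    return(list(records = empty_records,
                truth = list(records = empty_truth_records,
                             publication_counts = empty_publication_counts())))
  }

  drugs <- config$drug_names
  nd <- length(drugs)
  zipf_p <- (seq_len(nd))^(-config$publication_count_law$exponent)
  zipf_p <- zipf_p / sum(zipf_p)

  relevant <- runif(n) < config$relevant_fraction
  combo_names <- names(config$label_mix)
  combos <- sample(combo_names, n, replace = TRUE, prob = config$label_mix)
  gen_pops <- c("pregnancy", "postpartum", "neonate", "children", "adolescent")
  pops <- sample(gen_pops, n, replace = TRUE)
  drug1 <- drugs[sample.int(nd, n, replace = TRUE, prob = zipf_p)]
  has_second <- nd > 1L & runif(n) < config$second_drug_prob
  drug2 <- vapply(drug1, function(d) sample(setdiff(drugs, d), 1L), character(1))

  pop_lex <- default_population_lexicon()
  disease_tax <- default_disease_taxonomy()

  rows <- vector("list", n)
  truth_rows <- vector("list", n)
  for (i in seq_len(n)) {
    id <- sprintf("PMID%07d", i)
    year <- sample(2016:2024, 1L)
    if (!relevant[i]) {
      rows[[i]] <- list(
        record_id = id,
        title = paste(sample(lab_filler(), 5L), collapse = " "),
        abstract = paste(sample(lab_filler(), 15L, replace = TRUE), collapse = " "),
        mesh_terms = list(character()),
        keywords = list(sample(lab_filler(), 2L)),
        year = year, language = "eng"
      )
      truth_rows[[i]] <- list(record_id = id, relevant = FALSE,
                              drugs = list(character()), population = NA_character_,
                              study_types = list(character()))
      next
    }
    rec_drugs <- unique(c(drug1[i], if (has_second[i]) drug2[i]))
    types <- switch(combos[i],
                    PE = "PE", CT = "CT", PK = "PK",
                    PK_PE = c("PK", "PE"), PK_CT = c("PK", "CT"))
    pop <- pops[i]
    pop_syn <- sample(pop_lex$synonym[pop_lex$tag == pop], 1L)

    title <- c("assessment", "of", sample(clinical_filler(), 3L))
    abstract <- c(unlist(lapply(types, study_type_phrase)),
                  sample(clinical_filler(), 10L, replace = TRUE))
    mesh <- character()
    for (d in rec_drugs) {
      field <- sample(c("title", "abstract", "mesh"), 1L)
      if (field == "title") title <- c(title, d)
      else if (field == "abstract") abstract <- c(abstract, d)
      else mesh <- c(mesh, d)
    }
    pop_field <- sample(c("title", "abstract", "mesh"), 1L)
    if (pop_field == "title") title <- c(title, pop_syn)
    else if (pop_field == "abstract") abstract <- c(abstract, pop_syn)
    else mesh <- c(mesh, pop_syn)
    if (runif(1) < 0.5) mesh <- c(mesh, sample(disease_tax$term, 1L))

    rows[[i]] <- list(
      record_id = id,
      title = paste(title, collapse = " "),
      abstract = paste(abstract, collapse = " "),
      mesh_terms = list(mesh),
      keywords = list(sample(clinical_filler(), 2L)),
      year = year, language = "eng"
    )
    truth_rows[[i]] <- list(record_id = id, relevant = TRUE,
                            drugs = list(rec_drugs), population = pop,
                            study_types = list(types))
  }

  records <- bind_rows(lapply(rows, as_tibble))
  truth_records <- bind_rows(lapply(truth_rows, as_tibble))

  counts <- truth_records |>
    filter(.data$relevant) |>
    select("record_id", "drugs", "population", "study_types") |>
    unnest("drugs") |>
    unnest("study_types") |>
    distinct(.data$record_id, .data$drugs, .data$population, .data$study_types) |>
    count(drug = .data$drugs, population = .data$population,
          study_type = .data$study_types, name = "n_papers") |>
    arrange(.data$drug, .data$population, .data$study_type)

  list(records = records,
       truth = list(records = truth_records, publication_counts = counts))
}

empty_publication_counts <- function() {
  tibble(drug = character(), population = character(),
         study_type = character(), n_papers = integer())
}

study_type_phrase <- function(type) {
  switch(type,
    PK = c("pharmacokinetics", "absorption", "clearance", "halflife",
           "plasma", "concentration"),
    PE = c("observational", "cohort", "surveillance", "registry",
           "realworld", "incidence"),
    CT = c("randomized", "placebo", "doubleblind", "trial",
           "efficacy", "endpoint")
  )
}

clinical_filler <- function() {
  c("outcomes", "visits", "measurements", "baseline", "followup", "dosing",
    "response", "tolerability", "profiles", "records", "duration",
    "monitoring", "clinic", "therapy", "regimen")
}

lab_filler <- function() {
  c("mitochondrial", "enzyme", "substrate", "culture", "signaling",
    "protein", "kinase", "membrane", "receptor", "assay", "vitro",
    "expression", "pathway", "molecular", "binding")
}
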