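#' Identify pregnancy episodes and apply the enrollment-continuity filter
#'
#' A pregnancy episode is anchored at the person's first delivery-coded
#' event (the index day). The episode is eligible when the person's merged
#' enrollment spans cover the full window from 270 days before to 180 days
#' after the index day without a gap.
#'
#' @param claims Claims cohort: list with tibbles `enrollment`
#'   (`person_id`, `start_day`, `end_day`) and `deliveries` (`person_id`,
#'   `day`, `code`).
#' @param delivery_codes Codes identifying delivery events.
#' @param pre_days,post_days Continuity window around the index day.
#' @return Tibble (`person_id`, `index_day`, `eligible`).
#' @export
build_pregnancy_cohort <- function(claims,
                                   delivery_codes = default_delivery_codes(),
                                   pre_days = 270L, post_days = 180L) {
  if (length(delivery_codes) == 0L) {
    abort("`delivery_codes` must be nonempty.", class = "pharmgap_config_error")
  }
  idx <- claims$deliveries |>
    filter(.data$code %in% delivery_codes) |>
    arrange(.data$person_id, .data$day) |>
    distinct(.data$person_id, .keep_all = TRUE) |>
    transmute(.data$person_id, index_day = .data$day)
  if (nrow(idx) == 0L) {
    return(tibble(person_id = character(), index_day = integer(),
                  eligible = logical()))
  }
  spans <- merge_spans(claims$enrollment)
  idx |>
    left_join(spans, by = "person_id", relationship = "many-to-many") |>
    mutate(covers = !is.na(.data$start_day) &
             .data$start_day <= .data$index_day - pre_days &
             .data$end_day >= .data$index_day + post_days) |>
    summarise(eligible = any(.data$covers),
              .by = c("person_id", "index_day")) |>
    arrange(.data$person_id)
}

# merge overlapping/adjacent enrollment spans per person
merge_spans <- function(enrollment) {
  enrollment |>
    arrange(.data$person_id, .data$start_day) |>
    group_by(.data$person_id) |>
    mutate(gap = .data$start_day > cummax_lag(.data$end_day) + 1L,
           grp = cumsum(.data$gap)) |>
    group_by(.data$person_id, .data$grp) |>
    summarise(start_day = min(.data$start_day), end_day = max(.data$end_day),
              .groups = "drop") |>
    select(-"grp")
}

cummax_lag <- function(x) {
  if (length(x) <= 1L) return(rep(-.Machine$integer.max, length(x)))
  c(-.Machine$integer.max, cummax(x)[-length(x)])
}

#' Count prescriptions in the pregnancy and postpartum windows
#'
#' Over eligible episodes, a prescription on day d relative to the index
#' day falls in the pregnancy window when `index-270 <= d <= index-1` and in
#' the postpartum window when `index <= d <= index+180`; the two windows
#' partition `[index-270, index+180]`, so no event is double counted. The
#' sample size for both subpopulations is the number of eligible episodes.
#'
#' @param episodes From [build_pregnancy_cohort()].
#' @param prescriptions Tibble (`person_id`, `drug`, `day`).
#' @param distinct_persons Count each (person, drug) once per window instead
#'   of every fill.
#' @return Rate-table rows: `subpopulation`, `drug`, `n_prescriptions`,
#'   `sample_size`, `rate`, `rate_per_1000`.
#' @export
window_prescription_counts <- function(episodes, prescriptions,
                                       distinct_persons = FALSE) {
  elig <- filter(episodes, .data$eligible)
  n_elig <- nrow(elig)
  if (n_elig == 0L) {
    return(tibble(subpopulation = character(), drug = character(),
                  n_prescriptions = integer(), sample_size = integer(),
                  rate = double(), rate_per_1000 = double()))
  }
  events <- prescriptions |>
    inner_join(select(elig, "person_id", "index_day"), by = "person_id") |>
    mutate(rel = .data$day - .data$index_day,
           subpopulation = case_when(
             .data$rel >= -270L & .data$rel <= -1L ~ "pregnancy",
             .data$rel >= 0L & .data$rel <= 180L ~ "postpartum",
             TRUE ~ NA_character_)) |>
    filter(!is.na(.data$subpopulation))
  if (distinct_persons) {
    events <- distinct(events, .data$person_id, .data$drug, .data$subpopulation)
  }
  events |>
    count(.data$subpopulation, .data$drug, name = "n_prescriptions") |>
    mutate(sample_size = n_elig,
           rate = .data$n_prescriptions / .data$sample_size,
           rate_per_1000 = 1000 * .data$rate) |>
    arrange(.data$subpopulation, .data$drug)
}

#' Pediatric prescription rates by age group, cumulative across years
#'
#' Persons are assigned to an age group each calendar year by their age at
#' the start of that year, using half-open intervals `[0,1)`, `[1,12)`,
#' `[12,18]` (a child aged exactly 1 belongs to the 1-12 group). The sample
#' size of a group is the cumulative number of person-years across the
#' requested years; prescriptions are assigned to the group the person
#' occupies in the year of the fill. Person-years with negative age are
#' skipped and tallied in the `n_negative_age` attribute.
#'
#' @param claims Claims cohort list (`persons`, `enrollment`,
#'   `prescriptions`).
#' @param years Integer year offsets from the epoch (default the five-year
#'   window 0:4); year y spans days `[365*y, 365*y + 364]`.
#' @param year_length Days per year used for the day-number calendar.
#' @return Rate-table rows as in [window_prescription_counts()].
#' @export
pediatric_rates <- function(claims, years = 0:4, year_length = 365L) {
  grid <- crossing(claims$persons, year = years) |>
    mutate(year_start = .data$year * year_length,
           age = (.data$year_start - .data$birth_day) / year_length)
  n_neg <- sum(grid$age < 0)
  grid <- grid |>
    mutate(subpopulation = age_group_of(.data$age)) |>
    filter(!is.na(.data$subpopulation))
  # person-year counted only when enrollment overlaps the year
  spans <- merge_spans(claims$enrollment)
  py <- grid |>
    inner_join(spans, by = "person_id", relationship = "many-to-many") |>
    filter(.data$start_day <= .data$year_start + year_length - 1L,
           .data$end_day >= .data$year_start) |>
    distinct(.data$person_id, .data$year, .data$subpopulation)
  sample_sizes <- count(py, .data$subpopulation, name = "sample_size")

  rx <- claims$prescriptions |>
    mutate(year = .data$day %/% year_length) |>
    filter(.data$year %in% years) |>
    inner_join(py, by = c("person_id", "year")) |>
    count(.data$subpopulation, .data$drug, name = "n_prescriptions")

  out <- rx |>
    inner_join(sample_sizes, by = "subpopulation") |>
    mutate(rate = .data$n_prescriptions / .data$sample_size,
           rate_per_1000 = 1000 * .data$rate) |>
    arrange(.data$subpopulation, .data$drug)
  # person-years before birth are skipped; the count is kept for auditing
  attr(out, "n_negative_age") <- n_neg
  out
}

age_group_of <- function(age) {
  case_when(
    age >= 0 & age < 1 ~ "ped_0_1",
    age >= 1 & age < 12 ~ "ped_1_12",
    age >= 12 & age <= 18 ~ "ped_12_18",
    TRUE ~ NA_character_
  )
}

#' Full prescription-rate table across the five subpopulations
#'
#' Convenience wrapper combining [build_pregnancy_cohort()],
#' [window_prescription_counts()], and [pediatric_rates()].
#'
#' @inheritParams build_pregnancy_cohort
#' @inheritParams pediatric_rates
#' @return Combined rate table.
#' @export
prescription_rate_table <- function(claims,
                                    delivery_codes = default_delivery_codes(),
                                    years = 0:4) {
  episodes <- build_pregnancy_cohort(claims, delivery_codes)
  bind_rows(
    window_prescription_counts(episodes, claims$prescriptions),
    pediatric_rates(claims, years)
  )
}

#' Drop drugs at or below a minimum prescription count
#'
#' Retains rows with strictly more than `threshold` prescriptions
#' ("more than 10" is read as > 10).
#'
#' @param table A rate table.
#' @param threshold Strict lower bound on `n_prescriptions`.
#' @return Filtered table.
#' @export
filter_min_prescriptions <- function(table, threshold = 10L) {
  filter(table, .data$n_prescriptions > threshold)
}

#' Classify publication evidence for a drug
#'
#' Zero papers is `no_evidence`, one to four is `weak_evidence` (weak
#' evidence means fewer than five publications), five or more is `adequate`.
#'
#' @param paper_count Vector of nonnegative paper counts.
#' @return Character vector of evidence classes.
#' @export
classify_evidence <- function(paper_count) {
  if (any(paper_count < 0 | paper_count != floor(paper_count))) {
    abort("`paper_count` must be nonnegative integers.",
          class = "pharmgap_config_error")
  }
  case_when(
    paper_count == 0 ~ "no_evidence",
    paper_count < 5 ~ "weak_evidence",
    TRUE ~ "adequate"
  )
}

#' Map publication-count population tags onto claims subpopulations
#'
#' @return Named list: subpopulation -> population tags whose counts it
#'   aggregates.
#' @export
default_population_map <- function() {
  list(
    pregnancy = "pregnancy",
    postpartum = "postpartum",
    ped_0_1 = c("neonate", "newborn", "infant", "preterm"),
    ped_1_12 = c("children", "pediatric"),
    ped_12_18 = "adolescent"
  )
}

# per (subpopulation, drug, study_type) paper counts under a population map
map_publication_counts <- function(publication_table, pop_map) {
  map_tbl <- tibble(subpopulation = rep(names(pop_map), lengths(pop_map)),
                    population = unlist(pop_map, use.names = FALSE))
  publication_table |>
    inner_join(map_tbl, by = "population",
               relationship = "many-to-many") |>
    summarise(paper_count = sum(.data$paper_count),
              .by = c("subpopulation", "drug", "study_type"))
}

#' Evidence per prescribed drug, subpopulation, and study type
#'
#' Joins the prescribed-drug universe of each subpopulation with mapped
#' publication counts; drugs absent from the publication table count as 0
#' papers.
#'
#' @param rate_table Prescription rate table.
#' @param publication_table Output of [count_publications()].
#' @param pop_map Population tag mapping, see [default_population_map()].
#' @return Tibble (`subpopulation`, `drug`, `study_type`, `n_prescriptions`,
#'   `paper_count`, `evidence`).
#' @export
drug_evidence <- function(rate_table, publication_table,
                          pop_map = default_population_map()) {
  counts <- map_publication_counts(publication_table, pop_map)
  rate_table |>
    distinct(.data$subpopulation, .data$drug, .data$n_prescriptions) |>
    crossing(study_type = STUDY_TYPES) |>
    left_join(counts, by = c("subpopulation", "drug", "study_type")) |>
    mutate(paper_count = replace_na(.data$paper_count, 0L),
           evidence = classify_evidence(.data$paper_count)) |>
    arrange(.data$subpopulation, .data$drug, .data$study_type)
}

#' Knowledge-gap summary per subpopulation and study type
#'
#' For every (subpopulation, study type) cell, counts the prescribed drugs
#' with no (0 papers) and weak (1-4 papers) evidence and reports their
#' relative frequency over that subpopulation's prescribed-drug universe —
#' the knowledge-gap measure.
#'
#' @inheritParams drug_evidence
#' @return A `gap_summary` tibble: `subpopulation`, `study_type`,
#'   `n_drugs_total`, `n_no_evidence`, `n_weak`, `n_adequate`,
#'   `relative_frequency`.
#' @export
gap_summary <- function(rate_table, publication_table,
                        pop_map = default_population_map()) {
  if (nrow(rate_table) == 0L) {
    abort("Empty drug universe: rate_table has no rows.",
          class = "pharmgap_data_error")
  }
  out <- drug_evidence(rate_table, publication_table, pop_map) |>
    summarise(
      n_drugs_total = n(),
      n_no_evidence = sum(.data$evidence == "no_evidence"),
      n_weak = sum(.data$evidence == "weak_evidence"),
      n_adequate = sum(.data$evidence == "adequate"),
      relative_frequency = (.data$n_no_evidence + .data$n_weak) / .data$n_drugs_total,
      .by = c("subpopulation", "study_type")
    ) |>
    arrange(.data$subpopulation, .data$study_type)
  class(out) <- c("gap_summary", class(out))
  out
}

#' Rank no-evidence drugs by prescription volume
#'
#' Drugs of a subpopulation with zero publications across all three study
#' types, ordered by descending prescription count; ties break
#' alphabetically.
#'
#' @inheritParams drug_evidence
#' @param subpopulation Subpopulation to rank within.
#' @return Tibble (`drug`, `n_prescriptions`) in rank order.
#' @export
rank_no_evidence <- function(rate_table, publication_table, subpopulation,
                             pop_map = default_population_map()) {
  ev <- drug_evidence(rate_table, publication_table, pop_map) |>
    filter(.data$subpopulation == !!subpopulation)
  ev |>
    summarise(total_papers = sum(.data$paper_count),
              n_prescriptions = first(.data$n_prescriptions),
              .by = "drug") |>
    filter(.data$total_papers == 0L) |>
    arrange(desc(.data$n_prescriptions), .data$drug) |>
    select("drug", "n_prescriptions")
}

#' Probability that a per-paper classifier misses all evidence for a drug
#'
#' With per-paper recall r and n independent papers, the chance of missing
#' every one is (1-r)^n; with recall 0.93 and the four papers of a
#' weak-evidence drug this is 0.07^4 = 0.0024%.
#'
#' @param recall Per-paper recall in \[0, 1\].
#' @param n_papers Number of papers.
#' @return Miss probability as a percentage.
#' @examples
#' miss_probability(0.93, 4)  # ~0.0024
#' @export
miss_probability <- function(recall, n_papers) {
  check_prob(recall, "recall")
  if (any(n_papers < 0)) {
    abort("`n_papers` must be >= 0.", class = "pharmgap_config_error")
  }
  (1 - recall)^n_papers * 100
}
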