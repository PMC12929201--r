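#' Assign drug exposure windows within the pregnancy period
#'
#' A person is exposed when they have at least one prescription of the drug
#' inside the pregnancy period `[index-270, index]`; the exposure window
#' starts at the first qualifying prescription (the anchor) and runs
#' `window_days` days, truncated at the index day if it would overrun.
#' Unexposed persons receive a comparison window of equal nominal length
#' whose start offset is sampled (seeded) from the empirical distribution
#' of exposed window offsets, so the two groups observe comparable slices
#' of pregnancy.
#'
#' @param episodes Eligible pregnancy episodes
#'   ([build_pregnancy_cohort()] output; ineligible rows are dropped).
#' @param prescriptions Tibble (`person_id`, `drug`, `day`).
#' @param drug Drug to screen.
#' @param window_days Exposure window length in days (2 months = 60).
#' @param seed Seed for the control-window offset sampling.
#' @return Tibble (`person_id`, `index_day`, `exposed`, `anchor`,
#'   `window_start`, `window_end`).
#' @export
assign_exposure <- function(episodes, prescriptions, drug,
                            window_days = 60L, seed = 1L) {
  if (window_days < 1L) {
    abort("`window_days` must be >= 1.", class = "pharmgap_config_error")
  }
  elig <- filter(episodes, .data$eligible)
  anchors <- prescriptions |>
    filter(.data$drug == !!drug) |>
    inner_join(select(elig, "person_id", "index_day"), by = "person_id") |>
    filter(.data$day >= .data$index_day - 270L, .data$day <= .data$index_day) |>
    arrange(.data$person_id, .data$day) |>
    distinct(.data$person_id, .keep_all = TRUE) |>
    transmute(.data$person_id, .data$index_day, anchor = .data$day)
  if (nrow(anchors) == 0L) {
    abort(sprintf("No exposed persons for drug '%s'; screen not estimable.", drug),
          class = "pharmgap_data_error")
  }
  exposed <- anchors |>
    mutate(exposed = TRUE,
           window_start = .data$anchor,
           window_end = pmin(.data$anchor + window_days - 1L, .data$index_day))
  controls <- elig |>
    filter(!.data$person_id %in% anchors$person_id) |>
    select("person_id", "index_day")
  offsets <- exposed$anchor - (exposed$index_day - 270L)
  with_seed(seed, {
    controls <- controls |>
      mutate(anchor = .data$index_day - 270L +
               sample(offsets, n(), replace = TRUE),
             exposed = FALSE,
             window_start = .data$anchor,
             window_end = pmin(.data$anchor + window_days - 1L, .data$index_day))
  })
  bind_rows(exposed, controls) |>
    arrange(.data$person_id)
}

#' Collect windowed outcomes per ICD-10 code
#'
#' A person counts once for a code when at least one diagnosis of that code
#' falls inside their (exposure or comparison) window; repeated diagnoses
#' do not accumulate. Returns the exposed-by-outcome 2x2 counts per code
#' over every code observed in the diagnoses table.
#'
#' @param assignments Output of [assign_exposure()].
#' @param diagnoses Tibble (`person_id`, `icd10_code`, `day`).
#' @return Tibble (`icd10_code`, `n_exposed_pos`, `n_exposed_neg`,
#'   `n_unexposed_pos`, `n_unexposed_neg`).
#' @export
collect_outcomes <- function(assignments, diagnoses) {
  if (nrow(assignments) == 0L) {
    abort("`assignments` is empty.", class = "pharmgap_data_error")
  }
  n_exp <- sum(assignments$exposed)
  n_unexp <- sum(!assignments$exposed)
  pos <- diagnoses |>
    inner_join(select(assignments, "person_id", "exposed",
                      "window_start", "window_end"),
               by = "person_id") |>
    filter(.data$day >= .data$window_start, .data$day <= .data$window_end) |>
    distinct(.data$icd10_code, .data$person_id, .data$exposed)
  codes <- sort(unique(diagnoses$icd10_code))
  agg <- pos |>
    summarise(n_exposed_pos = sum(.data$exposed),
              n_unexposed_pos = sum(!.data$exposed), .by = "icd10_code")
  tibble(icd10_code = codes) |>
    left_join(agg, by = "icd10_code") |>
    mutate(n_exposed_pos = replace_na(.data$n_exposed_pos, 0L),
           n_unexposed_pos = replace_na(.data$n_unexposed_pos, 0L),
           n_exposed_neg = n_exp - .data$n_exposed_pos,
           n_unexposed_neg = n_unexp - .data$n_unexposed_pos) |>
    select("icd10_code", "n_exposed_pos", "n_exposed_neg",
           "n_unexposed_pos", "n_unexposed_neg") |>
    arrange(.data$icd10_code)
}

#' Pearson chi-square screen per code
#'
#' Applies the uncorrected Pearson chi-square test (1 df) to each
#' exposed-by-outcome 2x2 table; a code passes when `p_value < threshold`
#' (default 1e-5, the fixed stringent level standing in for a
#' multiple-testing correction). Tables with a zero margin get `NA`
#' statistics and never pass.
#'
#' @param outcome_tables Output of [collect_outcomes()].
#' @param threshold Significance threshold on the p-value.
#' @param continuity Use Yates continuity correction (off by default).
#' @return Input with `chi2`, `p_value`, `passes_threshold` appended.
#' @export
chi_square_screen <- function(outcome_tables, threshold = 1e-5,
                              continuity = FALSE) {
  res <- pmap(
    list(outcome_tables$n_exposed_pos, outcome_tables$n_exposed_neg,
         outcome_tables$n_unexposed_pos, outcome_tables$n_unexposed_neg),
    function(a, b, c_, d) {
      m <- matrix(c(a, b, c_, d), 2L, byrow = TRUE)
      if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
        return(c(NA_real_, NA_real_))
      }
      t <- suppressWarnings(chisq.test(m, correct = continuity))
      c(unname(t$statistic), unname(t$p.value))
    })
  outcome_tables |>
    mutate(chi2 = map_dbl(res, 1L), p_value = map_dbl(res, 2L),
           passes_threshold = !is.na(.data$p_value) & .data$p_value < threshold)
}

#' Attach blocklist filter reasons to screen results
#'
#' Codes matching a blocklist prefix are excluded from the new-ADE report
#' with the first matching reason, checked in the fixed order
#' pregnancy_related, indication_related, label_known, literature_known.
#' All rows are retained with their reasons; nothing is deleted.
#'
#' @param results Screen results with an `icd10_code` column.
#' @param blocklists Named list of code-prefix vectors (any subset of the
#'   four reasons above).
#' @return Input with `filtered_reason` (`NA` when unfiltered) appended.
#' @export
filter_codes <- function(results,
                         blocklists = list(pregnancy_related = character(),
                                           indication_related = character(),
                                           label_known = character(),
                                           literature_known = character())) {
  order_ <- c("pregnancy_related", "indication_related", "label_known",
              "literature_known")
  reason <- rep(NA_character_, nrow(results))
  for (nm in intersect(order_, names(blocklists))) {
    prefixes <- blocklists[[nm]]
    if (length(prefixes) == 0L) next
    hit <- map_lgl(results$icd10_code,
                   ~ any(startsWith(.x, prefixes))) & is.na(reason)
    reason[hit] <- nm
  }
  mutate(results, filtered_reason = reason)
}

#' Run the nested case-control ADE screen for a list of drugs
#'
#' Per drug: exposure assignment, windowed outcome collection, per-code
#' chi-square, thresholding, and blocklist filtering. A candidate new ADE
#' is a code that passes the threshold and matches no blocklist.
#'
#' @param claims Claims cohort list (needs `prescriptions`, `diagnoses`).
#' @param drugs Drugs to screen.
#' @param episodes Eligible episodes ([build_pregnancy_cohort()]); computed
#'   from `claims` with [default_delivery_codes()] when `NULL`.
#' @param blocklists Passed to [filter_codes()].
#' @param window_days,threshold,continuity,seed Screen settings.
#' @return Tibble of class `ncc_screen`: one row per (drug, code) with the
#'   2x2 cells, `chi2`, `p_value`, `passes_threshold`, `filtered_reason`,
#'   and `new_ade`.
#' @export
run_screen <- function(claims, drugs, episodes = NULL,
                       blocklists = list(), window_days = 60L,
                       threshold = 1e-5, continuity = FALSE, seed = 1L) {
  episodes <- episodes %||% build_pregnancy_cohort(claims)
  out <- map(drugs, function(d) {
    assign_exposure(episodes, claims$prescriptions, d,
                    window_days = window_days, seed = seed) |>
      collect_outcomes(claims$diagnoses) |>
      chi_square_screen(threshold = threshold, continuity = continuity) |>
      filter_codes(blocklists) |>
      mutate(drug = d, .before = 1L)
  })
  out <- bind_rows(out) |>
    mutate(new_ade = .data$passes_threshold & is.na(.data$filtered_reason))
  class(out) <- c("ncc_screen", class(out))
  out
}
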