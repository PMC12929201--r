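#' Configuration for the synthetic-data generators
#'
#' Bundles every knob of the three generators ([simulate_corpus()],
#' [simulate_reports()], [simulate_claims()]) together with the seed, so a
#' single `sim_config` determines all outputs bit-for-bit. Defaults emulate
#' the statistical structure of the real sources the package targets:
#' a heavy-tailed (Zipf) distribution of publication counts across drugs, a
#' relevant-abstract fraction and study-type label mix matching the published
#' manual-annotation counts of the maternal-pediatric pharmacology corpus
#' (see [annotated_corpus_counts()]), spontaneous-report databases with
#' independent drug/event marginals plus injected relative-reporting signals,
#' and claims cohorts with delivery-anchored pregnancy episodes and windowed
#' prescriptions and diagnoses.
#'
#' @param seed Integer seed; identical configs produce identical outputs.
#' @param n_papers,n_reports,n_persons Sizes of the corpus, report database,
#'   and claims cohort.
#' @param drug_names Canonical drug names (all at least 5 characters, so the
#'   synonym-length filter never silently removes them).
#' @param event_names Adverse-event terms for spontaneous reports.
#' @param publication_count_law List with `dist = "zipf"` and `exponent`;
#'   per-drug paper counts follow rank^(-exponent).
#' @param injected_signals Tibble with columns `drug`, `event`, `lambda`
#'   (relative reporting rate, all >= 1) of drug-event pairs boosted in the
#'   report database.
#' @param injected_ades Tibble with columns `drug`, `icd10_code`,
#'   `exposed_rate`, `baseline_rate` of adverse events elevated inside drug
#'   exposure windows in the claims cohort.
#' @param pregnancy_fraction Proportion of persons in the claims cohort that
#'   are pregnant (carry one delivery event).
#' @param enroll_violation_fraction Proportion of pregnant persons whose
#'   enrollment span fails the 270-day-before / 180-day-after continuity
#'   requirement, to exercise the eligibility filter.
#' @param relevant_fraction Proportion of corpus abstracts relevant to
#'   maternal-pediatric pharmacology.
#' @param label_mix Named probabilities over the five admissible study-type
#'   label combinations (`PE`, `CT`, `PK`, `PK_PE`, `PK_CT`); PE and CT are
#'   mutually exclusive by construction.
#' @param second_drug_prob Probability that a relevant abstract mentions a
#'   second drug.
#' @param report_drug_prob,report_event_prob Per-report inclusion
#'   probabilities for each drug/event (recycled to the vocabulary length).
#' @param claims_rx_prob Per-drug probability that a pregnant person receives
#'   a prescription during pregnancy (and, at 2/3 of this rate, postpartum),
#'   and that a pediatric person receives one in a covered year.
#' @param claims_null_codes ICD-10-like codes carried at `baseline_code_rate`
#'   by everyone, used as the null outcome universe for the case-control
#'   screen.
#' @param baseline_code_rate Probability that a 60-day window of the
#'   pregnancy period contains a diagnosis of a given null code.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(seed = 7, n_papers = 100)
#' corpus <- simulate_corpus(cfg)
#' @export
sim_config <- function(seed = 1L,
                       n_papers = 2000L,
                       n_reports = 10000L,
                       n_persons = 5000L,
                       drug_names = default_drug_names(20L),
                       event_names = default_event_names(20L),
                       publication_count_law = list(dist = "zipf", exponent = 1),
                       injected_signals = NULL,
                       injected_ades = NULL,
                       pregnancy_fraction = 0.5,
                       enroll_violation_fraction = 0.1,
                       relevant_fraction = 2778 / 4845,
                       label_mix = c(PE = 1363, CT = 512, PK = 269,
                                     PK_PE = 588, PK_CT = 46) / 2778,
                       second_drug_prob = 0.1,
                       report_drug_prob = NULL,
                       report_event_prob = NULL,
                       claims_rx_prob = 0.15,
                       claims_null_codes = sprintf("R%02d", 10:29),
                       baseline_code_rate = 0.02) {
  seed <- check_count(seed, "seed")
  n_papers <- check_count(n_papers, "n_papers")
  n_reports <- check_count(n_reports, "n_reports")
  n_persons <- check_count(n_persons, "n_persons")
  check_prob(pregnancy_fraction, "pregnancy_fraction")
  check_prob(enroll_violation_fraction, "enroll_violation_fraction")
  check_prob(relevant_fraction, "relevant_fraction")
  check_prob(second_drug_prob, "second_drug_prob")
  check_prob(claims_rx_prob, "claims_rx_prob")
  check_prob(baseline_code_rate, "baseline_code_rate")

  if (n_papers > 0L && length(drug_names) == 0L) {
    abort("`drug_names` must be nonempty when n_papers > 0.",
          class = "pharmgap_config_error")
  }
  if (!identical(publication_count_law$dist, "zipf") ||
      !is.numeric(publication_count_law$exponent) ||
      publication_count_law$exponent < 0) {
    abort("`publication_count_law` must be list(dist = \"zipf\", exponent >= 0).",
          class = "pharmgap_config_error")
  }
  if (abs(sum(label_mix) - 1) > 1e-8 ||
      !setequal(names(label_mix), c("PE", "CT", "PK", "PK_PE", "PK_CT"))) {
    abort("`label_mix` must be probabilities over PE, CT, PK, PK_PE, PK_CT summing to 1.",
          class = "pharmgap_config_error")
  }

  injected_signals <- injected_signals %||%
    tibble(drug = character(), event = character(), lambda = double())
  injected_signals <- as_tibble(injected_signals)
  if (nrow(injected_signals) > 0) {
    if (any(injected_signals$lambda < 1)) {
      abort("Injected signal lambda must be >= 1.", class = "pharmgap_config_error")
    }
    stopifnot(all(injected_signals$drug %in% drug_names),
              all(injected_signals$event %in% event_names))
  }

  injected_ades <- injected_ades %||%
    tibble(drug = character(), icd10_code = character(),
           exposed_rate = double(), baseline_rate = double())
  injected_ades <- as_tibble(injected_ades)
  if (nrow(injected_ades) > 0) {
    check_prob(injected_ades$exposed_rate, "exposed_rate")
    check_prob(injected_ades$baseline_rate, "baseline_rate")
    if (any(injected_ades$exposed_rate < injected_ades$baseline_rate)) {
      abort("Injected ADE exposed_rate must be >= baseline_rate.",
            class = "pharmgap_config_error")
    }
  }

  nd <- length(drug_names)
  ne <- length(event_names)
  report_drug_prob <- report_drug_prob %||% seq(0.08, 0.02, length.out = max(nd, 1L))
  report_event_prob <- report_event_prob %||% seq(0.08, 0.02, length.out = max(ne, 1L))
  check_prob(report_drug_prob, "report_drug_prob")
  check_prob(report_event_prob, "report_event_prob")

  structure(
    list(
      seed = seed, n_papers = n_papers, n_reports = n_reports,
      n_persons = n_persons, drug_names = drug_names,
      event_names = event_names,
      publication_count_law = publication_count_law,
      injected_signals = injected_signals, injected_ades = injected_ades,
      pregnancy_fraction = pregnancy_fraction,
      enroll_violation_fraction = enroll_violation_fraction,
      relevant_fraction = relevant_fraction, label_mix = label_mix,
      second_drug_prob = second_drug_prob,
      report_drug_prob = rep_len(report_drug_prob, nd),
      report_event_prob = rep_len(report_event_prob, ne),
      claims_rx_prob = claims_rx_prob,
      claims_null_codes = claims_null_codes,
      baseline_code_rate = baseline_code_rate
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> seed", x$seed,
      "| papers", x$n_papers, "| reports", x$n_reports,
      "| persons", x$n_persons, "\n")
  cat("  drugs:", length(x$drug_names), " events:", length(x$event_names),
      " injected signals:", nrow(x$injected_signals),
      " injected ADEs:", nrow(x$injected_ades), "\n")
  invisible(x)
}

#' Default synthetic vocabularies
#'
#' Phonetic-alphabet-derived drug and event names, all long enough to survive
#' the five-character synonym filter and chosen not to collide with any
#' population or filler vocabulary used by the corpus generator.
#'
#' @param n Number of names (up to 26).
#' @return Character vector of names.
#' @export
default_drug_names <- function(n = 20L) {
  paste0("drug", phonetic_names()[seq_len(n)])
}

#' @rdname default_drug_names
#' @export
default_event_names <- function(n = 20L) {
  paste0("event", phonetic_names()[seq_len(n)])
}

phonetic_names <- function() {
  c("alpha", "bravo", "charlie", "delta", "echo", "foxtrot", "golf",
    "hotel", "india", "juliett", "kilo", "lima", "mike", "november",
    "oscar", "papa", "quebec", "romeo", "sierra", "tango", "uniform",
    "victor", "whiskey", "xray", "yankee", "zulu")
}

#' Published label counts of the manually annotated corpus
#'
#' The manual double-annotation of 4845 randomly selected abstracts produced
#' 2067 non-relevant abstracts and 2778 relevant ones split into five
#' mutually exclusive study-type label combinations. These counts are the
#' reference for the default `label_mix` and `relevant_fraction` of
#' [sim_config()].
#'
#' @return A tibble with columns `label` and `n_abstracts`.
#' @examples
#' counts <- annotated_corpus_counts()
#' sum(counts$n_abstracts[counts$label != "non_relevant"])  # 2778
#' @export
annotated_corpus_counts <- function() {
  tibble(
    label = c("PE_only", "CT_only", "PK_only", "PK_PE", "PK_CT", "non_relevant"),
    n_abstracts = c(1363L, 512L, 269L, 588L, 46L, 2067L)
  )
}
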