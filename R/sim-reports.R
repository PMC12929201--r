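#' Simulate a spontaneous adverse-event report database
#'
#' Generates case reports in which each drug and each event enters a report
#' independently with its configured marginal probability, except for
#' injected drug-event pairs whose joint probability is set to
#' `lambda * p(drug) * p(event)` while both margins are preserved. Reports
#' with no drug (or no event) get one filled in from the non-injected
#' vocabulary, which keeps every report nonempty without touching the
#' injected pairs' margins or joint counts, so for a null pair the observed
#' to expected ratio n11/E is ~1 and for an injected pair it is ~lambda.
#'
#' A drug or event may appear in at most one injected pair, and each
#' `lambda` must satisfy `lambda <= 1/max(p(drug), p(event))` for the joint
#' law to exist; violations raise a configuration error.
#'
#' @param config A [sim_config()].
#' @return A list with `reports` (tibble: `report_id`, `age_group`, `drugs`
#'   and `events` list-columns, deduplicated and nonempty) and `truth`
#'   (list with `signal_pairs`, the injected drug-event tibble).
#' @examples
#' cfg <- sim_config(seed = 2, n_reports = 200,
#'   injected_signals = tibble::tibble(drug = "drugalpha",
#'     event = "eventbravo", lambda = 5))
#' db <- simulate_reports(cfg)
#' @export
simulate_reports <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  inj <- config$injected_signals
  if (nrow(inj) > 0) {
    if (anyDuplicated(inj$drug) || anyDuplicated(inj$event)) {
      abort("Each drug and event may appear in at most one injected signal.",
            class = "pharmgap_config_error")
    }
    p <- config$report_drug_prob[match(inj$drug, config$drug_names)]
    q <- config$report_event_prob[match(inj$event, config$event_names)]
    if (any(inj$lambda > 1 / pmax(p, q) + 1e-12)) {
      abort("Injected lambda too large for the configured margins.",
            class = "pharmgap_config_error")
    }
  }
  with_seed(config$seed + 202L, generate_reports_impl(config))
}

generate_reports_impl <- function(config) {
  n <- config$n_reports
  drugs <- config$drug_names
  events <- config$event_names
  truth <- list(signal_pairs = config$injected_signals)
  if (n == 0L) {
    return(list(reports = tibble(report_id = character(),
                                 age_group = character(),
                                 drugs = list(), events = list()),
                truth = truth))
  }

  draw_block <- function(m) {
    xd <- matrix(runif(m * length(drugs)), m) <
      matrix(config$report_drug_prob, m, length(drugs), byrow = TRUE)
    xe <- matrix(runif(m * length(events)), m) <
      matrix(config$report_event_prob, m, length(events), byrow = TRUE)
    inj <- config$injected_signals
    for (k in seq_len(nrow(inj))) {
      di <- match(inj$drug[k], drugs)
      ei <- match(inj$event[k], events)
      p <- config$report_drug_prob[di]
      q <- config$report_event_prob[ei]
      p11 <- inj$lambda[k] * p * q
      u <- runif(m)
      # joint law with margins (p, q) and P(both) = lambda*p*q
      xd[, di] <- u < p
      xe[, ei] <- u < p11 | (u >= p & u < p + (q - p11))
    }
    list(xd = xd, xe = xe)
  }

  blk <- draw_block(n)
  xd <- blk$xd
  xe <- blk$xe
  # guarantee >= 1 drug and >= 1 event per report by filling empties from the
  # non-injected vocabulary; this leaves the injected pairs' margins and
  # joint counts untouched, so their relative reporting ratio stays lambda
  fill_empty <- function(x, probs, protected) {
    free <- setdiff(seq_len(ncol(x)), protected)
    if (length(free) == 0L) free <- seq_len(ncol(x))
    bad <- which(rowSums(x) == 0L)
    if (length(bad) > 0L) {
      pick <- free[sample.int(length(free), length(bad), replace = TRUE,
                              prob = probs[free])]
      x[cbind(bad, pick)] <- TRUE
    }
    x
  }
  inj <- config$injected_signals
  xd <- fill_empty(xd, config$report_drug_prob, match(inj$drug, drugs))
  xe <- fill_empty(xe, config$report_event_prob, match(inj$event, events))

  reports <- tibble(
    report_id = sprintf("R%07d", seq_len(n)),
    age_group = sample(c("0-2", "3-11", "12-17"), n, replace = TRUE,
                       prob = c(0.5, 0.3, 0.2)),
    drugs = apply(xd, 1L, function(r) drugs[r], simplify = FALSE),
    events = apply(xe, 1L, function(r) events[r], simplify = FALSE)
  )
  list(reports = reports, truth = truth)
}
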