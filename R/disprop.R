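#' Build drug-event 2x2 contingency tables from a report database
#'
#' Report-level counting: each report contributes to exactly one cell of
#' each drug-event table (repeated mentions within a report count once), so
#' cells always sum to the number of reports. `E` is the expected
#' co-reporting count under independence of the margins,
#' `(n11+n10)(n11+n01)/N`.
#'
#' @param reports Report tibble (`report_id`, `drugs` and `events`
#'   list-columns).
#' @param drugs,events Vocabularies to tabulate; default every drug/event
#'   occurring in the database. A requested drug or event absent from the
#'   database yields a table with `n11 = 0`, not an error.
#' @param pairs Optional tibble (`drug`, `event`) restricting output to
#'   specific pairs; default all combinations.
#' @return Tibble with one row per pair: `drug`, `event`, `n11`, `n10`,
#'   `n01`, `n00`, `N`, `E`.
#' @export
build_contingency <- function(reports, drugs = NULL, events = NULL,
                              pairs = NULL) {
  if (nrow(reports) == 0L) {
    abort("Report database is empty.", class = "pharmgap_data_error")
  }
  drugs <- drugs %||% sort(unique(unlist(reports$drugs)))
  events <- events %||% sort(unique(unlist(reports$events)))
  n <- nrow(reports)

  ind <- function(sets, vocab) {
    j <- match(unlist(sets), vocab)
    i <- rep(seq_along(sets), lengths(sets))
    keep <- !is.na(j)
    m <- Matrix::sparseMatrix(i = i[keep], j = j[keep], x = 1,
                              dims = c(length(sets), length(vocab)))
    m@x[] <- 1  # dedupe repeated mentions within a report
    m
  }
  xd <- ind(reports$drugs, drugs)
  xe <- ind(reports$events, events)
  n11 <- as.matrix(Matrix::crossprod(xd, xe))
  drug_tot <- Matrix::colSums(xd)
  event_tot <- Matrix::colSums(xe)

  out <- crossing(drug = drugs, event = events) |>
    mutate(n11 = as.integer(n11[cbind(match(.data$drug, drugs),
                                      match(.data$event, events))]),
           n10 = as.integer(drug_tot[match(.data$drug, drugs)]) - .data$n11,
           n01 = as.integer(event_tot[match(.data$event, events)]) - .data$n11,
           n00 = n - .data$n11 - .data$n10 - .data$n01,
           N = n,
           E = (.data$n11 + .data$n10) * (.data$n11 + .data$n01) / n)
  if (!is.null(pairs)) {
    out <- inner_join(as_tibble(pairs), out, by = c("drug", "event"))
  }
  out
}

#' Proportional reporting ratio with its 95% lower bound
#'
#' PRR = \[n11/(n11+n10)\] / \[n01/(n01+n00)\]; the lower bound PRR025 is
#' the 2.5th-percentile limit on the log scale,
#' exp(ln PRR - 1.96 * sqrt(1/n11 - 1/(n11+n10) + 1/n01 - 1/(n01+n00))).
#' With a zero n11 or n01 cell the bound is undefined (`NA`) unless the
#' continuity correction (adds 0.5 to every cell) is enabled.
#'
#' @param tables Contingency tibble from [build_contingency()] (columns
#'   `n11`, `n10`, `n01`, `n00`).
#' @param continuity Add 0.5 to all cells before computing.
#' @return Input with `prr` and `prr025` columns appended.
#' @export
prr_with_bound <- function(tables, continuity = FALSE) {
  cc <- if (continuity) 0.5 else 0
  a <- tables$n11 + cc; b <- tables$n10 + cc
  c_ <- tables$n01 + cc; d <- tables$n00 + cc
  prr <- (a / (a + b)) / (c_ / (c_ + d))
  se <- sqrt(1 / a - 1 / (a + b) + 1 / c_ - 1 / (c_ + d))
  prr025 <- exp(log(prr) - 1.96 * se)
  bad <- a == 0 | c_ == 0
  prr025[bad] <- NA_real_
  prr[a == 0 & c_ > 0] <- 0
  mutate(tables, prr = prr, prr025 = prr025)
}

#' Reporting odds ratio with its 95% lower bound
#'
#' ROR = (n11*n00)/(n10*n01); lower bound
#' exp(ln ROR - 1.96 * sqrt(1/n11 + 1/n10 + 1/n01 + 1/n00)). Zero cells
#' leave the estimate/bound undefined (`NA`) unless the continuity
#' correction is enabled.
#'
#' @inheritParams prr_with_bound
#' @return Input with `ror` and `ror025` columns appended.
#' @export
ror_with_bound <- function(tables, continuity = FALSE) {
  cc <- if (continuity) 0.5 else 0
  a <- tables$n11 + cc; b <- tables$n10 + cc
  c_ <- tables$n01 + cc; d <- tables$n00 + cc
  ror <- (a * d) / (b * c_)
  se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  ror025 <- exp(log(ror) - 1.96 * se)
  bad <- a == 0 | b == 0 | c_ == 0 | d == 0
  ror[b == 0 | c_ == 0] <- NA_real_
  ror025[bad] <- NA_real_
  mutate(tables, ror = ror, ror025 = ror025)
}

#' Bayesian information component with its 2.5th-percentile bound
#'
#' Gamma-Poisson shrinkage formulation: IC = log2((n11+0.5)/(E+0.5)), and
#' IC025 is the exact 2.5th percentile of log2(lambda) under the posterior
#' lambda ~ Gamma(shape = n11 + 0.5, rate = E + 0.5). The +0.5 offsets keep
#' every quantity finite, including at n11 = 0.
#'
#' @inheritParams prr_with_bound
#' @return Input with `ic` and `ic025` columns appended.
#' @export
ic_with_bound <- function(tables) {
  shape <- tables$n11 + 0.5
  rate <- tables$E + 0.5
  mutate(tables,
         ic = log2(shape / rate),
         ic025 = log2(qgamma(0.025, shape = shape, rate = rate)))
}
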