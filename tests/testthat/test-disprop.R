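make_table <- function(n11, n10, n01, n00) {
  tibble::tibble(n11 = n11, n10 = n10, n01 = n01, n00 = n00,
                 N = n11 + n10 + n01 + n00,
                 E = (n11 + n10) * (n11 + n01) / (n11 + n10 + n01 + n00))
}

test_that("contingency counting is report-level and partitions the database", {
  db <- tibble::tibble(report_id = "r1", age_group = "0-2",
                       drugs = list("D"), events = list("E"))
  t1 <- build_contingency(db)
  expect_equal(unlist(t1[, c("n11", "n10", "n01", "n00")]),
               c(n11 = 1L, n10 = 0L, n01 = 0L, n00 = 0L))

  cfg <- sim_config(seed = 6, n_reports = 800)
  db2 <- simulate_reports(cfg)$reports
  tabs <- build_contingency(db2)
  expect_true(all(tabs$n11 + tabs$n10 + tabs$n01 + tabs$n00 == nrow(db2)))
  # absent drug: n11 = 0, no error
  t0 <- build_contingency(db2, pairs = tibble::tibble(drug = "absentdrug",
                                                      event = "eventalpha"),
                          drugs = "absentdrug", events = "eventalpha")
  expect_equal(t0$n11, 0L)
})

test_that("PRR matches its direct formula with a log-scale lower bound", {
  t <- make_table(25, 75, 25, 875)
  r <- prr_with_bound(t)
  expect_equal(r$prr, 9.0)
  lnse <- sqrt(1 / 25 - 1 / 100 + 1 / 25 - 1 / 900)
  expect_equal(r$prr025, exp(log(9) - 1.96 * lnse))
  # equal event proportions in exposed/unexposed
  expect_equal(prr_with_bound(make_table(10, 90, 20, 180))$prr, 1.0)
  # more information tightens the bound without moving the estimate
  r10 <- prr_with_bound(make_table(250, 750, 250, 8750))
  expect_equal(r10$prr, 9.0)
  expect_gt(r10$prr025, r$prr025)
  # undefined bound on a zero cell unless continuity-corrected
  z <- prr_with_bound(make_table(0, 100, 10, 890))
  expect_true(is.na(z$prr025))
  zc <- prr_with_bound(make_table(0, 100, 10, 890), continuity = TRUE)
  expect_false(is.na(zc$prr025))
})

test_that("ROR matches its formula and is symmetric under transposition", {
  expect_equal(ror_with_bound(make_table(10, 20, 30, 60))$ror, 1.0)
  r <- ror_with_bound(make_table(20, 10, 10, 20))
  expect_equal(r$ror, 4.0)
  expect_equal(r$ror025,
               exp(log(4) - 1.96 * sqrt(1 / 20 + 1 / 10 + 1 / 10 + 1 / 20)))
  tr <- ror_with_bound(make_table(20, 10, 10, 20)[, c(1, 3, 2, 4, 5, 6)] |>
                         stats::setNames(c("n11", "n01", "n10", "n00", "N", "E")))
  expect_equal(tr$ror, r$ror)
})

test_that("IC is the shrunk log2 observed-to-expected with an exact gamma bound", {
  # n11 = E exactly -> ic = 0
  t <- make_table(100, 900, 100, 8900)  # E = 1000*200/10000 = 20... pick exact
  t$E <- t$n11
  expect_equal(ic_with_bound(t)$ic, 0)
  # ic025 below ic on random tables
  tabs <- ic_with_bound(random_tables(50, seed = 2))
  expect_true(all(tabs$ic025 < tabs$ic))
  # Monte-Carlo posterior oracle
  mc <- withr::with_seed(9, rgamma(1e6, shape = 100 + 0.5, rate = 48.6 + 0.5))
  t2 <- make_table(100, 900, 400, 48600)
  t2$E <- 48.6
  r2 <- ic_with_bound(t2)
  expect_lt(abs(r2$ic - log2(mean(mc))), 0.01)
  expect_lt(abs(r2$ic025 - log2(quantile(mc, 0.025))), 0.01)
})

test_that("PRR and ROR agree for rare events; all statistics rise with n11", {
  tabs <- random_tables(40, seed = 3) |>
    dplyr::mutate(n00 = n00 * 50)  # push event prevalence below 1%
  tabs$N <- with(tabs, n11 + n10 + n01 + n00)
  tabs$E <- with(tabs, (n11 + n10) * (n11 + n01) / N)
  prev_exp <- with(tabs, n11 / (n11 + n10))
  prev_unexp <- with(tabs, n01 / (n01 + n00))
  rare <- prev_exp < 0.01 & prev_unexp < 0.01
  r <- ror_with_bound(prr_with_bound(tabs))
  expect_true(all(abs(r$prr[rare] / r$ror[rare] - 1) < 0.05))

  base <- make_table(10, 90, 100, 9800)
  grown <- make_table(40, 90, 100, 9800)
  grown$E <- base$E  # margins held fixed
  grown$N <- base$N
  prior <- pharmgap:::canonical_prior()
  s1 <- ebgm_with_bound(ic_with_bound(ror_with_bound(prr_with_bound(base))), prior)
  s2 <- ebgm_with_bound(ic_with_bound(ror_with_bound(prr_with_bound(grown))), prior)
  expect_true(all(c(s2$prr > s1$prr, s2$ror > s1$ror,
                    s2$ic > s1$ic, s2$ebgm > s1$ebgm)))
})

test_that("signal decisions require all four lower bounds and are strict", {
  cfg <- sim_config(seed = 41, n_reports = 20000,
                    injected_signals = tibble::tibble(
                      drug = "drugalpha", event = "eventbravo", lambda = 8))
  db <- simulate_reports(cfg)
  scr <- screen_signals(db$reports)
  hit <- dplyr::filter(scr, drug == "drugalpha", event == "eventbravo")
  expect_true(hit$is_signal)
  expect_true(all(c(hit$ic025 > 0, hit$prr025 > 1, hit$ror025 > 1,
                    hit$eb05 > 1)))
  nulls <- dplyr::filter(scr, !(drug == "drugalpha" & event == "eventbravo"))
  expect_lte(mean(nulls$is_signal), 0.05)
  # boundary: a bound exactly at threshold is a non-signal
  row <- hit
  row$prr025 <- 1.0
  expect_false(with(row, ic025 > 0 & prr025 > 1 & ror025 > 1 & eb05 > 1))
})
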