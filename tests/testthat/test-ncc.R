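simple_episodes <- function(ids, index = 1000L) {
  tibble::tibble(person_id = ids, index_day = index, eligible = TRUE)
}

test_that("exposure windows anchor at the first qualifying fill and clamp at index", {
  ep <- simple_episodes(c("p1", "p2", "p3"))
  rx <- tibble::tibble(
    person_id = c("p1", "p1", "p2"),
    drug = "druga",
    day = c(900L, 950L, 970L))
  asg <- assign_exposure(ep, rx, "druga", window_days = 60, seed = 1)
  a1 <- asg[asg$person_id == "p1", ]
  expect_true(a1$exposed)
  expect_equal(c(a1$window_start, a1$window_end), c(900L, 959L))
  # p2's nominal window would overrun the index day: truncated, still exposed
  a2 <- asg[asg$person_id == "p2", ]
  expect_true(a2$exposed)
  expect_equal(c(a2$window_start, a2$window_end), c(970L, 1000L))
  # p3 has no fills: control with a sampled window of the same shape
  a3 <- asg[asg$person_id == "p3", ]
  expect_false(a3$exposed)
  expect_true(a3$window_start >= 730L && a3$window_end <= 1000L)
  # windows never leave the pregnancy period
  expect_true(all(asg$window_start >= 730L & asg$window_end <= 1000L))
  # control sampling is seeded
  expect_identical(asg, assign_exposure(ep, rx, "druga", window_days = 60, seed = 1))

  expect_error(assign_exposure(ep, rx, "missingdrug", seed = 1),
               class = "pharmgap_data_error")
  # a fill before the pregnancy period does not qualify
  rx_out <- tibble::tibble(person_id = "p1", drug = "druga", day = 600L)
  expect_error(assign_exposure(ep, rx_out, "druga", seed = 1),
               class = "pharmgap_data_error")
})

test_that("outcomes are person-level indicators inside the window", {
  asg <- tibble::tibble(person_id = c("p1", "p2"), index_day = 1000L,
                        exposed = c(TRUE, FALSE), anchor = c(900L, 910L),
                        window_start = c(900L, 910L),
                        window_end = c(959L, 969L))
  dx <- tibble::tibble(
    person_id = c("p1", "p1", "p1", "p2"),
    icd10_code = c("I49", "I49", "R10", "R10"),
    day = c(920L, 930L, 960L, 930L))
  out <- collect_outcomes(asg, dx)
  i49 <- out[out$icd10_code == "I49", ]
  # two same-code diagnoses in window count once
  expect_equal(i49$n_exposed_pos, 1L)
  expect_equal(i49$n_unexposed_pos, 0L)
  r10 <- out[out$icd10_code == "R10", ]
  # p1's R10 at day 960 is one day after window_end: negative
  expect_equal(r10$n_exposed_pos, 0L)
  expect_equal(r10$n_unexposed_pos, 1L)
})

test_that("chi-square equals the textbook formula and thresholds strictly", {
  flat <- chi_square_screen(tibble::tibble(
    icd10_code = "X", n_exposed_pos = 10L, n_exposed_neg = 10L,
    n_unexposed_pos = 10L, n_unexposed_neg = 10L))
  expect_equal(flat$chi2, 0)
  expect_equal(flat$p_value, 1)

  # direct formula oracle: N(ad-bc)^2 / row/col margins
  tabs <- withr::with_seed(5, tibble::tibble(
    icd10_code = sprintf("C%02d", 1:25),
    n_exposed_pos = sample(1:50, 25, TRUE),
    n_exposed_neg = sample(50:500, 25, TRUE),
    n_unexposed_pos = sample(1:50, 25, TRUE),
    n_unexposed_neg = sample(50:500, 25, TRUE)))
  res <- chi_square_screen(tabs)
  oracle <- with(lapply(dplyr::select(tabs, -icd10_code), as.numeric), {
    n <- n_exposed_pos + n_exposed_neg + n_unexposed_pos + n_unexposed_neg
    n * (n_exposed_pos * n_unexposed_neg - n_exposed_neg * n_unexposed_pos)^2 /
      ((n_exposed_pos + n_exposed_neg) * (n_unexposed_pos + n_unexposed_neg) *
         (n_exposed_pos + n_unexposed_pos) * (n_exposed_neg + n_unexposed_neg))
  })
  expect_true(all(abs(res$chi2 - oracle) < 1e-10))
  expect_equal(res$p_value, pchisq(oracle, 1, lower.tail = FALSE))

  # p below the stringent threshold passes; a zero margin is flagged NA
  strong <- chi_square_screen(tibble::tibble(
    icd10_code = "S", n_exposed_pos = 60L, n_exposed_neg = 540L,
    n_unexposed_pos = 10L, n_unexposed_neg = 1390L))
  expect_lt(strong$p_value, 1e-5)
  expect_true(strong$passes_threshold)
  zero <- chi_square_screen(tibble::tibble(
    icd10_code = "Z", n_exposed_pos = 0L, n_exposed_neg = 0L,
    n_unexposed_pos = 5L, n_unexposed_neg = 5L))
  expect_true(is.na(zero$chi2))
  expect_false(zero$passes_threshold)
})

test_that("blocklist filtering is prefix-based with documented precedence", {
  res <- tibble::tibble(icd10_code = c("O26", "J45", "I49"))
  out <- filter_codes(res, list(pregnancy_related = "O",
                                indication_related = c("J", "O2")))
  expect_equal(out$filtered_reason, c("pregnancy_related",
                                      "indication_related", NA))
  none <- filter_codes(res, list())
  expect_true(all(is.na(none$filtered_reason)))
})

test_that("the screen recovers an injected ADE and respects blocklists", {
  cfg <- sim_config(seed = 55, n_persons = 4000, pregnancy_fraction = 1,
                    enroll_violation_fraction = 0,
                    injected_ades = tibble::tibble(
                      drug = "drugecho", icd10_code = "I49",
                      exposed_rate = 0.10, baseline_rate = 0.01))
  cc <- simulate_claims(cfg)
  scr <- run_screen(cc$cohort, "drugecho", seed = 1)
  hit <- scr[scr$icd10_code == "I49", ]
  expect_true(hit$passes_threshold)
  expect_true(hit$new_ade)
  # same screen with the code blocklisted as indication-related
  scr2 <- run_screen(cc$cohort, "drugecho",
                     blocklists = list(indication_related = "I4"), seed = 1)
  hit2 <- scr2[scr2$icd10_code == "I49", ]
  expect_true(hit2$passes_threshold)
  expect_false(hit2$new_ade)
  expect_equal(hit2$filtered_reason, "indication_related")
})
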