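test_that("eligibility depends on span coverage of the 270/180 window", {
  persons <- tibble::tibble(person_id = c("p1", "p2", "p3"),
                            birth_day = 0L, sex = "F")
  deliveries <- tibble::tibble(
    person_id = c("p1", "p2", "p3", "p3"),
    day = c(1000L, 1000L, 1100L, 1000L), code = "Z370")
  enrollment <- tibble::tibble(
    person_id = c("p1", "p2", "p3"),
    start_day = c(1000L - 300L, 1000L - 100L, 600L),
    end_day = c(1200L, 1200L, 1300L))
  claims <- make_claims(persons, enrollment, deliveries = deliveries)
  ep <- build_pregnancy_cohort(claims)
  expect_true(ep$eligible[ep$person_id == "p1"])    # superset window
  expect_false(ep$eligible[ep$person_id == "p2"])   # 270-day lookback fails
  # two delivery events: index is the earlier day
  expect_equal(ep$index_day[ep$person_id == "p3"], 1000L)
})

test_that("adjacent enrollment spans merge into continuous coverage", {
  persons <- tibble::tibble(person_id = "p1", birth_day = 0L, sex = "F")
  deliveries <- tibble::tibble(person_id = "p1", day = 1000L, code = "Z370")
  enrollment <- tibble::tibble(
    person_id = "p1", start_day = c(700L, 901L), end_day = c(900L, 1200L))
  ep <- build_pregnancy_cohort(make_claims(persons, enrollment,
                                           deliveries = deliveries))
  expect_true(ep$eligible)
  # a one-day gap breaks continuity
  enrollment2 <- tibble::tibble(
    person_id = "p1", start_day = c(700L, 903L), end_day = c(901L, 1200L))
  ep2 <- build_pregnancy_cohort(make_claims(persons, enrollment2,
                                            deliveries = deliveries))
  expect_false(ep2$eligible)
})

test_that("pregnancy and postpartum windows partition the episode", {
  episodes <- tibble::tibble(person_id = "p1", index_day = 1000L,
                             eligible = TRUE)
  rx <- tibble::tibble(person_id = "p1", drug = "druga",
                       day = c(999L, 1000L, 729L, 730L, 1180L, 1181L))
  counts <- window_prescription_counts(episodes, rx)
  preg <- counts$n_prescriptions[counts$subpopulation == "pregnancy"]
  post <- counts$n_prescriptions[counts$subpopulation == "postpartum"]
  expect_equal(preg, 2L)   # days 999 (index-1) and 730 (index-270)
  expect_equal(post, 2L)   # days 1000 (index) and 1180 (index+180)
  # 729 = index-271 and 1181 = index+181 fall in neither window
  expect_equal(preg + post, 4L)

  # property: every in-range day lands in exactly one window
  days <- 1000L + sample(-280:190, 200, replace = TRUE)
  rx2 <- tibble::tibble(person_id = "p1", drug = "druga", day = days)
  counts2 <- window_prescription_counts(episodes, rx2)
  in_range <- sum(days >= 730L & days <= 1180L)
  expect_equal(sum(counts2$n_prescriptions), in_range)
})

test_that("pediatric age groups use half-open intervals per year", {
  persons <- tibble::tibble(person_id = c("k1", "k2", "k3"),
                            birth_day = c(-182L, -365L, -6935L), sex = "M")
  # k1 is 0.5y at year 0 start and 1.5y at year 1; k2 exactly 1y at year 0;
  # k3 is 19y at year 0 (excluded)
  enrollment <- tibble::tibble(person_id = c("k1", "k2", "k3"),
                               start_day = 0L, end_day = 729L)
  rx <- tibble::tibble(person_id = c("k1", "k1", "k2", "k3"),
                       drug = "druga", day = c(100L, 400L, 100L, 100L))
  claims <- make_claims(persons, enrollment, prescriptions = rx)
  rates <- pediatric_rates(claims, years = 0:1)
  get <- function(g) {
    r <- rates$n_prescriptions[rates$subpopulation == g]
    if (length(r)) r else 0L
  }
  expect_equal(get("ped_0_1"), 1L)   # k1 in year 0
  expect_equal(get("ped_1_12"), 2L)  # k1 in year 1, k2 (age exactly 1) in year 0
  expect_false("k3" %in% rates$subpopulation)
})

test_that("minimum-prescription filter is strict and evidence classes split at 0/5", {
  tab <- tibble::tibble(subpopulation = "pregnancy",
                        drug = c("a", "b", "c"),
                        n_prescriptions = c(10L, 11L, 0L),
                        sample_size = 100L)
  kept <- filter_min_prescriptions(tab, 10)
  expect_equal(kept$drug, "b")
  expect_equal(nrow(filter_min_prescriptions(tab[0, ], 10)), 0L)
  expect_equal(filter_min_prescriptions(tab, 0)$drug, c("a", "b"))

  expect_equal(classify_evidence(c(0L, 1L, 4L, 5L, 50L)),
               c("no_evidence", "weak_evidence", "weak_evidence",
                 "adequate", "adequate"))
  expect_error(classify_evidence(-1), class = "pharmgap_config_error")
})

test_that("gap summary matches the enumeration oracle", {
  rate <- tibble::tibble(subpopulation = "pregnancy",
                         drug = sprintf("d%02d", 1:10),
                         n_prescriptions = 100L, sample_size = 1000L)
  # 3 drugs with 0 papers, 2 with 3 papers, 5 with 7 papers (PK only)
  pub <- tibble::tibble(
    drug = sprintf("d%02d", 4:10), population = "pregnancy",
    study_type = "PK", paper_count = c(3L, 3L, rep(7L, 5)))
  gs <- gap_summary(rate, pub)
  pk <- dplyr::filter(gs, study_type == "PK")
  expect_equal(pk$n_no_evidence, 3L)
  expect_equal(pk$n_weak, 2L)
  expect_equal(pk$relative_frequency, 0.5)
  expect_equal(pk$n_no_evidence + pk$n_weak + pk$n_adequate, pk$n_drugs_total)
  # no PE/CT papers at all: gap is total there
  expect_equal(dplyr::filter(gs, study_type == "PE")$relative_frequency, 1)

  pub_all <- tibble::tibble(drug = sprintf("d%02d", 1:10),
                            population = "pregnancy", study_type = "PK",
                            paper_count = 9L)
  gs2 <- gap_summary(rate, pub_all)
  expect_equal(dplyr::filter(gs2, study_type == "PK")$relative_frequency, 0)
  expect_error(gap_summary(rate[0, ], pub), class = "pharmgap_data_error")
})

test_that("no-evidence ranking orders by volume with alphabetical ties", {
  rate <- tibble::tibble(subpopulation = "pregnancy",
                         drug = c("zeta", "alpha", "mid", "covered"),
                         n_prescriptions = c(100L, 100L, 50L, 500L),
                         sample_size = 1000L)
  pub <- tibble::tibble(drug = "covered", population = "pregnancy",
                        study_type = "PE", paper_count = 6L)
  rk <- rank_no_evidence(rate, pub, "pregnancy")
  expect_equal(rk$drug, c("alpha", "zeta", "mid"))
  # no zero-evidence drugs -> empty
  pub_all <- tidyr::crossing(drug = rate$drug, population = "pregnancy",
                             study_type = "PK", paper_count = 9L)
  expect_equal(nrow(rank_no_evidence(rate, pub_all, "pregnancy")), 0L)
})

test_that("miss probability follows (1-recall)^n as a percentage", {
  expect_equal(signif(miss_probability(0.93, 4), 2), 0.0024)
  expect_equal(miss_probability(1.0, 7), 0)
  expect_equal(miss_probability(0.0, 3), 100)
})
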