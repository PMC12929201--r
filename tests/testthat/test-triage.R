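test_that("text assembly and chunking follow the integer-division contract", {
  toks <- paste0("w", 1:1030)
  rec <- make_record("T1", title = paste(toks[1:10], collapse = " "),
                     abstract = paste(toks[11:1030], collapse = " "))
  ts <- assemble_and_chunk(rec, max_chunk_len = 512)
  expect_equal(lengths(ts$chunks), c(512L, 512L, 6L))
  # title tokens precede abstract tokens in chunk 1
  expect_equal(ts$chunks[[1]][1:10], toks[1:10])
  # chunks concatenate to the full assembled stream
  expect_equal(unlist(ts$chunks), toks)

  short <- assemble_and_chunk(make_record("T2", title = "a b c"), 512)
  expect_equal(lengths(short$chunks), 3L)
  empty <- assemble_and_chunk(make_record("T3"), 512)
  expect_equal(empty$chunks, list(character()))
  expect_error(assemble_and_chunk(rec, 0), class = "pharmgap_config_error")
})

test_that("metrics honor their closed forms", {
  perfect <- eval_metrics(tp = 10, fp = 0, fn = 0, tn = 10)
  expect_equal(unlist(perfect), c(accuracy = 1, precision = 1, recall = 1, f1 = 1))
  # always-positive classifier on 50/50 data
  ap <- eval_metrics(tp = 50, fp = 50, fn = 0, tn = 0)
  expect_equal(ap$recall, 1)
  expect_equal(ap$precision, 0.5)
  expect_equal(ap$f1, 2 / 3)
  # empty-denominator convention
  none <- eval_metrics(tp = 0, fp = 0, fn = 5, tn = 5)
  expect_equal(none$precision, 0)
  expect_equal(none$f1, 0)
})

test_that("cross-validation is stratified, exhaustive, seeded, and learns a separable corpus", {
  cfg <- sim_config(seed = 8, n_papers = 1000)
  sim <- simulate_corpus(cfg)
  corpus <- dplyr::left_join(
    sim$records,
    dplyr::select(sim$truth$records, record_id, relevant, study_types),
    by = "record_id")
  cv <- crossval_evaluate(corpus, "PE", k_folds = 3, seed = 4)
  # each eligible record predicted exactly once as a held-out item
  expect_false(anyDuplicated(cv$predictions$record_id) > 0)
  expect_setequal(unique(cv$predictions$fold), 1:3)
  expect_gte(cv$pooled$f1, 0.9)
  # reshuffling with the same seed reproduces folds exactly
  cv2 <- crossval_evaluate(corpus, "PE", k_folds = 3, seed = 4)
  expect_identical(cv$predictions, cv2$predictions)
  # broom-style accessors
  expect_equal(nrow(tidy(cv)), 3L)
  expect_equal(glance(cv)$f1, cv$pooled$f1)
})

test_that("single-class data raises an error naming the missing class", {
  cfg <- sim_config(seed = 8, n_papers = 60, relevant_fraction = 1)
  sim <- simulate_corpus(cfg)
  corpus <- dplyr::left_join(
    sim$records,
    dplyr::select(sim$truth$records, record_id, relevant, study_types),
    by = "record_id")
  expect_error(crossval_evaluate(corpus, "PE", k_folds = 2, seed = 1),
               regexp = "negative", class = "pharmgap_data_error")
})

test_that("calibration is a fixed point on perfect predictions and never hurts", {
  ids <- sprintf("r%02d", 1:40)
  truth <- tibble::tibble(record_id = ids, label = rep(c(TRUE, FALSE), 20))
  pred_perfect <- truth
  cal <- calibration_pass(pred_perfect, truth, review_fn = function(ids) {
    tibble::tibble(record_id = character(), label = logical())
  })
  expect_equal(cal$corrected$label, truth$label)
  expect_equal(cal$delta$f1, 0)

  # 5 noisy labels; truthful oracle returns the true label
  noisy <- truth
  noisy$label[1:5] <- !noisy$label[1:5]
  oracle <- function(mis) tibble::tibble(
    record_id = mis, label = truth$label[match(mis, truth$record_id)])
  cal2 <- calibration_pass(pred_perfect, noisy, oracle)
  expect_gte(cal2$after$f1, cal2$before$f1)
  expect_equal(cal2$after$f1, 1)

  # the reviewer may not touch ids outside the misclassified set
  bad_oracle <- function(mis) tibble::tibble(record_id = ids[40], label = FALSE)
  expect_error(calibration_pass(pred_perfect, noisy, bad_oracle),
               class = "pharmgap_invariant_error")
})

test_that("agreement is exact-tuple and adjudication overrides disagreements", {
  lab <- function(ids, rel, types) tibble::tibble(
    record_id = ids, relevant = rel, study_types = types)
  a <- lab(c("1", "2", "3", "4"), c(TRUE, TRUE, FALSE, TRUE),
           list("PK", c("PK", "PE"), character(), "CT"))
  same <- agreement_and_adjudicate(a, a, a[0, ])
  expect_equal(same$report$agreement_rate, 1)

  b <- a
  b$study_types[[4]] <- "PE"
  cc <- lab("4", TRUE, list("CT"))
  res <- agreement_and_adjudicate(a, b, cc)
  expect_equal(res$report$agreement_rate, 0.75)
  expect_equal(res$report$disagreement_ids, "4")
  expect_equal(res$final$study_types[[4]], "CT")

  # adjudicator siding with b everywhere reproduces b
  b2 <- a
  b2$relevant <- !a$relevant
  b2$study_types <- list(character(), "CT", "PK", character())
  res2 <- agreement_and_adjudicate(a, b2, b2)
  expect_equal(res2$final$relevant, b2$relevant)
  expect_equal(res2$final$study_types, b2$study_types)

  expect_error(agreement_and_adjudicate(a, b, b[0, ]),
               class = "pharmgap_data_error")
})

test_that("inclusion requires at least one positive study type", {
  expect_true(inclusion_rule(c(PK = TRUE, PE = FALSE, CT = FALSE)))
  expect_false(inclusion_rule(c(PK = FALSE, PE = FALSE, CT = FALSE)))
  expect_true(inclusion_rule(c(PK = TRUE, PE = TRUE, CT = TRUE)))
  expect_error(inclusion_rule(c(PK = TRUE, PE = FALSE)),
               class = "pharmgap_config_error")
})
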