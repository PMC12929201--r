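#' Simulate a claims-style cohort with pregnancy episodes and injected ADEs
#'
#' Generates persons, enrollment spans, dated prescriptions, ICD-10-coded
#' diagnoses, and delivery events over a five-year observation window
#' (days 0-1824; dates are integer day numbers relative to an epoch). A
#' configurable fraction of persons is pregnant and carries exactly one
#' delivery index event; of those, `enroll_violation_fraction` receive an
#' enrollment span that fails the 270-day-before / 180-day-after continuity
#' requirement, so the eligibility filter has work to do. The remaining
#' persons are pediatric (ages 0-18 across the window) and feed the per-year
#' age-group prescription rates.
#'
#' Diagnoses of the configured null codes are scattered uniformly over each
#' pregnant person's pregnancy period at a rate calibrated so that any
#' 60-day exposure window contains one with probability `baseline_code_rate`.
#' For each injected ADE, persons exposed to the drug during pregnancy
#' receive the code inside their exposure window with probability
#' `exposed_rate`, and unexposed persons at the window-calibrated
#' `baseline_rate`, giving the nested case-control screen a recoverable
#' exposed/unexposed rate ratio.
#'
#' @param config A [sim_config()].
#' @return A list with `cohort` (list of tibbles: `persons`, `enrollment`,
#'   `prescriptions`, `diagnoses`, `deliveries`) and `truth` (list with
#'   `ade_pairs`, `n_pregnant`, `n_violators`).
#' @examples
#' cc <- simulate_claims(sim_config(seed = 3, n_persons = 200))
#' names(cc$cohort)
#' @export
simulate_claims <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 303L, generate_claims_impl(config))
}

#' Default delivery procedure/diagnosis codes
#'
#' Stand-in code list identifying delivery index events in synthetic claims.
#' @return Character vector of codes.
#' @export
default_delivery_codes <- function() c("Z370", "Z380", "O800")

generate_claims_impl <- function(config) {
  n <- config$n_persons
  drugs <- config$drug_names
  nd <- length(drugs)
  truth <- list(ade_pairs = config$injected_ades,
                n_pregnant = 0L, n_violators = 0L)
  empty <- list(
    persons = tibble(person_id = character(), birth_day = integer(),
                     sex = character()),
    enrollment = tibble(person_id = character(), start_day = integer(),
                        end_day = integer()),
    prescriptions = tibble(person_id = character(), drug = character(),
                           day = integer()),
    diagnoses = tibble(person_id = character(), icd10_code = character(),
                       day = integer()),
    deliveries = tibble(person_id = character(), day = integer(),
                        code = character())
  )
  if (n == 0L) return(list(cohort = empty, truth = truth))

  ids <- sprintf("P%06d", seq_len(n))
  pregnant <- runif(n) < config$pregnancy_fraction
  n_preg <- sum(pregnant)
  n_ped <- n - n_preg
  preg_ids <- ids[pregnant]
  ped_ids <- ids[!pregnant]
  truth$n_pregnant <- n_preg

  preg_len <- 271L   # days index-270 .. index inclusive
  window_len <- 60L  # default exposure window
  rx_parts <- list()
  dx_parts <- list()

  ## --- pregnant persons -----------------------------------------------
  if (n_preg > 0L) {
    index <- sample(500:1300, n_preg, replace = TRUE)
    birth_p <- index - sample(7300:14600, n_preg, replace = TRUE)
    violate <- runif(n_preg) < config$enroll_violation_fraction
    truth$n_violators <- sum(violate)
    front_fail <- violate & runif(n_preg) < 0.5
    back_fail <- violate & !front_fail
    start <- index - 270L - sample(0:100, n_preg, replace = TRUE)
    end <- index + 180L + sample(0:100, n_preg, replace = TRUE)
    start[front_fail] <- index[front_fail] - sample(50:269, sum(front_fail), replace = TRUE)
    end[back_fail] <- index[back_fail] + sample(0:179, sum(back_fail), replace = TRUE)

    deliveries <- tibble(
      person_id = preg_ids, day = index,
      code = sample(default_delivery_codes(), n_preg, replace = TRUE))
    enroll_p <- tibble(person_id = preg_ids, start_day = start, end_day = end)

    # pregnancy prescriptions: at most one per (person, drug)
    took <- matrix(runif(n_preg * nd) < config$claims_rx_prob, n_preg, nd)
    rx_day <- matrix(NA_integer_, n_preg, nd)
    hit <- which(took, arr.ind = TRUE)
    if (nrow(hit) > 0L) {
      d <- index[hit[, 1L]] - sample(1:270, nrow(hit), replace = TRUE)
      rx_day[hit] <- d
      rx_parts$preg <- tibble(person_id = preg_ids[hit[, 1L]],
                              drug = drugs[hit[, 2L]], day = d)
    }
    post <- which(matrix(runif(n_preg * nd) < config$claims_rx_prob * 2 / 3,
                         n_preg, nd), arr.ind = TRUE)
    if (nrow(post) > 0L) {
      rx_parts$post <- tibble(
        person_id = preg_ids[post[, 1L]], drug = drugs[post[, 2L]],
        day = index[post[, 1L]] + sample(0:180, nrow(post), replace = TRUE))
    }

    # null-code diagnoses spread over the pregnancy period
    codes <- config$claims_null_codes
    null_rate <- pmin(1, config$baseline_code_rate * preg_len / window_len)
    nullhit <- which(matrix(runif(n_preg * length(codes)) < null_rate,
                            n_preg, length(codes)), arr.ind = TRUE)
    if (nrow(nullhit) > 0L) {
      dx_parts$null <- tibble(
        person_id = preg_ids[nullhit[, 1L]], icd10_code = codes[nullhit[, 2L]],
        day = index[nullhit[, 1L]] - sample(0:270, nrow(nullhit), replace = TRUE))
    }

    # injected ADE outcomes
    inj <- config$injected_ades
    for (k in seq_len(nrow(inj))) {
      di <- match(inj$drug[k], drugs)
      exposed <- took[, di]
      exp_idx <- which(exposed)
      pos <- exp_idx[runif(length(exp_idx)) < inj$exposed_rate[k]]
      if (length(pos) > 0L) {
        anchor <- rx_day[cbind(pos, di)]
        hi <- pmin(anchor + window_len - 1L, index[pos])
        dx_parts[[paste0("inj", k, "e")]] <- tibble(
          person_id = preg_ids[pos], icd10_code = inj$icd10_code[k],
          day = anchor + floor(runif(length(pos)) * (hi - anchor + 1L)))
      }
      unexp <- which(!exposed)
      base_p <- min(1, inj$baseline_rate[k] * preg_len / window_len)
      neg <- unexp[runif(length(unexp)) < base_p]
      if (length(neg) > 0L) {
        dx_parts[[paste0("inj", k, "u")]] <- tibble(
          person_id = preg_ids[neg], icd10_code = inj$icd10_code[k],
          day = index[neg] - sample(0:270, length(neg), replace = TRUE))
      }
    }
  } else {
    deliveries <- empty$deliveries
    enroll_p <- empty$enrollment
    birth_p <- integer()
  }

  ## --- pediatric persons ----------------------------------------------
  if (n_ped > 0L) {
    birth_k <- sample(-6205:1460, n_ped, replace = TRUE)
    enroll_k <- tibble(person_id = ped_ids, start_day = 0L, end_day = 1824L)
    kid_hit <- which(matrix(runif(n_ped * nd) < config$claims_rx_prob,
                            n_ped, nd), arr.ind = TRUE)
    if (nrow(kid_hit) > 0L) {
      rx_parts$ped <- tibble(
        person_id = ped_ids[kid_hit[, 1L]], drug = drugs[kid_hit[, 2L]],
        day = sample(0:1824, nrow(kid_hit), replace = TRUE))
    }
  } else {
    enroll_k <- empty$enrollment
    birth_k <- integer()
  }

  persons <- bind_rows(
    tibble(person_id = preg_ids, birth_day = as.integer(birth_p), sex = "F"),
    tibble(person_id = ped_ids, birth_day = as.integer(birth_k),
           sex = if (n_ped) sample(c("F", "M"), n_ped, replace = TRUE) else character())
  ) |> arrange(.data$person_id)

  cohort <- list(
    persons = persons,
    enrollment = bind_rows(enroll_p, enroll_k) |> arrange(.data$person_id),
    prescriptions = if (length(rx_parts)) {
      bind_rows(rx_parts) |> arrange(.data$person_id, .data$drug, .data$day)
    } else empty$prescriptions,
    diagnoses = if (length(dx_parts)) {
      bind_rows(dx_parts) |> arrange(.data$person_id, .data$icd10_code, .data$day)
    } else empty$diagnoses,
    deliveries = deliveries |> arrange(.data$person_id)
  )
  list(cohort = cohort, truth = truth)
}
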