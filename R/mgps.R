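#' Fit the two-component gamma mixture prior of the empirical-Bayes
#' gamma-Poisson shrinker
#'
#' Under the MGPS model the relative reporting rate lambda of each
#' drug-event pair is drawn from a two-component gamma mixture
#' `p * Gamma(alpha1, beta1) + (1-p) * Gamma(alpha2, beta2)` and the
#' observed count is `n11 ~ Poisson(lambda * E)`. Marginally n11 is a
#' mixture of negative binomials with size `alpha_j` and probability
#' `beta_j / (beta_j + E)`. The five prior parameters are estimated by
#' maximizing the marginal likelihood over all pairs with a bounded
#' quasi-Newton search (L-BFGS-B on log/logit-transformed parameters) from
#' the canonical start point (0.2, 0.1, 2.0, 4.0, 1/3).
#'
#' @param tables Contingency tibble with columns `n11` and `E` (all `E > 0`;
#'   at least two pairs).
#' @param start Numeric start values `c(alpha1, beta1, alpha2, beta2, p)`.
#' @param maxit Iteration cap for the optimizer.
#' @param fix_p Set to `1` to fit the degenerate single-component model
#'   (only `alpha1`, `beta1` free); default `NULL` fits the full mixture.
#' @return Object of class `mgps_prior`: `alpha1`, `beta1`, `alpha2`,
#'   `beta2`, `p`, `loglik`, `convergence`, `n_pairs`. Non-convergence
#'   raises an error of class `pharmgap_convergence_error` whose condition
#'   carries the best-so-far parameters in `$prior`.
#' @export
fit_mgps_prior <- function(tables,
                           start = c(alpha1 = 0.2, beta1 = 0.1,
                                     alpha2 = 2.0, beta2 = 4.0, p = 1 / 3),
                           maxit = 500L, fix_p = NULL) {
  n <- tables$n11
  E <- tables$E
  if (length(n) < 2L) {
    abort("Need at least two pairs to fit the prior.",
          class = "pharmgap_data_error")
  }
  if (any(E <= 0)) {
    abort("All expected counts E must be > 0.", class = "pharmgap_data_error")
  }

  # moment-informed auxiliary start: lambda-scale mean/variance
  m_lam <- max(mean(n / E), 1e-3)
  v_lam <- max((stats::var(n) - mean(n)) / mean(E^2), 1e-3)
  a_mom <- max(m_lam^2 / v_lam, 1e-3)
  b_mom <- max(m_lam / v_lam, 1e-3)

  if (identical(fix_p, 1)) {
    # degenerate single-gamma fit: only (alpha1, beta1) free
    negll1 <- function(theta) {
      -sum(dnbinom(n, size = exp(theta[1]),
                   prob = exp(theta[2]) / (exp(theta[2]) + E), log = TRUE))
    }
    starts <- list(log(start[1:2]), c(0, 0), log(c(a_mom, b_mom)))
    opt <- multi_optim(starts, negll1, maxit)
    prior <- structure(
      list(alpha1 = exp(opt$par[1]), beta1 = exp(opt$par[2]),
           alpha2 = exp(opt$par[1]), beta2 = exp(opt$par[2]), p = 1,
           loglik = -opt$value, convergence = opt$convergence,
           n_pairs = length(n)),
      class = "mgps_prior")
    if (opt$convergence != 0) {
      abort("MGPS single-component fit did not converge.",
            class = "pharmgap_convergence_error", prior = prior)
    }
    return(prior)
  }

  negll <- function(theta) {
    a1 <- exp(theta[1]); b1 <- exp(theta[2])
    a2 <- exp(theta[3]); b2 <- exp(theta[4])
    p <- stats::plogis(theta[5])
    l1 <- dnbinom(n, size = a1, prob = b1 / (b1 + E), log = TRUE)
    l2 <- dnbinom(n, size = a2, prob = b2 / (b2 + E), log = TRUE)
    m <- pmax(l1, l2)
    ll <- m + log(p * exp(l1 - m) + (1 - p) * exp(l2 - m))
    -sum(ll)
  }
  starts <- list(
    c(log(start[1:4]), stats::qlogis(start[5])),
    c(0, 0, 0, 0, 0),
    c(log(c(a_mom, b_mom)), log(c(a_mom, b_mom)) + c(1, -1),
      stats::qlogis(start[5]))
  )
  opt <- multi_optim(starts, negll, maxit)
  prior <- structure(
    list(alpha1 = exp(opt$par[1]), beta1 = exp(opt$par[2]),
         alpha2 = exp(opt$par[3]), beta2 = exp(opt$par[4]),
         p = stats::plogis(opt$par[5]),
         loglik = -opt$value, convergence = opt$convergence,
         n_pairs = length(n)),
    class = "mgps_prior"
  )
  if (opt$convergence != 0) {
    abort(paste0("MGPS prior fit did not converge: ", opt$message),
          class = "pharmgap_convergence_error", prior = prior)
  }
  prior
}

#' @export
print.mgps_prior <- function(x, ...) {
  cat(sprintf("<mgps_prior> alpha=(%.3g, %.3g) beta=(%.3g, %.3g) p=%.3f  logLik=%.1f (%d pairs)\n",
              x$alpha1, x$alpha2, x$beta1, x$beta2, x$p, x$loglik, x$n_pairs))
  invisible(x)
}

# bounded quasi-Newton from several start points; returns the best optimum
# (the marginal likelihood has ridges along which a single start can stall
# on the parameter bounds)
multi_optim <- function(starts, fn, maxit) {
  k <- length(starts[[1]])
  fits <- map(starts, function(s) {
    tryCatch(
      optim(s, fn, method = "L-BFGS-B",
            lower = rep(-12, k), upper = rep(12, k),
            control = list(maxit = maxit)),
      error = function(e) list(par = s, value = Inf, convergence = 99L)
    )
  })
  conv <- keep(fits, ~ .x$convergence == 0)
  pool <- if (length(conv) > 0) conv else fits
  pool[[which.min(map_dbl(pool, "value"))]]
}

# canonical MGPS start point as a ready-made prior (used as a reference
# prior in oracles and degenerate checks)
canonical_prior <- function() {
  structure(list(alpha1 = 0.2, beta1 = 0.1, alpha2 = 2, beta2 = 4, p = 1 / 3,
                 loglik = NA_real_, convergence = 0L, n_pairs = 0L),
            class = "mgps_prior")
}

# posterior mixture weights and component parameters for each (n11, E)
mgps_posterior <- function(prior, n, E) {
  l1 <- dnbinom(n, size = prior$alpha1, prob = prior$beta1 / (prior$beta1 + E),
                log = TRUE) + log(prior$p)
  l2 <- dnbinom(n, size = prior$alpha2, prob = prior$beta2 / (prior$beta2 + E),
                log = TRUE) + log(1 - prior$p)
  m <- pmax(l1, l2)
  w1 <- exp(l1 - m) / (exp(l1 - m) + exp(l2 - m))
  list(w1 = w1,
       shape1 = prior$alpha1 + n, rate1 = prior$beta1 + E,
       shape2 = prior$alpha2 + n, rate2 = prior$beta2 + E)
}

#' Empirical-Bayes geometric mean and its 5th percentile
#'
#' The posterior of lambda given (n11, E) is a two-component gamma mixture
#' with components `Gamma(alpha_j + n11, beta_j + E)` and weights updated by
#' the negative-binomial evidence. EBGM = 2^E\[log2 lambda | data\], with
#' the expectation evaluated exactly via digamma; EB05 is the 5th
#' percentile of the mixture, found by root-finding on the mixture CDF to
#' 1e-8 tolerance.
#'
#' @param tables Contingency tibble with `n11` and `E` columns.
#' @param prior An [fit_mgps_prior()] object.
#' @return Input with `ebgm` and `eb05` columns appended.
#' @export
ebgm_with_bound <- function(tables, prior) {
  if (!inherits(prior, "mgps_prior")) {
    abort("`prior` must be an mgps_prior object.", class = "pharmgap_config_error")
  }
  post <- mgps_posterior(prior, tables$n11, tables$E)
  elog <- post$w1 * (digamma(post$shape1) - log(post$rate1)) +
    (1 - post$w1) * (digamma(post$shape2) - log(post$rate2))
  ebgm <- exp(elog)
  eb05 <- vapply(seq_len(nrow(tables)), function(i) {
    mixture_quantile(0.05, post$w1[i],
                     post$shape1[i], post$rate1[i],
                     post$shape2[i], post$rate2[i])
  }, double(1))
  mutate(tables, ebgm = ebgm, eb05 = eb05)
}

mixture_quantile <- function(q, w1, shape1, rate1, shape2, rate2) {
  # degenerate weights: the mixture collapses to one component
  if (w1 <= 1e-14) return(qgamma(q, shape2, rate2))
  if (w1 >= 1 - 1e-14) return(qgamma(q, shape1, rate1))
  cdf <- function(x) {
    w1 * pgamma(x, shape1, rate1) + (1 - w1) * pgamma(x, shape2, rate2) - q
  }
  q1 <- qgamma(q, shape1, rate1)
  q2 <- qgamma(q, shape2, rate2)
  lo <- min(q1, q2)
  hi <- max(q1, q2)
  if (hi - lo < 1e-12 || (cdf(lo) >= 0 && cdf(hi) >= 0)) {
    # numerically flat bracket: both endpoints already past the quantile
    return(lo)
  }
  while (cdf(lo) > 0) lo <- lo / 2
  while (cdf(hi) < 0) hi <- hi * 2
  uniroot(cdf, c(lo, hi), tol = 1e-8)$root
}

#' Screen a report database for signals with the four-statistic rule
#'
#' Builds all drug-event 2x2 tables, fits the MGPS prior once on the whole
#' database, computes PRR, ROR, IC, and EBGM with their lower bounds, and
#' declares a pair a signal iff `IC025 > 0`, `PRR025 > 1`, `ROR025 > 1`,
#' and `EB05 > 1` (all strict). Pairs with an undefined statistic are
#' non-signals with a reason code.
#'
#' @param reports Report tibble as in [build_contingency()].
#' @param pairs Optional tibble (`drug`, `event`) of pairs to decide;
#'   default all pairs. The prior is always fitted on all pairs.
#' @param continuity Continuity correction flag for PRR/ROR.
#' @param age_group Optional age-group label filtering reports before
#'   tabulation (e.g. `"0-2"`).
#' @return Tibble of class `signal_screen`: contingency cells, all eight
#'   statistics, `is_signal`, and `reason` (`NA` when all statistics are
#'   defined).
#' @export
screen_signals <- function(reports, pairs = NULL, continuity = FALSE,
                           age_group = NULL) {
  if (!is.null(age_group)) {
    reports <- filter(reports, .data$age_group %in% !!age_group)
  }
  all_tables <- build_contingency(reports)
  prior <- fit_mgps_prior(all_tables)
  tabs <- if (is.null(pairs)) all_tables else {
    inner_join(as_tibble(pairs), all_tables, by = c("drug", "event"))
  }
  out <- tabs |>
    prr_with_bound(continuity = continuity) |>
    ror_with_bound(continuity = continuity) |>
    ic_with_bound() |>
    ebgm_with_bound(prior) |>
    mutate(
      reason = if_else(is.na(.data$prr025) | is.na(.data$ror025),
                       "undefined_statistic", NA_character_),
      is_signal = !is.na(.data$prr025) & !is.na(.data$ror025) &
        .data$ic025 > 0 & .data$prr025 > 1 & .data$ror025 > 1 & .data$eb05 > 1
    )
  attr(out, "prior") <- prior
  class(out) <- c("signal_screen", class(out))
  out
}
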