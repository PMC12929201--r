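# simulate pairs from a known two-gamma mixture prior
simulate_mgps_pairs <- function(n_pairs, alpha, beta, p, seed) {
  withr::with_seed(seed, {
    E <- exp(runif(n_pairs, log(0.5), log(100)))
    comp <- runif(n_pairs) < p
    lambda <- ifelse(comp, rgamma(n_pairs, alpha[1], beta[1]),
                     rgamma(n_pairs, alpha[2], beta[2]))
    tibble::tibble(n11 = rpois(n_pairs, lambda * E), E = E)
  })
}

test_that("the mixture fit recovers a known prior on simulated pairs", {
  tabs <- simulate_mgps_pairs(5000, alpha = c(0.2, 2), beta = c(0.1, 4),
                              p = 1 / 3, seed = 10)
  fit <- fit_mgps_prior(tabs)
  est <- if (fit$alpha1 <= fit$alpha2) {
    c(fit$alpha1, fit$beta1, fit$alpha2, fit$beta2, fit$p)
  } else {
    c(fit$alpha2, fit$beta2, fit$alpha1, fit$beta1, 1 - fit$p)
  }
  truth <- c(0.2, 0.1, 2, 4, 1 / 3)
  expect_true(all(abs(est - truth) / truth < 0.4))
  expect_equal(fit$convergence, 0)
  expect_equal(nrow(tidy(fit)), 5L)
  expect_true(is.finite(glance(fit)$logLik))
})

test_that("a no-signal database concentrates the prior near lambda = 1", {
  tabs <- withr::with_seed(11, {
    E <- exp(runif(3000, log(1), log(100)))
    tibble::tibble(n11 = rpois(3000, E), E = E)
  })
  fit <- fit_mgps_prior(tabs)
  expect_gt(glance(fit)$prior_mean, 0.8)
  expect_lt(glance(fit)$prior_mean, 1.2)
})

test_that("the degenerate single-component fit matches a moment check", {
  tabs <- withr::with_seed(12, {
    E <- rep(10, 4000)
    lambda <- rgamma(4000, shape = 3, rate = 3)
    tibble::tibble(n11 = rpois(4000, lambda * E), E = E)
  })
  fit <- fit_mgps_prior(tabs, fix_p = 1)
  expect_equal(fit$p, 1)
  # gamma-Poisson moments: mean(n) = (a/b) E, var(n) = mean + (a/b^2) E^2
  expect_lt(abs(fit$alpha1 / fit$beta1 - mean(tabs$n11 / tabs$E)), 0.1)
  mom_ab2 <- (var(tabs$n11) - mean(tabs$n11)) / 100
  expect_lt(abs(fit$alpha1 / fit$beta1^2 - mom_ab2) / mom_ab2, 0.25)
})

test_that("EBGM shrinks toward the prior and matches its limits", {
  # prior ~ point mass at 1: huge shapes with alpha/beta = 1
  point <- structure(list(alpha1 = 1e6, beta1 = 1e6, alpha2 = 1e6,
                          beta2 = 1e6, p = 0.5, loglik = NA_real_,
                          convergence = 0L, n_pairs = 0L),
                     class = "mgps_prior")
  t <- tibble::tibble(n11 = 50, E = 5)
  expect_lt(abs(ebgm_with_bound(t, point)$ebgm - 1), 0.02)

  # large-count limit: diffuse prior, ebgm within 1% of n11/E
  diffuse <- structure(list(alpha1 = 0.01, beta1 = 0.001, alpha2 = 0.01,
                            beta2 = 0.001, p = 0.5, loglik = NA_real_,
                            convergence = 0L, n_pairs = 0L),
                       class = "mgps_prior")
  big <- tibble::tibble(n11 = 10000, E = 1000)
  expect_lt(abs(ebgm_with_bound(big, diffuse)$ebgm / 10 - 1), 0.01)

  # shrinkage decreases as counts grow at fixed observed ratio
  prior <- pharmgap:::canonical_prior()
  small <- ebgm_with_bound(tibble::tibble(n11 = 5, E = 1), prior)$ebgm
  large <- ebgm_with_bound(tibble::tibble(n11 = 500, E = 100), prior)$ebgm
  expect_lt(abs(large - 5), abs(small - 5))
})

test_that("EB05 sits below EBGM and matches the Monte-Carlo mixture quantile", {
  prior <- pharmgap:::canonical_prior()
  tabs <- tibble::tibble(n11 = c(3L, 20L, 120L), E = c(1.2, 10, 40))
  res <- ebgm_with_bound(tabs, prior)
  expect_true(all(res$eb05 < res$ebgm))
  post <- pharmgap:::mgps_posterior(prior, tabs$n11, tabs$E)
  for (i in seq_len(nrow(tabs))) {
    draws <- withr::with_seed(50 + i, {
      comp <- runif(1e6) < post$w1[i]
      ifelse(comp, rgamma(1e6, post$shape1[i], post$rate1[i]),
             rgamma(1e6, post$shape2[i], post$rate2[i]))
    })
    expect_lt(abs(res$eb05[i] - quantile(draws, 0.05)), 0.01)
    expect_lt(abs(log(res$ebgm[i]) - mean(log(draws))), 0.01)
  }
})

test_that("invalid inputs are rejected", {
  expect_error(fit_mgps_prior(tibble::tibble(n11 = 1L, E = 1)),
               class = "pharmgap_data_error")
  expect_error(fit_mgps_prior(tibble::tibble(n11 = c(1L, 2L), E = c(0, 1))),
               class = "pharmgap_data_error")
  expect_error(ebgm_with_bound(tibble::tibble(n11 = 1, E = 1), prior = list()),
               class = "pharmgap_config_error")
})
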