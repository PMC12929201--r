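#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a cross-validation result
#'
#' One row per fold with accuracy, precision, recall, and F1.
#'
#' @param x A `triage_cv` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.triage_cv <- function(x, ...) {
  mutate(x$fold_metrics, study_type = x$study_type, .before = 1L)
}

#' @rdname tidy.triage_cv
#' @export
glance.triage_cv <- function(x, ...) {
  bind_cols(tibble(study_type = x$study_type, k_folds = x$k_folds),
            x$pooled)
}

#' Tidy an MGPS prior fit
#'
#' One row per prior parameter (long form), or a one-row model summary
#' with `glance()`.
#'
#' @param x An `mgps_prior` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.mgps_prior <- function(x, ...) {
  tibble(term = c("alpha1", "beta1", "alpha2", "beta2", "p"),
         estimate = c(x$alpha1, x$beta1, x$alpha2, x$beta2, x$p))
}

#' @rdname tidy.mgps_prior
#' @export
glance.mgps_prior <- function(x, ...) {
  tibble(logLik = x$loglik, convergence = x$convergence, n_pairs = x$n_pairs,
         prior_mean = x$p * x$alpha1 / x$beta1 +
           (1 - x$p) * x$alpha2 / x$beta2)
}
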