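#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a scenario-choice result
#'
#' @param x An `abc_model_choice`.
#' @param ... Unused.
#' @return Tibble with `scenario`, `posterior_prob`, `conf_low`, `conf_high`.
#' @export
tidy.abc_model_choice <- function(x, ...) x$probabilities

#' @rdname tidy.abc_model_choice
#' @export
glance.abc_model_choice <- function(x, ...) {
  tibble::tibble(n_retained = x$n_retained, tol = x$tol, method = x$method,
                 best_scenario = x$probabilities$scenario[
                   which.max(x$probabilities$posterior_prob)])
}

#' Tidy an ABC parameter posterior
#'
#' @param x An `abc_posterior`.
#' @param ... Unused.
#' @return Tibble with one row per parameter: mean, median, mode and the
#'   2.5/5/95/97.5% quantiles of the regression-adjusted posterior.
#' @export
tidy.abc_posterior <- function(x, ...) x$summary

#' @rdname tidy.abc_posterior
#' @export
glance.abc_posterior <- function(x, ...) {
  tibble::tibble(scenario = x$scenario, n_retained = x$n_retained)
}

#' Tidy a posterior-predictive model check
#'
#' @param x An `abc_model_check`.
#' @param ... Unused.
#' @export
tidy.abc_model_check <- function(x, ...) x$stats

#' @rdname tidy.abc_model_check
#' @export
glance.abc_model_check <- function(x, ...) {
  tibble::tibble(scenario = x$scenario, n_sim = x$n_sim,
                 n_flagged = sum(x$stats$flagged),
                 observed_rank = x$observed_rank)
}

#' Tidy a form assignment
#'
#' @param x A `form_assignment`.
#' @param ... Unused.
#' @return Tibble with `population`, `score`, `cluster`, `form`, `margin`,
#'   `overridden`.
#' @export
tidy.form_assignment <- function(x, ...) x$assignment

#' @rdname tidy.form_assignment
#' @export
glance.form_assignment <- function(x, ...) {
  tibble::tibble(n_populations = nrow(x$assignment), linkage = x$linkage,
                 min_margin = min(x$assignment$margin))
}
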