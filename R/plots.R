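#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_errorbar geom_point
#'   geom_line geom_vline geom_histogram facet_wrap labs theme_minimal
#'   scale_fill_manual
#' @export
ggplot2::autoplot

FORM_COLORS <- c(LW = "#3B6FB6", ML = "#4BA34B", HG = "#E08214")

#' Plot scenario posterior probabilities
#'
#' Bar chart of the posterior probability of each demographic scenario with
#' its confidence interval.
#'
#' @param object An `abc_model_choice`.
#' @param ... Unused.
#' @export
autoplot.abc_model_choice <- function(object, ...) {
  d <- object$probabilities
  ggplot(d, aes(x = factor(.data$scenario), y = .data$posterior_prob)) +
    geom_col(fill = "grey35") +
    geom_errorbar(aes(ymin = .data$conf_low, ymax = .data$conf_high),
                  width = 0.25) +
    labs(x = "Scenario", y = "Posterior probability",
         title = "ABC scenario choice") +
    theme_minimal()
}

#' Plot posterior parameter densities
#'
#' Weighted density of each adjusted posterior sample with the posterior
#' median marked.
#'
#' @param object An `abc_posterior`.
#' @param ... Unused.
#' @export
autoplot.abc_posterior <- function(object, ...) {
  pars <- object$summary$parameter
  dens <- dplyr::bind_rows(lapply(pars, function(p) {
    d <- stats::density(object$samples[[p]],
                        weights = object$samples$weight /
                          sum(object$samples$weight), n = 256)
    tibble::tibble(parameter = p, value = d$x, density = d$y)
  }))
  med <- object$summary[, c("parameter", "median")]
  ggplot(dens, aes(x = .data$value, y = .data$density)) +
    geom_line() +
    geom_vline(data = med, aes(xintercept = .data$median), linetype = 2) +
    facet_wrap(~parameter, scales = "free") +
    labs(x = NULL, y = "Posterior density",
         title = paste("Adjusted parameter posteriors, scenario",
                       object$scenario)) +
    theme_minimal()
}

#' Plot the posterior-predictive PCA cloud
#'
#' First two principal components of the posterior-predictive statistic
#' cloud with the observed data point.
#'
#' @param object An `abc_model_check`.
#' @param ... Unused.
#' @export
autoplot.abc_model_check <- function(object, ...) {
  cloud <- tibble::as_tibble(object$pca_scores[, 1:2, drop = FALSE])
  names(cloud) <- c("PC1", "PC2")
  obs <- tibble::tibble(PC1 = object$observed_scores[1],
                        PC2 = object$observed_scores[2])
  ggplot(cloud, aes(x = .data$PC1, y = .data$PC2)) +
    geom_point(alpha = 0.3, size = 0.8) +
    geom_point(data = obs, colour = "red", size = 3, shape = 17) +
    labs(title = "Posterior-predictive model check",
         subtitle = "red triangle = observed data") +
    theme_minimal()
}

#' Plot population morph scores coloured by assigned form
#'
#' @param object A `form_assignment`.
#' @param ... Unused.
#' @export
autoplot.form_assignment <- function(object, ...) {
  d <- object$assignment
  d$form <- factor(d$form, levels = names(FORM_COLORS))
  ggplot(d, aes(x = .data$score, fill = .data$form)) +
    geom_histogram(bins = 30) +
    scale_fill_manual(values = FORM_COLORS, name = "Form") +
    labs(x = "Population mean log(leg I / leg III)", y = "Populations",
         title = "Weapon-morph form assignment") +
    theme_minimal()
}
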