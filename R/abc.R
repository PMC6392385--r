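#' Build an ABC reference table
#'
#' For each requested scenario, draws `n_per_scenario` parameter vectors from
#' the priors, simulates a genealogy and an HKY alignment for each draw, and
#' computes the 33 summary statistics. Rows are blocked by scenario in the
#' order given. The whole loop runs in compiled code; all randomness comes
#' from R's RNG, so results are reproducible under `set.seed()` or the
#' `seed` argument.
#'
#' @param scenario_ids Integer vector, subset of 1--9.
#' @param priors Prior tibble ([default_priors()]).
#' @param n_per_scenario Simulations per scenario.
#' @param sample_sizes Named per-form sample sizes (default the study design
#'   10 LW, 13 ML, 18 HG).
#' @param n_sites Alignment length (default 618).
#' @param base_freq Stationary base frequencies for the HKY model.
#' @param seed Optional integer seed applied before simulation.
#' @return A tibble of class `abc_reftable` with columns `scenario`, the
#'   eight parameters, and the 33 statistics; priors and simulation settings
#'   are kept as attributes.
#' @export
#' @examples
#' ref <- build_reference_table(c(2, 9), n_per_scenario = 5, seed = 1,
#'                              n_sites = 100)
#' dim(ref)
build_reference_table <- function(scenario_ids = 1:9,
                                  priors = default_priors(),
                                  n_per_scenario = 1000,
                                  sample_sizes = c(LW = 10, ML = 13, HG = 18),
                                  n_sites = 618,
                                  base_freq = rep(0.25, 4),
                                  seed = NULL) {
  stopifnot(n_per_scenario >= 1, all(scenario_ids %in% 1:9))
  validate_priors(priors)
  if (!is.null(seed)) set.seed(seed)
  draws <- dplyr::bind_rows(lapply(scenario_ids, function(id)
    sample_prior(priors, id, n = n_per_scenario)))
  pcols <- c("N_LW", "N_ML", "N_HG", "t1", "t2", "r", "mu", "kappa")
  templates <- lapply(1:9, scenario_event_template)
  stats <- abc_batch_cpp(templates, as.integer(draws$scenario),
                         as.matrix(draws[, pcols]),
                         as.integer(sample_sizes[FORMS]),
                         as.integer(n_sites), as.numeric(base_freq))
  colnames(stats) <- sumstat_names()
  out <- dplyr::bind_cols(draws, tibble::as_tibble(stats))
  class(out) <- c("abc_reftable", class(out))
  attr(out, "priors") <- priors
  attr(out, "sample_sizes") <- sample_sizes[FORMS]
  attr(out, "n_sites") <- as.integer(n_sites)
  attr(out, "base_freq") <- as.numeric(base_freq)
  attr(out, "layout") <- "blocked_by_scenario"
  out
}

# robust per-statistic scale for standardization: MAD, falling back to SD;
# a statistic constant over the table gets scale 0 and drops out of the
# distance (its deviation carries no information).
reftable_scale <- function(stats_mat) {
  sc <- apply(stats_mat, 2, mad)
  zero <- sc == 0
  sc[zero] <- apply(stats_mat[, zero, drop = FALSE], 2, sd)
  sc
}

#' ABC rejection step
#'
#' Standardizes every statistic by a robust scale (median absolute
#' deviation, with SD fallback for MAD-degenerate columns) estimated from
#' the reference table, computes Euclidean distances to the observed vector,
#' retains the closest `ceiling(tol * n)` rows and attaches Epanechnikov
#' kernel weights \eqn{1 - (d/d_{max})^2}.
#'
#' @param ref An `abc_reftable`.
#' @param observed One-row tibble or named vector holding the 33 observed
#'   statistics (see [summarize_alignment()]).
#' @param tol Tolerance: fraction of rows retained, in (0, 1].
#' @return A tibble of class `abc_rejection`: retained rows plus `dist` and
#'   `weight`; standardization scale, observed vector and settings kept as
#'   attributes.
#' @export
abc_reject <- function(ref, observed, tol = 0.01) {
  stopifnot(inherits(ref, "abc_reftable"), tol > 0, tol <= 1)
  obs <- unlist(tibble::as_tibble(as.list(observed))[1, sumstat_names()])
  sm <- as.matrix(ref[, sumstat_names()])
  sc <- reftable_scale(sm)
  use <- sc > 0
  z <- sweep(sweep(sm[, use, drop = FALSE], 2, obs[use]), 2, sc[use], "/")
  d <- sqrt(rowSums(z^2))
  keep <- ceiling(tol * nrow(ref))
  if (keep < length(unique(ref$scenario)))
    stop("retention too small: fewer retained rows than scenarios")
  ord <- order(d)[seq_len(keep)]
  dmax <- d[ord[keep]]
  w <- if (dmax > 0) 1 - (d[ord] / dmax)^2 else rep(1, keep)
  w[w <= 0] <- min(w[w > 0], 1e-8) / 2  # boundary rows keep infinitesimal mass
  out <- dplyr::bind_cols(tibble::as_tibble(ref[ord, ]),
                          tibble::tibble(dist = d[ord], weight = w))
  class(out) <- c("abc_rejection", class(out))
  attr(out, "observed") <- obs
  attr(out, "scale") <- sc
  attr(out, "tol") <- tol
  attr(out, "n_total") <- nrow(ref)
  attr(out, "priors") <- attr(ref, "priors")
  attr(out, "sample_sizes") <- attr(ref, "sample_sizes")
  attr(out, "n_sites") <- attr(ref, "n_sites")
  attr(out, "base_freq") <- attr(ref, "base_freq")
  out
}

#' Scenario choice by weighted multinomial logistic regression
#'
#' Regresses the scenario indicator of the retained simulations on the
#' standardized deviations of their statistics from the observed vector,
#' with the Epanechnikov rejection weights; a linear-discriminant
#' pre-projection onto at most K-1 axes keeps the fit well-posed at modest
#' retained counts. The posterior probability of each scenario is the
#' fitted category probability at the origin (deviation zero). 95%
#' intervals come from the delta method applied to the asymptotic
#' covariance of the fitted intercepts. If the maximum likelihood fit
#' separates, a ridge-penalized (weight-decay) fit is used; if even that
#' fails, weighted retained-class frequencies with an effective-sample-size
#' binomial interval.
#'
#' @param rejection An `abc_rejection` containing at least two scenarios.
#' @param level Confidence level for the intervals.
#' @return An object of class `abc_model_choice`; see [tidy.abc_model_choice()].
#' @export
choose_model <- function(rejection, level = 0.95) {
  stopifnot(inherits(rejection, "abc_rejection"))
  scen <- sort(unique(rejection$scenario))
  if (length(scen) < 2) stop("retained set contains fewer than 2 scenarios")
  obs <- attr(rejection, "observed")
  sc <- attr(rejection, "scale")
  use <- sc > 0
  X <- sweep(sweep(as.matrix(rejection[, sumstat_names()])[, use, drop = FALSE],
                   2, obs[use]), 2, sc[use], "/")
  # drop columns with no spread among retained rows (would be inestimable)
  keepc <- apply(X, 2, sd) > 1e-10
  X <- X[, keepc, drop = FALSE]
  y <- factor(rejection$scenario, levels = scen)
  w <- rejection$weight
  # linear-discriminant pre-projection of the statistics onto at most
  # K-1 axes before the logistic fit; the observed point (deviation zero)
  # stays at the origin because the projection is linear in the deviations
  proj <- tryCatch(suppressWarnings(MASS::lda(x = X, grouping = y, tol = 1e-8)),
                   error = function(e) NULL)
  if (!is.null(proj)) {
    X <- X %*% proj$scaling
    colnames(X) <- colnames(proj$scaling)
  }
  dat <- data.frame(.y = y, .w = w, X, check.names = TRUE)
  fit_one <- function(decay) tryCatch(
    nnet::multinom(.y ~ . - .w, data = dat, weights = .w, trace = FALSE,
                   maxit = 1000, MaxNWts = 10000, Hess = TRUE, decay = decay),
    error = function(e) NULL)
  coef_mat <- function(fit) {
    cf <- stats::coef(fit)
    if (length(scen) == 2) cf <- matrix(cf, nrow = 1, dimnames = list(scen[2], names(cf)))
    cf
  }
  fit <- fit_one(0)
  method <- "multinomial logistic (ML)"
  # complete or quasi-separation shows up as runaway coefficients on the
  # standardized-deviation scale; refit with an L2 (ridge) penalty
  if (is.null(fit) || max(abs(coef_mat(fit))) > 20) {
    fit <- fit_one(0.1)
    method <- "multinomial logistic (ridge, decay = 0.1)"
  }
  probs <- lo <- hi <- NULL
  if (!is.null(fit)) {
    cf <- coef_mat(fit)
    eta <- c(0, cf[, "(Intercept)"])
    p <- exp(eta - max(eta)); p <- p / sum(p)
    V <- tryCatch(stats::vcov(fit), error = function(e) NULL)
    if (!is.null(V) && all(is.finite(V)) && all(is.finite(p))) {
      inames <- grep("\\(Intercept\\)", colnames(V), value = TRUE)
      Vi <- V[inames, inames, drop = FALSE]
      K <- length(p)
      se <- numeric(K)
      for (k in seq_len(K)) {
        # d p_k / d b_j for j = 2..K (class 1 is reference)
        g <- vapply(2:K, function(j) p[k] * ((k == j) - p[j]), numeric(1))
        se[k] <- sqrt(max(0, t(g) %*% Vi %*% g))
      }
      zq <- stats::qnorm(1 - (1 - level) / 2)
      probs <- p
      lo <- pmax(0, p - zq * se)
      hi <- pmin(1, p + zq * se)
    } else fit <- NULL
  }
  if (is.null(fit)) {
    # last resort when even the penalised fit fails: weighted class
    # frequencies of the retained set (direct-rejection estimate)
    method <- "weighted class frequencies (rejection fallback)"
    tw <- tapply(w, y, sum)
    tw[is.na(tw)] <- 0
    probs <- as.numeric(tw / sum(tw))
    neff <- sum(w)^2 / sum(w^2)
    zq <- stats::qnorm(1 - (1 - level) / 2)
    se <- sqrt(probs * (1 - probs) / neff)
    lo <- pmax(0, probs - zq * se)
    hi <- pmin(1, probs + zq * se)
  }
  structure(
    list(probabilities = tibble::tibble(scenario = scen,
                                        posterior_prob = as.numeric(probs),
                                        conf_low = as.numeric(lo),
                                        conf_high = as.numeric(hi)),
         method = method, level = level,
         n_retained = nrow(rejection), tol = attr(rejection, "tol")),
    class = "abc_model_choice")
}

#' @export
print.abc_model_choice <- function(x, ...) {
  cat("ABC scenario choice (", x$method, "), ", x$n_retained,
      " retained simulations\n", sep = "")
  print(as.data.frame(x$probabilities), digits = 4)
  invisible(x)
}

# weighted quantiles by the weighted empirical CDF
wquantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]; w <- w[o] / sum(w)
  cw <- cumsum(w)
  vapply(probs, function(p) x[which(cw >= p)[1]], numeric(1))
}

#' Posterior parameter estimation by local-linear adjustment
#'
#' For the retained simulations of one scenario, each parameter is mapped to
#' the real line by a logit transform over its prior bounds, regressed
#' (weighted by the rejection kernel) on the standardized deviations of the
#' statistics from the observed vector, and adjusted to the observed point
#' by subtracting the fitted systematic part; adjusted values are mapped
#' back inside the prior bounds. Point summaries are the weighted mean,
#' median, kernel-density mode (Gaussian kernel, Silverman bandwidth, 512
#' grid points within the prior bounds) and the 2.5/5/95/97.5% weighted
#' quantiles.
#'
#' @param rejection An `abc_rejection`.
#' @param scenario Scenario id whose retained rows are used.
#' @param min_rows Minimum retained rows required (default 50).
#' @return An `abc_posterior` with elements `summary` (tibble: parameter,
#'   mean, median, mode, q2.5, q5, q95, q97.5), `samples` (adjusted draws
#'   with weights) and settings.
#' @export
estimate_parameters <- function(rejection, scenario, min_rows = 50) {
  stopifnot(inherits(rejection, "abc_rejection"))
  sub <- rejection[rejection$scenario == scenario, , drop = FALSE]
  if (nrow(sub) < min_rows)
    stop("only ", nrow(sub), " retained rows for scenario ", scenario,
         "; need >= ", min_rows)
  priors <- attr(rejection, "priors")
  obs <- attr(rejection, "observed")
  sc <- attr(rejection, "scale")
  use <- sc > 0
  X <- sweep(sweep(as.matrix(sub[, sumstat_names()])[, use, drop = FALSE],
                   2, obs[use]), 2, sc[use], "/")
  w <- sub$weight
  pars <- c("N_LW", "N_ML", "N_HG", "t2", "mu", "kappa")
  if (scenario != 9) pars <- append(pars, "t1", after = 3)
  if (scenario %in% 7:8) pars <- c(pars, "r")
  adj <- list()
  summ <- list()
  for (p in pars) {
    b <- priors[priors$parameter == p, ]
    a <- b$lower; bb <- b$upper
    u <- (sub[[p]] - a) / (bb - a)
    u <- pmin(pmax(u, 1e-9), 1 - 1e-9)
    z <- stats::qlogis(u)
    beta <- tryCatch({
      f <- stats::lm.wfit(cbind(1, X), z, w)
      cf <- f$coefficients[-1]
      cf[is.na(cf)] <- 0
      cf
    }, error = function(e) rep(0, ncol(X)))
    if (nrow(X) <= ncol(X) + 1) {
      # saturated regression would collapse the posterior to a point
      warning("too few retained rows for the local-linear adjustment of ", p,
              "; reporting unadjusted values")
      beta <- rep(0, ncol(X))
    }
    if (sd(z) < 1e-12) {
      warning("degenerate posterior spread for ", p, "; reporting unadjusted values")
      beta <- rep(0, ncol(X))
    }
    zadj <- z - drop(X %*% beta)
    xadj <- a + (bb - a) * stats::plogis(zadj)
    adj[[p]] <- xadj
    bw <- stats::bw.nrd0(xadj)
    if (!is.finite(bw) || bw <= 0) bw <- (bb - a) / 512
    dens <- stats::density(xadj, weights = w / sum(w), bw = bw,
                           n = 512, from = a, to = bb)
    q <- wquantile(xadj, w, c(0.025, 0.05, 0.5, 0.95, 0.975))
    summ[[p]] <- tibble::tibble(
      parameter = p,
      mean = weighted.mean(xadj, w),
      median = q[3],
      mode = dens$x[which.max(dens$y)],
      q2.5 = q[1], q5 = q[2], q95 = q[4], q97.5 = q[5])
  }
  samples <- tibble::as_tibble(adj)
  samples$weight <- w
  structure(list(summary = dplyr::bind_rows(summ),
                 samples = samples,
                 scenario = as.integer(scenario),
                 n_retained = nrow(sub)),
            class = "abc_posterior")
}

#' @export
print.abc_posterior <- function(x, ...) {
  cat("ABC posterior, scenario", x$scenario, "(", x$n_retained, "retained draws )\n")
  print(as.data.frame(x$summary), digits = 4)
  invisible(x)
}

#' Posterior-predictive model checking with PCA
#'
#' Draws parameter vectors from the adjusted posterior sample (with its
#' weights), simulates new datasets under the chosen scenario, and compares
#' the observed statistics to the posterior-predictive cloud: a PCA is
#' fitted on the simulated statistics and the observed vector projected into
#' it, and each statistic gets a two-sided posterior-predictive tail
#' probability \eqn{2\min(P(sim \le obs), P(sim \ge obs))}; statistics with
#' tail probability below `alpha` are flagged.
#'
#' @param posterior An `abc_posterior`.
#' @param rejection The `abc_rejection` it came from (supplies the observed
#'   vector and simulation settings).
#' @param n_sim Number of posterior-predictive simulations.
#' @param alpha Flagging level (default 0.05).
#' @return An `abc_model_check`: per-statistic table, PCA scores of the
#'   cloud and of the observed point, and the observed point's distance rank
#'   within the cloud.
#' @export
model_check <- function(posterior, rejection, n_sim = 500, alpha = 0.05) {
  stopifnot(inherits(posterior, "abc_posterior"),
            inherits(rejection, "abc_rejection"), n_sim >= 2)
  obs <- attr(rejection, "observed")
  smp <- posterior$samples
  # the local-linear adjustment is marginal per parameter, so a handful of
  # adjusted draws can violate t1 < t2; those are excluded from resampling
  valid <- if (all(c("t1", "t2") %in% names(smp))) which(smp$t1 < smp$t2)
           else seq_len(nrow(smp))
  if (length(valid) < 2) stop("too few posterior draws satisfy t1 < t2")
  idx <- valid[sample.int(length(valid), n_sim, replace = TRUE,
                          prob = smp$weight[valid] / sum(smp$weight[valid]))]
  pcols <- c("N_LW", "N_ML", "N_HG", "t1", "t2", "r", "mu", "kappa")
  par <- matrix(0, n_sim, length(pcols), dimnames = list(NULL, pcols))
  for (p in pcols)
    par[, p] <- if (p %in% names(smp)) smp[[p]][idx] else
      if (p == "t1") smp$t2[idx] / 2 else 0.5  # unused by the scenario
  templates <- lapply(1:9, scenario_event_template)
  sims <- abc_batch_cpp(templates, rep(posterior$scenario, n_sim), par,
                        as.integer(attr(rejection, "sample_sizes")),
                        attr(rejection, "n_sites"),
                        attr(rejection, "base_freq"))
  colnames(sims) <- sumstat_names()
  tail_prob <- vapply(sumstat_names(), function(s) {
    lo <- mean(sims[, s] <= obs[s]); hi <- mean(sims[, s] >= obs[s])
    min(1, 2 * min(lo, hi))
  }, numeric(1))
  tab <- tibble::tibble(statistic = sumstat_names(),
                        observed = as.numeric(obs),
                        sim_mean = colMeans(sims),
                        tail_prob = tail_prob,
                        flagged = tail_prob < alpha)
  keep <- apply(sims, 2, sd) > 0
  pca <- prcomp(sims[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
  obs_sc <- predict(pca, newdata = t(obs[keep]))
  d_cloud <- sqrt(rowSums(sweep(pca$x, 2, colMeans(pca$x))^2))
  d_obs <- sqrt(sum((obs_sc - colMeans(pca$x))^2))
  structure(list(stats = tab,
                 pca_scores = pca$x,
                 observed_scores = obs_sc,
                 observed_rank = mean(d_cloud <= d_obs),
                 n_sim = n_sim, alpha = alpha,
                 scenario = posterior$scenario),
            class = "abc_model_check")
}

#' @export
print.abc_model_check <- function(x, ...) {
  nf <- sum(x$stats$flagged)
  cat("Posterior-predictive check, scenario ", x$scenario, ": ", nf, " of ",
      nrow(x$stats), " statistics flagged at alpha = ", x$alpha, "\n", sep = "")
  cat("Observed point's distance rank within the PC cloud: ",
      round(x$observed_rank, 3), "\n", sep = "")
  if (nf > 0) print(as.data.frame(x$stats[x$stats$flagged, ]), digits = 3)
  invisible(x)
}

#' Convert generations to years
#'
#' Divides a time in generations by the number of generations per year and
#' rounds half-up to the nearest year. The mite completes an estimated 8
#' (minimum) to 16 (maximum) generations per year, so a generation-scale
#' time maps to a year range.
#'
#' @param g Time in generations, >= 0 (vectorized).
#' @param generations_per_year Generations per year, > 0; 8 or 16 in the
#'   study system.
#' @return Years, rounded half-up.
#' @export
#' @examples
#' generations_to_years(87900, 16)   # 5494
#' generations_to_years(320000, 8)   # 40000
generations_to_years <- function(g, generations_per_year) {
  stopifnot(all(g >= 0))
  if (any(generations_per_year <= 0)) stop("generations_per_year must be positive")
  floor(g / generations_per_year + 0.5)
}
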