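test_that("reference tables are reproducible and carry finite statistics", {
  r1 <- build_reference_table(c(2, 9), n_per_scenario = 30, seed = 41,
                              n_sites = 100)
  r2 <- build_reference_table(c(2, 9), n_per_scenario = 30, seed = 41,
                              n_sites = 100)
  expect_equal(as.data.frame(r1), as.data.frame(r2))
  expect_true(all(is.finite(as.matrix(r1[, sumstat_names()]))))
  expect_equal(nrow(r1), 60)
  r3 <- build_reference_table(5, n_per_scenario = 1, seed = 1, n_sites = 50)
  expect_equal(nrow(r3), 1)
})

test_that("drawn parameters pass through their priors (KS)", {
  ref <- build_reference_table(9, n_per_scenario = 1000, seed = 42,
                               n_sites = 30)
  p <- default_priors()
  for (par in c("t2", "N_ML", "mu")) {
    b <- p[p$parameter == par, ]
    ks <- suppressWarnings(stats::ks.test(ref[[par]], "punif", b$lower, b$upper))
    expect_gt(ks$p.value, 0.001)
  }
})

test_that("rejection retains the distance-closest rows with kernel weights", {
  set.seed(43)
  ref <- fake_reftable(list(`2` = function() rnorm(33),
                            `9` = function() rnorm(33, 2)), n_each = 50)
  obs <- setNames(rep(0, 33), sumstat_names())
  rej <- abc_reject(ref, obs, tol = 1)
  expect_equal(nrow(rej), 100)  # tol = 1 keeps everything
  # brute-force check of the retained set at tol = 0.2
  sm <- as.matrix(ref[, sumstat_names()])
  sc <- apply(sm, 2, mad)
  sc[sc == 0] <- apply(sm[, sc == 0, drop = FALSE], 2, sd)
  dd <- sqrt(colSums(((t(sm) - obs) / sc)^2))
  rej2 <- abc_reject(ref, obs, tol = 0.2)
  expect_equal(sort(rej2$dist), sort(dd)[1:20], tolerance = 1e-12)
  expect_true(all(diff(rej2$weight[order(rej2$dist)]) <= 0))
})

test_that("a row equal to the observed vector gets distance 0 and top weight", {
  set.seed(44)
  ref <- fake_reftable(list(`2` = function() rnorm(33),
                            `9` = function() rnorm(33)), n_each = 40)
  obs <- unlist(ref[17, sumstat_names()])
  rej <- abc_reject(ref, obs, tol = 0.5)
  expect_equal(min(rej$dist), 0)
  expect_equal(rej$weight[which.min(rej$dist)], max(rej$weight))
})

test_that("underpowered retention is an error", {
  set.seed(45)
  ref <- fake_reftable(list(`1` = function() rnorm(33),
                            `2` = function() rnorm(33),
                            `3` = function() rnorm(33)), n_each = 50)
  obs <- setNames(rep(0, 33), sumstat_names())
  expect_error(abc_reject(ref, obs, tol = 0.01), "fewer retained rows")
})

test_that("model choice recognises an overwhelmingly closer scenario", {
  set.seed(46)
  ref <- fake_reftable(list(`2` = function() rnorm(33, 0, 0.5),
                            `9` = function() rnorm(33, 6, 0.5)),
                       n_each = 300)
  obs <- setNames(rep(0, 33), sumstat_names())
  rej <- abc_reject(ref, obs, tol = 1)
  ch <- choose_model(rej)
  pr <- ch$probabilities
  expect_gt(pr$posterior_prob[pr$scenario == 2], 0.99)
  expect_equal(sum(pr$posterior_prob), 1, tolerance = 1e-6)
  expect_true(all(pr$conf_low <= pr$posterior_prob + 1e-12 &
                  pr$posterior_prob <= pr$conf_high + 1e-12))
})

test_that("indistinguishable scenarios get symmetric probabilities", {
  set.seed(47)
  gen <- function() rnorm(33, 0, 1)
  ref <- fake_reftable(list(`1` = gen, `5` = gen), n_each = 400)
  obs <- setNames(rep(0, 33), sumstat_names())
  ch <- choose_model(abc_reject(ref, obs, tol = 0.5))
  expect_lt(max(abs(ch$probabilities$posterior_prob - 0.5)), 0.15)
})

test_that("logistic and direct-rejection rankings agree when well separated", {
  set.seed(48)
  ref <- fake_reftable(list(`1` = function() rnorm(33, 0, 1),
                            `2` = function() rnorm(33, 0.3, 1),
                            `3` = function() rnorm(33, 0.6, 1)), n_each = 300)
  obs <- setNames(rep(0, 33), sumstat_names())
  rej <- abc_reject(ref, obs, tol = 0.5)
  ch <- choose_model(rej)
  freq <- table(factor(rej$scenario, levels = c(1, 2, 3)))
  expect_equal(order(-ch$probabilities$posterior_prob), order(-as.numeric(freq)))
})

test_that("probabilities are invariant to rescaling a statistic column", {
  set.seed(49)
  ref <- build_reference_table(c(2, 9), n_per_scenario = 400, seed = 50,
                               n_sites = 100)
  obs <- unlist(ref[5, sumstat_names()])
  p1 <- choose_model(abc_reject(ref, obs, tol = 0.1))$probabilities
  ref2 <- ref
  ref2$LW_pi_mean <- ref2$LW_pi_mean * 1000
  obs2 <- obs
  obs2["LW_pi_mean"] <- obs2["LW_pi_mean"] * 1000
  p2 <- choose_model(abc_reject(ref2, obs2, tol = 0.1))$probabilities
  expect_equal(p1$posterior_prob, p2$posterior_prob, tolerance = 1e-6)
})

test_that("probabilities are invariant to duplicating the reference table", {
  set.seed(50)
  ref <- build_reference_table(c(2, 9), n_per_scenario = 300, seed = 51,
                               n_sites = 80)
  obs <- unlist(ref[7, sumstat_names()])
  dup <- dplyr::bind_rows(ref, ref)
  class(dup) <- class(ref)
  for (a in c("priors", "sample_sizes", "n_sites", "base_freq"))
    attr(dup, a) <- attr(ref, a)
  p1 <- choose_model(abc_reject(ref, obs, tol = 0.1))$probabilities
  p2 <- choose_model(abc_reject(dup, obs, tol = 0.1))$probabilities
  expect_equal(p1$posterior_prob, p2$posterior_prob, tolerance = 0.02)
})

test_that("posterior summaries are ordered and inside the prior box", {
  set.seed(52)
  ref <- build_reference_table(2, n_per_scenario = 3000, seed = 53,
                               n_sites = 200)
  syn <- make_sequence_dataset(study_shape(n_sites = 200), seed = 54)
  rej <- abc_reject(ref, summarize_alignment(syn$alignment), tol = 0.1)
  post <- estimate_parameters(rej, 2)
  s <- post$summary
  expect_true(all(s$q2.5 <= s$q5 & s$q5 <= s$median &
                  s$median <= s$q95 & s$q95 <= s$q97.5))
  p <- default_priors()
  for (i in seq_len(nrow(s))) {
    b <- p[p$parameter == s$parameter[i], ]
    expect_true(s$mode[i] >= b$lower && s$mode[i] <= b$upper)
    expect_true(all(post$samples[[s$parameter[i]]] >= b$lower &
                    post$samples[[s$parameter[i]]] <= b$upper))
  }
  expect_error(estimate_parameters(rej, 2, min_rows = 1e6), "need >=")
})

test_that("weighted quantiles follow the weighted empirical CDF", {
  x <- c(1, 2, 3, 4)
  w <- c(10, 1, 1, 10)
  expect_equal(acariabc:::wquantile(x, w, c(0.05, 0.5, 0.99)), c(1, 2, 4))
})

test_that("model check flags a far-outlying observation and not a typical one", {
  set.seed(55)
  ref <- build_reference_table(2, n_per_scenario = 2000, seed = 56,
                               n_sites = 150)
  syn <- make_sequence_dataset(study_shape(n_sites = 150), seed = 57)
  obs <- summarize_alignment(syn$alignment)
  rej <- abc_reject(ref, obs, tol = 0.1)
  post <- estimate_parameters(rej, 2)
  chk <- model_check(post, rej, n_sim = 300)
  expect_s3_class(chk, "abc_model_check")
  expect_lt(sum(chk$stats$flagged), 10)  # typical data: few flags
  expect_true(chk$observed_rank < 1)
  # push one statistic far outside the cloud
  obs_far <- unlist(obs)
  obs_far["LW_pi_mean"] <- obs_far["LW_pi_mean"] + 1e4
  rej2 <- rej
  attr(rej2, "observed") <- obs_far
  chk2 <- model_check(post, rej2, n_sim = 300)
  expect_true(chk2$stats$flagged[chk2$stats$statistic == "LW_pi_mean"])
})

test_that("generation-to-year conversion rounds half-up", {
  expect_equal(generations_to_years(87900, 16), 5494)
  expect_equal(generations_to_years(0, 8), 0)
  expect_equal(generations_to_years(12, 8), 2)      # 1.5 rounds up
  expect_equal(generations_to_years(c(8, 20), 8), c(1, 3))  # vectorized
  expect_error(generations_to_years(10, 0), "positive")
})

test_that("tidy and glance expose the fitted objects as tibbles", {
  set.seed(58)
  ref <- fake_reftable(list(`2` = function() rnorm(33, 0, 0.5),
                            `9` = function() rnorm(33, 3, 0.5)), n_each = 200)
  obs <- setNames(rep(0, 33), sumstat_names())
  rej <- abc_reject(ref, obs, tol = 1)
  ch <- choose_model(rej)
  expect_named(tidy(ch), c("scenario", "posterior_prob", "conf_low", "conf_high"))
  expect_equal(glance(ch)$best_scenario, 2)
  post <- estimate_parameters(rej, 2)
  expect_true(all(c("parameter", "mean", "median", "mode") %in% names(tidy(post))))
  expect_equal(glance(post)$scenario, 2)
})
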