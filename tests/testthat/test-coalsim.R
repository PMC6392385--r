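single_deme_spec <- function(N) {
  build_scenario(9, list(N_LW = N, N_ML = N, N_HG = N, t2 = 1e-9))
}

test_that("pairwise coalescence time matches the analytic haploid expectation", {
  set.seed(21)
  N <- 1000
  spec <- single_deme_spec(N)
  tm <- replicate(10000, max(simulate_genealogy(spec, c(ML = 2))$node_time))
  # E[T2] = N, SD[T2] = N for the exponential waiting time
  expect_lt(abs(mean(tm) - N), 3 * N / sqrt(10000))
})

test_that("TMRCA of a two-deme split model matches the closed form (KS)", {
  set.seed(22)
  N <- 500; t2 <- 300
  spec <- build_scenario(9, list(N_LW = 2000, N_ML = N, N_HG = 2000, t2 = t2))
  tm <- replicate(10000,
    max(simulate_genealogy(spec, c(LW = 1, ML = 1))$node_time))
  # one lineage per deme: no coalescence before t2, then Exp(1/N) in ML
  expect_true(all(tm > t2))
  ks <- suppressWarnings(stats::ks.test(tm - t2, "pexp", 1 / N))
  expect_gt(ks$p.value, 0.001)
})

test_that("degenerate event times reduce scenario 2 to a single panmictic deme", {
  set.seed(23)
  N <- 800
  sp2 <- build_scenario(2, list(N_LW = N, N_ML = N, N_HG = N,
                                t1 = 1e-9, t2 = 2e-9))
  sp9 <- single_deme_spec(N)
  t_a <- replicate(2000, max(simulate_genealogy(sp2, c(LW = 2, ML = 2, HG = 2))$node_time))
  t_b <- replicate(2000, max(simulate_genealogy(sp9, c(LW = 2, ML = 2, HG = 2))$node_time))
  ks <- suppressWarnings(stats::ks.test(t_a, t_b))
  expect_gt(ks$p.value, 0.001)
})

test_that("admixture fraction r = 1 sends every ML lineage to the LW side", {
  set.seed(24)
  # with r = 1 both sampled ML lineages join the huge LW deme and coalesce
  # slowly; with r ~ 0 they join the tiny HG deme and coalesce almost at t1
  base <- list(N_LW = 1e7, N_ML = 1e7, N_HG = 10, t1 = 50, t2 = 1e8)
  tm_r1 <- replicate(200, {
    spec <- build_scenario(7, c(base, r = 1))
    max(simulate_genealogy(spec, c(ML = 2))$node_time)
  })
  tm_r0 <- replicate(200, {
    spec <- build_scenario(7, c(base, r = 1e-6))
    max(simulate_genealogy(spec, c(ML = 2))$node_time)
  })
  expect_lt(max(tm_r0), 5000)
  expect_gt(mean(tm_r1), 1000 * mean(tm_r0))
})

test_that("genealogies convert to valid ape trees with generation branch lengths", {
  set.seed(25)
  spec <- build_scenario(2, list(N_LW = 100, N_ML = 100, N_HG = 100,
                                 t1 = 50, t2 = 500))
  g <- simulate_genealogy(spec, c(LW = 4, ML = 5, HG = 6))
  tr <- ape::as.phylo(g)
  expect_s3_class(tr, "phylo")
  expect_equal(ape::Ntip(tr), 15)
  expect_true(ape::is.rooted(tr))
  expect_true(all(tr$edge.length >= 0))
  # tip depths equal the TMRCA since all tips are sampled at time 0
  depths <- ape::node.depth.edgelength(tr)[seq_len(15)]
  expect_equal(max(abs(depths - max(g$node_time))), 0, tolerance = 1e-9)
  expect_match(ape::write.tree(tr), "^\\(")
})

test_that("a zero mutation rate yields identical sequences", {
  set.seed(26)
  g <- simulate_genealogy(single_deme_spec(1000), c(LW = 3, ML = 3, HG = 3))
  aln <- evolve_sequences(g, mutation_model(0, 2, n_sites = 50))
  expect_equal(n_haplotypes(aln), 1)
  expect_true(all(aln$seqs %in% c("A", "C", "G", "T")))
})

test_that("branch substitution process matches an eigendecomposition oracle", {
  set.seed(27)
  pi <- c(0.35, 0.15, 0.2, 0.3)
  kappa <- 3; d <- 0.3
  g <- two_tip_genealogy(height = 1)
  aln <- evolve_sequences(g, mutation_model(mu = d, kappa = kappa,
                                            base_freq = pi, n_sites = 2e5))
  P <- hky_pmat_oracle(d, kappa, pi)
  J_exp <- t(P) %*% diag(pi) %*% P  # joint distribution of the two tips
  J_obs <- table(factor(aln$seqs[1, ], levels = DNA4),
                 factor(aln$seqs[2, ], levels = DNA4)) / 2e5
  expect_lt(max(abs(J_obs - J_exp)), 0.005)
})

test_that("kappa = 1 with equal frequencies reduces to Jukes-Cantor", {
  set.seed(28)
  d <- 0.4
  g <- two_tip_genealogy(height = 1)
  aln <- evolve_sequences(g, mutation_model(mu = d, kappa = 1, n_sites = 1e5))
  # total tip-tip distance 2d; JC identity = 1/4 + 3/4 exp(-8d/3)
  p_same_exp <- 0.25 + 0.75 * exp(-8 * d / 3)
  p_same_obs <- mean(aln$seqs[1, ] == aln$seqs[2, ])
  expect_lt(abs(p_same_obs - p_same_exp), 0.006)
  # and all 12 ordered mismatch pairs are equally likely
  mm <- aln$seqs[, aln$seqs[1, ] != aln$seqs[2, ], drop = FALSE]
  pairs <- table(paste0(mm[1, ], mm[2, ]))
  expect_equal(length(pairs), 12)
  expect_lt(max(abs(pairs / sum(pairs) - 1 / 12)), 0.01)
})

test_that("saturated branches approach stationary homozygosity", {
  set.seed(29)
  pi <- c(0.4, 0.3, 0.2, 0.1)
  g <- two_tip_genealogy(height = 1)
  aln <- evolve_sequences(g, mutation_model(mu = 50, kappa = 2,
                                            base_freq = pi, n_sites = 1e5))
  expect_lt(abs(mean(aln$seqs[1, ] == aln$seqs[2, ]) - sum(pi^2)), 0.007)
})

test_that("single-deme diversity matches the haploid theta expectation", {
  set.seed(30)
  N <- 1000; mu <- 1e-6; L <- 618
  spec <- single_deme_spec(N)
  mm <- mutation_model(mu, 2, n_sites = L)
  pis <- replicate(1000, {
    g <- simulate_genealogy(spec, c(ML = 10))
    pairwise_diff_moments(evolve_sequences(g, mm)$seqs)[["mean"]]
  })
  expect_lt(abs(mean(pis) - 2 * N * mu * L), 3 * sd(pis) / sqrt(1000))
})

test_that("mutation model constructor validates its inputs", {
  expect_error(mutation_model(1e-8, 0), "kappa > 0")
  expect_error(mutation_model(1e-8, 1, base_freq = c(0.5, 0.5, 0.2, 0.1)),
               "sum to 1")
  expect_s3_class(mutation_model(1e-8, 1.5), "mutation_model")
})
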