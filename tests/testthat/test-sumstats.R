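test_that("haplotype and segregating-site counts match their definitions", {
  m <- str_rows("ACGT", "ACGA", "ACGT")
  rownames(m) <- paste0("s", 1:3)
  expect_equal(n_haplotypes(m), 2)
  expect_equal(n_haplotypes(m[c(1, 1, 1), , drop = FALSE]), 1)
  expect_equal(segregating_sites(str_rows("AAAA", "AAAT")), 1)
  expect_equal(segregating_sites(str_rows("AAAA", "AAAA")), 0)
})

test_that("pairwise difference moments match hand enumeration", {
  expect_equal(pairwise_diff_moments(str_rows("AAA", "ATT")),
               c(mean = 2, variance = 0))
  # {AA, AT, TT}: diffs 1, 2, 1
  expect_equal(pairwise_diff_moments(str_rows("AA", "AT", "TT")),
               c(mean = 4 / 3, variance = 2 / 9))
})

test_that("Tajima's D matches the direct-formula oracle and conventions", {
  expect_equal(tajimas_d(str_rows("AAAA", "AAAA")), 0)
  m <- str_rows("AAAA", "AAAA", "AAAT", "AATT")
  expect_equal(tajimas_d(m), bf_tajimas_d(m), tolerance = 1e-12)
  expect_equal(tajimas_d(m), 0.591584, tolerance = 1e-5)
})

test_that("private segregating sites follow the stated definition", {
  focal <- str_rows("AA", "AT")
  others <- str_rows("AA", "AA", "AA")
  expect_equal(private_segregating_sites(focal, others), 1)
  expect_equal(private_segregating_sites(str_rows("AA", "AA"), others), 0)
  # segregating in focal but polymorphic elsewhere is not private
  expect_equal(private_segregating_sites(focal, str_rows("AA", "AT")), 0)
})

test_that("rarest-nucleotide mean handles ties and fixed sites", {
  expect_equal(mean_rarest_nucleotide_count(str_rows("AA", "AA")), 0)
  expect_equal(mean_rarest_nucleotide_count(str_rows("A", "A", "A", "T")), 1)
  # two segregating sites with minority counts 2 and 1
  m <- str_rows("AC", "AG", "TG", "TG", "TG")
  expect_equal(mean_rarest_nucleotide_count(m), 1.5)
})

test_that("HSM FST hits its boundary cases", {
  a <- str_rows("AAAA", "AAAA")
  b <- str_rows("TTAA", "TTAA")
  expect_equal(fst_hsm(a, b), 1)
  expect_equal(fst_hsm(a, a), 0)
})

test_that("pooled pair statistics equal one-sample statistics on the union", {
  a <- str_rows("AAAA", "AATA")
  b <- str_rows("CAAA", "CAAA")
  ps <- pooled_pair_stats(a, b)
  u <- rbind(a, b)
  expect_equal(ps[["haplotypes"]], n_haplotypes(u))
  expect_equal(ps[["segregating_sites"]], segregating_sites(u))
  expect_equal(ps[["mean_pairwise_diff"]], pairwise_diff_moments(u)[["mean"]])
  # duplicating a group leaves the haplotype count unchanged
  expect_equal(pooled_pair_stats(a, a)[["haplotypes"]], n_haplotypes(a))
})

test_that("every statistic matches brute force on random alignments", {
  set.seed(31)
  for (rep in 1:5) {
    m <- random_alignment(20, 100)
    expect_equal(n_haplotypes(m), bf_n_hap(m))
    expect_equal(segregating_sites(m), bf_segregating(m))
    d <- bf_pair_diffs(m)
    expect_equal(pairwise_diff_moments(m),
                 c(mean = mean(d), variance = mean(d^2) - mean(d)^2))
    expect_equal(tajimas_d(m), bf_tajimas_d(m), tolerance = 1e-12)
    expect_equal(mean_rarest_nucleotide_count(m), bf_rarest(m))
    expect_equal(parsimony_informative_sites(m), bf_parsimony_informative(m))
    a <- m[1:8, ]; b <- m[9:20, ]
    expect_equal(fst_hsm(a, b), bf_fst(a, b), tolerance = 1e-12)
    expect_equal(private_segregating_sites(a, b), bf_private(a, b))
  }
})

test_that("missing and ambiguous characters are excluded site-wise", {
  set.seed(32)
  m <- random_alignment(12, 60, p_missing = 0.1)
  expect_equal(segregating_sites(m), bf_segregating(m))
  d <- bf_pair_diffs(m)
  expect_equal(pairwise_diff_moments(m)[["mean"]], mean(d))
  expect_equal(parsimony_informative_sites(m), bf_parsimony_informative(m))
  expect_equal(mean_rarest_nucleotide_count(m), bf_rarest(m))
})

test_that("the full statistic vector matches frozen hand-computed values", {
  aln <- make_aln(str_rows("AAAAAAAA", "AAAAAAAT"),
                  str_rows("AAAACAAA", "AAAACAAT"),
                  str_rows("GGAACAAA", "GGAACAAA"))
  s <- summarize_alignment(aln)
  expect_equal(names(s), sumstat_names())
  expect_equal(unname(unlist(s[1, c("LW_nhap", "LW_segsites", "LW_pi_mean",
                                    "LW_pi_var", "LW_tajd", "LW_private",
                                    "LW_rarest")])),
               c(2, 1, 1, 0, 0, 0, 1))
  expect_equal(unname(unlist(s[1, c("ML_nhap", "ML_segsites", "ML_pi_mean",
                                    "ML_tajd", "ML_private", "ML_rarest")])),
               c(2, 1, 1, 0, 0, 1))
  expect_equal(unname(unlist(s[1, c("HG_nhap", "HG_segsites", "HG_pi_mean",
                                    "HG_pi_var", "HG_tajd", "HG_private",
                                    "HG_rarest")])),
               c(1, 0, 0, 0, 0, 0, 0))
  expect_equal(unname(unlist(s[1, c("LW_ML_nhap", "LW_ML_segsites")])), c(4, 2))
  expect_equal(s$LW_ML_pi_mean, 8 / 6)
  expect_equal(s$LW_ML_fst, 1 / 3)
  expect_equal(unname(unlist(s[1, c("LW_HG_nhap", "LW_HG_segsites")])), c(3, 4))
  expect_equal(s$LW_HG_pi_mean, 2.5)
  expect_equal(s$LW_HG_fst, 6 / 7)
  expect_equal(unname(unlist(s[1, c("ML_HG_nhap", "ML_HG_segsites")])), c(3, 3))
  expect_equal(s$ML_HG_pi_mean, 11 / 6)
  expect_equal(s$ML_HG_fst, 0.8)
  expect_equal(parsimony_informative_sites(rbind(
    acariabc:::form_rows(aln, c("LW", "ML", "HG")))), 4)
})

test_that("statistics are invariant to row order within groups", {
  set.seed(33)
  syn <- make_sequence_dataset(study_shape(n_sites = 120), seed = 7)
  aln <- syn$alignment
  s1 <- summarize_alignment(aln)
  perm <- unlist(tapply(seq_len(41), aln$labels$form, sample), use.names = FALSE)
  aln2 <- labeled_alignment(aln$seqs[perm, ], aln$labels[perm, ])
  expect_equal(summarize_alignment(aln2), s1)
})

test_that("compiled batch statistics agree with the R implementations", {
  set.seed(34)
  syn <- make_sequence_dataset(study_shape(), seed = 19)
  aln <- syn$alignment
  m <- matrix(match(aln$seqs, DNA4) - 1L, nrow = nrow(aln$seqs))
  cpp <- acariabc:::sumstats_cpp(m, c(10L, 13L, 18L))
  expect_equal(as.numeric(cpp), as.numeric(unlist(summarize_alignment(aln))),
               tolerance = 1e-12)
})

test_that("identical alignments give all-zero diversity statistics", {
  aln <- make_aln(str_rows("ACGT", "ACGT"), str_rows("ACGT", "ACGT"),
                  str_rows("ACGT", "ACGT"))
  s <- unlist(summarize_alignment(aln))
  expect_true(all(s[grep("nhap", names(s))] == 1 |
                  names(s)[grep("nhap", names(s))] %in% ""))
  expect_true(all(s[grep("segsites|pi_|tajd|private|rarest|fst", names(s))] == 0))
})

test_that("parsimony-informative definition separates the textbook cases", {
  expect_equal(parsimony_informative_sites(str_rows("A", "A", "C", "C")), 1)
  expect_equal(parsimony_informative_sites(str_rows("A", "A", "A", "C")), 0)
  expect_equal(parsimony_informative_sites(str_rows("AAAA", "AAAA", "AAAA",
                                                    "AAAA")), 0)
  expect_error(parsimony_informative_sites(str_rows("AA", "AA")), "at least 4")
})
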