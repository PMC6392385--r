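# Summary statistics of the ABC analysis. All operate on character matrices
# of aligned sequences (rows = haploid individuals); any character outside
# A/C/G/T counts as missing: pairwise differences are taken over sites where
# both rows are unambiguous, and a site's states are the unambiguous ones.

BASES <- c("A", "C", "G", "T")

as_base_matrix <- function(x) {
  if (inherits(x, "labeled_alignment")) x <- x$seqs
  stopifnot(is.matrix(x), is.character(x))
  toupper(x)
}

# per-site counts of the four bases, sites in columns
site_base_counts <- function(m) {
  out <- vapply(BASES, function(b) colSums(m == b), numeric(ncol(m)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1, dimnames = list(NULL, BASES))
  out
}

#' Number of distinct haplotypes
#'
#' @param x Character matrix of aligned sequences (or a `labeled_alignment`).
#' @return Integer count of distinct row strings (missing characters are
#'   compared literally).
#' @export
n_haplotypes <- function(x) {
  m <- as_base_matrix(x)
  if (nrow(m) < 1) stop("alignment subset is empty")
  length(unique(apply(m, 1, paste, collapse = "")))
}

#' Number of segregating sites
#'
#' A site segregates if it carries at least two distinct unambiguous bases.
#'
#' @inheritParams n_haplotypes
#' @export
segregating_sites <- function(x) {
  m <- as_base_matrix(x)
  if (nrow(m) < 2) stop("need at least 2 sequences")
  cnt <- site_base_counts(m)
  sum(rowSums(cnt > 0) >= 2)
}

# all unordered pairwise difference counts
pairwise_diffs <- function(m) {
  n <- nrow(m)
  ok <- matrix(m %in% BASES, nrow = n)
  out <- numeric(n * (n - 1) / 2)
  k <- 1
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      both <- ok[i, ] & ok[j, ]
      out[k] <- sum(m[i, both] != m[j, both])
      k <- k + 1
    }
  }
  out
}

#' Mean and variance of pairwise differences
#'
#' Over all unordered pairs of sequences, the number of differing
#' (mutually unambiguous) sites; the variance is the population variance
#' with the number of pairs as denominator.
#'
#' @inheritParams n_haplotypes
#' @return Named numeric vector `c(mean = , variance = )`.
#' @export
pairwise_diff_moments <- function(x) {
  m <- as_base_matrix(x)
  if (nrow(m) < 2) stop("need at least 2 sequences")
  d <- pairwise_diffs(m)
  c(mean = mean(d), variance = mean(d^2) - mean(d)^2)
}

#' Tajima's D
#'
#' The standard normalized difference between the pairwise-diversity and
#' segregating-sites estimators of theta,
#' \eqn{D = (\pi - S/a_1)/\sqrt{e_1 S + e_2 S(S-1)}}, with the usual
#' constants in the sample size. Returns 0 when there are no segregating
#' sites, so downstream ABC distances are always defined.
#'
#' @inheritParams n_haplotypes
#' @export
tajimas_d <- function(x) {
  m <- as_base_matrix(x)
  n <- nrow(m)
  if (n < 2) stop("need at least 2 sequences")
  S <- segregating_sites(m)
  if (S == 0) return(0)
  pi_mean <- pairwise_diff_moments(m)[["mean"]]
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  den <- sqrt(e1 * S + e2 * S * (S - 1))
  if (den <= 0) return(0)
  (pi_mean - S / a1) / den
}

#' Number of private segregating sites
#'
#' Sites segregating within the focal group while monomorphic (at most one
#' unambiguous state) across the union of all other groups.
#'
#' @param focal Character matrix for the focal group.
#' @param others Character matrix for the union of the remaining groups.
#' @export
private_segregating_sites <- function(focal, others) {
  mf <- as_base_matrix(focal)
  mo <- as_base_matrix(others)
  stopifnot(ncol(mf) == ncol(mo))
  segf <- rowSums(site_base_counts(mf) > 0) >= 2
  mono <- rowSums(site_base_counts(mo) > 0) <= 1
  sum(segf & mono)
}

#' Mean count of the rarest nucleotide at segregating sites
#'
#' At each segregating site, the count of the least frequent observed base
#' (ties resolve to the shared minimum count); averaged over segregating
#' sites, 0 when none segregate.
#'
#' @inheritParams n_haplotypes
#' @export
mean_rarest_nucleotide_count <- function(x) {
  m <- as_base_matrix(x)
  if (nrow(m) < 2) stop("need at least 2 sequences")
  cnt <- site_base_counts(m)
  seg <- rowSums(cnt > 0) >= 2
  if (!any(seg)) return(0)
  mins <- apply(cnt[seg, , drop = FALSE], 1, function(z) min(z[z > 0]))
  mean(mins)
}

#' Hudson--Slatkin--Maddison FST between two groups
#'
#' \eqn{F_{ST} = 1 - H_w/H_b} with \eqn{H_w} the average of the two
#' within-group mean pairwise differences and \eqn{H_b} the mean pairwise
#' difference between groups. Returns 0 when \eqn{H_b = 0}; negative values
#' are retained.
#'
#' @param a,b Character matrices, one per group, each with at least 2 rows.
#' @export
fst_hsm <- function(a, b) {
  ma <- as_base_matrix(a); mb <- as_base_matrix(b)
  if (nrow(ma) < 2 || nrow(mb) < 2) stop("each group needs at least 2 sequences")
  stopifnot(ncol(ma) == ncol(mb))
  hw <- (pairwise_diff_moments(ma)[["mean"]] + pairwise_diff_moments(mb)[["mean"]]) / 2
  okb <- matrix(mb %in% BASES, nrow = nrow(mb))
  oka <- matrix(ma %in% BASES, nrow = nrow(ma))
  tot <- 0
  for (i in seq_len(nrow(ma)))
    for (j in seq_len(nrow(mb))) {
      both <- oka[i, ] & okb[j, ]
      tot <- tot + sum(ma[i, both] != mb[j, both])
    }
  hb <- tot / (nrow(ma) * nrow(mb))
  if (hb <= 0) return(0)
  1 - hw / hb
}

#' One-sample statistics of a pooled pair of groups
#'
#' @param a,b Character matrices for the two groups.
#' @return Named vector: `haplotypes`, `segregating_sites`,
#'   `mean_pairwise_diff` of the pooled rows.
#' @export
pooled_pair_stats <- function(a, b) {
  m <- rbind(as_base_matrix(a), as_base_matrix(b))
  c(haplotypes = n_haplotypes(m),
    segregating_sites = segregating_sites(m),
    mean_pairwise_diff = pairwise_diff_moments(m)[["mean"]])
}

#' Canonical names of the 33 summary statistics
#'
#' Seven one-sample statistics for each form (LW, ML, HG) followed by four
#' two-sample statistics for each pair (LW-ML, LW-HG, ML-HG), in the fixed
#' order used by the reference table and all ABC steps.
#'
#' @return Character vector of length 33.
#' @export
sumstat_names <- function() {
  one <- c("nhap", "segsites", "pi_mean", "pi_var", "tajd", "private", "rarest")
  two <- c("nhap", "segsites", "pi_mean", "fst")
  c(as.vector(t(outer(FORMS, one, paste, sep = "_"))),
    paste0(rep(c("LW_ML", "LW_HG", "ML_HG"), each = 4), "_", rep(two, 3)))
}

#' Full DIYABC-style summary-statistic vector of a labeled alignment
#'
#' Computes, for each of the three form groups, the number of haplotypes,
#' number of segregating sites, mean and variance of pairwise differences,
#' Tajima's D, the number of private segregating sites and the mean count of
#' the rarest nucleotide at segregating sites; and for each pair of groups
#' the pooled haplotype/segregating-site counts, pooled mean pairwise
#' differences and Hudson--Slatkin--Maddison FST.
#'
#' @param aln A `labeled_alignment` whose labels cover the three forms
#'   LW, ML, HG with at least 2 sequences each.
#' @return A one-row tibble with the 33 columns of [sumstat_names()].
#' @export
summarize_alignment <- function(aln) {
  stopifnot(inherits(aln, "labeled_alignment"))
  groups <- lapply(FORMS, function(f) form_rows(aln, f))
  names(groups) <- FORMS
  if (any(vapply(groups, nrow, 1L) < 2))
    stop("each form group needs at least 2 sequences")
  out <- numeric(0)
  for (f in FORMS) {
    g <- groups[[f]]
    oth <- form_rows(aln, setdiff(FORMS, f))
    mom <- pairwise_diff_moments(g)
    out <- c(out, n_haplotypes(g), segregating_sites(g), mom[["mean"]],
             mom[["variance"]], tajimas_d(g),
             private_segregating_sites(g, oth),
             mean_rarest_nucleotide_count(g))
  }
  for (pr in list(c("LW", "ML"), c("LW", "HG"), c("ML", "HG"))) {
    ps <- pooled_pair_stats(groups[[pr[1]]], groups[[pr[2]]])
    out <- c(out, ps[["haplotypes"]], ps[["segregating_sites"]],
             ps[["mean_pairwise_diff"]],
             fst_hsm(groups[[pr[1]]], groups[[pr[2]]]))
  }
  names(out) <- sumstat_names()
  tibble::as_tibble(as.list(out))
}

#' Number of parsimony-informative sites
#'
#' Columns carrying at least two distinct unambiguous states, each present
#' in at least two sequences.
#'
#' @inheritParams n_haplotypes
#' @export
parsimony_informative_sites <- function(x) {
  m <- as_base_matrix(x)
  if (nrow(m) < 4) stop("need at least 4 sequences")
  cnt <- site_base_counts(m)
  sum(rowSums(cnt >= 2) >= 2)
}
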