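# Brute-force reference implementations of every summary statistic, written
# directly from the definitions with plain loops. They exist only to check
# the package's vectorized/compiled versions and share no code with them.

DNA4 <- c("A", "C", "G", "T")

random_alignment <- function(n, L, p_missing = 0, theta_like = 0.3) {
  # correlated-ish columns: most sites near-monomorphic, some variable
  m <- matrix("A", n, L)
  for (s in seq_len(L)) {
    if (runif(1) < theta_like) {
      bases <- sample(DNA4, 2)
      m[, s] <- sample(bases, n, replace = TRUE)
    } else {
      m[, s] <- sample(DNA4, 1)
    }
  }
  if (p_missing > 0) m[runif(length(m)) < p_missing] <- "-"
  rownames(m) <- paste0("seq", seq_len(n))
  m
}

bf_n_hap <- function(m) {
  uniq <- 0
  for (i in seq_len(nrow(m))) {
    new <- TRUE
    for (j in seq_len(i - 1)) if (all(m[i, ] == m[j, ])) { new <- FALSE; break }
    if (new) uniq <- uniq + 1
  }
  uniq
}

bf_segregating <- function(m) {
  count <- 0
  for (s in seq_len(ncol(m))) {
    states <- unique(m[m[, s] %in% DNA4, s])
    if (length(states) >= 2) count <- count + 1
  }
  count
}

bf_pair_diffs <- function(m) {
  out <- c()
  for (i in seq_len(nrow(m) - 1))
    for (j in (i + 1):nrow(m)) {
      d <- 0
      for (s in seq_len(ncol(m)))
        if (m[i, s] %in% DNA4 && m[j, s] %in% DNA4 && m[i, s] != m[j, s])
          d <- d + 1
      out <- c(out, d)
    }
  out
}

bf_tajimas_d <- function(m) {
  n <- nrow(m)
  S <- bf_segregating(m)
  if (S == 0) return(0)
  pim <- mean(bf_pair_diffs(m))
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (pim - S / a1) / sqrt((c1 / a1) * S + (c2 / (a1^2 + a2)) * S * (S - 1))
}

bf_private <- function(focal, others) {
  count <- 0
  for (s in seq_len(ncol(focal))) {
    sf <- unique(focal[focal[, s] %in% DNA4, s])
    so <- unique(others[others[, s] %in% DNA4, s])
    if (length(sf) >= 2 && length(so) <= 1) count <- count + 1
  }
  count
}

bf_rarest <- function(m) {
  vals <- c()
  for (s in seq_len(ncol(m))) {
    col <- m[m[, s] %in% DNA4, s]
    if (length(unique(col)) >= 2) vals <- c(vals, min(table(col)))
  }
  if (length(vals) == 0) 0 else mean(vals)
}

bf_fst <- function(a, b) {
  hw <- (mean(bf_pair_diffs(a)) + mean(bf_pair_diffs(b))) / 2
  tot <- 0
  for (i in seq_len(nrow(a)))
    for (j in seq_len(nrow(b))) {
      d <- 0
      for (s in seq_len(ncol(a)))
        if (a[i, s] %in% DNA4 && b[j, s] %in% DNA4 && a[i, s] != b[j, s])
          d <- d + 1
      tot <- tot + d
    }
  hb <- tot / (nrow(a) * nrow(b))
  if (hb <= 0) 0 else 1 - hw / hb
}

bf_parsimony_informative <- function(m) {
  count <- 0
  for (s in seq_len(ncol(m))) {
    tab <- table(m[m[, s] %in% DNA4, s])
    if (sum(tab >= 2) >= 2) count <- count + 1
  }
  count
}

# a labeled alignment from explicit per-form row blocks
make_aln <- function(lw, ml, hg) {
  m <- rbind(lw, ml, hg)
  ids <- c(paste0("LW", seq_len(nrow(lw))), paste0("ML", seq_len(nrow(ml))),
           paste0("HG", seq_len(nrow(hg))))
  rownames(m) <- ids
  labeled_alignment(m, tibble::tibble(
    id = ids, form = rep(c("LW", "ML", "HG"), c(nrow(lw), nrow(ml), nrow(hg)))))
}

str_rows <- function(...) {
  x <- c(...)
  do.call(rbind, lapply(x, function(s) strsplit(s, "")[[1]]))
}

# a hand-constructed reference table with given per-scenario stat generators
fake_reftable <- function(stats_by_scenario, n_each = 100) {
  rows <- list()
  for (k in seq_along(stats_by_scenario)) {
    sm <- t(replicate(n_each, stats_by_scenario[[k]]()))
    colnames(sm) <- sumstat_names()
    d <- sample_prior(default_priors(), 2, n = n_each)
    d$scenario <- as.integer(names(stats_by_scenario)[k])
    rows[[k]] <- dplyr::bind_cols(d, tibble::as_tibble(sm))
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("abc_reftable", class(out))
  attr(out, "priors") <- default_priors()
  attr(out, "sample_sizes") <- c(LW = 10, ML = 13, HG = 18)
  attr(out, "n_sites") <- 618L
  attr(out, "base_freq") <- rep(0.25, 4)
  out
}

# two-tip genealogy with a fixed divergence time, for mutation-model checks
two_tip_genealogy <- function(height) {
  structure(list(parent = c(2L, 2L, -1L),
                 node_time = c(0, 0, height),
                 n_tip = 2L,
                 sample_sizes = c(LW = 1, ML = 1, HG = 0),
                 tip_form = c("LW", "ML"),
                 tip_id = c("LW_1", "ML_1"),
                 scenario = NA_integer_),
            class = "genealogy")
}

# HKY transition matrix by numerical eigendecomposition of the rate matrix
# (independent of the closed form used in the simulator)
hky_pmat_oracle <- function(d, kappa, pi) {
  Q <- matrix(0, 4, 4, dimnames = list(DNA4, DNA4))
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    ts <- (DNA4[c(i, j)] %in% c("A", "G")) |> all() ||
          (DNA4[c(i, j)] %in% c("C", "T")) |> all()
    Q[i, j] <- if (ts) kappa * pi[j] else pi[j]
  }
  diag(Q) <- -rowSums(Q)
  Q <- Q / sum(-diag(Q) * pi)  # mean rate 1
  e <- eigen(Q %*% diag(rep(1, 4)))
  V <- e$vectors
  Re(V %*% diag(exp(e$values * d)) %*% solve(V))
}
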