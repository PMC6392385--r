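#' HKY85 mutation model
#'
#' Container for the nucleotide substitution model used along simulated
#' genealogies: per-site per-generation rate `mu`, transition/transversion
#' coefficient `kappa` (the "coefficient k C/T"), stationary base frequencies
#' and alignment length.
#'
#' @param mu Per-site per-generation mutation rate, > 0 (a rate of exactly 0
#'   is allowed and yields invariant alignments, useful for checks).
#' @param kappa Transition/transversion coefficient, > 0. `kappa = 1` with
#'   equal frequencies reduces the model to Jukes--Cantor.
#' @param base_freq Stationary frequencies of A, C, G, T; must sum to 1.
#' @param n_sites Number of aligned sites.
#' @return An object of class `mutation_model`.
#' @export
#' @examples
#' mutation_model(mu = 8.7e-8, kappa = 1.67, n_sites = 618)
mutation_model <- function(mu, kappa, base_freq = rep(0.25, 4), n_sites = 618) {
  stopifnot(mu >= 0, kappa > 0, length(base_freq) == 4, n_sites >= 1)
  if (any(base_freq < 0) || abs(sum(base_freq) - 1) > 1e-9)
    stop("base_freq must be nonnegative and sum to 1")
  structure(list(mu = mu, kappa = kappa,
                 base_freq = as.numeric(base_freq),
                 n_sites = as.integer(n_sites)),
            class = "mutation_model")
}

#' Simulate a genealogy under a demographic scenario
#'
#' Runs the structured Kingman coalescent backward in time: within each
#' extant deme of haploid size N, k lineages coalesce at rate k(k-1)/(2N)
#' per generation; at a split event the source deme's lineages move to the
#' target deme; at an admixture event each source lineage is independently
#' reassigned to one of the two parental demes. Appropriate for maternally
#' inherited haploid loci such as mtCOI.
#'
#' @param spec A `scenario_spec` from [build_scenario()].
#' @param sample_sizes Named vector of sampled lineages per form; the study
#'   design is one sequence per sampled population, 10 LW + 13 ML + 18 HG.
#' @return An object of class `genealogy`: parent pointers, node times in
#'   generations (tips at 0), tip form labels, and tip ids of the form
#'   `LW_1, ..., HG_18`. Convert with [as.phylo.genealogy()] for Newick
#'   export.
#' @export
#' @examples
#' set.seed(1)
#' spec <- build_scenario(2, list(N_LW = 1e4, N_ML = 4e4, N_HG = 2e4,
#'                                t1 = 8e3, t2 = 3e4))
#' g <- simulate_genealogy(spec)
#' g$n_tip
simulate_genealogy <- function(spec, sample_sizes = c(LW = 10, ML = 13, HG = 18)) {
  stopifnot(inherits(spec, "scenario_spec"))
  ss <- sample_sizes[FORMS]
  ss[is.na(ss)] <- 0
  names(ss) <- FORMS
  if (any(ss < 0) || sum(ss) < 2)
    stop("sample_sizes must be nonnegative per form with at least 2 lineages total")
  res <- sim_genealogy_cpp(as.integer(ss), as.numeric(spec$sizes[FORMS]),
                           scenario_event_matrix(spec))
  tip_form <- rep(FORMS, times = ss)
  tip_id <- paste0(tip_form, "_", unlist(lapply(ss, seq_len)))
  structure(list(parent = res$parent, node_time = res$node_time,
                 n_tip = sum(ss), sample_sizes = ss,
                 tip_form = tip_form, tip_id = tip_id,
                 scenario = spec$id),
            class = "genealogy")
}

#' Convert a simulated genealogy to an ape phylo tree
#'
#' Branch lengths are in generations; tip labels are `{form}_{index}`.
#'
#' @param x A `genealogy`.
#' @param ... Unused.
#' @return An [ape::as.phylo] object.
#' @export
#' @method as.phylo genealogy
as.phylo.genealogy <- function(x, ...) {
  n <- x$n_tip
  nmax <- 2L * n - 1L
  root <- nmax  # 1-based id of the last-created node
  parent <- x$parent + 1L  # to 1-based; root has parent 0
  # ape convention: tips 1..n, root n+1, internals n+2..2n-1.
  # our internal ids (1-based) n+1..2n-1 were created oldest-last, root last.
  remap <- integer(nmax)
  remap[seq_len(n)] <- seq_len(n)
  remap[root] <- n + 1L
  others <- setdiff((n + 1L):nmax, root)
  remap[others] <- n + 1L + seq_along(others)
  edge <- cbind(remap[parent[-root]], remap[seq_len(nmax)[-root]])
  len <- (x$node_time[parent[-root]] - x$node_time[seq_len(nmax)[-root]])
  tr <- list(edge = edge, edge.length = len, tip.label = x$tip_id,
             Nnode = n - 1L)
  class(tr) <- "phylo"
  ape::reorder.phylo(tr, "cladewise")
}

#' @importFrom ape as.phylo
#' @export
ape::as.phylo

#' @export
print.genealogy <- function(x, ...) {
  cat("Coalescent genealogy:", x$n_tip, "tips (",
      paste(names(x$sample_sizes), x$sample_sizes, sep = "=", collapse = ", "),
      ")\n")
  cat("TMRCA:", format(max(x$node_time), big.mark = ","), "generations\n")
  invisible(x)
}

#' Evolve sequences along a genealogy under HKY
#'
#' The root sequence is drawn from the stationary base frequencies and each
#' site evolves independently down every branch using the exact closed-form
#' HKY transition probabilities for the elapsed expected substitutions
#' (`mu` times the branch length in generations).
#'
#' @param genealogy A `genealogy` from [simulate_genealogy()].
#' @param model A [mutation_model()].
#' @return A `labeled_alignment`: character matrix of bases (rows named by
#'   tip id) plus a label tibble mapping each sequence to its form.
#' @export
#' @examples
#' set.seed(1)
#' spec <- build_scenario(9, list(N_LW = 1e4, N_ML = 1e4, N_HG = 1e4, t2 = 1e4))
#' g <- simulate_genealogy(spec)
#' aln <- evolve_sequences(g, mutation_model(mu = 1e-6, kappa = 2, n_sites = 100))
#' dim(aln$seqs)
evolve_sequences <- function(genealogy, model) {
  stopifnot(inherits(genealogy, "genealogy"), inherits(model, "mutation_model"))
  m <- evolve_sequences_cpp(genealogy$parent, genealogy$node_time,
                            genealogy$n_tip, model$mu, model$kappa,
                            model$base_freq, model$n_sites)
  seqs <- matrix(c("A", "C", "G", "T")[m + 1L], nrow = nrow(m))
  rownames(seqs) <- genealogy$tip_id
  labeled_alignment(seqs, tibble::tibble(id = genealogy$tip_id,
                                         form = genealogy$tip_form))
}

#' Labeled alignment
#'
#' A multiple-sequence alignment of haploid sequences together with the
#' form-group label of each sequence. Bases are uppercase single characters;
#' anything outside A/C/G/T (gaps, IUPAC ambiguity) is retained and treated
#' as missing by the summary statistics.
#'
#' @param seqs Character matrix, rows = sequences (rownames are sequence
#'   ids), columns = aligned sites.
#' @param labels Tibble with columns `id` and `form` covering every row.
#' @return An object of class `labeled_alignment`.
#' @export
labeled_alignment <- function(seqs, labels) {
  stopifnot(is.matrix(seqs), is.character(seqs), !is.null(rownames(seqs)))
  labels <- tibble::as_tibble(labels)
  stopifnot(all(c("id", "form") %in% names(labels)))
  if (anyDuplicated(rownames(seqs))) stop("duplicate sequence ids in alignment")
  miss <- setdiff(rownames(seqs), labels$id)
  if (length(miss) > 0)
    stop("no form label for sequence id(s): ", paste(miss, collapse = ", "))
  labels <- labels[match(rownames(seqs), labels$id), ]
  seqs[] <- toupper(seqs)
  structure(list(seqs = seqs, labels = labels), class = "labeled_alignment")
}

#' @export
print.labeled_alignment <- function(x, ...) {
  cat("Labeled alignment:", nrow(x$seqs), "sequences x", ncol(x$seqs), "sites\n")
  print(table(x$labels$form))
  invisible(x)
}

# rows of the alignment belonging to one or more forms
form_rows <- function(aln, forms) {
  aln$seqs[aln$labels$form %in% forms, , drop = FALSE]
}
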