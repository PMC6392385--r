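# Study-shaped synthetic data: stand-ins for the GenBank mtCOI alignment and
# the morphometric table, generated under known truth so every stage of the
# pipeline can be exercised and checked end to end.

#' Study shape: the dimensions and truth of the synthetic datasets
#'
#' Captures the sampling design being emulated: 41 haploid mtCOI sequences
#' of 618 sites split 10/13/18 across the LW/ML/HG forms, generated under a
#' chosen scenario (default the supported scenario 2) at the posterior
#' medians of the real analysis (N_LW 97,500; N_ML 419,000; N_HG 180,000;
#' t1 87,900; t2 320,000 generations; mu 8.7e-8; kappa 1.67) -- posterior
#' medians used as a realistic anchor, not as ground truth of nature. The
#' morphometric block emulates three overlapping log-ratio distributions:
#' form means 0.20 / 0.25 / 0.33 (LW/ML/HG, natural-log leg I / leg III),
#' between-population SD 0.012, within-population SD 0.02, 11/13/18
#' populations and 8--22 males measured per population.
#'
#' @param sample_sizes Sequences per form.
#' @param n_sites Alignment length.
#' @param scenario Generating scenario id.
#' @param params Named list of true parameters (see [sample_prior()] names).
#' @param morph_pops Populations per form in the morph table.
#' @param morph_means,morph_pop_sd,morph_ind_sd Log-ratio distribution of
#'   the three forms.
#' @return A list of class `study_shape`.
#' @export
study_shape <- function(sample_sizes = c(LW = 10, ML = 13, HG = 18),
                        n_sites = 618,
                        scenario = 2,
                        params = list(N_LW = 97500, N_ML = 419000,
                                      N_HG = 180000, t1 = 87900, t2 = 320000,
                                      r = 0.5, mu = 8.7e-8, kappa = 1.67),
                        morph_pops = c(LW = 11, ML = 13, HG = 18),
                        morph_means = c(LW = 0.20, ML = 0.25, HG = 0.33),
                        morph_pop_sd = 0.012,
                        morph_ind_sd = 0.02) {
  stopifnot(all(sample_sizes > 0), n_sites > 0, scenario %in% 1:9,
            morph_pop_sd >= 0, morph_ind_sd >= 0)
  structure(list(sample_sizes = sample_sizes[FORMS],
                 n_sites = as.integer(n_sites),
                 scenario = as.integer(scenario),
                 params = params,
                 morph_pops = morph_pops[FORMS],
                 morph_means = morph_means[FORMS],
                 morph_pop_sd = morph_pop_sd,
                 morph_ind_sd = morph_ind_sd),
            class = "study_shape")
}

#' Generate a study-shaped synthetic sequence dataset
#'
#' Simulates one genealogy and alignment under the shape's scenario and true
#' parameters. When `dir` is given, writes `alignment.fasta`, a two-column
#' tab-separated `labels.tsv` (sequence id, form), and `truth.yml` recording
#' scenario, parameters and seed, sufficient to re-run any recovery
#' experiment.
#'
#' @param shape A [study_shape()].
#' @param seed Optional integer seed.
#' @param dir Optional output directory (created if needed).
#' @param base_freq HKY stationary frequencies.
#' @return List with `alignment` (a `labeled_alignment`) and `truth`.
#' @export
make_sequence_dataset <- function(shape = study_shape(), seed = NULL,
                                  dir = NULL, base_freq = rep(0.25, 4)) {
  stopifnot(inherits(shape, "study_shape"))
  if (!is.null(seed)) set.seed(seed)
  spec <- build_scenario(shape$scenario, shape$params)
  g <- simulate_genealogy(spec, shape$sample_sizes)
  aln <- evolve_sequences(g, mutation_model(shape$params$mu, shape$params$kappa,
                                            base_freq, shape$n_sites))
  truth <- list(scenario = shape$scenario, params = shape$params,
                sample_sizes = as.list(shape$sample_sizes),
                n_sites = shape$n_sites, seed = seed)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta_with_labels(aln, file.path(dir, "alignment.fasta"),
                            file.path(dir, "labels.tsv"))
    yaml::write_yaml(truth, file.path(dir, "truth.yml"))
  }
  list(alignment = aln, truth = truth)
}

#' Generate a study-shaped synthetic morphometric table
#'
#' Per population, draws leg III segment lengths around fixed baselines and
#' scales leg I so that each male's log leg-ratio is normal with the form's
#' mean (plus a population-level offset) and SD; the segment split of leg I
#' keeps the intended ratio exact. Returns the per-individual table and the
#' true form of every population.
#'
#' @inheritParams make_sequence_dataset
#' @param dir Optional directory; writes `morphometry.tsv` and
#'   `morph_truth.yml`.
#' @return List with `morph` (tibble, one row per male) and `truth_labels`
#'   (tibble population/form).
#' @export
make_morph_dataset <- function(shape = study_shape(), seed = NULL, dir = NULL) {
  stopifnot(inherits(shape, "study_shape"))
  if (!is.null(seed)) set.seed(seed)
  base3 <- c(tibia = 62, tarsus = 38, genu = 30, femur = 84)  # micrometers
  rows <- list()
  labs <- list()
  for (f in FORMS) {
    for (k in seq_len(shape$morph_pops[[f]])) {
      pop <- paste0(f, "pop", k)
      pop_mu <- stats::rnorm(1, shape$morph_means[[f]], shape$morph_pop_sd)
      n <- sample(8:22, 1)
      z <- stats::rnorm(n, pop_mu, shape$morph_ind_sd)
      leg3 <- vapply(base3, function(b) b * exp(stats::rnorm(n, 0, 0.04)),
                     numeric(n))
      tot3 <- rowSums(leg3)
      share <- vapply(base3, function(b) b * exp(stats::rnorm(n, 0, 0.04)),
                      numeric(n))
      share <- share / rowSums(share)
      leg1 <- share * tot3 * exp(z)
      rows[[pop]] <- tibble::tibble(
        population = pop, individual = seq_len(n),
        tibia_leg1 = leg1[, "tibia"], tarsus_leg1 = leg1[, "tarsus"],
        genu_leg1 = leg1[, "genu"], femur_leg1 = leg1[, "femur"],
        tibia_leg3 = leg3[, "tibia"], tarsus_leg3 = leg3[, "tarsus"],
        genu_leg3 = leg3[, "genu"], femur_leg3 = leg3[, "femur"])
      labs[[pop]] <- tibble::tibble(population = pop, form = f)
    }
  }
  morph <- dplyr::bind_rows(rows)
  truth <- dplyr::bind_rows(labs)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(morph, file.path(dir, "morphometry.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    yaml::write_yaml(list(labels = stats::setNames(as.list(truth$form),
                                                   truth$population),
                          seed = seed),
                     file.path(dir, "morph_truth.yml"))
  }
  list(morph = morph, truth_labels = truth)
}
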