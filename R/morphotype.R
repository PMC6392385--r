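# Male weapon-morph classification. Males fight with the enlarged first pair
# of legs; the ratio of total leg I length to total leg III length tracks
# male-male aggressiveness and separates the LW / ML / HG forms.

MORPH_SEGMENTS <- c("tibia", "tarsus", "genu", "femur")
MORPH_COLS <- c(paste0(MORPH_SEGMENTS, "_leg1"), paste0(MORPH_SEGMENTS, "_leg3"))

#' Weapon ratio per individual
#'
#' Adds the leg I / leg III ratio, computed from the totals of the four
#' measured segments (tibia, tarsus, genu, femur) of each leg.
#'
#' @param data Tibble with one row per measured male and the eight length
#'   columns `tibia_leg1 ... femur_leg1`, `tibia_leg3 ... femur_leg3`
#'   (micrometers, all > 0).
#' @return The input with an added `ratio` column.
#' @export
leg_ratio <- function(data) {
  data <- tibble::as_tibble(data)
  miss <- setdiff(MORPH_COLS, names(data))
  if (length(miss) > 0) stop("missing columns: ", paste(miss, collapse = ", "))
  lens <- as.matrix(data[, MORPH_COLS])
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("all segment lengths must be positive")
  leg1 <- rowSums(lens[, 1:4, drop = FALSE])
  leg3 <- rowSums(lens[, 5:8, drop = FALSE])
  dplyr::mutate(data, ratio = leg1 / leg3)
}

#' Population weapon-morph score
#'
#' The population average of the natural-log-transformed leg I / leg III
#' ratio, the quantity clustered to assign forms.
#'
#' @param data Tibble with a `population` column and the segment columns of
#'   [leg_ratio()] (a `ratio` column is computed if absent).
#' @return Tibble with columns `population`, `score`, `n_individuals`.
#' @export
population_score <- function(data) {
  data <- tibble::as_tibble(data)
  if (!"population" %in% names(data)) stop("data must have a population column")
  if (!"ratio" %in% names(data)) data <- leg_ratio(data)
  if (nrow(data) == 0) stop("no individuals")
  data |>
    dplyr::group_by(.data$population) |>
    dplyr::summarise(score = mean(log(.data$ratio)),
                     n_individuals = dplyr::n(), .groups = "drop")
}

#' Classify populations into the three aggression forms
#'
#' Hierarchical agglomerative clustering (Euclidean distance, Ward linkage
#' as the Ward.D2 criterion) of the scalar population scores, cut at three
#' clusters. Clusters are labelled by their mean score: highest = HG,
#' lowest = LW, intermediate = ML. A per-population borderline diagnostic
#' (`margin`) reports the gap between the distance to the population's own
#' cluster mean and to the nearest other cluster mean, in units of the score
#' range; small values mark populations whose assignment flips under small
#' perturbations (the behaviour seen for borderline field populations).
#'
#' @param scores Tibble from [population_score()] (columns `population`,
#'   `score`), >= 3 populations.
#' @param linkage `"ward.D2"` (default) or `"ward.D"`.
#' @param overrides Optional named character vector of manual form
#'   overrides, e.g. `c(SR3 = "ML")`, applied after clustering and recorded.
#' @return An object of class `form_assignment` with the assignment tibble,
#'   the `hclust` dendrogram and the linkage used.
#' @export
cluster_forms <- function(scores, linkage = c("ward.D2", "ward.D"),
                          overrides = NULL) {
  scores <- tibble::as_tibble(scores)
  stopifnot(all(c("population", "score") %in% names(scores)))
  if (nrow(scores) < 3) stop("need at least 3 populations")
  linkage <- match.arg(linkage)
  x <- scores$score
  names(x) <- scores$population
  hc <- hclust(dist(x), method = linkage)
  cl <- cutree(hc, k = 3)
  cmeans <- tapply(x, cl, mean)
  form_of_cluster <- character(3)
  form_of_cluster[order(cmeans)] <- c("LW", "ML", "HG")
  form <- form_of_cluster[cl]
  margin <- vapply(seq_along(x), function(i) {
    down <- abs(x[i] - cmeans[cl[i]])
    doth <- min(abs(x[i] - cmeans[-cl[i]]))
    (doth - down) / diff(range(x))
  }, numeric(1))
  tab <- tibble::tibble(population = scores$population,
                        score = x,
                        cluster = as.integer(cl),
                        form = form,
                        margin = margin,
                        overridden = FALSE)
  if (!is.null(overrides)) {
    bad <- setdiff(names(overrides), tab$population)
    if (length(bad) > 0) stop("override for unknown population: ",
                              paste(bad, collapse = ", "))
    i <- match(names(overrides), tab$population)
    tab$form[i] <- unname(overrides)
    tab$overridden[i] <- TRUE
  }
  structure(list(assignment = tab, dendrogram = hc, linkage = linkage),
            class = "form_assignment")
}

#' @export
print.form_assignment <- function(x, ...) {
  cat("Form assignment of", nrow(x$assignment), "populations (",
      x$linkage, "linkage )\n")
  print(table(x$assignment$form))
  b <- x$assignment[order(x$assignment$margin), ]
  cat("Most borderline:", b$population[1],
      sprintf("(margin %.3f)\n", b$margin[1]))
  invisible(x)
}

#' Export the morph dendrogram as Newick
#'
#' @param x A `form_assignment`.
#' @param file Optional path; if `NULL` the Newick string is returned.
#' @return Newick string (invisibly when written to file); merge heights
#'   become branch lengths.
#' @export
morph_dendrogram_newick <- function(x, file = NULL) {
  stopifnot(inherits(x, "form_assignment"))
  tr <- ape::as.phylo(x$dendrogram)
  if (is.null(file)) return(ape::write.tree(tr))
  ape::write.tree(tr, file = file)
  invisible(ape::write.tree(tr))
}
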