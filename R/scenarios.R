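#' Default prior set for the demographic parameters
#'
#' Returns the prior distributions used for the nine competing demographic
#' scenarios: independent uniforms for the haploid effective size of each
#' form group (`N_LW`, `N_ML`, `N_HG`, individuals), the two event times
#' (`t1`, `t2`, generations before present), the admixture fraction `r`
#' (share of the ML gene pool contributed by the LW side in the admixture
#' scenarios), the per-site per-generation mutation rate `mu`, and the HKY
#' transition/transversion coefficient `kappa`.
#'
#' @return A tibble with columns `parameter`, `lower`, `upper`, `scale`
#'   (`"linear"` or `"log"`; draws on the log scale are uniform in log10).
#' @export
#' @examples
#' default_priors()
default_priors <- function() {
  tibble::tibble(
    parameter = c("N_LW", "N_ML", "N_HG", "t1", "t2", "r", "mu", "kappa"),
    lower = c(10, 10, 10, 10, 10, 0.001, 1e-8, 0.05),
    upper = c(5e5, 5e5, 5e5, 4e5, 4e5, 0.999, 1e-7, 20),
    scale = "linear"
  )
}

validate_priors <- function(priors) {
  stopifnot(is.data.frame(priors),
            all(c("parameter", "lower", "upper", "scale") %in% names(priors)))
  need <- c("N_LW", "N_ML", "N_HG", "t1", "t2", "r", "mu", "kappa")
  if (!all(need %in% priors$parameter))
    stop("priors must contain rows for: ", paste(need, collapse = ", "))
  if (any(priors$lower >= priors$upper)) stop("every prior lower bound must be < upper bound")
  pr <- function(p) priors[priors$parameter == p, , drop = FALSE]
  for (p in c("N_LW", "N_ML", "N_HG", "t1", "t2", "mu", "kappa"))
    if (pr(p)$lower <= 0) stop("prior for ", p, " must be strictly positive")
  rb <- pr("r")
  if (rb$lower <= 0 || rb$upper >= 1) stop("prior for r must lie inside (0, 1)")
  invisible(priors)
}

#' Sample parameter draws from the priors
#'
#' Draws each parameter independently from its prior. For scenarios 1--8 the
#' event-time ordering constraint `t1 < t2` is enforced by rejecting and
#' redrawing the whole joint draw (not by conditional sampling), so marginals
#' remain the truncated joint prior.
#'
#' @param priors A prior tibble as returned by [default_priors()].
#' @param scenario_id Integer in 1--9; determines which ordering constraint
#'   applies (scenario 9 has a single event time and no constraint).
#' @param n Number of joint draws.
#' @return A tibble with `n` rows and columns `scenario`, `N_LW`, `N_ML`,
#'   `N_HG`, `t1`, `t2`, `r`, `mu`, `kappa`.
#' @export
#' @examples
#' set.seed(1)
#' sample_prior(default_priors(), scenario_id = 2, n = 3)
sample_prior <- function(priors = default_priors(), scenario_id, n = 1) {
  validate_priors(priors)
  stopifnot(length(scenario_id) == 1, scenario_id %in% 1:9, n >= 1)
  draw1 <- function(m) {
    out <- lapply(seq_len(nrow(priors)), function(i) {
      lo <- priors$lower[i]; up <- priors$upper[i]
      if (identical(priors$scale[i], "log")) 10^runif(m, log10(lo), log10(up))
      else runif(m, lo, up)
    })
    names(out) <- priors$parameter
    tibble::as_tibble(out)
  }
  d <- draw1(n)
  if (scenario_id <= 8) {
    bad <- which(d$t1 >= d$t2)
    while (length(bad) > 0) {
      repl <- draw1(length(bad))
      d[bad, ] <- repl
      bad <- bad[repl$t1 >= repl$t2]
    }
  }
  dplyr::bind_cols(tibble::tibble(scenario = as.integer(scenario_id)),
                   d[, c("N_LW", "N_ML", "N_HG", "t1", "t2", "r", "mu", "kappa")])
}

# Event templates for the nine scenarios, backward in time. Columns:
# type (0 split, 1 admixture), tcode (1 -> t1, 2 -> t2), src, tgt, tgt2
# (0-based deme codes LW=0, ML=1, HG=2; -1 unused), use_r (0/1).
# Scenario 1: LW splits from ML at t1, HG from ML at t2.
# Scenario 2: HG splits from ML at t1, LW from ML at t2 (the supported one:
#   LW derived from ML first, then HG derived from ML).
# Scenario 3: HG from LW at t1, LW from ML at t2. Scenario 4: LW from HG at
#   t1, HG from ML at t2. Scenario 5: HG from ML at t1, ML from LW at t2.
# Scenario 6: HG from LW at t1, ML from LW at t2. Scenarios 7/8: ML formed
#   at t1 by admixture of LW (fraction r) and HG; LW/HG split at t2 with
#   ancestor LW (7) or HG (8). Scenario 9: one three-way split at t2.
scenario_event_template <- function(id) {
  stopifnot(length(id) == 1, id %in% 1:9)
  sp <- function(tcode, src, tgt) c(0, tcode, src, tgt, -1, 0)
  ad <- function(tcode, src, tgt, tgt2) c(1, tcode, src, tgt, tgt2, 1)
  rows <- switch(id,
    `1` = list(sp(1, 0, 1), sp(2, 2, 1)),
    `2` = list(sp(1, 2, 1), sp(2, 0, 1)),
    `3` = list(sp(1, 2, 0), sp(2, 0, 1)),
    `4` = list(sp(1, 0, 2), sp(2, 2, 1)),
    `5` = list(sp(1, 2, 1), sp(2, 1, 0)),
    `6` = list(sp(1, 2, 0), sp(2, 1, 0)),
    `7` = list(ad(1, 1, 0, 2), sp(2, 2, 0)),
    `8` = list(ad(1, 1, 0, 2), sp(2, 0, 2)),
    `9` = list(sp(2, 0, 1), sp(2, 2, 1))
  )
  m <- do.call(rbind, rows)
  colnames(m) <- c("type", "tcode", "src", "tgt", "tgt2", "use_r")
  m
}

#' Build a concrete demographic scenario from a parameter draw
#'
#' Instantiates one of the nine competing scenarios as an ordered
#' backward-in-time event list. Scenarios 1--6 are pure split models,
#' 7--8 are isolation-with-admixture models (the ML form arises at `t1` as a
#' mixture of the LW and HG sides with fraction `r` from LW), and 9 is a
#' simultaneous three-way split at `t2`.
#'
#' @param id Scenario id, integer 1--9.
#' @param draw A one-row tibble (or named list) with at least `N_LW`, `N_ML`,
#'   `N_HG`, `t1`, `t2` and, for scenarios 7--8, `r` (see [sample_prior()]).
#' @return An object of class `scenario_spec`: the scenario id, a tibble of
#'   events (columns `type`, `time`, `src`, `tgt`, `tgt2`, `r`, demes as form
#'   labels) sorted by time, and the per-deme haploid sizes.
#' @export
#' @examples
#' build_scenario(2, sample_prior(scenario_id = 2))
build_scenario <- function(id, draw) {
  stopifnot(length(id) == 1, id %in% 1:9)
  draw <- as.list(draw)
  need <- c("N_LW", "N_ML", "N_HG", "t2")
  if (id <= 8) need <- c(need, "t1")
  if (id %in% 7:8) need <- c(need, "r")
  miss <- setdiff(need, names(draw))
  if (length(miss) > 0) stop("draw is missing: ", paste(miss, collapse = ", "))
  if (id <= 8 && draw$t1 >= draw$t2)
    stop("invalid draw: scenario ", id, " requires t1 < t2")
  tpl <- scenario_event_template(id)
  lab <- function(code) ifelse(code < 0, NA_character_, FORMS[code + 1])
  ev <- tibble::tibble(
    type = ifelse(tpl[, "type"] == 0, "split", "admixture"),
    time = ifelse(tpl[, "tcode"] == 1, draw$t1, draw$t2),
    src = lab(tpl[, "src"]),
    tgt = lab(tpl[, "tgt"]),
    tgt2 = lab(tpl[, "tgt2"]),
    r = ifelse(tpl[, "use_r"] == 1, draw$r, NA_real_)
  )
  ev <- ev[order(ev$time), , drop = FALSE]
  structure(
    list(id = as.integer(id),
         events = ev,
         sizes = c(LW = draw$N_LW, ML = draw$N_ML, HG = draw$N_HG)),
    class = "scenario_spec"
  )
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("Demographic scenario", x$id, "\n")
  cat("Haploid deme sizes: ",
      paste(names(x$sizes), round(x$sizes), sep = "=", collapse = ", "), "\n")
  cat("Events (backward in time):\n")
  print(as.data.frame(x$events))
  invisible(x)
}

# concrete numeric event matrix for the C++ engine
scenario_event_matrix <- function(spec) {
  ev <- spec$events
  cbind(
    type = ifelse(ev$type == "split", 0, 1),
    time = ev$time,
    src = form_code(ev$src),
    tgt = form_code(ev$tgt),
    tgt2 = vapply(ev$tgt2, function(z) if (is.na(z)) -1 else form_code(z), numeric(1)),
    r = ifelse(is.na(ev$r), 0, ev$r)
  )
}
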