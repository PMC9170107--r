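#' Prevalence of detected untreated AF above a score threshold
#'
#' Fraction of the screened cohort found to have untreated AF with a CHADS2
#' score at or above `min_score` -- the prevalence applied to a target
#' population when projecting how many cases a national screen would find.
#' (Guidelines anchor anticoagulation eligibility at CHADS2 >= 1, hence the
#' default threshold.)
#'
#' @param score_dist a [score_distribution()] of the detected untreated-AF
#'   cases' CHADS2 scores, or `NULL`/empty for no cases.
#' @param n_screened number screened (`> 0`).
#' @param min_score minimum qualifying score (default 1).
#' @return the prevalence as a fraction.
#' @examples
#' detected_prevalence(score_distribution(c(`0` = 3, `1` = 8, `2` = 2,
#'                                          `3` = 2)), 1607)  # 12/1607
#' @export
detected_prevalence <- function(score_dist, n_screened, min_score = 1) {
  if (n_screened <= 0) stop("n_screened must be positive")
  if (min_score < 0) stop("min_score must be >= 0")
  if (is.null(score_dist) || !length(score_dist)) return(0)
  if (!inherits(score_dist, "score_distribution"))
    score_dist <- score_distribution(score_dist)
  sum(score_dist[as.numeric(names(score_dist)) >= min_score]) / n_screened
}

#' Population projection of screen-detected AF and preventable strokes
#'
#' Scales the screening detection prevalence up to an age-by-sex population
#' and asks how many strokes a fixed number of years of anticoagulant
#' treatment of every detected case would prevent.  For each sex and single
#' year of age `a` (5-year band headcounts divided by 5): identified cases
#' `b = population x prevalence`; per-person absolute risk reduction
#' `c = cumulative strokes over the horizon untreated - treated` from the
#' cohort model (undiscounted, acute deaths included); number needed to
#' treat `d = 1 / c`; strokes prevented `e = b x c`.
#'
#' @param pop a [population_table()] covering ages 65-80 for both sexes.
#' @param prevalence detected-prevalence fraction applied uniformly to every
#'   cell (see [detected_prevalence()]).
#' @param transitions_men,transitions_women [transition_table()]s.
#' @param horizon treatment horizon in years (default 10).
#' @param config a [model_config()] (conventions; discounting is not applied
#'   to stroke counts).
#' @param ages single years of age to project (default 65:80).
#' @param risk_by `"single_year"` (risk reduction recomputed at every single
#'   year of starting age) or `"band"` (computed once at each 5-year band's
#'   lower edge and reused within the band).
#' @return data frame of class `projection_result` with columns `sex`, `age`,
#'   `population`, `identified`, `risk_reduction`, `nnt`,
#'   `strokes_prevented`; totals in `attr(, "totals")`.
#' @export
project <- function(pop, prevalence, transitions_men, transitions_women,
                    horizon = 10, config = model_config(), ages = 65:80,
                    risk_by = c("single_year", "band")) {
  risk_by <- match.arg(risk_by)
  stopifnot(inherits(pop, "population_table"))
  if (!is.finite(prevalence) || prevalence < 0 || prevalence > 1)
    stop("prevalence must be a fraction in [0, 1]")
  if (horizon < 1) stop("horizon must be >= 1")
  sy <- single_year_population(pop, ages = ages)
  tabs <- list(men = transitions_men, women = transitions_women)

  risk_at <- function(sex, age) {
    cumulative_strokes("untreated_af", sex, age, horizon, tabs[[sex]],
                       config = config) -
      cumulative_strokes("treated_af", sex, age, horizon, tabs[[sex]],
                         config = config)
  }
  risk_age <- if (risk_by == "single_year") sy$age
              else .af_band_lower[.band_index(sy$age)]
  key <- paste(sy$sex, risk_age)
  uniq <- !duplicated(key)
  cvals <- stats::setNames(mapply(risk_at, sy$sex[uniq], risk_age[uniq]),
                           key[uniq])
  out <- data.frame(sex = sy$sex, age = sy$age, population = sy$count)
  out$identified <- out$population * prevalence
  out$risk_reduction <- unname(cvals[key])
  out$nnt <- ifelse(out$risk_reduction > 0, 1 / out$risk_reduction, Inf)
  out$strokes_prevented <- out$identified * out$risk_reduction
  structure(out,
            class = c("projection_result", "data.frame"),
            horizon = horizon, prevalence = prevalence,
            totals = c(population = sum(out$population),
                       identified = sum(out$identified),
                       strokes_prevented = sum(out$strokes_prevented)))
}

#' @export
print.projection_result <- function(x, digits = 1, ...) {
  tot <- attr(x, "totals")
  cat(sprintf("Projection: %d-year treatment horizon, prevalence %.4f%%\n",
              attr(x, "horizon"), 100 * attr(x, "prevalence")))
  print.data.frame(x, digits = 4, row.names = FALSE)
  cat(sprintf("Totals: population %.0f, identified untreated AF %.0f, strokes prevented %.0f\n",
              tot[["population"]], tot[["identified"]],
              tot[["strokes_prevented"]]))
  invisible(x)
}
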