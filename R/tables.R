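#' Life-year/QALY effectiveness table by sex and starting age
#'
#' Assembles the headline effectiveness table: for both sexes at starting
#' ages 65, 70, 75 and 80 (by default), lifetime discounted life-years and
#' QALYs under anticoagulant treatment and no treatment, with differences.
#'
#' @param transitions_men,transitions_women [transition_table()]s (defaults:
#'   the shipped published tables).
#' @param qol a [qol_params()].
#' @param config a [model_config()].
#' @param ages starting ages (default `c(65, 70, 75, 80)`).
#' @return data frame with columns `sex`, `age`, `ly_treated`,
#'   `ly_untreated`, `ly_difference`, `qaly_treated`, `qaly_untreated`,
#'   `qaly_difference`.
#' @examples
#' \donttest{qaly_table(ages = c(65, 75))}
#' @export
qaly_table <- function(transitions_men = default_transition_table("men"),
                       transitions_women = default_transition_table("women"),
                       qol = default_qol_params(), config = model_config(),
                       ages = c(65, 70, 75, 80)) {
  tabs <- list(men = transitions_men, women = transitions_women)
  rows <- lapply(.af_sexes, function(s) {
    do.call(rbind, lapply(ages, function(a) {
      e <- effectiveness_difference(s, a, tabs[[s]], qol, config)
      data.frame(sex = s, age = a,
                 ly_treated = e$totals$life_years[1],
                 ly_untreated = e$totals$life_years[2],
                 ly_difference = e$difference[["life_years"]],
                 qaly_treated = e$totals$qalys[1],
                 qaly_untreated = e$totals$qalys[2],
                 qaly_difference = e$difference[["qalys"]])
    }))
  })
  do.call(rbind, rows)
}

#' Summary statistics of a screening cohort
#'
#' One-stop report for a screening-record data frame: cohort
#' characteristics, overall untreated-AF detection rate and number needed to
#' screen, the stratified detection table (2x2 counts, rates and Fisher p
#' per CHADS2 component), interobserver kappa, and the detected cases'
#' score summaries.
#'
#' @param records screening-record data frame ([generate_cohort()] schema).
#' @return list of class `screening_summary` with elements
#'   `characteristics` (data frame), `detection` ([detection_rate()]),
#'   `nns`, `stratified` (data frame), `kappa`, `scores` (list with
#'   `chads2`/`cha2ds2_vasc` distributions and mean/SD).
#' @export
screening_summary <- function(records) {
  records <- as.data.frame(records)
  if (!nrow(records)) stop("empty cohort")
  n <- nrow(records)
  detected <- records$adjudicated == "AF" & !as.logical(records$known_af)
  chars <- data.frame(
    variable = c("n", "age_mean", "age_sd", "female_n", "chf_n",
                 "hypertension_n", "diabetes_n", "stroke_tia_n",
                 "vascular_n", "known_af_n"),
    value = c(n, mean(records$age), stats::sd(records$age),
              sum(records$sex %in% c("women", "female", "F")),
              sum(records$chf, na.rm = TRUE),
              sum(records$hypertension, na.rm = TRUE),
              sum(records$diabetes, na.rm = TRUE),
              sum(records$stroke_tia, na.rm = TRUE),
              sum(records$vascular, na.rm = TRUE),
              sum(records$known_af)))
  strat <- do.call(rbind, lapply(
    c("chf", "hypertension", "age75", "diabetes", "stroke_tia"),
    function(f) {
      s <- stratified_detection(records, f)
      data.frame(factor = f, detected_pos = s$table[1, 1],
                 other_pos = s$table[1, 2], detected_neg = s$table[2, 1],
                 other_neg = s$table[2, 2], rate_pos = s$rate_pos,
                 rate_neg = s$rate_neg, p = s$p)
    }))
  interpretable <- records$adjudicated != "uninterpretable"
  kap <- if (all(c("reader1", "reader2") %in% names(records)))
    cohen_kappa(records$reader1[interpretable],
                records$reader2[interpretable]) else NA_real_
  det_scores <- records[detected, ]
  scores <- list()
  if (nrow(det_scores)) {
    for (sc in c("chads2", "cha2ds2_vasc")) {
      d <- score_distribution(det_scores[[sc]], tabulate = TRUE)
      scores[[sc]] <- list(distribution = d, summary = score_summary(d))
    }
  }
  structure(list(characteristics = chars,
                 detection = detection_rate(sum(detected), n),
                 nns = nns(sum(detected), n),
                 stratified = strat, kappa = kap, scores = scores),
            class = "screening_summary")
}

#' @export
print.screening_summary <- function(x, ...) {
  cat("Screening cohort summary\n")
  print(x$detection)
  cat(sprintf("Number needed to screen: %.1f\n", x$nns))
  cat(sprintf("Interobserver kappa: %.3f\n", x$kappa))
  cat("Stratified detection:\n")
  print(x$stratified, digits = 3, row.names = FALSE)
  for (nm in names(x$scores))
    cat(sprintf("%s of detected cases: mean %.1f, SD %.1f\n", nm,
                x$scores[[nm]]$summary[["mean"]],
                x$scores[[nm]]$summary[["sd"]]))
  invisible(x)
}

#' Population projection table
#'
#' Wrapper assembling the national projection from a population table and
#' the screening results: derives the detected prevalence (CHADS2 at or
#' above `min_score`) and runs [project()].
#'
#' @param pop a [population_table()].
#' @param score_dist CHADS2 [score_distribution()] of detected cases.
#' @param n_screened number screened behind `score_dist`.
#' @param min_score qualifying-score threshold (default 1).
#' @inheritParams project
#' @return a [project()] result.
#' @export
projection_table <- function(pop, score_dist, n_screened, min_score = 1,
                             transitions_men = default_transition_table("men"),
                             transitions_women = default_transition_table("women"),
                             horizon = 10, config = model_config(), ...) {
  project(pop,
          detected_prevalence(score_dist, n_screened, min_score),
          transitions_men, transitions_women, horizon, config, ...)
}
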