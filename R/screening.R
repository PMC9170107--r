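.af_factors <- c(chf = "chf", hypertension = "hypertension",
                 diabetes = "diabetes", stroke_tia = "stroke_tia",
                 vascular = "vascular", age75 = "age75")

#' Detection rate with exact binomial confidence interval
#'
#' Proportion of screened subjects in whom the condition was detected, with a
#' Clopper-Pearson (exact binomial) confidence interval.
#'
#' @param n_detected number of cases detected.
#' @param n_screened number screened (`> 0`).
#' @param conf.level confidence level (default 0.95).
#' @return list of class `detection_rate`: `rate` (fraction), `lower`,
#'   `upper`, `n_detected`, `n_screened`, `conf.level`.
#' @examples
#' detection_rate(15, 1607)
#' @export
detection_rate <- function(n_detected, n_screened, conf.level = 0.95) {
  if (n_screened <= 0) stop("n_screened must be positive")
  if (n_detected < 0 || n_detected > n_screened)
    stop("n_detected must lie in [0, n_screened]")
  ci <- stats::binom.test(n_detected, n_screened,
                          conf.level = conf.level)$conf.int
  structure(list(rate = n_detected / n_screened,
                 lower = ci[1], upper = ci[2],
                 n_detected = n_detected, n_screened = n_screened,
                 conf.level = conf.level),
            class = "detection_rate")
}

#' @export
print.detection_rate <- function(x, ...) {
  cat(sprintf("Detection rate: %d/%d = %.2f%% (%.0f%% CI %.2f%%-%.2f%%)\n",
              x$n_detected, x$n_screened, 100 * x$rate,
              100 * x$conf.level, 100 * x$lower, 100 * x$upper))
  invisible(x)
}

#' Number needed to screen
#'
#' Screens performed per case detected: the raw quotient
#' `n_screened / n_detected` (callers round for display as needed).
#'
#' @param n_detected cases detected.
#' @param n_screened number screened.
#' @return the quotient; `Inf` with a warning when nothing was detected.
#' @examples
#' nns(15, 1607)  # ~107
#' nns(10, 628)   # 62.8
#' @export
nns <- function(n_detected, n_screened) {
  if (n_screened <= 0) stop("n_screened must be positive")
  if (n_detected == 0) {
    warning("no cases detected: number needed to screen is infinite")
    return(Inf)
  }
  n_screened / n_detected
}

#' 2x2 contingency table
#'
#' Validated container for a 2x2 table of counts: `a` exposed-positive,
#' `b` exposed-negative, `c` unexposed-positive, `d` unexposed-negative.
#'
#' @param a,b,c,d non-negative integer counts, grand total `> 0`.
#' @return a 2x2 integer matrix of class `contingency_2x2` (rows exposed /
#'   unexposed, columns positive / negative).
#' @export
contingency_2x2 <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (sum(counts) == 0) stop("grand total must be positive")
  m <- matrix(as.integer(counts[c("a", "b", "c", "d")]), nrow = 2,
              byrow = TRUE,
              dimnames = list(c("exposed", "unexposed"),
                              c("positive", "negative")))
  structure(m, class = c("contingency_2x2", class(m)))
}

#' Fisher's exact test, two-sided
#'
#' Two-sided p-value for independence in a 2x2 table, defined (as in
#' mainstream statistical software) as the sum of hypergeometric
#' probabilities, over all tables with the same margins, that do not exceed
#' the probability of the observed table.
#'
#' @param table a [contingency_2x2()] (or 2x2 matrix of counts).
#' @return the two-sided p-value; a degenerate margin yields 1 with a warning.
#' @examples
#' fisher_exact(contingency_2x2(10, 618, 5, 972))
#' @export
fisher_exact <- function(table) {
  m <- unclass(table)
  if (!is.matrix(m) || !all(dim(m) == 2))
    stop("a 2x2 table of counts is required")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    warning("degenerate margin: p = 1 by convention")
    return(1)
  }
  stats::fisher.test(m, alternative = "two.sided")$p.value
}

#' Untreated-AF detection stratified by a risk factor
#'
#' Builds the 2x2 table of newly detected untreated AF by presence/absence of
#' a stroke risk factor in a screening cohort, with per-stratum detection
#' rates and the two-sided Fisher p-value.  The numerator is subjects whose
#' adjudicated rhythm is AF and who have no known (already treated) AF; the
#' denominator of each stratum is every screened subject with a recorded
#' value for the factor, matching how such stratified tables are published
#' (subjects with known AF or uninterpretable recordings count in
#' denominators; subjects missing the factor are dropped).
#'
#' @param records screening-cohort data frame (see [generate_cohort()] for
#'   the schema).
#' @param factor one of `"chf"`, `"hypertension"`, `"diabetes"`,
#'   `"stroke_tia"`, `"vascular"`, `"age75"` (age 75 and over).
#' @return list of class `stratified_detection`: `factor`, `table` (a
#'   [contingency_2x2()]), `rate_pos`, `rate_neg` (fractions), `p`.
#' @export
stratified_detection <- function(records, factor) {
  if (!factor %in% names(.af_factors))
    stop("unknown factor: ", factor, " (expected one of ",
         paste(names(.af_factors), collapse = ", "), ")")
  records <- as.data.frame(records)
  need <- c("adjudicated", "known_af")
  if (!all(need %in% names(records)))
    stop("records lack column(s): ",
         paste(setdiff(need, names(records)), collapse = ", "))
  fac <- if (factor == "age75") as.integer(records$age >= 75)
         else records[[factor]]
  keep <- !is.na(fac)
  fac <- as.logical(fac[keep])
  detected <- with(records[keep, ],
                   adjudicated == "AF" & !as.logical(known_af))
  a <- sum(detected & fac);  b <- sum(!detected & fac)
  cc <- sum(detected & !fac); d <- sum(!detected & !fac)
  if ((a + b) == 0 || (cc + d) == 0)
    warning("empty stratum for factor ", factor)
  tab <- contingency_2x2(a, b, cc, d)
  structure(list(factor = factor, table = tab,
                 rate_pos = if (a + b > 0) a / (a + b) else NA_real_,
                 rate_neg = if (cc + d > 0) cc / (cc + d) else NA_real_,
                 p = fisher_exact(tab)),
            class = "stratified_detection")
}

#' @export
print.stratified_detection <- function(x, ...) {
  cat(sprintf("Untreated AF by %s: %.2f%% (+) vs %.2f%% (-), Fisher p = %.3f\n",
              x$factor, 100 * x$rate_pos, 100 * x$rate_neg, x$p))
  invisible(x)
}

#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement between two label sequences over the same
#' categories: `(p_o - p_e) / (1 - p_e)` with expected agreement from the
#' product of marginal proportions.
#'
#' @param labels_a,labels_b equal-length, non-empty label vectors.
#' @return kappa; `NA` with a warning when both raters are constant and
#'   identical (chance agreement 1, kappa undefined).
#' @examples
#' cohen_kappa(c("AF", "AF", "non-AF"), c("AF", "non-AF", "non-AF"))
#' @export
cohen_kappa <- function(labels_a, labels_b) {
  if (!length(labels_a) || length(labels_a) != length(labels_b))
    stop("label sequences must be non-empty and of equal length")
  lev <- sort(unique(c(as.character(labels_a), as.character(labels_b))))
  a <- factor(labels_a, levels = lev)
  b <- factor(labels_b, levels = lev)
  n <- length(a)
  tab <- table(a, b) / n
  p_o <- sum(diag(tab))
  p_e <- sum(rowSums(tab) * colSums(tab))
  if (1 - p_e < .Machine$double.eps) {
    warning("both raters constant and identical: kappa undefined")
    return(NA_real_)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Score distribution container
#'
#' A distribution of integer risk scores as counts per score value.
#'
#' @param counts named numeric vector (names are score values) or a vector
#'   of raw scores when `tabulate = TRUE`.
#' @param tabulate if `TRUE`, `counts` holds raw scores to be tabulated.
#' @return named integer vector of class `score_distribution`.
#' @examples
#' score_distribution(c(`0` = 3, `1` = 8, `2` = 2, `3` = 2))
#' @export
score_distribution <- function(counts, tabulate = FALSE) {
  if (tabulate) {
    tab <- table(counts)
    counts <- stats::setNames(as.integer(tab), names(tab))
  }
  if (is.null(names(counts)) || anyNA(suppressWarnings(as.numeric(names(counts)))))
    stop("counts must be named by integer score values")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (sum(counts) == 0) stop("at least one positive count is required")
  structure(as.integer(counts), names = names(counts),
            class = "score_distribution")
}

#' Mean and SD of a score distribution
#'
#' @param dist a [score_distribution()] (or named count vector).
#' @return named vector `c(mean, sd)`; sample SD uses the `n - 1`
#'   denominator and is `NA` with a warning for a single observation.
#' @examples
#' score_summary(score_distribution(c(`0` = 3, `1` = 8, `2` = 2, `3` = 2)))
#' @export
score_summary <- function(dist) {
  if (!inherits(dist, "score_distribution")) dist <- score_distribution(dist)
  x <- rep(as.numeric(names(dist)), dist)
  if (length(x) < 2) {
    warning("SD undefined for fewer than 2 observations")
    return(c(mean = mean(x), sd = NA_real_))
  }
  c(mean = mean(x), sd = stats::sd(x))
}

#' Diagnostic sensitivity and specificity with confidence intervals
#'
#' Sensitivity `TP / (TP + FN)` and specificity `TN / (TN + FP)` from a
#' confusion table, each with a binomial confidence interval
#' (Clopper-Pearson exact by default, Wilson score optionally).
#'
#' @param confusion a [contingency_2x2()] laid out as `a` = TP, `b` = FN,
#'   `c` = FP, `d` = TN (rows: condition present / absent; columns: test
#'   positive on the diagonal convention above).
#' @param ci `"clopper-pearson"` or `"wilson"`.
#' @param conf.level confidence level.
#' @return list of class `diag_accuracy` with `sensitivity`, `specificity`,
#'   each a vector `c(estimate, lower, upper)`, plus the counts.
#' @examples
#' diag_accuracy(contingency_2x2(29, 1, 40, 950))
#' @export
diag_accuracy <- function(confusion, ci = c("clopper-pearson", "wilson"),
                          conf.level = 0.95) {
  ci <- match.arg(ci)
  m <- unclass(confusion)
  tp <- m[1, 1]; fn <- m[1, 2]; fp <- m[2, 1]; tn <- m[2, 2]
  if (tp + fn == 0) stop("no condition-positive subjects")
  if (tn + fp == 0) stop("no condition-negative subjects")
  one <- function(x, n) {
    est <- x / n
    if (ci == "clopper-pearson") {
      int <- stats::binom.test(x, n, conf.level = conf.level)$conf.int
      c(estimate = est, lower = int[1], upper = int[2])
    } else {
      z <- stats::qnorm(1 - (1 - conf.level) / 2)
      mid <- (est + z^2 / (2 * n)) / (1 + z^2 / n)
      hw <- z * sqrt(est * (1 - est) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
      c(estimate = est, lower = max(0, mid - hw), upper = min(1, mid + hw))
    }
  }
  structure(list(sensitivity = one(tp, tp + fn),
                 specificity = one(tn, tn + fp),
                 counts = c(tp = tp, fn = fn, fp = fp, tn = tn),
                 ci = ci, conf.level = conf.level),
            class = "diag_accuracy")
}

#' @export
print.diag_accuracy <- function(x, ...) {
  f <- function(v) sprintf("%.3f (%.0f%% CI %.3f-%.3f)", v[["estimate"]],
                           100 * x$conf.level, v[["lower"]], v[["upper"]])
  cat("Sensitivity:", f(x$sensitivity), "\n")
  cat("Specificity:", f(x$specificity), "\n")
  invisible(x)
}

#' CHADS2 and CHA2DS2-VASc stroke-risk scores
#'
#' Computes both additive stroke-risk scores for each record.  CHADS2 scores
#' congestive heart failure, hypertension, age 75 and over, diabetes (1 point
#' each) and prior stroke/TIA (2 points).  CHA2DS2-VASc additionally scores
#' vascular disease, age 65-74 and female sex (1 point each) and gives age 75
#' and over 2 points.
#'
#' @param records data frame with columns `age`, `sex` (`"men"`/`"women"` or
#'   `"female"` flag coercible to logical via `sex == "women"`), and 0/1
#'   indicators `chf`, `hypertension`, `diabetes`, `stroke_tia`, `vascular`.
#' @return data frame with integer columns `chads2` and `cha2ds2_vasc`.
#' @examples
#' compute_scores(data.frame(age = 80, sex = "women", chf = 0,
#'                           hypertension = 1, diabetes = 0, stroke_tia = 0,
#'                           vascular = 0))
#' @export
compute_scores <- function(records) {
  records <- as.data.frame(records)
  need <- c("age", "sex", "chf", "hypertension", "diabetes", "stroke_tia",
            "vascular")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records lack component field(s): ", paste(miss, collapse = ", "))
  for (cc in need)
    if (anyNA(records[[cc]]))
      stop("missing values in component field: ", cc)
  if (any(records$age < 0)) stop("age must be non-negative")
  female <- records$sex %in% c("women", "female", "F")
  chf <- as.integer(as.logical(records$chf))
  htn <- as.integer(as.logical(records$hypertension))
  dm  <- as.integer(as.logical(records$diabetes))
  st  <- as.integer(as.logical(records$stroke_tia))
  va  <- as.integer(as.logical(records$vascular))
  a75 <- as.integer(records$age >= 75)
  a65 <- as.integer(records$age >= 65 & records$age < 75)
  data.frame(chads2 = chf + htn + a75 + dm + 2L * st,
             cha2ds2_vasc = chf + htn + 2L * a75 + dm + 2L * st + va + a65 +
               as.integer(female))
}
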