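#' @keywords internal
"_PACKAGE"

## canonical 5-year age bands of the transition table, 65 through 100+
.af_bands <- c("65-69", "70-74", "75-79", "80-84", "85-89", "90-94",
               "95-99", "100+")
.af_band_lower <- c(65, 70, 75, 80, 85, 90, 95, 100)

.af_prob_cols <- c("p_s0e1", "p_s0e2", "p_t1e1", "p_t1e2",
                   "p_t0e1", "p_t0e2", "p_e1e2")

.af_sexes <- c("men", "women")

#' Annual transition probability table
#'
#' Constructs and validates the table of annual transition probabilities that
#' drives the Markov cohort model: for each sex and 5-year age band from 65-69
#' up to 100+, the probabilities of stroke and of death from any cause for the
#' non-AF, anticoagulant-treated AF and untreated AF profiles, plus the annual
#' death probability in the post-stroke state.  Probabilities are stored as
#' fractions.  The terminal 100+ band must carry death probability 1 and
#' stroke probability 0 so that every cohort closes.
#'
#' @param probs data frame with columns `age_band` (the eight bands
#'   `"65-69"` ... `"95-99"`, `"100+"`) and the seven probability columns
#'   `p_s0e1`, `p_s0e2` (non-AF stroke/death), `p_t1e1`, `p_t1e2` (treated
#'   AF), `p_t0e1`, `p_t0e2` (untreated AF) and `p_e1e2` (post-stroke death),
#'   as fractions in \[0, 1\].
#' @param sex `"men"` or `"women"`; selects which published column set the
#'   table transcribes and is carried along for labelling.
#' @param acute_fatality length-2 numeric, the fractions of incident strokes
#'   that die during the acute stage, for ages 65-74 and 75+ respectively.
#'   Defaults to the published estimates 5.7% and 10.1%.
#' @return an object of class `transition_table`.
#' @seealso [read_transition_table()], [lookup_transition()], [acute_fatality()]
#' @export
transition_table <- function(probs, sex = c("men", "women"),
                             acute_fatality = c(`65-74` = 0.057,
                                                `75+`   = 0.101)) {
  sex <- match.arg(sex)
  probs <- as.data.frame(probs)
  if (!"age_band" %in% names(probs))
    stop("transition table needs an 'age_band' column")
  missing_cols <- setdiff(.af_prob_cols, names(probs))
  if (length(missing_cols))
    stop("missing probability column(s): ", paste(missing_cols, collapse = ", "))
  probs$age_band <- .normalise_band(probs$age_band)
  missing_bands <- setdiff(.af_bands, probs$age_band)
  if (length(missing_bands))
    stop("missing age band(s): ", paste(missing_bands, collapse = ", "))
  probs <- probs[match(.af_bands, probs$age_band),
                 c("age_band", .af_prob_cols)]
  rownames(probs) <- NULL
  for (cc in .af_prob_cols) {
    v <- probs[[cc]]
    if (any(!is.finite(v)))
      stop("non-finite value in column ", cc)
    bad <- which(v < 0 | v > 1)
    if (length(bad))
      stop(sprintf("probability outside [0, 1]: column %s, band %s (%g)",
                   cc, probs$age_band[bad[1]], v[bad[1]]))
  }
  term <- probs[probs$age_band == "100+", ]
  if (any(term[, c("p_s0e2", "p_t1e2", "p_t0e2", "p_e1e2")] != 1) ||
      any(term[, c("p_s0e1", "p_t1e1", "p_t0e1")] != 0))
    stop("terminal 100+ band must have all death probabilities 1 and all stroke probabilities 0")
  acute_fatality <- as.numeric(acute_fatality)
  if (length(acute_fatality) != 2 ||
      any(!is.finite(acute_fatality)) ||
      any(acute_fatality < 0 | acute_fatality > 1))
    stop("acute_fatality must be two fractions in [0, 1] (ages 65-74, 75+)")
  names(acute_fatality) <- c("65-74", "75+")
  structure(list(sex = sex, probs = probs, acute_fatality = acute_fatality),
            class = "transition_table")
}

# accept unicode dashes and "100-" style labels as printed in sources
.normalise_band <- function(x) {
  x <- gsub("–|—", "-", trimws(as.character(x)))
  x[x %in% c("100-", "100", "100plus")] <- "100+"
  x
}

#' Read a transition table from CSV
#'
#' Reads a CSV transcription of the annual transition probabilities (columns
#' `age_band,p_s0e1,p_s0e2,p_t1e1,p_t1e2,p_t0e1,p_t0e2,p_e1e2`).  Values may
#' be carried as percents (as such tables are usually printed) or as
#' fractions; the `unit` flag declares which, and percent columns may carry a
#' literal `%` suffix.
#'
#' @param path CSV file path.
#' @param sex `"men"` or `"women"`.
#' @param unit `"percent"` (default, divides by 100) or `"fraction"`.
#' @param acute_fatality passed to [transition_table()].
#' @return a validated `transition_table`.
#' @export
read_transition_table <- function(path, sex = c("men", "women"),
                                  unit = c("percent", "fraction"),
                                  acute_fatality = c(`65-74` = 0.057,
                                                     `75+`   = 0.101)) {
  sex <- match.arg(sex)
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(.af_prob_cols, names(raw))
  if (length(missing_cols))
    stop("CSV header lacks column(s): ", paste(missing_cols, collapse = ", "))
  for (cc in .af_prob_cols) {
    v <- as.numeric(gsub("%", "", as.character(raw[[cc]])))
    raw[[cc]] <- if (unit == "percent") v / 100 else v
  }
  transition_table(raw, sex = sex, acute_fatality = acute_fatality)
}

#' Write a transition table to CSV
#'
#' Inverse of [read_transition_table()]: writes the eight bands and seven
#' probability columns, by default as percents rounded to 3 decimals (the
#' precision such tables are printed at), so that a read/write round trip
#' reproduces the source file.
#'
#' @param x a `transition_table`.
#' @param path output CSV path.
#' @param unit `"percent"` or `"fraction"`.
#' @param digits decimals kept when writing percents.
#' @return `path`, invisibly.
#' @export
write_transition_table <- function(x, path, unit = c("percent", "fraction"),
                                   digits = 3) {
  stopifnot(inherits(x, "transition_table"))
  unit <- match.arg(unit)
  out <- x$probs
  for (cc in .af_prob_cols) {
    out[[cc]] <- if (unit == "percent")
      formatC(out[[cc]] * 100, format = "f", digits = digits)
    else out[[cc]]
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Published transition tables shipped with the package
#'
#' Loads the transcribed published table of annual transition probabilities
#' for the requested sex from the CSVs installed with the package.
#'
#' @param sex `"men"` or `"women"`.
#' @return a `transition_table`.
#' @export
default_transition_table <- function(sex = c("men", "women")) {
  sex <- match.arg(sex)
  path <- system.file("extdata", paste0("transitions_", sex, ".csv"),
                      package = "afscreen", mustWork = TRUE)
  read_transition_table(path, sex = sex, unit = "percent")
}

#' @export
print.transition_table <- function(x, ...) {
  cat(sprintf("Annual transition probabilities (%s), fractions\n", x$sex))
  print(x$probs, digits = 5)
  cat(sprintf("Acute-stage stroke fatality: %.1f%% (65-74), %.1f%% (75+)\n",
              100 * x$acute_fatality[["65-74"]],
              100 * x$acute_fatality[["75+"]]))
  invisible(x)
}

.band_index <- function(age) {
  if (any(age < 65)) stop("age below 65: the model starts at age 65")
  pmin(findInterval(age, .af_band_lower), length(.af_bands))
}

#' Look up a transition probability by age
#'
#' Resolves the 5-year band containing `age` (bands are closed on the left;
#' ages 100 and over use the terminal 100+ band) and returns the named
#' transition probability.
#'
#' @param table a `transition_table`.
#' @param age age in years, `>= 65`.
#' @param transition one of `"p_s0e1"`, `"p_s0e2"`, `"p_t1e1"`, `"p_t1e2"`,
#'   `"p_t0e1"`, `"p_t0e2"`, `"p_e1e2"`.
#' @return the annual probability as a fraction.
#' @export
lookup_transition <- function(table, age, transition) {
  stopifnot(inherits(table, "transition_table"))
  transition <- match.arg(transition, .af_prob_cols)
  table$probs[[transition]][.band_index(age)]
}

#' Acute-stage stroke fatality by age
#'
#' Fraction of incident strokes that die during the acute stage: one value
#' for ages 65-74 and one for 75 and over, the boundary switching exactly at
#' age 75.
#'
#' @param table a `transition_table`.
#' @param age age in years, `>= 65`.
#' @return a fraction in \[0, 1\].
#' @export
acute_fatality <- function(table, age) {
  stopifnot(inherits(table, "transition_table"))
  if (any(age < 65)) stop("age below 65: the model starts at age 65")
  ifelse(age >= 75, table$acute_fatality[["75+"]],
         table$acute_fatality[["65-74"]])
}

#' Utility (quality-of-life) parameters
#'
#' Utility weights for the QALY calculation: the baseline utility of the
#' alive, pre-stroke state; the utility after the acute stage of stroke, by
#' current age band (65-74 vs 75+); and the transient acute-stage decrement
#' applied during the cycle in which a stroke occurs (a decrement of 0.14
#' lasting 0.25 years subtracts 0.035 from that cycle's weight).
#'
#' @param u_baseline utility per year while alive and stroke-free (default 1).
#' @param acute_decrement utility decrement during the acute stage of stroke.
#' @param acute_duration duration of the acute stage in years.
#' @param u_poststroke named length-2 numeric, utilities after the acute
#'   stage for ages `65-74` and `75+`.
#' @return an object of class `qol_params`.
#' @export
qol_params <- function(u_baseline = 1.0, acute_decrement = 0.14,
                       acute_duration = 0.25,
                       u_poststroke = c(`65-74` = 0.68, `75+` = 0.56)) {
  u_poststroke <- as.numeric(u_poststroke)
  vals <- c(u_baseline, u_poststroke)
  if (any(!is.finite(vals)) || any(vals < 0 | vals > 1))
    stop("utilities must be fractions in [0, 1]")
  if (!is.finite(acute_decrement) || acute_decrement < 0)
    stop("acute_decrement must be >= 0")
  if (!is.finite(acute_duration) || acute_duration < 0)
    stop("acute_duration must be >= 0")
  structure(list(u_baseline = u_baseline,
                 acute_decrement = acute_decrement,
                 acute_duration = acute_duration,
                 u_poststroke = c(`65-74` = u_poststroke[1],
                                  `75+`   = u_poststroke[2])),
            class = "qol_params")
}

#' Read utility parameters from CSV
#'
#' Reads a two-column `parameter,value` CSV with rows `u_baseline`,
#' `acute_decrement`, `acute_duration`, `u_poststroke_65_74`,
#' `u_poststroke_75plus`.  A negative `acute_decrement` (a decrement printed
#' with its sign) is folded to its magnitude.
#'
#' @param path CSV path.
#' @return a `qol_params`.
#' @export
read_qol_params <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("parameter", "value") %in% names(raw)))
    stop("qol CSV needs 'parameter' and 'value' columns")
  get <- function(p) {
    i <- match(p, raw$parameter)
    if (is.na(i)) stop("qol CSV lacks parameter: ", p)
    as.numeric(raw$value[i])
  }
  qol_params(u_baseline = get("u_baseline"),
             acute_decrement = abs(get("acute_decrement")),
             acute_duration = get("acute_duration"),
             u_poststroke = c(`65-74` = get("u_poststroke_65_74"),
                              `75+`   = get("u_poststroke_75plus")))
}

#' Published utility parameters shipped with the package
#' @return a `qol_params` loaded from the installed CSV.
#' @export
default_qol_params <- function() {
  read_qol_params(system.file("extdata", "qol.csv", package = "afscreen",
                              mustWork = TRUE))
}

#' @export
print.qol_params <- function(x, ...) {
  cat("Utility parameters\n")
  cat(sprintf("  baseline (alive, pre-stroke): %.2f\n", x$u_baseline))
  cat(sprintf("  post-stroke: %.2f (65-74), %.2f (75+)\n",
              x$u_poststroke[["65-74"]], x$u_poststroke[["75+"]]))
  cat(sprintf("  acute-stage decrement: %.2f for %.2f years\n",
              x$acute_decrement, x$acute_duration))
  invisible(x)
}

#' Model configuration
#'
#' Run-time conventions of the cohort model.  `accrual` fixes how much of a
#' cycle members who die (or die acutely of a stroke) during it accrue:
#' `"half_cycle"` credits half a year (the usual half-cycle correction),
#' `"cycle_start"` a full year, `"cycle_end"` none.  `discount_base` fixes
#' whether the first cycle is discounted (`1`) or not (`0`).  Since source
#' publications rarely state either convention, [calibrate_conventions()] can
#' select both against a single published anchor value.
#'
#' @param discount_rate annual discount rate, in \[0, 0.10\] (default 0.02).
#' @param terminal_age age at which the terminal band forces death (100).
#' @param accrual `"half_cycle"`, `"cycle_start"` or `"cycle_end"`.
#' @param discount_base 0 (first cycle undiscounted, default) or 1.
#' @param poststroke_utility_by `"current_age"` (post-stroke utility switches
#'   from the 65-74 to the 75+ value as the cohort passes 75) or
#'   `"age_at_stroke"` (fixed at stroke onset).
#' @return an object of class `model_config`.
#' @export
model_config <- function(discount_rate = 0.02, terminal_age = 100,
                         accrual = c("half_cycle", "cycle_start", "cycle_end"),
                         discount_base = 0L,
                         poststroke_utility_by = c("current_age",
                                                   "age_at_stroke")) {
  accrual <- match.arg(accrual)
  poststroke_utility_by <- match.arg(poststroke_utility_by)
  if (!is.finite(discount_rate) || discount_rate < 0 || discount_rate > 0.10)
    stop("discount_rate must lie in [0, 0.10]")
  if (!discount_base %in% c(0L, 1L))
    stop("discount_base must be 0 or 1")
  if (terminal_age != 100)
    stop("terminal_age is fixed at 100 by the terminal band of the transition table")
  structure(list(discount_rate = discount_rate,
                 terminal_age = terminal_age,
                 accrual = accrual,
                 discount_base = as.integer(discount_base),
                 poststroke_utility_by = poststroke_utility_by),
            class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf(paste0("Model configuration: discount %.1f%% (%d-based), ",
                     "accrual %s, terminal age %d,\n  post-stroke utility by %s\n"),
              100 * x$discount_rate, x$discount_base, x$accrual,
              x$terminal_age, x$poststroke_utility_by))
  invisible(x)
}

#' Read an age-by-sex population table
#'
#' Reads a `sex,age_band,count` CSV of 5-year band headcounts.  The bands
#' must at least cover ages 65 through 80 for both sexes (the ages screened
#' and projected).  Vital-statistics tables are published in 5-year bands;
#' [single_year_population()] divides each band count by 5.
#'
#' @param path CSV path.
#' @return a data frame of class `population_table`.
#' @export
read_population <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  population_table(raw)
}

#' @rdname read_population
#' @param x data frame with columns `sex`, `age_band`, `count`.
#' @export
population_table <- function(x) {
  x <- as.data.frame(x)
  if (!all(c("sex", "age_band", "count") %in% names(x)))
    stop("population table needs columns sex, age_band, count")
  x$sex <- tolower(trimws(x$sex))
  if (!all(x$sex %in% .af_sexes))
    stop("sex must be 'men' or 'women'")
  x$age_band <- .normalise_band(x$age_band)
  if (any(!is.finite(x$count)) || any(x$count < 0))
    stop("population counts must be non-negative")
  need <- c("65-69", "70-74", "75-79", "80-84")
  for (s in .af_sexes) {
    miss <- setdiff(need, x$age_band[x$sex == s])
    if (length(miss))
      stop(sprintf("population table must cover ages 65-80 for %s; missing band(s): %s",
                   s, paste(miss, collapse = ", ")))
  }
  class(x) <- c("population_table", "data.frame")
  x
}

#' Per-single-year population from 5-year bands
#'
#' Expands a banded population table to single years of age by dividing each
#' band headcount by 5, restricted to the requested ages.
#'
#' @param pop a `population_table`.
#' @param ages integer ages to keep (default 65:80).
#' @return data frame with columns `sex`, `age`, `count`.
#' @export
single_year_population <- function(pop, ages = 65:80) {
  stopifnot(inherits(pop, "population_table"))
  out <- expand.grid(age = ages, sex = .af_sexes,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  band_of <- function(a) .af_bands[.band_index(a)]
  out$count <- mapply(function(a, s) {
    i <- which(pop$sex == s & pop$age_band == band_of(a))
    if (!length(i)) stop("population table lacks band ", band_of(a), " for ", s)
    sum(pop$count[i]) / 5
  }, out$age, out$sex)
  out[, c("sex", "age", "count")]
}
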