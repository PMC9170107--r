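.af_strategies <- c(non_af = "s0", treated_af = "t1", untreated_af = "t0")

# per-cycle inputs for a strategy at a given age
.cycle_params <- function(strategy, transitions, age) {
  code <- .af_strategies[[strategy]]
  i <- .band_index(age)
  list(p_death  = transitions$probs[[paste0("p_", code, "e2")]][i],
       p_stroke = transitions$probs[[paste0("p_", code, "e1")]][i],
       p_post_death = transitions$probs$p_e1e2[i],
       fatality = unname(acute_fatality(transitions, age)))
}

.poststroke_u <- function(qol, age) {
  if (age >= 75) qol$u_poststroke[["75+"]] else qol$u_poststroke[["65-74"]]
}

#' Run the Markov cohort model
#'
#' Propagates a closed cohort through the three-state model -- alive
#' pre-stroke, post-stroke, dead -- in annual cycles from `start_age` until
#' the terminal 100+ band has absorbed everyone.  Within a cycle, death from
#' any cause is applied first; survivors then suffer an incident stroke with
#' the age-banded stroke probability.  Incident strokes split by the
#' acute-stage fatality fraction into acute deaths and entrants to the
#' post-stroke state; the post-stroke state has its own total annual death
#' probability.  Life-years and QALYs are accrued under the configured
#' accrual convention (members who die during a cycle accrue a half, full or
#' zero year) and discounted at the configured rate.
#'
#' Utility weights: `u_baseline` while alive pre-stroke; the age-banded
#' post-stroke utility thereafter; stroke survivors accrue, in the stroke
#' cycle itself, the post-stroke utility minus the transient acute-stage
#' decrement (decrement times its duration in years).  Acute deaths accrue
#' the stroke-cycle weight for whatever cycle fraction the accrual convention
#' grants them.
#'
#' @param strategy `"non_af"`, `"treated_af"` or `"untreated_af"`: which
#'   stroke/death probability columns drive the alive pre-stroke state.
#' @param sex `"men"` or `"women"` (must match the transition table).
#' @param start_age starting age, between 65 and 80.
#' @param transitions a [transition_table()].
#' @param qol a [qol_params()].
#' @param config a [model_config()].
#' @return an object of class `cohort_trace`: a data frame with one row per
#'   cycle (`cycle`, `age`, start-of-cycle occupancies `alive`, `post_stroke`,
#'   `dead`, the cycle's `strokes` and `acute_deaths`, and undiscounted and
#'   discounted `ly`, `qaly`, `ly_disc`, `qaly_disc`), with the run inputs
#'   and the summary totals attached as attributes.  Use [summary()] for the
#'   totals and [simulate()] for a microsimulation replicate.
#' @examples
#' tr <- default_transition_table("men")
#' tt <- run_cohort("treated_af", "men", 65, tr)
#' summary(tt)
#' @export
run_cohort <- function(strategy = names(.af_strategies),
                       sex = c("men", "women"), start_age,
                       transitions, qol = default_qol_params(),
                       config = model_config()) {
  strategy <- match.arg(strategy)
  sex <- match.arg(sex)
  stopifnot(inherits(transitions, "transition_table"),
            inherits(qol, "qol_params"), inherits(config, "model_config"))
  if (!is.finite(start_age) || start_age < 65 || start_age > 80)
    stop("start_age must lie in [65, 80]")
  if (transitions$sex != sex)
    stop(sprintf("transition table is for %s, not %s", transitions$sex, sex))

  n_cycles <- config$terminal_age - start_age + 1L
  delta <- switch(config$accrual,
                  cycle_start = 1, cycle_end = 0, half_cycle = 0.5)
  w_acute <- qol$acute_decrement * qol$acute_duration

  ## post-stroke occupancy is split by age at stroke (<75 vs >=75) so that
  ## either post-stroke utility convention can be evaluated
  A <- 1; P_young <- 0; P_old <- 0; D <- 0
  rows <- vector("list", n_cycles)
  for (k in seq_len(n_cycles) - 1L) {
    age <- start_age + k
    cp <- .cycle_params(strategy, transitions, age)
    P <- P_young + P_old

    a_death  <- A * cp$p_death
    a_stroke <- A * (1 - cp$p_death) * cp$p_stroke
    acute    <- a_stroke * cp$fatality
    s_surv   <- a_stroke - acute
    a_stay   <- A - a_death - a_stroke
    p_death  <- P * cp$p_post_death
    py_stay  <- P_young * (1 - cp$p_post_death)
    po_stay  <- P_old   * (1 - cp$p_post_death)

    u_now <- .poststroke_u(qol, age)
    u_post_weighted <- if (config$poststroke_utility_by == "current_age") {
      P * u_now
    } else {
      P_young * qol$u_poststroke[["65-74"]] + P_old * qol$u_poststroke[["75+"]]
    }
    u_post_mean <- if (P > 0) u_post_weighted / P else u_now
    w_stroke <- u_now - w_acute   # stroke-cycle weight for incident strokes

    ly <- a_stay + s_surv + py_stay + po_stay +
      delta * (a_death + acute + p_death)
    qaly <- a_stay * qol$u_baseline + s_surv * w_stroke +
      (py_stay + po_stay) * u_post_mean +
      delta * (a_death * qol$u_baseline + acute * w_stroke +
               p_death * u_post_mean)
    disc <- (1 + config$discount_rate)^(-(k + config$discount_base))

    rows[[k + 1L]] <- c(cycle = k, age = age, alive = A, post_stroke = P,
                        dead = D, strokes = a_stroke, acute_deaths = acute,
                        ly = ly, qaly = qaly,
                        ly_disc = ly * disc, qaly_disc = qaly * disc)

    A <- a_stay
    if (age >= 75) {
      ## survivors entering post-stroke at >= 75 join the old bucket
      P_young <- py_stay
      P_old <- po_stay + s_surv
    } else {
      P_young <- py_stay + s_surv
      P_old <- po_stay
    }
    D <- D + a_death + acute + p_death
  }
  trace <- as.data.frame(do.call(rbind, rows))
  final <- c(alive = A, post_stroke = P_young + P_old, dead = D)

  structure(trace,
            class = c("cohort_trace", "data.frame"),
            strategy = strategy, sex = sex, start_age = start_age,
            transitions = transitions, qol = qol, config = config,
            final_occupancy = final,
            totals = c(life_years = sum(trace$ly_disc),
                       qalys = sum(trace$qaly_disc),
                       life_years_undiscounted = sum(trace$ly),
                       qalys_undiscounted = sum(trace$qaly),
                       strokes = sum(trace$strokes)))
}

#' @export
print.cohort_trace <- function(x, ...) {
  tot <- attr(x, "totals")
  cat(sprintf("Markov cohort trace: %s, %s, start age %d (%d cycles)\n",
              attr(x, "strategy"), attr(x, "sex"), attr(x, "start_age"),
              nrow(x)))
  cat(sprintf("  discounted life-years %.3f, QALYs %.3f; lifetime strokes per person %.4f\n",
              tot[["life_years"]], tot[["qalys"]], tot[["strokes"]]))
  invisible(x)
}

#' @export
summary.cohort_trace <- function(object, ...) {
  out <- c(as.list(attr(object, "totals")),
           list(strategy = attr(object, "strategy"),
                sex = attr(object, "sex"),
                start_age = attr(object, "start_age"),
                cycles = nrow(object),
                final_occupancy = attr(object, "final_occupancy")))
  class(out) <- "summary.cohort_trace"
  out
}

#' @export
print.summary.cohort_trace <- function(x, ...) {
  cat(sprintf("Cohort: %s, %s, start age %d; %d annual cycles\n",
              x$strategy, x$sex, x$start_age, x$cycles))
  cat(sprintf("  life-years  %8.3f discounted  (%8.3f undiscounted)\n",
              x$life_years, x$life_years_undiscounted))
  cat(sprintf("  QALYs       %8.3f discounted  (%8.3f undiscounted)\n",
              x$qalys, x$qalys_undiscounted))
  cat(sprintf("  lifetime incident strokes per person: %.4f\n", x$strokes))
  invisible(x)
}

#' @export
plot.cohort_trace <- function(x, ...) {
  graphics::matplot(x$age, cbind(x$alive, x$post_stroke, x$dead),
                    type = "l", lty = 1, lwd = 2,
                    col = c("#2166ac", "#d6604d", "grey40"),
                    xlab = "Age (years)", ylab = "State occupancy",
                    main = sprintf("%s, %s, start age %d",
                                   attr(x, "strategy"), attr(x, "sex"),
                                   attr(x, "start_age")), ...)
  graphics::legend("right", c("alive pre-stroke", "post-stroke", "dead"),
                   lty = 1, lwd = 2, col = c("#2166ac", "#d6604d", "grey40"),
                   bty = "n")
  invisible(x)
}

#' Life-year and QALY difference between treated and untreated AF
#'
#' Runs the cohort model for the anticoagulant-treated and untreated AF
#' profiles and returns lifetime discounted life-years and QALYs for each,
#' with their differences (treated minus untreated).
#'
#' @inheritParams run_cohort
#' @return an object of class `effectiveness_result`: a list with `sex`,
#'   `start_age`, a `totals` data frame (one row per strategy) and a
#'   `difference` vector (`life_years`, `qalys`).
#' @examples
#' eff <- effectiveness_difference("men", 65, default_transition_table("men"))
#' eff$difference
#' @export
effectiveness_difference <- function(sex = c("men", "women"), start_age,
                                     transitions,
                                     qol = default_qol_params(),
                                     config = model_config()) {
  sex <- match.arg(sex)
  tr1 <- run_cohort("treated_af", sex, start_age, transitions, qol, config)
  tr0 <- run_cohort("untreated_af", sex, start_age, transitions, qol, config)
  t1 <- attr(tr1, "totals"); t0 <- attr(tr0, "totals")
  totals <- data.frame(strategy = c("treated_af", "untreated_af"),
                       life_years = c(t1[["life_years"]], t0[["life_years"]]),
                       qalys = c(t1[["qalys"]], t0[["qalys"]]))
  structure(list(sex = sex, start_age = start_age, totals = totals,
                 difference = c(life_years = totals$life_years[1] - totals$life_years[2],
                                qalys = totals$qalys[1] - totals$qalys[2]),
                 config = config),
            class = "effectiveness_result")
}

#' @export
print.effectiveness_result <- function(x, ...) {
  cat(sprintf("Effectiveness of anticoagulation, %s starting at age %d (discount %.0f%%)\n",
              x$sex, x$start_age, 100 * x$config$discount_rate))
  tt <- x$totals
  cat(sprintf("  %-13s life-years %7.3f  QALYs %7.3f\n", "treated:",
              tt$life_years[1], tt$qalys[1]))
  cat(sprintf("  %-13s life-years %7.3f  QALYs %7.3f\n", "untreated:",
              tt$life_years[2], tt$qalys[2]))
  cat(sprintf("  %-13s life-years %7.3f  QALYs %7.3f\n", "difference:",
              x$difference[["life_years"]], x$difference[["qalys"]]))
  invisible(x)
}

#' Discount-rate sensitivity of the treatment effect
#'
#' Re-runs [effectiveness_difference()] at each supplied discount rate.
#'
#' @param rates numeric vector of annual discount rates, each in \[0, 0.10\].
#' @inheritParams run_cohort
#' @return data frame of class `discount_sensitivity`, one row per rate, with
#'   treated/untreated life-year and QALY totals and their differences.
#' @export
sensitivity_discount <- function(rates, sex = c("men", "women"), start_age,
                                 transitions, qol = default_qol_params(),
                                 config = model_config()) {
  sex <- match.arg(sex)
  if (!length(rates)) stop("at least one discount rate is required")
  rows <- lapply(rates, function(r) {
    cfg <- model_config(discount_rate = r, terminal_age = config$terminal_age,
                        accrual = config$accrual,
                        discount_base = config$discount_base,
                        poststroke_utility_by = config$poststroke_utility_by)
    e <- effectiveness_difference(sex, start_age, transitions, qol, cfg)
    data.frame(discount_rate = r,
               ly_treated = e$totals$life_years[1],
               ly_untreated = e$totals$life_years[2],
               ly_difference = e$difference[["life_years"]],
               qaly_treated = e$totals$qalys[1],
               qaly_untreated = e$totals$qalys[2],
               qaly_difference = e$difference[["qalys"]])
  })
  out <- do.call(rbind, rows)
  class(out) <- c("discount_sensitivity", "data.frame")
  out
}

#' Expected cumulative strokes over a fixed horizon
#'
#' Sum of incident strokes per person (acute deaths included) over the first
#' `horizon` annual cycles of the cohort model, undiscounted.
#'
#' @inheritParams run_cohort
#' @param horizon number of annual cycles, `>= 1`.
#' @return expected strokes per person over the horizon.
#' @export
cumulative_strokes <- function(strategy = names(.af_strategies),
                               sex = c("men", "women"), start_age, horizon,
                               transitions, qol = default_qol_params(),
                               config = model_config()) {
  if (!is.finite(horizon) || horizon < 1) stop("horizon must be >= 1")
  trace <- run_cohort(strategy, sex, start_age, transitions, qol, config)
  sum(trace$strokes[seq_len(min(horizon, nrow(trace)))])
}

#' Calibrate the unstated accrual and discounting conventions
#'
#' Published cohort analyses rarely state their cycle-correction or
#' discount-base conventions.  This selects, over the grid of accrual
#' conventions (`half_cycle`, `cycle_start`, `cycle_end`) crossed with the
#' discount base (0- or 1-based), the combination whose discounted life-years
#' for one anchor cell come closest to a published value, and returns the
#' corresponding frozen [model_config()].  Calibration touches only these two
#' switches, never the model parameters.
#'
#' @param transitions a [transition_table()] for the anchor cell's sex.
#' @param target_life_years the published discounted life-years anchor
#'   (default 13.585, treated men starting at 65).
#' @param strategy,sex,start_age the anchor cell (defaults: treated AF, men, 65).
#' @param qol a [qol_params()].
#' @param config a [model_config()] supplying everything but the two
#'   calibrated switches.
#' @return a `model_config` with `accrual` and `discount_base` set; the grid
#'   of candidate fits is attached as attribute `"grid"`.
#' @export
calibrate_conventions <- function(transitions, target_life_years = 13.585,
                                  strategy = "treated_af", sex = "men",
                                  start_age = 65,
                                  qol = default_qol_params(),
                                  config = model_config()) {
  grid <- expand.grid(accrual = c("half_cycle", "cycle_start", "cycle_end"),
                      discount_base = c(0L, 1L),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$life_years <- vapply(seq_len(nrow(grid)), function(i) {
    cfg <- model_config(discount_rate = config$discount_rate,
                        terminal_age = config$terminal_age,
                        accrual = grid$accrual[i],
                        discount_base = grid$discount_base[i],
                        poststroke_utility_by = config$poststroke_utility_by)
    attr(run_cohort(strategy, sex, start_age, transitions, qol, cfg),
         "totals")[["life_years"]]
  }, numeric(1))
  grid$abs_error <- abs(grid$life_years - target_life_years)
  best <- grid[which.min(grid$abs_error), ]
  out <- model_config(discount_rate = config$discount_rate,
                      terminal_age = config$terminal_age,
                      accrual = best$accrual,
                      discount_base = best$discount_base,
                      poststroke_utility_by = config$poststroke_utility_by)
  attr(out, "grid") <- grid
  out
}
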