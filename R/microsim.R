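#' Microsimulation of individual trajectories
#'
#' Simulates `n` independent individuals through exactly the per-cycle
#' probabilities, accrual convention and discounting used by [run_cohort()],
#' and returns Monte-Carlo means and standard errors of lifetime discounted
#' life-years, QALYs and incident stroke counts.  This is an independent
#' stochastic estimator of the deterministic cohort recursion: the two must
#' agree within Monte-Carlo error, which makes it the standard cross-check
#' for the cohort implementation.
#'
#' The simulation is vectorised over individuals, so `n` in the hundreds of
#' thousands runs in seconds.
#'
#' @inheritParams run_cohort
#' @param n number of simulated individuals, `>= 1`.
#' @param seed integer seed; the run is reproducible given the seed.
#' @return an object of class `microsim_result`: list with `mean` and `se`
#'   (each named `life_years`, `qalys`, `strokes`), `n` and `seed`.
#' @examples
#' tr <- default_transition_table("men")
#' microsim_cohort("treated_af", "men", 65, n = 5000, seed = 1,
#'                 transitions = tr)
#' @export
microsim_cohort <- function(strategy = names(.af_strategies),
                            sex = c("men", "women"), start_age, n, seed,
                            transitions, qol = default_qol_params(),
                            config = model_config()) {
  strategy <- match.arg(strategy)
  sex <- match.arg(sex)
  stopifnot(inherits(transitions, "transition_table"),
            inherits(qol, "qol_params"), inherits(config, "model_config"))
  if (!is.finite(n) || n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  if (!is.finite(start_age) || start_age < 65 || start_age > 80)
    stop("start_age must lie in [65, 80]")
  if (transitions$sex != sex)
    stop(sprintf("transition table is for %s, not %s", transitions$sex, sex))

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  delta <- switch(config$accrual,
                  cycle_start = 1, cycle_end = 0, half_cycle = 0.5)
  w_acute <- qol$acute_decrement * qol$acute_duration
  n_cycles <- config$terminal_age - start_age + 1L

  ## states: 0 alive pre-stroke, 1 post-stroke (onset < 75),
  ##         2 post-stroke (onset >= 75), 3 dead
  state <- integer(n)
  ly <- numeric(n); qaly <- numeric(n); strokes <- numeric(n)
  for (k in seq_len(n_cycles) - 1L) {
    age <- start_age + k
    cp <- .cycle_params(strategy, transitions, age)
    u_now <- .poststroke_u(qol, age)
    w_stroke <- u_now - w_acute
    disc <- (1 + config$discount_rate)^(-(k + config$discount_base))

    alive <- state == 0L
    post  <- state == 1L | state == 2L
    if (!any(alive) && !any(post)) break

    u_post <- if (config$poststroke_utility_by == "current_age") {
      rep(u_now, n)
    } else {
      ifelse(state == 1L, qol$u_poststroke[["65-74"]], qol$u_poststroke[["75+"]])
    }

    u1 <- stats::runif(n); u2 <- stats::runif(n); u3 <- stats::runif(n)
    a_dies   <- alive & u1 < cp$p_death
    a_stroke <- alive & !a_dies & u2 < cp$p_stroke
    a_acute  <- a_stroke & u3 < cp$fatality
    p_dies   <- post & u1 < cp$p_post_death

    strokes <- strokes + a_stroke
    frac <- numeric(n)
    wt <- numeric(n)
    stays <- (alive & !a_dies & !a_stroke) | (a_stroke & !a_acute) |
      (post & !p_dies)
    frac[stays] <- 1
    frac[a_dies | a_acute | p_dies] <- delta
    wt[alive] <- qol$u_baseline
    wt[post] <- u_post[post]
    wt[a_stroke] <- w_stroke
    ly <- ly + frac * disc
    qaly <- qaly + frac * wt * disc

    state[a_dies | a_acute | p_dies] <- 3L
    new_post <- a_stroke & !a_acute
    state[new_post] <- if (age >= 75) 2L else 1L
  }
  est <- cbind(life_years = ly, qalys = qaly, strokes = strokes)
  structure(list(strategy = strategy, sex = sex, start_age = start_age,
                 mean = colMeans(est),
                 se = apply(est, 2, stats::sd) / sqrt(n),
                 n = n, seed = seed),
            class = "microsim_result")
}

#' @export
print.microsim_result <- function(x, ...) {
  cat(sprintf("Microsimulation (%s, %s, start age %d; n = %d, seed %s)\n",
              x$strategy, x$sex, x$start_age, x$n, format(x$seed)))
  for (nm in names(x$mean))
    cat(sprintf("  %-11s %8.4f (SE %.4f)\n", nm, x$mean[[nm]], x$se[[nm]]))
  invisible(x)
}

#' Simulate individual trajectories matching a cohort trace
#'
#' [simulate()] method for [run_cohort()] objects: reruns the same strategy,
#' sex, start age, parameter tables and conventions as an individual-level
#' microsimulation via [microsim_cohort()].
#'
#' @param object a `cohort_trace`.
#' @param nsim number of replicate microsimulations.
#' @param seed integer seed for the first replicate; replicate `i` uses
#'   `seed + i - 1`.
#' @param n individuals per replicate.
#' @param ... unused.
#' @return a single `microsim_result` when `nsim = 1`, else a list of them.
#' @export
simulate.cohort_trace <- function(object, nsim = 1, seed = 1L, n = 10000L,
                                  ...) {
  runs <- lapply(seq_len(nsim), function(i)
    microsim_cohort(attr(object, "strategy"), attr(object, "sex"),
                    attr(object, "start_age"), n = n, seed = seed + i - 1L,
                    transitions = attr(object, "transitions"),
                    qol = attr(object, "qol"),
                    config = attr(object, "config")))
  if (nsim == 1) runs[[1]] else runs
}
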