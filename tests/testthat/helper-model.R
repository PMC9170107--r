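# Shared fixtures and independent oracles for the test suite.

published_tables <- list(men = default_transition_table("men"),
                         women = default_transition_table("women"))

# the calibrated run-time conventions used throughout (anchored once on the
# published treated-men-65 discounted life-years)
calibrated_config <- calibrate_conventions(published_tables$men)

# published effectiveness table: life-years and QALYs, treated / untreated /
# difference, for men and women starting at 65, 70, 75, 80 (discounted 2%)
published_effectiveness <- data.frame(
  sex = rep(c("men", "women"), each = 4),
  age = rep(c(65, 70, 75, 80), 2),
  ly_treated    = c(13.585, 11.086, 8.620, 6.400, 16.818, 14.022, 11.137, 8.409),
  ly_untreated  = c(12.858, 10.405, 8.001, 5.858, 16.187, 13.396, 10.529, 7.845),
  ly_difference = c(0.727, 0.681, 0.619, 0.542, 0.631, 0.626, 0.607, 0.564),
  qaly_treated    = c(13.076, 10.657, 8.268, 6.187, 15.999, 13.323, 10.566, 8.052),
  qaly_untreated  = c(12.217, 9.867, 7.558, 5.593, 15.142, 12.507, 9.803, 7.394),
  qaly_difference = c(0.859, 0.790, 0.710, 0.594, 0.856, 0.816, 0.763, 0.658))

# transition table with the same annual probabilities in every pre-terminal
# band (terminal 100+ band keeps its forced values)
make_flat_table <- function(p_stroke = 0, p_death = 0, p_post_death = 0,
                            sex = "men", fatality = c(0, 0)) {
  probs <- data.frame(
    age_band = c("65-69", "70-74", "75-79", "80-84", "85-89", "90-94",
                 "95-99", "100+"))
  for (cc in c("p_s0e1", "p_t1e1", "p_t0e1"))
    probs[[cc]] <- c(rep(p_stroke, 7), 0)
  for (cc in c("p_s0e2", "p_t1e2", "p_t0e2"))
    probs[[cc]] <- c(rep(p_death, 7), 1)
  probs$p_e1e2 <- c(rep(p_post_death, 7), 1)
  transition_table(probs, sex = sex,
                   acute_fatality = c(`65-74` = fatality[1],
                                      `75+` = fatality[2]))
}

# independent two-sided Fisher oracle: direct hypergeometric enumeration of
# all tables with the observed margins, summing probabilities not exceeding
# the observed one (with the conventional relative guard for ties)
fisher_enum <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  if (m == 0 || n2 == 0 || k == 0 || (b + d) == 0) return(1)
  xs <- max(0, k - n2):min(k, m)
  pr <- stats::dhyper(xs, m, n2, k)
  sum(pr[pr <= stats::dhyper(a, m, n2, k) * (1 + 1e-7)])
}

# independent Clopper-Pearson oracle: bisection on the binomial tail
cp_bisect <- function(x, n, conf.level = 0.95) {
  alpha <- 1 - conf.level
  lower <- if (x == 0) 0 else
    stats::uniroot(function(p) stats::pbinom(x - 1, n, p, lower.tail = FALSE) - alpha / 2,
                   c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  upper <- if (x == n) 1 else
    stats::uniroot(function(p) stats::pbinom(x, n, p) - alpha / 2,
                   c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  c(lower, upper)
}
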