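toy_population <- function(per_band = 500000) {
  population_table(expand.grid(
    sex = c("men", "women"),
    age_band = c("65-69", "70-74", "75-79", "80-84"),
    count = per_band, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE))
}

test_that("detected prevalence thresholds on the score", {
  dist <- score_distribution(c(`0` = 3, `1` = 8, `2` = 2, `3` = 2))
  expect_equal(detected_prevalence(dist, 1607, 1), 12 / 1607)
  expect_equal(detected_prevalence(dist, 1607, 0), 15 / 1607)
  expect_equal(detected_prevalence(dist, 1607, 3), 2 / 1607)
  expect_equal(detected_prevalence(NULL, 1607), 0)
  expect_error(detected_prevalence(dist, 0), "positive")
})

test_that("a zero population projects to zero everywhere", {
  pr <- project(toy_population(0), 12 / 1607, published_tables$men,
                published_tables$women, config = calibrated_config)
  expect_true(all(pr$identified == 0))
  expect_true(all(pr$strokes_prevented == 0))
  expect_equal(unname(attr(pr, "totals")[["strokes_prevented"]]), 0)
})

test_that("projection matches an independent spreadsheet-style recursion", {
  # toy flat tables so the oracle is a short hand recursion
  toy_m <- make_flat_table(p_stroke = 0.02, p_death = 0.03,
                           p_post_death = 0.05, fatality = c(0.1, 0.1))
  toy_w <- make_flat_table(p_stroke = 0.01, p_death = 0.02,
                           p_post_death = 0.04, sex = "women",
                           fatality = c(0.1, 0.1))
  treat <- function(tab, scale) {
    t2 <- tab$probs
    t2$p_t1e1 <- t2$p_t1e1 * scale
    transition_table(t2, tab$sex, tab$acute_fatality)
  }
  toy_m <- treat(toy_m, 0.6); toy_w <- treat(toy_w, 0.6)

  hand_strokes <- function(ps, pd, horizon) {
    alive <- 1; total <- 0
    for (k in seq_len(horizon)) {
      s <- alive * (1 - pd) * ps
      total <- total + s
      alive <- alive * (1 - pd) * (1 - ps)
    }
    total
  }
  prev <- 12 / 1607
  pr <- project(toy_population(500000), prev, toy_m, toy_w, horizon = 10,
                ages = 65)
  men_row <- pr[pr$sex == "men", ]
  c_hand <- hand_strokes(0.02, 0.03, 10) - hand_strokes(0.02 * 0.6, 0.03, 10)
  expect_equal(men_row$identified, 100000 * prev)
  expect_equal(men_row$risk_reduction, c_hand)
  expect_equal(men_row$strokes_prevented, 100000 * prev * c_hand)
})

test_that("projection identities and dominance hold", {
  pr1 <- project(toy_population(500000), 12 / 1607, published_tables$men,
                 published_tables$women, config = calibrated_config)
  pr2 <- project(toy_population(1000000), 12 / 1607, published_tables$men,
                 published_tables$women, config = calibrated_config)
  # linearity in the population
  expect_equal(pr2$identified, 2 * pr1$identified)
  expect_equal(pr2$strokes_prevented, 2 * pr1$strokes_prevented)
  # e / b = c and d = 1 / c in every cell
  expect_equal(pr1$strokes_prevented / pr1$identified, pr1$risk_reduction)
  expect_equal(pr1$nnt, 1 / pr1$risk_reduction)
  # treating can only prevent strokes under the published tables
  expect_true(all(pr1$risk_reduction >= 0))
  # banded risk evaluation agrees with single-year within the same band edge
  prb <- project(toy_population(500000), 12 / 1607, published_tables$men,
                 published_tables$women, config = calibrated_config,
                 risk_by = "band")
  expect_equal(prb$risk_reduction[prb$age == 65],
               pr1$risk_reduction[pr1$age == 65])
  expect_error(project(toy_population(), 1.5, published_tables$men,
                       published_tables$women), "fraction")
})
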