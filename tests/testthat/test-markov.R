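test_that("a cohort that only dies at 100 accrues the forced life-years", {
  flat <- make_flat_table()
  for (conv in list(c("half_cycle", 35.5), c("cycle_start", 36),
                    c("cycle_end", 35))) {
    cfg <- model_config(discount_rate = 0, accrual = conv[1])
    tr <- run_cohort("treated_af", "men", 65, flat, config = cfg)
    expect_equal(sum(tr$ly), as.numeric(conv[2]))
    expect_equal(attr(tr, "final_occupancy")[["dead"]], 1)
  }
})

test_that("state occupancies are conserved and death is absorbing", {
  for (sex in c("men", "women")) {
    for (strategy in c("non_af", "treated_af", "untreated_af")) {
      for (age0 in c(65, 73, 80)) {
        tr <- run_cohort(strategy, sex, age0, published_tables[[sex]],
                         config = calibrated_config)
        occ <- tr$alive + tr$post_stroke + tr$dead
        expect_lt(max(abs(occ - 1)), 1e-12)
        expect_true(all(diff(tr$dead) >= 0))
        expect_equal(attr(tr, "final_occupancy")[["dead"]], 1,
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("identical strategy columns give exactly zero differences", {
  trm <- published_tables$men
  same <- trm
  same$probs$p_t1e1 <- same$probs$p_t0e1
  same$probs$p_t1e2 <- same$probs$p_t0e2
  same <- transition_table(same$probs, "men")
  e <- effectiveness_difference("men", 70, same, config = calibrated_config)
  expect_identical(unname(e$difference), c(0, 0))
})

test_that("cumulative strokes follow the hand recursion", {
  expect_equal(cumulative_strokes("treated_af", "men", 65, 10,
                                  make_flat_table(p_stroke = 0)), 0)
  toy <- make_flat_table(p_stroke = 0.01, p_death = 0)
  expect_equal(cumulative_strokes("untreated_af", "men", 65, 2, toy),
               0.01 + 0.99 * 0.01)
  # treated never strokes more than untreated under the published tables
  for (sex in c("men", "women")) for (age0 in 65:80) {
    expect_gte(cumulative_strokes("untreated_af", sex, age0, 10,
                                  published_tables[[sex]],
                                  config = calibrated_config),
               cumulative_strokes("treated_af", sex, age0, 10,
                                  published_tables[[sex]],
                                  config = calibrated_config))
  }
})

test_that("discounting is monotone and the sensitivity table is consistent", {
  expect_error(sensitivity_discount(numeric(0), "men", 65,
                                    published_tables$men),
               "at least one")
  sens <- sensitivity_discount(c(0, 0.02, 0.04), "men", 65,
                               published_tables$men,
                               config = calibrated_config)
  expect_true(all(diff(sens$ly_treated) < 0))
  expect_true(all(diff(sens$qaly_untreated) < 0))
  e <- effectiveness_difference("men", 65, published_tables$men,
                                config = calibrated_config)
  expect_equal(sens$qaly_difference[sens$discount_rate == 0.02],
               unname(e$difference[["qalys"]]))
})

test_that("QALY gains shrink with starting age within each sex", {
  qt <- qaly_table(config = calibrated_config)
  for (s in c("men", "women"))
    expect_true(all(diff(qt$qaly_difference[qt$sex == s]) < 0))
})

test_that("input domain errors are raised", {
  expect_error(run_cohort("treated_af", "men", 60, published_tables$men),
               "\\[65, 80\\]")
  expect_error(run_cohort("treated_af", "men", 81, published_tables$men),
               "\\[65, 80\\]")
  expect_error(run_cohort("treated_af", "women", 70, published_tables$men),
               "for men")
  expect_error(cumulative_strokes("treated_af", "men", 65, 0,
                                  published_tables$men), "horizon")
})

test_that("microsimulation is reproducible and matches degenerate cases", {
  trm <- published_tables$men
  m1 <- microsim_cohort("treated_af", "men", 65, n = 2000, seed = 5,
                        transitions = trm, config = calibrated_config)
  m2 <- microsim_cohort("treated_af", "men", 65, n = 2000, seed = 5,
                        transitions = trm, config = calibrated_config)
  expect_identical(m1$mean, m2$mean)
  expect_error(microsim_cohort("treated_af", "men", 65, n = 0, seed = 1,
                               transitions = trm), "n must be")
  # with death certain each cycle, every trajectory lasts one half-cycle
  doom <- make_flat_table(p_death = 1)
  md <- microsim_cohort("treated_af", "men", 65, n = 500, seed = 9,
                        transitions = doom,
                        config = model_config(discount_rate = 0))
  expect_equal(unname(md$mean[["life_years"]]), 0.5)
  expect_equal(unname(md$se[["life_years"]]), 0)
})

test_that("microsimulation agrees with the cohort recursion", {
  tr <- run_cohort("untreated_af", "women", 70, published_tables$women,
                   config = calibrated_config)
  ms <- simulate(tr, seed = 31, n = 50000)
  tot <- attr(tr, "totals")
  for (nm in c("life_years", "qalys", "strokes")) {
    z <- (ms$mean[[nm]] - tot[[nm]]) / ms$se[[nm]]
    expect_lt(abs(z), 3)
  }
})
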