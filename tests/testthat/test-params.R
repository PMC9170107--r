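test_that("shipped transition tables parse to the published fractions", {
  trm <- published_tables$men
  trw <- published_tables$women
  expect_equal(trm$probs$p_t1e1[trm$probs$age_band == "65-69"], 0.01006)
  expect_equal(trw$probs$p_t0e2[trw$probs$age_band == "100+"], 1.0)
  expect_equal(trm$probs$p_e1e2[trm$probs$age_band == "95-99"], 0.55675)
})

test_that("transition table validation rejects malformed input", {
  bad <- tempfile(fileext = ".csv")
  raw <- read.csv(system.file("extdata", "transitions_men.csv",
                              package = "afscreen"))
  raw$p_s0e1[1] <- "150%"
  write.csv(raw, bad, row.names = FALSE)
  expect_error(read_transition_table(bad, "men"), "outside \\[0, 1\\]")

  raw2 <- read.csv(system.file("extdata", "transitions_men.csv",
                               package = "afscreen"))
  raw2 <- raw2[raw2$age_band != "75-79", ]
  write.csv(raw2, bad, row.names = FALSE)
  expect_error(read_transition_table(bad, "men"), "75-79")

  raw3 <- read.csv(system.file("extdata", "transitions_men.csv",
                               package = "afscreen"))
  raw3$p_t1e2[raw3$age_band == "100+"] <- 50
  write.csv(raw3, bad, row.names = FALSE)
  expect_error(read_transition_table(bad, "men"), "terminal")
})

test_that("band lookup is piecewise constant and closed on the left", {
  trm <- published_tables$men
  trw <- published_tables$women
  expect_equal(lookup_transition(trm, 67, "p_t1e1"), 0.01006)
  expect_equal(lookup_transition(trw, 102, "p_t0e2"), 1.0)
  expect_error(lookup_transition(trm, 60, "p_t1e1"), "age below 65")
  # midpoints of every band agree with direct row access, for every column
  lowers <- c(65, 70, 75, 80, 85, 90, 95, 100)
  for (i in seq_along(lowers)) {
    for (cc in c("p_s0e1", "p_s0e2", "p_t1e1", "p_t1e2", "p_t0e1", "p_t0e2",
                 "p_e1e2")) {
      expect_identical(lookup_transition(trm, lowers[i] + 2.5, cc),
                       trm$probs[[cc]][i])
    }
    # left edge belongs to its own band
    expect_identical(lookup_transition(trm, lowers[i], "p_e1e2"),
                     trm$probs$p_e1e2[i])
  }
})

test_that("acute-stage fatality switches exactly at age 75", {
  trm <- published_tables$men
  expect_equal(acute_fatality(trm, 70), 0.057)
  expect_equal(acute_fatality(trm, 74), 0.057)
  expect_equal(acute_fatality(trm, 75), 0.101)
  expect_equal(acute_fatality(trm, 90), 0.101)
  expect_error(acute_fatality(trm, 60), "age below 65")
})

test_that("write/read round trip preserves all probabilities", {
  for (sex in c("men", "women")) {
    tab <- published_tables[[sex]]
    f <- tempfile(fileext = ".csv")
    write_transition_table(tab, f)
    back <- read_transition_table(f, sex)
    expect_equal(back$probs, tab$probs)
  }
})

test_that("utility parameters load with the published values", {
  q <- default_qol_params()
  expect_equal(q$u_baseline, 1.0)
  expect_equal(q$acute_decrement, 0.14)
  expect_equal(q$acute_duration, 0.25)
  expect_equal(unname(q$u_poststroke), c(0.68, 0.56))
  expect_error(qol_params(u_baseline = 1.2), "\\[0, 1\\]")
  expect_error(qol_params(acute_decrement = -0.1), ">= 0")
})

test_that("model configuration validates its ranges", {
  expect_error(model_config(discount_rate = 0.2), "\\[0, 0.10\\]")
  expect_error(model_config(discount_base = 2), "0 or 1")
  cfg <- model_config(discount_rate = 0, accrual = "cycle_end",
                      discount_base = 1L)
  expect_s3_class(cfg, "model_config")
})

test_that("population tables validate coverage and expand to single years", {
  pop <- read_population(system.file("extdata", "population_synthetic.csv",
                                     package = "afscreen"))
  sy <- single_year_population(pop)
  expect_equal(nrow(sy), 32)
  expect_equal(sy$count[sy$sex == "men" & sy$age == 65],
               pop$count[pop$sex == "men" & pop$age_band == "65-69"] / 5)
  expect_equal(sy$count[sy$sex == "women" & sy$age == 80],
               pop$count[pop$sex == "women" & pop$age_band == "80-84"] / 5)
  expect_error(population_table(data.frame(sex = "men", age_band = "65-69",
                                           count = 10)),
               "missing band")
  expect_error(population_table(data.frame(sex = rep(c("men", "women"), each = 4),
                                           age_band = rep(c("65-69", "70-74",
                                                            "75-79", "80-84"), 2),
                                           count = -1)),
               "non-negative")
})
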