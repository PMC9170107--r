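test_that("detection rates and their exact intervals behave", {
  d <- detection_rate(15, 1607)
  expect_equal(round(100 * d$rate, 2), 0.93)
  expect_equal(round(100 * detection_rate(10, 628)$rate, 2), 1.59)
  z <- detection_rate(0, 100)
  expect_equal(z$rate, 0)
  expect_equal(z$lower, 0)
  expect_error(detection_rate(5, 0), "positive")
  expect_error(detection_rate(20, 10), "n_screened")
  # interval always contains the point estimate; width shrinks with n
  widths <- sapply(c(50, 200, 800, 3200), function(n) {
    dd <- detection_rate(round(0.2 * n), n)
    expect_gte(dd$rate, dd$lower); expect_lte(dd$rate, dd$upper)
    dd$upper - dd$lower
  })
  expect_true(all(diff(widths) < 0))
})

test_that("number needed to screen is the raw quotient", {
  expect_equal(round(nns(15, 1607)), 107)
  expect_equal(nns(10, 628), 62.8)
  expect_equal(nns(100, 100), 1)
  expect_warning(v <- nns(0, 50), "infinite")
  expect_identical(v, Inf)
})

test_that("the exact test matches direct hypergeometric enumeration", {
  expect_equal(fisher_exact(contingency_2x2(5, 95, 10, 190)), 1)
  expect_equal(fisher_exact(contingency_2x2(2, 8, 6, 4)),
               fisher_enum(2, 8, 6, 4), tolerance = 1e-12)
  expect_warning(p <- fisher_exact(contingency_2x2(0, 0, 3, 4)),
                 "degenerate")
  expect_equal(p, 1)
  expect_error(contingency_2x2(-1, 2, 3, 4), "non-negative")
  expect_error(contingency_2x2(0, 0, 0, 0), "positive")
})

test_that("kappa matches hand computation and its invariances", {
  a <- c(rep("x", 25), rep("y", 75))
  expect_equal(cohen_kappa(a, a), 1)
  # agreement table [[20, 5], [10, 65]]: p_o = 0.85, p_e = 0.60
  r1 <- c(rep("A", 25), rep("B", 75))
  r2 <- c(rep("A", 20), rep("B", 5), rep("A", 10), rep("B", 65))
  expect_equal(cohen_kappa(r1, r2), 0.625)
  # invariant under relabelling
  swap <- function(x) ifelse(x == "A", "Z", "Q")
  expect_equal(cohen_kappa(swap(r1), swap(r2)), 0.625)
  # independent raters give near-zero kappa
  set.seed(17)
  x <- sample(c("AF", "non-AF"), 10000, TRUE)
  y <- sample(c("AF", "non-AF"), 10000, TRUE)
  expect_lt(abs(cohen_kappa(x, y)), 0.05)
  expect_warning(k <- cohen_kappa(rep("A", 5), rep("A", 5)), "undefined")
  expect_true(is.na(k))
  expect_error(cohen_kappa(character(0), character(0)), "non-empty")
})

test_that("score summaries reproduce the printed means and SDs", {
  chads2 <- score_distribution(c(`0` = 3, `1` = 8, `2` = 2, `3` = 2))
  s <- score_summary(chads2)
  expect_equal(round(unname(s), 1), c(1.2, 0.9))
  vasc <- score_distribution(c(`1` = 1, `2` = 5, `3` = 6, `4` = 2, `5` = 1))
  s2 <- score_summary(vasc)
  expect_equal(round(unname(s2), 1), c(2.8, 1.0))
  s3 <- score_summary(score_distribution(c(`2` = 10)))
  expect_equal(unname(s3), c(2, 0))
  expect_warning(s4 <- score_summary(score_distribution(c(`3` = 1))),
                 "undefined")
  expect_true(is.na(s4[["sd"]]))
})

test_that("diagnostic accuracy matches hand arithmetic and the exact oracle", {
  perfect <- diag_accuracy(contingency_2x2(30, 0, 0, 990))
  expect_equal(perfect$sensitivity[["estimate"]], 1)
  expect_equal(perfect$specificity[["estimate"]], 1)
  da <- diag_accuracy(contingency_2x2(29, 1, 40, 950))
  expect_equal(da$sensitivity[["estimate"]], 29 / 30)
  expect_equal(da$specificity[["estimate"]], 950 / 990)
  # Clopper-Pearson interval for 29/30 equals the bisection oracle
  oracle <- cp_bisect(29, 30)
  expect_equal(unname(da$sensitivity[c("lower", "upper")]), oracle,
               tolerance = 1e-6)
  w <- diag_accuracy(contingency_2x2(29, 1, 40, 950), ci = "wilson")
  expect_true(w$sensitivity[["lower"]] > 0.8 && w$sensitivity[["upper"]] <= 1)
  expect_error(diag_accuracy(contingency_2x2(0, 0, 5, 5)), "positive")
})

test_that("risk scores follow their definitions", {
  r <- compute_scores(data.frame(age = 80, sex = "women", chf = 0,
                                 hypertension = 1, diabetes = 0,
                                 stroke_tia = 0, vascular = 0))
  expect_equal(c(r$chads2, r$cha2ds2_vasc), c(2L, 4L))
  r2 <- compute_scores(data.frame(age = 66, sex = "men", chf = 0,
                                  hypertension = 0, diabetes = 0,
                                  stroke_tia = 0, vascular = 0))
  expect_equal(c(r2$chads2, r2$cha2ds2_vasc), c(0L, 1L))
  expect_error(compute_scores(data.frame(age = 70, sex = "men")),
               "component field")
  # every subject 65+ scores at least 1 on the sex/age-extended scale, and
  # never less than on the simpler scale
  set.seed(3)
  rec <- data.frame(age = runif(500, 65, 100),
                    sex = sample(c("men", "women"), 500, TRUE),
                    chf = rbinom(500, 1, 0.3), hypertension = rbinom(500, 1, 0.4),
                    diabetes = rbinom(500, 1, 0.2), stroke_tia = rbinom(500, 1, 0.1),
                    vascular = rbinom(500, 1, 0.2))
  sc <- compute_scores(rec)
  expect_true(all(sc$cha2ds2_vasc >= 1))
  expect_true(all(sc$cha2ds2_vasc >= sc$chads2))
})

test_that("stratified detection validates its inputs", {
  fx <- fixture_table4()
  expect_error(stratified_detection(fx, "smoking"), "unknown factor")
  tiny <- fx[fx$chf == 1 & !is.na(fx$chf), ]
  expect_warning(expect_warning(stratified_detection(tiny, "chf"),
                                "empty stratum"),
                 "degenerate margin")
})
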