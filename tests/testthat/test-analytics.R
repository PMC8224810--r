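test_that("attainment percentages match known cohort counts", {
  w <- therapeutic_window("trough")
  # 14 of 31 within, 2 below, 15 above
  values <- c(rep(30, 2), rep(75, 14), rep(150, 15))
  s <- attainment_summary(values, w)
  expect_equal(s$n, c(2, 14, 15))
  expect_equal(s$percent[s$category == "within"], 45.2)
  expect_equal(sum(s$n), 31)
  # 8 of 31 within the AUC window
  s2 <- attainment_summary(c(rep(1500, 8), rep(3000, 22), 800),
                           therapeutic_window("auc"))
  expect_equal(s2$percent[s2$category == "within"], 25.8)
  # all inside
  s3 <- attainment_summary(rep(60, 10), w)
  expect_equal(s3$percent, c(0, 100, 0))
  # invariant to patient ordering
  expect_equal(attainment_summary(sample(values), w), s)
})

test_that("percentages always recompute exactly from their counts", {
  w <- therapeutic_window("trough")
  set.seed(5)
  values <- runif(37, 10, 200)
  s <- attainment_summary(values, w)
  expect_equal(s$percent, round(100 * s$n / 37, 1))
  expect_equal(sum(s$percent), 100, tolerance = 0.15)  # rounding drift only
})

test_that("benefit by exposure-and-adjustment group matches hand counts", {
  # groups of 9/8/6 with 7/5/1 responders
  adequate <- rep(c(TRUE, FALSE, FALSE), c(9, 8, 6))
  changed <- rep(c(FALSE, TRUE, FALSE), c(9, 8, 6))
  benefit <- c(rep(TRUE, 7), rep(FALSE, 2), rep(TRUE, 5), rep(FALSE, 3),
               TRUE, rep(FALSE, 5))
  b <- benefit_by_group(adequate, changed, benefit)
  expect_equal(b$benefit_percent, c(77.8, 62.5, 16.7))
  # groups of 4/11/8 with 3/8/1 responders
  b2 <- benefit_by_group(rep(c(TRUE, FALSE, FALSE), c(4, 11, 8)),
                         rep(c(FALSE, TRUE, FALSE), c(4, 11, 8)),
                         c(rep(TRUE, 3), FALSE, rep(TRUE, 8), rep(FALSE, 3),
                           TRUE, rep(FALSE, 7)))
  expect_equal(b2$benefit_percent, c(75, 72.7, 12.5))
  # zero responders and empty groups
  b3 <- benefit_by_group(c(TRUE, TRUE), c(FALSE, FALSE), c(FALSE, FALSE))
  expect_equal(b3$benefit_percent[1], 0)
  expect_true(is.na(b3$benefit_percent[2]))
})

test_that("reduction proportions reproduce the printed action table", {
  actions <- read.csv(sunidose_example("example_toxicity_dose_actions.csv"))
  r <- reduction_proportions(actions)
  expect_equal(r$n_decrease[r$strategy == "clinical_dose"], 7L)
  expect_equal(r$percent_int, c(41L, 82L, 88L))
  expect_equal(r$fraction, c(7, 14, 15) / 17)
  # all-zero changes
  r0 <- reduction_proportions(data.frame(initial_dose = c(50, 50),
                                         model_dose = c(50, 50)))
  expect_equal(r0$percent, 0)
})

test_that("toxicity stratification by exposure matches hand counts", {
  cat5_9 <- rep(c("within", "above"), c(9, 14))
  toxic <- c(rep(TRUE, 5), rep(FALSE, 4), rep(TRUE, 11), rep(FALSE, 3))
  t1 <- toxicity_by_exposure(cat5_9, toxic)
  expect_equal(t1$percent_int, c(56L, 79L))
  t0 <- toxicity_by_exposure(rep("within", 4), rep(FALSE, 4))
  expect_equal(t0$percent[1], 0)
  # below-target patients are excluded from the stratification
  t2 <- toxicity_by_exposure(c("below", "within", "within"),
                             c(TRUE, TRUE, FALSE))
  expect_equal(t2$n, c(2L, 0L))
})

test_that("action concordance counts matched action classes", {
  a <- c("decrease", "keep", "increase")
  expect_equal(action_concordance(a, a)$action_match, 1)
  expect_equal(action_concordance(a, c("keep", "decrease", "keep"))$action_match, 0)
  # hand count over the printed 17-patient action table: the two
  # mismatching rows are keep-vs-decrease and increase-vs-keep
  actions <- read.csv(sunidose_example("example_toxicity_dose_actions.csv"))
  cc <- action_concordance(
    classify_action(actions$initial_dose, actions$cmin_dose),
    classify_action(actions$initial_dose, actions$auc_dose),
    dose_a = actions$cmin_dose, dose_b = actions$auc_dose)
  expect_equal(cc$action_match, 15 / 17)
  expect_lt(cc$dose_match, cc$action_match)
  expect_error(action_concordance(a, a[1:2]), "length")
})

test_that("association tests match their textbook formulas", {
  x <- c(1.1, 2.3, 3.2, 4.0)
  t0 <- exposure_ttest(c(x, x), rep(c("a", "b"), each = 4))
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p_value, 1)
  # identical row proportions -> chi-square 0
  expect_equal(exposure_chisq(matrix(c(10, 5, 20, 10), 2))$statistic, 0)
  # hand-computed Pearson statistic on {{5,4},{11,3}}
  tab <- matrix(c(5, 11, 4, 3), 2)
  n <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  hand <- sum((tab - expected)^2 / expected)
  expect_equal(exposure_chisq(tab)$statistic, hand)
  expect_error(exposure_ttest(1:4, c("a", "a", "a", "b")), "at least two")
})

test_that("type-I error of the exposure t-test is calibrated", {
  # flat exposure-benefit link: rejections should occur at ~5%
  pop <- toy_pop()
  link <- tox_efficacy_link(benefit_intercept = 0, benefit_slope = 0)
  rej <- 0; n_rep <- 400
  for (r in seq_len(n_rep)) {
    coh <- generate_cohort(pop, cohort_config(60, outcome = link,
                                              seed = 50000 + r))
    p <- coh$patients
    if (length(unique(p$clinical_benefit)) < 2 ||
        min(table(p$clinical_benefit)) < 2) next
    tt <- exposure_ttest(log(p$true_auc_total), p$clinical_benefit)
    if (tt$p_value < 0.05) rej <- rej + 1
  }
  expect_lt(abs(rej / n_rep - 0.05), 0.02)
})
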