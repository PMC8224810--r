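test_that("identical seed and inputs give bit-identical draws", {
  pop <- toy_pop()
  reg <- dose_regimen(50)
  obs <- truth_obs(pop$typical, 50, 13)
  a <- sample_conditional(pop, obs, reg, n_draws = 150, seed = 9,
                          burn_in = 200)
  b <- sample_conditional(pop, obs, reg, n_draws = 150, seed = 9,
                          burn_in = 200)
  expect_identical(a$draws, b$draws)
  expect_false(identical(
    a$draws,
    sample_conditional(pop, obs, reg, n_draws = 150, seed = 10,
                       burn_in = 200)$draws))
})

test_that("with no observations the sampler recovers the prior", {
  pop <- toy_pop()
  pd <- sample_conditional(pop, NULL, dose_regimen(50), n_draws = 2000,
                           seed = 42, burn_in = 1000, thin = 10)
  set.seed(7)
  prior <- sample_individual(pop, 2000)
  ks <- suppressWarnings(
    ks.test(log(pd$draws[, "parent.cl"]), log(prior[, "parent.cl"])))
  expect_gt(ks$p.value, 0.01)
  # fixed (no-IIV) parameters never move
  expect_true(all(pd$draws[, "parent.ka"] == 0.195))
})

test_that("a low-noise observation pair recovers the true clearance", {
  pop <- toy_pop(error = residual_error(sigma_prop = 0.02, sigma_add = 0.1))
  set.seed(11)
  truth <- sample_individual(pop)
  obs <- truth_obs(truth, 50, 24)
  pd <- sample_conditional(pop, obs, dose_regimen(50), n_draws = 2000,
                           seed = 5, burn_in = 1000)
  med <- median(pd$draws[, "parent.cl"])
  expect_lt(abs(med - truth$parent$cl) / truth$parent$cl, 0.15)
})

test_that("posterior contracts relative to the prior", {
  pop <- toy_pop()
  reg <- dose_regimen(50)
  set.seed(77)
  worse <- 0
  for (i in 1:15) {
    truth <- sample_individual(pop)
    t_obs <- runif(1, 2, 26)
    obs <- truth_obs(truth, 50, t_obs)
    obs$conc <- pmax(obs$conc * (1 + rnorm(2, 0, 0.2)), 0.5)
    pd <- sample_conditional(pop, obs, reg, n_draws = 400, seed = 1000 + i,
                             burn_in = 400)
    if (sd(log(pd$draws[, "parent.cl"])) > 0.35) worse <- worse + 1
  }
  expect_equal(worse, 0)
})

test_that("MAP with no data is the prior mode", {
  pop <- toy_pop()
  mp <- map_estimate(pop, NULL, dose_regimen(50), n_starts = 1)
  expect_equal(mp$parent$cl, 51.8 * exp(-0.35^2), tolerance = 1e-6)
  expect_equal(mp$metabolite$v1, 3020 * exp(-0.50^2), tolerance = 1e-6)
  expect_equal(mp$parent$q, 7.22)  # fixed parameter untouched
})

test_that("MAP beats every retained draw in natural log-posterior", {
  pop <- toy_pop()
  reg <- dose_regimen(50)
  set.seed(55)
  n_ok <- 0
  for (i in 1:10) {
    truth <- sample_individual(pop)
    obs <- truth_obs(truth, 50, runif(1, 2, 26))
    obs$conc <- pmax(obs$conc * (1 + rnorm(2, 0, 0.2)), 0.5)
    mp <- map_estimate(pop, obs, reg, seed = i)
    pd <- sample_conditional(pop, obs, reg, n_draws = 300, seed = i,
                             burn_in = 300)
    lp_draws <- vapply(seq_len(pd$n_kept), function(j) {
      ind <- draw_individual(pd, j)
      prior_logdensity(pop, ind) + observation_loglik(ind, obs, reg,
                                                      pop$error)
    }, numeric(1))
    if (attr(mp, "logpost") >= max(lp_draws) - 1e-6) n_ok <- n_ok + 1
  }
  expect_gte(n_ok, 9.5)  # >= 95% of patients
})

test_that("MAP on a 2-parameter restriction matches a grid search", {
  pop <- toy_pop(omega = c(parent.cl = 0.35, metabolite.cl = 0.40))
  reg <- dose_regimen(50)
  set.seed(21)
  truth <- sample_individual(pop)
  obs <- truth_obs(truth, 50, 24)
  mp <- map_estimate(pop, obs, reg)
  # 200 x 200 log-grid oracle (full 400 x 400 in the acceptance suite)
  g1 <- seq(log(51.8) - 3 * 0.35, log(51.8) + 3 * 0.35, length.out = 200)
  g2 <- seq(log(81.4) - 3 * 0.40, log(81.4) + 3 * 0.40, length.out = 200)
  best <- c(NA, NA); best_lp <- -Inf
  for (a in g1) {
    ind <- pop$typical
    ind$parent <- analyte_pk(0.195, exp(a), 2030, 7.22, 583)
    for (b in g2) {
      ind$metabolite <- analyte_pk(0.195, exp(b), 3020, 95.7, 1850)
      lp <- prior_logdensity(pop, ind) +
        observation_loglik(ind, obs, reg, pop$error)
      if (lp > best_lp) { best_lp <- lp; best <- c(a, b) }
    }
  }
  expect_lt(abs(log(mp$parent$cl) - best[1]), diff(g1[1:2]))
  expect_lt(abs(log(mp$metabolite$cl) - best[2]), diff(g2[1:2]))
})

test_that("MAP under a flat prior approaches the least-squares fit", {
  pop <- toy_pop(omega = c(parent.cl = 5, parent.v1 = 5),
                 error = residual_error(sigma_prop = 0, sigma_add = 1))
  reg <- dose_regimen(50)
  truth <- individual_pk(analyte_pk(0.195, 40, 1700, 7.22, 583),
                         toy_pop()$typical$metabolite)
  tt <- seq(1, 96, length.out = 20)
  obs <- observations(rep("parent", 20), tt,
                      conc_steady_state(truth$parent, 50, 24, tt))
  mp <- map_estimate(pop, obs, reg, seed = 3)
  # weighted-least-squares oracle: direct optim on the sum of squares
  ssq <- function(p) {
    if (any(!is.finite(exp(p))) || any(exp(p) <= 0)) return(1e12)
    pred <- conc_steady_state(analyte_pk(0.195, exp(p[1]), exp(p[2]),
                                         7.22, 583), 50, 24, tt)
    sum((obs$conc - pred)^2)
  }
  ls <- optim(c(log(50), log(2000)), ssq, method = "BFGS",
              control = list(reltol = 1e-12))
  expect_equal(mp$parent$cl, exp(ls$par[1]), tolerance = 0.01)
  expect_equal(mp$parent$v1, exp(ls$par[2]), tolerance = 0.01)
})

test_that("virtual trough summarizes draws and scales with dose", {
  pop <- toy_pop()
  reg <- dose_regimen(50)
  pd <- sample_conditional(pop, NULL, reg, n_draws = 200, seed = 2,
                           burn_in = 200)
  vt <- virtual_trough(pd, reg)
  vt2 <- virtual_trough(pd, dose_regimen(100))
  expect_equal(vt2$median, 2 * vt$median)
  expect_equal(vt2$q95, 2 * vt$q95)
  # degenerate single-parameter check: all draws identical
  pd1 <- pd
  pd1$draws <- pd$draws[rep(1, 100), ]
  m <- exposure_at_steady_state(draw_individual(pd, 1), reg)
  expect_equal(virtual_trough(pd1, reg)$median, m$cmin_total)
  expect_equal(virtual_trough(pd1, reg)$mean, m$cmin_total)
})

test_that("virtual trough is self-consistent with a trough observation", {
  pop <- toy_pop(error = residual_error(sigma_prop = 0.01, sigma_add = 0.1))
  set.seed(19)
  truth <- sample_individual(pop)
  obs <- truth_obs(truth, 50, 24)
  measured_total <- sum(obs$conc)
  pd <- sample_conditional(pop, obs, dose_regimen(50), n_draws = 1000,
                           seed = 4, burn_in = 1000)
  vt <- virtual_trough(pd, dose_regimen(50))
  expect_lt(abs(vt$median - measured_total) / measured_total, 0.10)
})
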