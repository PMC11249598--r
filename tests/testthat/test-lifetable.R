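g_std <- gompertz_dist()

exp_table <- function(rate = 0.2, t_max = 120, step = 0.05) {
  ages <- seq(0, t_max, by = step)
  bioclock:::new_life_table(ages, exp(-rate * ages))
}

test_that("exponential table reproduces the memoryless closed forms", {
  tb <- exp_table(rate = 0.2)
  for (t in c(0, 10, 40)) {
    expect_equal(residual_life(tb, t, "mean"), 1 / 0.2, tolerance = 1e-3)
    expect_equal(residual_life(tb, t, "median"), log(2) / 0.2,
                 tolerance = 1e-3)
  }
  # constant residual life is not invertible
  expect_error(invert_residual_life(tb, 5), "not invertible")
})

test_that("trapezoidal mean residual life converges at O(h^2)", {
  err <- vapply(c(0.2, 0.05), function(h) {
    abs(residual_life(exp_table(rate = 0.2, step = h), 10, "mean") - 5)
  }, numeric(1))
  expect_gt(err[1] / err[2], 8)  # h ratio 4 => error ratio ~16
})

test_that("Gompertz baseline table matches the parametric median lifespan", {
  tb <- lifetable_from_parametric(g_std)
  expect_equal(residual_life(tb, 0, "median"), inv_cumhaz(g_std, log(2)),
               tolerance = 0.02)
  # mean residual life decreasing over adult ages (increasing hazard law)
  mrl <- residual_life(tb, seq(20, 100, by = 1), "mean")
  expect_true(all(diff(mrl) < 0))
})

test_that("marginal table with null effect equals the baseline table", {
  eff <- covariate_effect(c(0, 0), "AFT")
  tb_m <- lifetable_from_parametric(g_std, effect = eff, sigma_lp = 0,
                                    mode = "marginal")
  tb_b <- lifetable_from_parametric(g_std)
  expect_equal(tb_m$survival, tb_b$survival, tolerance = 1e-12)
  expect_error(lifetable_from_parametric(g_std, mode = "marginal"),
               "requires a covariate effect")
})

test_that("Gauss-Hermite marginal survival agrees with Monte Carlo", {
  beta <- c(0.05, 0.05)
  eff <- covariate_effect(beta, "AFT")
  slp <- sqrt(sum(beta^2))
  tb <- lifetable_from_parametric(g_std, effect = eff, sigma_lp = slp,
                                  mode = "marginal")
  set.seed(401)
  n_mc <- 2e5
  lp <- rnorm(n_mc, 0, slp)
  for (t in c(40, 60, 80)) {
    draws <- exp(-base_cumhaz(g_std, exp(lp) * t))
    mc <- mean(draws)
    se <- sd(draws) / sqrt(n_mc)
    expect_lt(abs(bioclock:::.table_survival_at(tb, t) - mc), 3 * se)
  }
})

test_that("grid refinement changes median residual life negligibly", {
  eff <- covariate_effect(c(0.05, 0.05), "AFT")
  t1 <- lifetable_from_parametric(g_std, eff, sqrt(0.005), "marginal",
                                  step = 0.05)
  t2 <- lifetable_from_parametric(g_std, eff, sqrt(0.005), "marginal",
                                  step = 0.01)
  expect_lt(abs(residual_life(t1, 50) - residual_life(t2, 50)), 0.02)
})

test_that("delayed-entry Kaplan-Meier table matches the textbook step function", {
  # n = 6, all entering at ~0, no censoring, death ages 10,20,...,60
  d <- survival_data(rep(1e-3, 6), 10 * (1:6), rep(1, 6),
                     matrix(0, 6, 1))
  tb <- lifetable_from_data(d)
  for (k in 1:5) {
    expect_equal(bioclock:::.table_survival_at(tb, 10 * k + 5), (6 - k) / 6,
                 tolerance = 1e-12)
  }
  # duplicating the cohort leaves the KM unchanged
  d2 <- survival_data(rep(d$entry_age, 2), rep(d$exit_age, 2),
                      rep(d$status, 2), matrix(0, 12, 1))
  expect_equal(lifetable_from_data(d2)$survival, tb$survival)
  # no events -> error
  expect_error(
    lifetable_from_data(survival_data(c(1, 2), c(5, 6), c(0, 0),
                                      matrix(0, 2, 1))),
    "no events")
})

test_that("life-table file dialects are read correctly", {
  dir <- withr::local_tempdir()
  # lx dialect: normalization by the first value
  f_lx <- file.path(dir, "lx.csv")
  write.csv(data.frame(age = 0:4, lx = c(100000, 99000, 97000, 90000, 50000)),
            f_lx, row.names = FALSE)
  tb <- read_lifetable(f_lx, dialect = "lx")
  expect_equal(tb$survival, c(1, 0.99, 0.97, 0.90, 0.50))
  # qx dialect: constant q gives geometric survival
  f_qx <- file.path(dir, "qx.csv")
  write.csv(data.frame(age = 0:50, qx = rep(0.1, 51)), f_qx, row.names = FALSE)
  tb <- read_lifetable(f_qx, dialect = "qx")
  expect_equal(tb$survival, 0.9^(0:50), tolerance = 1e-12)
  # write -> read round trip
  tb0 <- lifetable_from_parametric(g_std, step = 0.5)
  f_rt <- file.path(dir, "rt.csv")
  write_lifetable(tb0, f_rt)
  tb1 <- read_lifetable(f_rt, dialect = "survival")
  expect_equal(tb1$survival, tb0$survival, tolerance = 1e-12)
  expect_equal(tb1$ages, tb0$ages, tolerance = 1e-12)
  # malformed files: errors name the offending line
  f_bad <- file.path(dir, "bad.csv")
  write.csv(data.frame(age = c(0, 2, 1), survival = c(1, 0.9, 0.8)),
            f_bad, row.names = FALSE)
  expect_error(read_lifetable(f_bad, "survival"), "non-monotone ages.*line")
  write.csv(data.frame(age = 0:2, survival = c(1, 0.8, 0.9)),
            f_bad, row.names = FALSE)
  expect_error(read_lifetable(f_bad, "survival"), "increases.*line")
  write.csv(data.frame(age = 0:2, foo = 1:3), f_bad, row.names = FALSE)
  expect_error(read_lifetable(f_bad, "survival"), "lacks")
})

test_that("stratified files split into per-stratum tables", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "strat.csv")
  df <- rbind(data.frame(age = 0:100, survival = exp(-(0:100) / 30),
                         sex = "male"),
              data.frame(age = 0:100, survival = exp(-(0:100) / 40),
                         sex = "female"))
  write.csv(df, f, row.names = FALSE)
  tabs <- read_lifetable(f, "survival", stratum_col = "sex")
  expect_named(tabs, c("female", "male"))
  expect_equal(tabs$male$survival, exp(-(0:100) / 30), tolerance = 1e-12)
  expect_equal(tabs$male$stratum, "male")
})

test_that("inverting residual life round-trips within one grid step", {
  tb <- lifetable_from_parametric(g_std)
  for (kind in c("median", "mean")) {
    for (cc in c(30, 50, 70)) {
      m <- residual_life(tb, cc, kind)
      expect_equal(invert_residual_life(tb, m, kind), cc,
                   tolerance = tb$step)
    }
  }
  # out-of-range values raise (or flag as NA when strict = FALSE)
  big <- residual_life(tb, 0, "median") + 10
  expect_error(invert_residual_life(tb, big), "out of the range")
  expect_true(is.na(invert_residual_life(tb, big, strict = FALSE)))
})

test_that("a reference population with 20 remaining years at age 57 maps 20 -> 57", {
  # self-consistency construction: tune the Gompertz slope so that the mean
  # residual life at 57 is exactly 20 years
  mrl57 <- function(b) {
    tb <- lifetable_from_parametric(gompertz_dist(a = exp(-9), b = b),
                                    t_max = 150)
    residual_life(tb, 57, "mean")
  }
  b_star <- uniroot(function(b) mrl57(b) - 20, c(0.08, 0.15), tol = 1e-10)$root
  tb <- lifetable_from_parametric(gompertz_dist(a = exp(-9), b = b_star),
                                  t_max = 150)
  expect_equal(invert_residual_life(tb, 20, "mean"), 57, tolerance = 0.05)
})
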