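test_that("Gompertz AFT fitter recovers the generating coefficients", {
  cfg <- sim_config("gompertz_aft", n_obs = 10000, seed = 101)
  co <- draw_cohort(cfg)
  fit <- fit_gompertz_aft(co$data)
  expect_true(fit$converged)
  for (k in 1:2) {
    expect_lt(abs(fit$beta_hat[k] - 0.05), 3 * fit$se_beta[k])
  }
  # baseline parameters land near the truth too
  expect_equal(fit$a_hat, exp(-9), tolerance = 0.5)
  expect_equal(fit$b_hat, 0.085, tolerance = 0.1)
})

test_that("the returned optimum is a stationary point of the likelihood", {
  cfg <- sim_config("gompertz_aft", n_obs = 2000, seed = 102)
  co <- draw_cohort(cfg)
  fit <- fit_gompertz_aft(co$data)
  d <- co$data
  ll <- function(par) {
    a <- exp(par[1]); b <- exp(par[2])
    theta <- exp(drop(d$markers %*% par[3:4]))
    sum(d$status * (log(theta) + log(a) + b * theta * d$exit_age)) -
      (a / b) * sum(exp(b * theta * d$exit_age) - exp(b * theta * d$entry_age))
  }
  par_hat <- c(log(fit$a_hat), log(fit$b_hat), fit$beta_hat)
  g <- fd_gradient(ll, par_hat)
  expect_lt(sqrt(sum(g^2)), 1e-4)
})

test_that("duplicating every record doubles the log-likelihood, not the estimates", {
  cfg <- sim_config("gompertz_aft", n_obs = 800, seed = 103)
  d <- draw_cohort(cfg)$data
  d2 <- survival_data(rep(d$entry_age, 2), rep(d$exit_age, 2),
                      rep(d$status, 2), rbind(d$markers, d$markers))
  f1 <- fit_gompertz_aft(d)
  f2 <- fit_gompertz_aft(d2)
  expect_equal(f2$beta_hat, f1$beta_hat, tolerance = 1e-6)
  expect_equal(f2$a_hat, f1$a_hat, tolerance = 1e-6)
  expect_equal(f2$loglik, 2 * f1$loglik, tolerance = 1e-8)
})

test_that("subject order does not affect the estimates", {
  cfg <- sim_config("gompertz_ph", n_obs = 600, seed = 104)
  d <- draw_cohort(cfg)$data
  set.seed(1)
  perm <- sample(n_subjects(d))
  dp <- survival_data(d$entry_age[perm], d$exit_age[perm], d$status[perm],
                      d$markers[perm, ])
  f1 <- fit_gompertz_aft(d); f2 <- fit_gompertz_aft(dp)
  expect_equal(f2$beta_hat, f1$beta_hat, tolerance = 1e-8)
  c1 <- fit_cox_age(d); c2 <- fit_cox_age(dp)
  expect_equal(c2$beta_hat, c1$beta_hat, tolerance = 1e-10)
})

test_that("Cox partial likelihood with delayed entry equals risk-set enumeration", {
  cfg <- sim_config("gompertz_ph", n_obs = 20, seed = 105)
  d <- draw_cohort(cfg)$data
  fit <- fit_cox_age(d)
  ll_enum <- cox_loglik_enum(d$entry_age, d$exit_age, d$status, d$markers,
                             fit$beta_hat)
  expect_equal(fit$loglik, ll_enum, tolerance = 1e-10)
})

test_that("Cox-on-age fitter recovers the generating log hazard ratios", {
  cfg <- sim_config("gompertz_ph", n_obs = 10000, seed = 106)
  co <- draw_cohort(cfg)
  fit <- fit_cox_age(co$data)
  for (k in 1:2) {
    expect_lt(abs(fit$beta_hat[k] - 0.3), 3 * fit$se_beta[k])
  }
  # Breslow baseline is a nondecreasing step function within the age support
  expect_true(all(diff(fit$breslow$cumhaz) >= 0))
  expect_gte(min(fit$breslow$time), fit$support[1])
})

test_that("GrimAge-style fit reproduces the training age moments exactly", {
  cfg <- sim_config("gompertz_ph", n_obs = 1500, seed = 107)
  co <- draw_cohort(cfg)
  fit <- fit_grimage_type(co$data)
  pr <- predict_grimage(fit, co$data)
  expect_equal(mean(pr$bioage_hat), mean(co$data$entry_age), tolerance = 1e-10)
  expect_equal(sd(pr$bioage_hat), sd(co$data$entry_age), tolerance = 1e-10)
  # the Cox stage equals a generic time-on-study Cox fit on the same design
  df <- data.frame(tos = time_on_study(co$data), status = co$data$status,
                   age = co$data$entry_age, co$data$markers)
  ref <- survival::coxph(survival::Surv(tos, status) ~ age + x1 + x2,
                         data = df, ties = "breslow")
  expect_equal(unname(fit$beta_hat), unname(coef(ref)), tolerance = 1e-10)
})

test_that("null markers leave predictions aligned with entry age", {
  cfg <- sim_config("gompertz_ph", n_obs = 3000, beta = c(0, 0), seed = 108)
  co <- draw_cohort(cfg)
  fit <- fit_grimage_type(co$data)
  pr <- predict_grimage(fit, co$data)
  r <- cor(pr$bioage_hat, co$data$entry_age)
  expect_equal(sign(r), sign(fit$beta_hat[["age"]]))
  expect_gt(abs(r), 0.9)
})

test_that("conditional residual life from a Gompertz AFT fit is coherent", {
  fit <- structure(list(a_hat = exp(-9), b_hat = 0.085,
                        beta_hat = c(x1 = 0.05, x2 = 0.05), converged = TRUE),
                   class = "gompertz_aft_fit")
  # x = 0: equals the baseline residual life of Gompertz(a_hat, b_hat)
  tb <- lifetable_from_parametric(gompertz_dist(fit$a_hat, fit$b_hat))
  for (cc in c(30, 55, 70)) {
    expect_equal(conditional_residual_life(fit, cc, c(0, 0), "median"),
                 residual_life(tb, cc, "median"), tolerance = 0.01)
    expect_equal(conditional_residual_life(fit, cc, c(0, 0), "mean"),
                 residual_life(tb, cc, "mean"), tolerance = 0.01)
  }
  # residual life strictly decreasing in the acceleration factor
  lps <- seq(-2, 2, by = 0.5)
  m <- conditional_residual_life(fit, rep(60, length(lps)),
                                 cbind(lps / 0.05 / 2, lps / 0.05 / 2),
                                 "median")
  expect_true(all(diff(m) < 0))
  # mean and median residual life differ modestly at age 60
  m_med <- conditional_residual_life(fit, 60, c(0, 0), "median")
  m_mean <- conditional_residual_life(fit, 60, c(0, 0), "mean")
  expect_lt(abs(m_med - m_mean) / m_mean, 0.15)
})

test_that("Cox conditional residual life fails loudly without tail support", {
  cfg <- sim_config("gompertz_ph", n_obs = 400, seed = 109, c_min = 20,
                    c_max = 40, followup = 10)
  co <- draw_cohort(cfg)
  fit <- fit_cox_age(co$data)
  # support ends near age 50: a young subject's survival cannot halve in it
  expect_error(conditional_residual_life(fit, 25, c(0, 0), "median"),
               "insufficient tail support")
  expect_error(conditional_residual_life(fit, 25, c(0, 0), "mean"),
               "insufficient tail support")
})

test_that("degenerate inputs raise informative fitting errors", {
  d <- survival_data(c(20, 30, 40), c(25, 35, 45), c(1, 0, 0),
                     matrix(rnorm(3), 3, 1))
  expect_error(fit_gompertz_aft(d), "at least 2 events")
  # collinear markers
  X <- cbind(1:20, 2 * (1:20))
  d2 <- survival_data(rep(20, 20), 21:40, rep(1, 20), X)
  expect_error(fit_gompertz_aft(d2), "full column rank")
})
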