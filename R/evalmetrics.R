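#' Root-mean-square error of biological age predictions
#'
#' @param bioage_hat Predicted biological ages (no missing values; flagged
#'   out-of-range predictions must be excluded by the caller — their presence
#'   here is an error, not silently dropped).
#' @param bioage_true True biological ages, same length.
#' @return RMSE in years.
#' @export
rmse <- function(bioage_hat, bioage_true) {
  if (length(bioage_hat) != length(bioage_true))
    stop("prediction and truth vectors must have the same length")
  if (anyNA(bioage_hat) || anyNA(bioage_true))
    stop("missing values present; exclude flagged predictions before RMSE")
  sqrt(mean((bioage_hat - bioage_true)^2))
}

# censoring-distribution Kaplan-Meier evaluated just before each time point:
# G(t-) on the time-on-study scale (entry is time 0; events and censorings
# swap roles)
.censoring_km_minus <- function(y, d, at) {
  fit <- survival::survfit(survival::Surv(y, 1 - d) ~ 1)
  # left-continuous version: value at the largest jump time strictly < at
  sf <- stats::stepfun(fit$time, c(1, fit$surv), right = TRUE)
  sf(at)
}

#' Uno's inverse-probability-of-censoring-weighted concordance
#'
#' Estimates the probability that of two comparable subjects, the one who dies
#' earlier carries the higher risk score; unlike Harrell's C, the IPCW
#' weighting (`1 / G(T_i-)^2`, `G` the Kaplan-Meier of the censoring
#' distribution on time-on-study) makes the estimate independent of the
#' study-specific censoring distribution. A pair `(i, j)` is comparable when
#' `T_i < T_j`, `T_i < tau` and subject i died; score ties count one half.
#' With no censoring all weights are 1 and the estimator reduces to
#' Harrell's C.
#'
#' The standard error comes from the per-subject influence of the ratio
#' U-statistic (the usual first-order jackknife approximation).
#'
#' @param data A [survival_data()] cohort; times are time-on-study.
#' @param risk_scores Scores oriented so that larger = higher risk (e.g.
#'   predicted biological age, or minus predicted residual life).
#' @param tau Truncation time in years; by default the largest event time at
#'   which the censoring survival is still at least 0.1, which caps the IPCW
#'   weights.
#' @return List with `c_index`, `se`, `tau`, `n_pairs`.
#' @export
uno_concordance <- function(data, risk_scores, tau = NULL) {
  stopifnot(inherits(data, "survival_data"))
  y <- time_on_study(data)
  d <- data$status
  n <- length(y)
  if (length(risk_scores) != n)
    stop("need one risk score per subject")
  g_at_event <- .censoring_km_minus(y, d, y)
  if (is.null(tau)) {
    ev <- y[d == 1 & g_at_event >= 0.1]
    if (!length(ev)) stop("no event time with censoring survival >= 0.1; ",
                          "supply tau explicitly")
    tau <- max(ev)
  }
  if (any(d == 1 & y <= tau & g_at_event <= 0))
    stop("censoring survival reaches 0 before tau = ", format(tau),
         "; choose a smaller tau")
  w <- ifelse(d == 1 & y <= tau, 1 / g_at_event^2, 0)
  # pairwise double sum, vectorized one row at a time to bound memory
  num_i <- den_i <- numeric(n)
  for (i in which(w > 0)) {
    later <- y > y[i]
    if (!any(later)) next
    conc <- (risk_scores[i] > risk_scores[later]) +
      0.5 * (risk_scores[i] == risk_scores[later])
    den_i[i] <- w[i] * sum(later)
    num_i[i] <- w[i] * sum(conc)
  }
  num <- sum(num_i); den <- sum(den_i)
  if (den == 0) stop("no comparable pairs below tau")
  cidx <- num / den
  # influence of subject k: contributions as the "i" of a pair plus as the
  # "j"; first-order expansion of the ratio
  numj_k <- denj_k <- numeric(n)
  for (i in which(w > 0)) {
    later <- which(y > y[i])
    if (!length(later)) next
    conc <- (risk_scores[i] > risk_scores[later]) +
      0.5 * (risk_scores[i] == risk_scores[later])
    denj_k[later] <- denj_k[later] + w[i]
    numj_k[later] <- numj_k[later] + w[i] * conc
  }
  h <- (num_i + numj_k) - cidx * (den_i + denj_k)
  se <- sqrt(sum(h^2)) / den
  list(c_index = cidx, se = se, tau = tau, n_pairs = sum(den_i > 0))
}

#' Life-table calibration of biological age predictions
#'
#' Each subject's predicted biological age implies a predicted `horizon`-year
#' mortality probability in the reference population:
#' `q_i = 1 - S_pop(b_i + horizon) / S_pop(b_i)`. Subjects are placed in
#' `n_groups` equally sized groups by sorted `q`, and within each group the
#' mean predicted probability is compared with the observed event rate, the
#' Kaplan-Meier complement at the horizon on time-on-study (raw event
#' fractions would be biased by censoring within the horizon).
#'
#' @param preds A `bioage_predictions` data frame (no flagged subjects).
#' @param table The reference `life_table` (or named list of strata tables).
#' @param data The [survival_data()] cohort the predictions refer to.
#' @param horizon Mortality horizon in years (default 5).
#' @param n_groups Number of equally sized groups (default 5).
#' @return Data frame with one row per group: `group`, `n`,
#'   `mean_predicted`, `observed`, `observed_se`.
#' @export
calibration <- function(preds, table, data, horizon = 5, n_groups = 5) {
  stopifnot(inherits(data, "survival_data"))
  if (any(preds$flag)) stop("flagged predictions present; exclude them first")
  b <- preds$bioage_hat
  n <- length(b)
  if (n < n_groups) stop("fewer subjects than groups")
  surv_at <- function(ages, idx) {
    if (inherits(table, "life_table")) return(.table_survival_at(table, ages))
    vapply(seq_along(ages), function(k)
      .table_survival_at(table[[data$stratum[idx[k]]]], ages[k]), numeric(1))
  }
  idx_all <- seq_len(n)
  s_now <- surv_at(b, idx_all)
  s_then <- surv_at(b + horizon, idx_all)
  q <- 1 - s_then / s_now
  ord <- order(q)
  grp <- integer(n)
  grp[ord] <- floor((idx_all - 1) * n_groups / n) + 1L
  y <- time_on_study(data)
  d <- data$status
  out <- lapply(seq_len(n_groups), function(g) {
    sel <- grp == g
    obs <- obs_se <- NA_real_
    if (sum(d[sel] * (y[sel] <= horizon)) > 0 || any(y[sel] >= horizon)) {
      km <- survival::survfit(survival::Surv(y[sel], d[sel]) ~ 1)
      sm <- summary(km, times = horizon, extend = TRUE)
      obs <- 1 - sm$surv
      obs_se <- sm$std.err
    } else {
      warning("group ", g, ": observed event rate at the horizon is not ",
              "estimable (all subjects censored earlier)")
    }
    data.frame(group = g, n = sum(sel), mean_predicted = mean(q[sel]),
               observed = obs, observed_se = obs_se)
  })
  do.call(rbind, out)
}

#' Association of age acceleration with mortality
#'
#' The conventional clock evaluation: a Cox model on time-on-study for the
#' standardized age acceleration, adjusted for chronological age (and stratum
#' dummies if present). Reports the hazard ratio per standard-deviation
#' increase in delta with a Wald 95% confidence interval.
#'
#' @param data A [survival_data()] cohort.
#' @param delta Age-acceleration values, one per subject.
#' @return List with `hr`, `ci` (length 2), `p`, `coef`, `se`.
#' @export
delta_association <- function(data, delta) {
  stopifnot(inherits(data, "survival_data"))
  if (length(delta) != n_subjects(data))
    stop("need one delta per subject")
  if (stats::sd(delta) < 1e-12) stop("delta is constant")
  dstd <- (delta - mean(delta)) / stats::sd(delta)
  df <- data.frame(y = time_on_study(data), status = data$status,
                   dstd = dstd, age = data$entry_age)
  fml <- y ~ dstd + age
  if (!is.null(data$stratum)) {
    df$stratum <- factor(data$stratum)
    if (nlevels(df$stratum) > 1)
      fml <- y ~ dstd + age + stratum
  }
  fml <- stats::as.formula(paste("survival::Surv(y, status) ~",
                                 as.character(fml)[3]))
  fit <- survival::coxph(fml, data = df, ties = "breslow")
  if (any(is.na(stats::coef(fit))))
    stop("collinearity between delta and adjusters; model not identifiable")
  co <- stats::coef(fit)["dstd"]
  se <- sqrt(stats::vcov(fit)["dstd", "dstd"])
  z <- co / se
  list(hr = unname(exp(co)),
       ci = unname(exp(co + c(-1, 1) * 1.96 * se)),
       p = unname(2 * stats::pnorm(-abs(z))),
       coef = unname(co), se = unname(se))
}
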