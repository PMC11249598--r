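# Independent oracles used across tests: deliberately naive implementations
# (nested loops, finite differences, enumeration) that the vectorized package
# code is compared against.

# central finite-difference gradient
fd_gradient <- function(f, x, eps = 1e-6) {
  vapply(seq_along(x), function(i) {
    h <- eps * max(1, abs(x[i]))
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

# IPCW concordance by explicit double loop over all ordered pairs
uno_bruteforce <- function(data, scores, tau) {
  y <- data$exit_age - data$entry_age
  d <- data$status
  n <- length(y)
  km <- survival::survfit(survival::Surv(y, 1 - d) ~ 1)
  Gminus <- function(t) {
    # left limit of the censoring KM at t
    idx <- which(km$time < t)
    if (!length(idx)) 1 else km$surv[max(idx)]
  }
  num <- den <- 0
  for (i in seq_len(n)) {
    if (d[i] != 1 || y[i] > tau) next
    w <- 1 / Gminus(y[i])^2
    for (j in seq_len(n)) {
      if (y[j] <= y[i]) next
      den <- den + w
      if (scores[i] > scores[j]) num <- num + w
      else if (scores[i] == scores[j]) num <- num + 0.5 * w
    }
  }
  num / den
}

# delayed-entry Cox partial log-likelihood by explicit risk-set enumeration
cox_loglik_enum <- function(entry, exit, status, X, beta) {
  lp <- drop(X %*% beta)
  ll <- 0
  for (i in which(status == 1)) {
    risk <- entry < exit[i] & exit[i] <= exit
    ll <- ll + lp[i] - log(sum(exp(lp[risk])))
  }
  ll
}

# one-sample Kolmogorov-Smirnov statistic against a cdf evaluated at draws
ks_stat <- function(draws, cdf_at_draws) {
  n <- length(draws)
  Fv <- sort(cdf_at_draws)
  max(abs(Fv - seq_len(n) / n), abs(Fv - (seq_len(n) - 1) / n))
}

# quick tabular predictions object for calibration tests
make_preds <- function(data, bioage_hat) {
  structure(data.frame(id = seq_along(bioage_hat),
                       entry_age = data$entry_age,
                       residual_life_hat = NA_real_,
                       bioage_hat = bioage_hat,
                       delta = NA_real_, flag = FALSE),
            class = c("bioage_predictions", "data.frame"))
}
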