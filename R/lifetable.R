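#' Reference life tables
#'
#' A life table holds population survival `S_pop(t)` on a regular age grid and
#' supports the two residual-life summaries used for biological age: mean
#' residual life `mrl(t) = E(T - t | T > t)` and median residual life
#' `medrl(t)`, the `m` with `S(t + m) = S(t) / 2`. Inverting the residual-life
#' curve maps a model-predicted residual life onto the chronological age in the
#' reference population with the same residual life — the biological age.
#'
#' The default grid is ages 0 to 120 years in steps of 0.05, which keeps
#' inversion accurate to about 0.01 years.
#'
#' @name life_table
NULL

.default_t_max <- 120
.default_step <- 0.05

new_life_table <- function(ages, survival, stratum = NULL,
                           provenance = "parametric") {
  stopifnot(length(ages) == length(survival), length(ages) >= 3)
  step <- diff(ages)
  if (any(step <= 0) || max(step) - min(step) > 1e-8)
    stop("life-table ages must be strictly increasing with a constant step")
  if (any(!is.finite(survival)) || any(survival < 0))
    stop("life-table survival must be finite and nonnegative")
  if (any(diff(survival) > 1e-9))
    stop("life-table survival must be nonincreasing")
  survival <- cummin(pmin(survival / survival[1], 1))  # normalize, clean wiggle
  structure(list(ages = ages, survival = survival, step = step[1],
                 stratum = stratum, provenance = provenance),
            class = "life_table")
}

#' @export
print.life_table <- function(x, ...) {
  cat(sprintf("Life table (%s%s): ages %g-%g y, step %g y\n",
              x$provenance,
              if (!is.null(x$stratum)) paste0(", stratum ", x$stratum) else "",
              min(x$ages), max(x$ages), x$step))
  probe <- c(0, 20, 40, 60, 80, 100)
  probe <- probe[probe <= max(x$ages)]
  s <- .table_survival_at(x, probe)
  cat("  S_pop:", paste(sprintf("%g y: %.4f", probe, s), collapse = ", "), "\n")
  invisible(x)
}

# linear interpolation of S_pop on the grid; constant beyond the ends
.table_survival_at <- function(table, t) {
  stats::approx(table$ages, table$survival, xout = t, rule = 2)$y
}

#' Build a life table from a parametric survival law
#'
#' `mode = "baseline"` tabulates the baseline survival `S0(t)`.
#' `mode = "marginal"` tabulates the population-average survival
#' `E_Z[S(t | lp = Z)]` where the linear predictor `Z = beta' X` is normal with
#' mean 0 and standard deviation `sigma_lp`; the expectation is computed by
#' Gauss-Hermite quadrature (markers enter survival only through the scalar
#' linear predictor, so a univariate quadrature is exact up to the rule order).
#'
#' @param dist A `baseline_dist`.
#' @param effect A [covariate_effect()]; required for `mode = "marginal"`.
#' @param sigma_lp Standard deviation of the linear predictor `beta' X`
#'   (e.g. `sqrt(sum(beta^2 * sigma^2))` for independent normal markers).
#' @param mode `"baseline"` or `"marginal"`.
#' @param t_max,step Age grid specification, in years.
#' @param stratum Optional stratum label carried on the table.
#' @param gh_nodes Number of Gauss-Hermite nodes for the marginal mode.
#' @return A `life_table`.
#' @export
lifetable_from_parametric <- function(dist, effect = NULL, sigma_lp = 0,
                                      mode = c("baseline", "marginal"),
                                      t_max = .default_t_max,
                                      step = .default_step,
                                      stratum = NULL, gh_nodes = 40) {
  mode <- match.arg(mode)
  stopifnot(step > 0, t_max > step)
  ages <- seq(0, t_max, by = step)
  if (mode == "baseline") {
    s <- base_survival(dist, ages)
  } else {
    if (is.null(effect))
      stop("mode = 'marginal' requires a covariate effect")
    if (sigma_lp < 0) stop("'sigma_lp' must be nonnegative")
    gh <- pracma::gaussHermite(gh_nodes)
    theta <- exp(sqrt(2) * sigma_lp * gh$x)
    w <- gh$w / sqrt(pi)
    s <- numeric(length(ages))
    for (k in seq_along(theta)) {
      s <- s + w[k] *
        exp(-.cond_cumhaz(dist, theta[k], effect$assumption, ages))
    }
  }
  new_life_table(ages, s, stratum = stratum, provenance = "parametric")
}

#' Build a life table from cohort data by delayed-entry Kaplan-Meier
#'
#' Estimates population survival on the age axis with left truncation:
#' subjects contribute to the risk set only between their entry and exit ages.
#' Survival is set to 1 below the earliest entry age (no mortality information
#' there) and the Kaplan-Meier step function is carried onto the regular grid.
#'
#' @param data A [survival_data()] cohort.
#' @inheritParams lifetable_from_parametric
#' @return A `life_table` with provenance `"empirical"`.
#' @export
lifetable_from_data <- function(data, t_max = .default_t_max,
                                step = .default_step, stratum = NULL) {
  stopifnot(inherits(data, "survival_data"))
  if (sum(data$status) == 0)
    stop("cannot build a life table: the cohort contains no events")
  fit <- survival::survfit(
    survival::Surv(entry_age, exit_age, status) ~ 1,
    data = data.frame(entry_age = data$entry_age, exit_age = data$exit_age,
                      status = data$status))
  ages <- seq(0, t_max, by = step)
  # step function: S(t) = KM value at the largest event/censor time <= t;
  # 1 below the earliest entry age
  s <- stats::approx(c(0, fit$time), c(1, fit$surv), xout = ages,
                     method = "constant", rule = 2)$y
  s[ages < min(data$entry_age)] <- 1
  if (min(s) > 0.5 * max(s))
    warning("estimated survival never falls below half its maximum; ",
            "median residual life is undefined at every age of this table")
  new_life_table(ages, s, stratum = stratum, provenance = "empirical")
}

# residual life evaluated at every grid age; NA where the table's tail cannot
# support the computation
.residual_life_grid <- function(table, kind) {
  .residual_life_core(table, table$ages, kind, on_error = NA_real_)
}

.residual_life_core <- function(table, t, kind, on_error = c("stop", NA_real_)) {
  S <- table$survival
  ages <- table$ages
  m <- length(S)
  raise <- identical(on_error, "stop")
  s_t <- .table_survival_at(table, t)
  bad_zero <- s_t <= 0
  if (any(bad_zero) && raise)
    stop("S_pop(t) = 0 at some requested ages; residual life undefined")
  out <- rep(NA_real_, length(t))
  if (kind == "mean") {
    # relative tail mass at t_max must be negligible for the truncated
    # integral to stand in for the full expectation
    seg <- (S[-1] + S[-m]) / 2 * diff(ages)
    integ <- c(rev(cumsum(rev(seg))), 0)  # I(age_j) = int_{age_j}^{t_max} S
    i_t <- stats::approx(ages, integ, xout = t, rule = 2)$y
    tail_bad <- !bad_zero & S[m] / s_t > 1e-6
    if (any(tail_bad) && raise)
      stop("insufficient tail support: relative survival at t_max exceeds ",
           "1e-6; extend the table before computing mean residual life")
    ok <- !bad_zero & !tail_bad
    out[ok] <- i_t[ok] / s_t[ok]
  } else {
    v <- s_t / 2
    revS <- rev(S)
    k <- findInterval(v, revS)      # count of grid survivals <= v
    j <- m - k + 1                  # first grid index with S[j] <= v
    no_cross <- k == 0
    if (any(no_cross & !bad_zero) && raise)
      stop("insufficient tail support: survival never reaches half its ",
           "current value before t_max")
    ok <- !bad_zero & !no_cross
    jj <- j[ok]
    t_med <- ages[jj]
    interp <- jj > 1
    if (any(interp)) {
      jiv <- jj[interp]
      drop_ <- S[jiv - 1] - S[jiv]
      frac <- ifelse(drop_ > 0, (S[jiv - 1] - v[ok][interp]) / drop_, 1)
      t_med[interp] <- ages[jiv - 1] + frac * (ages[jiv] - ages[jiv - 1])
    }
    out[ok] <- pmax(t_med - t[ok], 0)
  }
  if (raise && any(is.na(out))) stop("residual life undefined at some ages")
  out
}

#' Residual life of a reference population
#'
#' @param table A `life_table`.
#' @param t Ages in years (within the grid, with `S_pop(t) > 0`).
#' @param kind `"median"` (default) or `"mean"`.
#' @return Residual life in years, vectorized over `t`.
#' @export
residual_life <- function(table, t, kind = c("median", "mean")) {
  kind <- match.arg(kind)
  stopifnot(inherits(table, "life_table"))
  if (any(t < min(table$ages)) || any(t > max(table$ages)))
    stop("ages outside the life-table grid")
  .residual_life_core(table, t, kind, on_error = "stop")
}

#' Invert a residual-life curve to a biological age
#'
#' Finds the chronological age in the reference population whose residual life
#' equals `value`: the first downward crossing of the tabulated residual-life
#' curve, refined by linear interpolation between neighboring grid ages. The
#' first-crossing rule resolves any numerical non-monotonicity in the ragged
#' tail of empirical tables.
#'
#' @param table A `life_table`.
#' @param value Residual-life values in years (> 0); vectorized.
#' @param kind `"median"` or `"mean"`.
#' @return Biological ages in years. Values outside the range spanned by the
#'   table's residual-life curve raise an error when `strict = TRUE`,
#'   otherwise return `NA`.
#' @param strict Raise on out-of-range values (default) or return `NA`.
#' @export
invert_residual_life <- function(table, value, kind = c("median", "mean"),
                                 strict = TRUE) {
  kind <- match.arg(kind)
  stopifnot(inherits(table, "life_table"))
  if (any(!is.finite(value)) || any(value <= 0))
    stop("residual-life values must be positive")
  rl <- .residual_life_grid(table, kind)
  valid <- which(!is.na(rl))
  if (length(valid) < 2)
    stop("life table supports residual life at fewer than two grid ages")
  ages <- table$ages[valid]
  rl <- rl[valid]
  if (max(rl) - min(rl) < 1e-8)
    stop("residual-life curve is constant; not invertible ",
         "(memoryless reference population)")
  out <- rep(NA_real_, length(value))
  n <- length(rl)
  # the first downward crossing of rl below v coincides with the first
  # crossing of its running minimum, which is nonincreasing and therefore
  # invertible by a single vectorized findInterval
  rmin <- cummin(rl)
  k <- findInterval(value, rev(rmin))
  j <- n - k + 1
  ok <- k >= 1 & value <= rl[1]
  jj <- j[ok]
  b <- ages[jj]
  interp <- jj > 1
  if (any(interp)) {
    jiv <- jj[interp]
    drop_ <- rl[jiv - 1] - rl[jiv]
    frac <- ifelse(drop_ > 0, (rl[jiv - 1] - value[ok][interp]) / drop_, 1)
    b[interp] <- ages[jiv - 1] + frac * (ages[jiv] - ages[jiv - 1])
  }
  out[ok] <- b
  if (strict && any(is.na(out)))
    stop("residual-life value out of the range spanned by the table ",
         "(", sum(is.na(out)), " of ", length(value), " values)")
  out
}
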