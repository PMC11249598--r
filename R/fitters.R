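#' Fit a Gompertz accelerated failure time model with delayed entry
#'
#' Maximizes the left-truncated, right-censored log-likelihood
#' \deqn{\sum_i \delta_i \log h(t_i|x_i) - [H(t_i|x_i) - H(c_i|x_i)]}
#' where, under the AFT assumption with a Gompertz baseline, the conditional
#' law is again Gompertz with parameters `(a*theta, b*theta)`,
#' `theta_i = exp(beta' x_i)`:
#' `h(t|x) = theta * a * exp(b * theta * t)` and
#' `H(t|x) = (a/b) * (exp(b * theta * t) - 1)`.
#' Each subject contributes hazard mass only over their observed window
#' `(entry, exit]`, which is the likelihood conditioning on being alive at
#' study entry.
#'
#' Optimization is quasi-Newton (BFGS with analytic gradient) on
#' `(log a, log b, beta)`, started from a marginal Gompertz fit that ignores
#' covariates, followed by Newton polishing until the gradient norm falls
#' below tolerance. This is a numerically delicate model; non-convergence or a
#' singular observed information matrix raises an error carrying the optimizer
#' diagnostics rather than returning a half-fitted object.
#'
#' @param data A [survival_data()] cohort with at least 2 events.
#' @param control List: `maxit` (default 500), `grad_tol` (1e-5),
#'   `reltol` (1e-9).
#' @return Object of class `gompertz_aft_fit`: natural-scale `a_hat`, `b_hat`,
#'   `beta_hat`, covariance `vcov` of `(log a, log b, beta)`, `loglik`,
#'   `converged`, `se_beta`.
#' @export
fit_gompertz_aft <- function(data, control = list()) {
  stopifnot(inherits(data, "survival_data"))
  if (sum(data$status) < 2) stop("need at least 2 events to fit")
  X <- data$markers
  if (qr(X)$rank < ncol(X)) stop("marker matrix is not of full column rank")
  ctl <- utils::modifyList(list(maxit = 500, grad_tol = 1e-5, reltol = 1e-9),
                           control)
  tt <- data$exit_age; cc <- data$entry_age; d <- data$status
  p <- ncol(X)

  # H(t|x) - H(c|x) = (a/b) e^v expm1(u - v) with u = b*theta*t, v = b*theta*c:
  # the expm1 form stays exact as b -> 0, where exp(u) - exp(v) would cancel
  # catastrophically and open a spurious unbounded likelihood direction
  negll <- function(par) {
    la <- par[1]; b <- exp(par[2]); lp <- drop(X %*% par[-(1:2)])
    u <- b * exp(lp) * tt; v <- b * exp(lp) * cc
    le <- la - par[2] + v
    if (any(!is.finite(u)) || any(u > 690) || any(le > 700)) return(1e300)
    val <- sum(d * (lp + la + u)) - sum(exp(le) * expm1(u - v))
    if (!is.finite(val)) return(1e300)
    -val
  }
  neggr <- function(par) {
    la <- par[1]; b <- exp(par[2]); lp <- drop(X %*% par[-(1:2)])
    th <- exp(lp)
    u <- b * th * tt; v <- b * th * cc
    le <- la - par[2] + v
    if (any(!is.finite(u)) || any(u > 690) || any(le > 700))
      return(rep(0, length(par)))
    w_ <- exp(le)                    # (a/b) e^v per subject
    D <- expm1(u - v)                # e^{u-v} - 1
    s1 <- w_ * D                     # (a/b)(e^u - e^v)
    s2 <- w_ * (u * (D + 1) - v)     # (a/b)(u e^u - v e^v)
    g_la <- sum(d) - sum(s1)
    g_lb <- sum(d * u) + sum(s1) - sum(s2)
    g_beta <- drop(crossprod(X, d * (1 + u) - s2))
    -c(g_la, g_lb, g_beta)
  }

  # stage 1: marginal Gompertz (beta = 0), started at a = exp(-9), b = 0.085
  Xfull <- X
  X <- matrix(0, n_subjects(data), 1)
  marg <- stats::optim(c(-9, log(0.085), 0), fn = negll, gr = neggr,
                       method = "BFGS",
                       control = list(maxit = ctl$maxit, reltol = 1e-12))
  X <- Xfull
  start <- c(marg$par[1:2], rep(0, p))

  opt <- stats::optim(start, fn = negll, gr = neggr, method = "BFGS",
                      control = list(maxit = ctl$maxit, reltol = 1e-12))
  par <- opt$par
  # Newton polish: drive the gradient to tolerance
  for (it in 1:25) {
    g <- neggr(par)
    if (sqrt(sum(g^2)) < ctl$grad_tol) break
    H <- stats::optimHess(par, fn = negll, gr = neggr)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    cand <- par - step
    shrink <- 0
    while (negll(cand) > negll(par) + 1e-12 && shrink < 30) {
      step <- step / 2; cand <- par - step; shrink <- shrink + 1
    }
    if (negll(cand) > negll(par) + 1e-12) break
    par <- cand
  }
  g <- neggr(par)
  grad_norm <- sqrt(sum(g^2))
  converged <- opt$convergence == 0 && grad_norm < ctl$grad_tol
  if (!converged)
    stop("Gompertz AFT fit did not converge (optim code ", opt$convergence,
         ", gradient norm ", format(grad_norm), ")")
  H <- stats::optimHess(par, fn = negll, gr = neggr)
  vcov <- tryCatch(solve(H), error = function(e)
    stop("Gompertz AFT fit failed: the Hessian was singular at the optimum ",
         "(", conditionMessage(e), ")"))
  if (any(!is.finite(vcov)) || any(diag(vcov) <= 0))
    stop("Gompertz AFT fit failed: the Hessian was singular or indefinite ",
         "at the optimum")
  beta_hat <- par[-(1:2)]
  names(beta_hat) <- colnames(data$markers)
  structure(list(a_hat = exp(par[1]), b_hat = exp(par[2]),
                 beta_hat = beta_hat,
                 vcov = vcov,
                 se_beta = sqrt(diag(vcov)[-(1:2)]),
                 loglik = -negll(par),
                 grad_norm = grad_norm,
                 n = n_subjects(data), n_events = sum(d),
                 converged = TRUE),
            class = "gompertz_aft_fit")
}

#' @export
print.gompertz_aft_fit <- function(x, ...) {
  cat(sprintf("Gompertz AFT fit (age timescale, delayed entry)\n"))
  cat(sprintf("  a = %.4g, b = %.4g; loglik = %.2f (n = %d, events = %d)\n",
              x$a_hat, x$b_hat, x$loglik, x$n, x$n_events))
  cat("  beta (SE):", paste(sprintf("%.4f (%.4f)", x$beta_hat, x$se_beta),
                            collapse = ", "), "\n")
  invisible(x)
}

#' Fit a semiparametric Cox model on the age timescale with delayed entry
#'
#' Cox partial likelihood with chronological age as the time axis: subject i
#' is in the risk set at event age t iff `entry_age_i < t <= exit_age_i`.
#' Ties are handled by the Breslow approximation and the baseline cumulative
#' hazard is the Breslow estimator.
#'
#' @param data A [survival_data()] cohort.
#' @return Object of class `cox_age_fit` with `beta_hat`, `se_beta`,
#'   `vcov`, the Breslow step function (`breslow$time`, `breslow$cumhaz`) and
#'   its age `support`.
#' @export
fit_cox_age <- function(data) {
  stopifnot(inherits(data, "survival_data"))
  if (sum(data$status) < 2) stop("need at least 2 events to fit")
  df <- data.frame(entry = data$entry_age, exit = data$exit_age,
                   status = data$status)
  df <- cbind(df, as.data.frame(data$markers))
  fml <- stats::as.formula(paste("survival::Surv(entry, exit, status) ~",
                                 paste(colnames(data$markers), collapse = "+")))
  fit <- survival::coxph(fml, data = df, ties = "breslow")
  bh <- survival::basehaz(fit, centered = FALSE)
  structure(list(beta_hat = stats::coef(fit),
                 se_beta = sqrt(diag(stats::vcov(fit))),
                 vcov = stats::vcov(fit),
                 breslow = list(time = bh$time, cumhaz = bh$hazard),
                 support = c(min(data$entry_age), max(data$exit_age)),
                 loglik = fit$loglik[2],
                 n = n_subjects(data), n_events = sum(data$status)),
            class = "cox_age_fit")
}

#' @export
print.cox_age_fit <- function(x, ...) {
  cat("Cox PH fit on the age timescale (Breslow baseline, delayed entry)\n")
  cat(sprintf("  support %.1f-%.1f y; n = %d, events = %d\n",
              x$support[1], x$support[2], x$n, x$n_events))
  cat("  beta (SE):", paste(sprintf("%.4f (%.4f)", x$beta_hat, x$se_beta),
                            collapse = ", "), "\n")
  invisible(x)
}

#' Fit a GrimAge-style predictor
#'
#' Reconstruction of the mortality-trained clock recipe: (i) a Cox model on
#' the time-on-study scale (time 0 at study entry) with chronological age at
#' entry and the markers as covariates; (ii) an ad hoc affine rescaling that
#' maps the full linear predictor onto the training cohort's chronological-age
#' scale using the training mean and SD of entry age.
#'
#' @param data A [survival_data()] cohort.
#' @return Object of class `grimage_fit` with the Cox coefficients
#'   (`beta_hat`, age coefficient first) and the training moments `lp_mean`,
#'   `lp_sd`, `age_mean`, `age_sd`.
#' @export
fit_grimage_type <- function(data) {
  stopifnot(inherits(data, "survival_data"))
  if (sum(data$status) < 2) stop("need at least 2 events to fit")
  df <- data.frame(tos = time_on_study(data), status = data$status,
                   age = data$entry_age)
  df <- cbind(df, as.data.frame(data$markers))
  fml <- stats::as.formula(paste("survival::Surv(tos, status) ~ age +",
                                 paste(colnames(data$markers), collapse = "+")))
  fit <- survival::coxph(fml, data = df, ties = "breslow")
  beta <- stats::coef(fit)
  lp <- drop(cbind(data$entry_age, data$markers) %*% beta)
  lp_sd <- stats::sd(lp)
  age_sd <- stats::sd(data$entry_age)
  if (!is.finite(lp_sd) || lp_sd < 1e-12)
    stop("degenerate linear predictor (zero variance); cannot rescale to age")
  if (age_sd < 1e-12) stop("entry age is constant; cannot rescale to age")
  structure(list(beta_hat = beta,
                 se_beta = sqrt(diag(stats::vcov(fit))),
                 lp_mean = mean(lp), lp_sd = lp_sd,
                 age_mean = mean(data$entry_age), age_sd = age_sd,
                 n = n_subjects(data), n_events = sum(data$status)),
            class = "grimage_fit")
}

#' @export
print.grimage_fit <- function(x, ...) {
  cat("GrimAge-style fit (Cox on time-on-study + affine age rescaling)\n")
  cat(sprintf("  age scale: mean %.2f y, sd %.2f y; n = %d, events = %d\n",
              x$age_mean, x$age_sd, x$n, x$n_events))
  cat("  beta:", paste(sprintf("%.4f", x$beta_hat), collapse = ", "), "\n")
  invisible(x)
}

#' Conditional residual life from a fitted model
#'
#' For a subject alive at age `c` with markers `x`, computes the mean or
#' median of their remaining lifespan under the fitted conditional survival
#' law. For the Gompertz AFT fit the conditional law is Gompertz
#' `(a*theta, b*theta)` in closed form; for the Cox fit the conditional
#' survival is `exp(-H0_breslow(t) * exp(beta' x))`, a step function whose
#' support ends at the last observed age — when the requested level is never
#' reached within support, an "insufficient tail support" error is raised.
#'
#' @param fit A `gompertz_aft_fit` or `cox_age_fit`.
#' @param c Current ages (vector).
#' @param x Marker matrix (rows aligned with `c`) or a single marker vector.
#' @param kind `"median"` (default) or `"mean"`.
#' @param ... Method-specific arguments; the Cox method accepts
#'   `strict = FALSE` to return `NA` for unsupported subjects instead of
#'   raising.
#' @return Residual life in years, one value per subject.
#' @export
conditional_residual_life <- function(fit, c, x, kind = c("median", "mean"),
                                      ...) {
  UseMethod("conditional_residual_life")
}

.as_marker_matrix <- function(x, n, p) {
  if (!is.matrix(x)) x <- matrix(x, nrow = if (length(x) == p) 1 else n,
                                 ncol = p, byrow = length(x) == p)
  if (ncol(x) != p) stop("marker dimension mismatch: expected ", p, " columns")
  if (nrow(x) == 1 && n > 1) x <- x[rep(1, n), , drop = FALSE]
  if (nrow(x) != n) stop("need one marker row per age")
  x
}

#' @export
conditional_residual_life.gompertz_aft_fit <- function(fit, c, x,
                                                       kind = c("median", "mean"),
                                                       ...) {
  kind <- match.arg(kind)
  p <- length(fit$beta_hat)
  x <- .as_marker_matrix(x, length(c), p)
  theta <- exp(drop(x %*% fit$beta_hat))
  dist <- gompertz_dist(fit$a_hat, fit$b_hat)
  if (kind == "median") return(cond_medrl(dist, theta, "AFT", c))
  # mean: Gauss-Legendre on s in [0, s_max], integrand exp(-(H(c+s)-H(c)))
  # per subject; s_max chosen so the omitted tail is below 1e-15 relative
  Hc <- .cond_cumhaz(dist, theta, "AFT", c)
  s_max <- .cond_inv_cumhaz(dist, theta, "AFT", Hc + 34.5) - c
  gl <- pracma::gaussLegendre(64, 0, 1)
  out <- numeric(length(c))
  for (k in seq_along(gl$x)) {
    s <- gl$x[k] * s_max
    out <- out + gl$w[k] * s_max *
      exp(-(.cond_cumhaz(dist, theta, "AFT", c + s) - Hc))
  }
  out
}

#' @export
conditional_residual_life.cox_age_fit <- function(fit, c, x,
                                                  kind = c("median", "mean"),
                                                  strict = TRUE, ...) {
  kind <- match.arg(kind)
  p <- length(fit$beta_hat)
  x <- .as_marker_matrix(x, length(c), p)
  theta <- exp(drop(x %*% fit$beta_hat))
  tt <- fit$breslow$time
  HH <- fit$breslow$cumhaz
  # Breslow H0 evaluated at c (step function, 0 below the first time)
  Hc <- stats::approx(c(-Inf, tt), c(0, HH), xout = c, method = "constant",
                      rule = 2)$y
  if (kind == "median") {
    target <- Hc + log(2) / theta
    j <- findInterval(target, HH, left.open = TRUE) + 1
    bad <- j > length(HH)
    if (any(bad) && strict)
      stop("insufficient tail support: the Breslow baseline ends before ",
           "conditional survival reaches half its value for subject(s) ",
           paste(utils::head(which(bad), 5), collapse = ", "),
           if (sum(bad) > 5) ", ..." else "")
    out <- rep(NA_real_, length(c))
    out[!bad] <- pmax(tt[j[!bad]] - c[!bad], 0)
    out
  } else {
    ratio_end <- exp(-(HH[length(HH)] - Hc) * theta)
    bad <- ratio_end > 1e-6
    if (any(bad) && strict)
      stop("insufficient tail support: conditional survival at the end of ",
           "the Breslow support exceeds 1e-6 of its value at entry for ",
           "subject(s) ", paste(utils::head(which(bad), 5), collapse = ", "),
           if (sum(bad) > 5) ", ..." else "")
    # exact integral of the piecewise-constant conditional survival
    out <- rep(NA_real_, length(c))
    for (i in which(!bad)) {
      ci <- c[i]
      keep <- tt > ci
      times <- c(ci, tt[keep])
      Hseg <- c(Hc[i], HH[keep])
      surv <- exp(-(Hseg - Hc[i]) * theta[i])
      out[i] <- sum(surv[-length(surv)] * diff(times))
    }
    out
  }
}
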