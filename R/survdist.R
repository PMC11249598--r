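#' Parametric baseline distributions for adult mortality
#'
#' Constructors for the two baseline hazard families used throughout the
#' package: the Gompertz law `h0(t) = a * exp(b * t)`, the canonical model of
#' adult mortality, and the Weibull law in the rate parameterization
#' `h0(t) = lambda * nu * t^(nu - 1)`.
#'
#' Parameters are stored on the log scale internally (positivity and
#' conditioning: typical values such as `a = exp(-9)` are tiny) but exposed on
#' the natural scale through `$a`, `$b`, `$lambda`, `$nu`.
#'
#' @param a Gompertz hazard level at age 0, per year (> 0).
#' @param b Gompertz exponential rate of hazard increase, per year (> 0).
#' @return An object of class `c("gompertz_dist", "baseline_dist")` or
#'   `c("weibull_dist", "baseline_dist")`.
#' @examples
#' g <- gompertz_dist(a = exp(-9), b = 0.085)
#' base_survival(g, c(0, 50, 80))
#' @export
gompertz_dist <- function(a = exp(-9), b = 0.085) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) == 1, length(b) == 1)
  if (!is.finite(a) || a <= 0) stop("Gompertz 'a' must be a positive number")
  if (!is.finite(b) || b <= 0) stop("Gompertz 'b' must be a positive number")
  structure(list(family = "gompertz", log_a = log(a), log_b = log(b)),
            class = c("gompertz_dist", "baseline_dist"))
}

#' @param lambda Weibull rate parameter (> 0).
#' @param nu Weibull shape parameter (> 0).
#' @rdname gompertz_dist
#' @export
weibull_dist <- function(lambda = 34^(-10), nu = 8) {
  stopifnot(is.numeric(lambda), is.numeric(nu), length(lambda) == 1, length(nu) == 1)
  if (!is.finite(lambda) || lambda <= 0) stop("Weibull 'lambda' must be a positive number")
  if (!is.finite(nu) || nu <= 0) stop("Weibull 'nu' must be a positive number")
  structure(list(family = "weibull", log_lambda = log(lambda), log_nu = log(nu)),
            class = c("weibull_dist", "baseline_dist"))
}

#' @export
`$.baseline_dist` <- function(x, name) {
  switch(name,
    a = exp(.subset2(x, "log_a")),
    b = exp(.subset2(x, "log_b")),
    lambda = exp(.subset2(x, "log_lambda")),
    nu = exp(.subset2(x, "log_nu")),
    .subset2(x, name)
  )
}

#' @export
print.baseline_dist <- function(x, ...) {
  if (x$family == "gompertz") {
    cat(sprintf("Gompertz baseline: a = %.6g, b = %.6g (hazard a*exp(b*t))\n",
                x$a, x$b))
  } else {
    cat(sprintf("Weibull baseline: lambda = %.6g, nu = %.6g (hazard lambda*nu*t^(nu-1))\n",
                x$lambda, x$nu))
  }
  invisible(x)
}

.check_age <- function(t) {
  if (any(!is.finite(t)) || any(t < 0)) stop("ages 't' must be finite and >= 0")
  t
}

#' Baseline hazard, cumulative hazard and survival
#'
#' Vectorized baseline functions. For Gompertz,
#' `H0(t) = (a/b) * (exp(b*t) - 1)`; for Weibull, `H0(t) = lambda * t^nu`.
#' Survival is computed as `exp(-H0(t))` on the log scale so that large ages
#' underflow cleanly to 0 rather than overflow.
#'
#' @param dist A `baseline_dist` object.
#' @param t Vector of ages in years (>= 0).
#' @return Numeric vector of the same length as `t`.
#' @export
base_hazard <- function(dist, t) UseMethod("base_hazard")

#' @export
base_hazard.gompertz_dist <- function(dist, t) {
  .check_age(t)
  dist$a * exp(dist$b * t)
}

#' @export
base_hazard.weibull_dist <- function(dist, t) {
  .check_age(t)
  dist$lambda * dist$nu * t^(dist$nu - 1)
}

#' @rdname base_hazard
#' @export
base_cumhaz <- function(dist, t) UseMethod("base_cumhaz")

#' @export
base_cumhaz.gompertz_dist <- function(dist, t) {
  .check_age(t)
  # expm1 keeps precision near t = 0; b*t beyond ~700 would overflow double
  # precision, so such ages are mapped to +Inf cumulative hazard (survival 0)
  bt <- dist$b * t
  out <- rep(Inf, length(t))
  ok <- bt < 700
  out[ok] <- (dist$a / dist$b) * expm1(bt[ok])
  out
}

#' @export
base_cumhaz.weibull_dist <- function(dist, t) {
  .check_age(t)
  dist$lambda * t^dist$nu
}

#' @rdname base_hazard
#' @export
base_survival <- function(dist, t) {
  exp(-base_cumhaz(dist, t))
}

#' Inverse baseline cumulative hazard
#'
#' Closed-form inverse of `H0`. For Gompertz,
#' `H0^{-1}(x) = log(1 + b*x/a) / b`; for Weibull, `(x/lambda)^(1/nu)`.
#' Used to draw event times by inversion sampling.
#'
#' @param dist A `baseline_dist` object.
#' @param x Nonnegative cumulative-hazard values.
#' @return Ages in years; `inv_cumhaz(dist, base_cumhaz(dist, t))` recovers `t`.
#' @export
inv_cumhaz <- function(dist, x) UseMethod("inv_cumhaz")

.check_cumhaz <- function(x) {
  if (any(is.na(x)) || any(x < 0)) stop("cumulative-hazard values must be >= 0")
  x
}

#' @export
inv_cumhaz.gompertz_dist <- function(dist, x) {
  .check_cumhaz(x)
  log1p(dist$b * x / dist$a) / dist$b
}

#' @export
inv_cumhaz.weibull_dist <- function(dist, x) {
  .check_cumhaz(x)
  (x / dist$lambda)^(1 / dist$nu)
}

#' Covariate effects under the PH or AFT assumption
#'
#' Bundles a coefficient vector with the assumption on how markers act on
#' survival: proportional hazards (`"PH"`, hazard multiplied by
#' `theta = exp(beta' x)`) or accelerated failure time (`"AFT"`, age rescaled
#' by `theta`, so `S(t | x) = S0(theta * t)`).
#'
#' @param beta Numeric vector of coefficients, one per marker.
#' @param assumption `"PH"` or `"AFT"`.
#' @export
covariate_effect <- function(beta, assumption = c("AFT", "PH")) {
  assumption <- match.arg(assumption)
  beta <- as.numeric(beta)
  if (length(beta) < 1 || any(!is.finite(beta)))
    stop("'beta' must be a nonempty vector of finite coefficients")
  structure(list(beta = beta, assumption = assumption),
            class = "covariate_effect")
}

#' @export
print.covariate_effect <- function(x, ...) {
  cat(sprintf("%s covariate effect, beta = (%s)\n", x$assumption,
              paste(format(x$beta), collapse = ", ")))
  invisible(x)
}

# beta' x for a vector x (one subject) or a row-per-subject matrix
.linear_predictor <- function(effect, x) {
  p <- length(effect$beta)
  if (is.matrix(x)) {
    if (ncol(x) != p) stop("marker matrix has ", ncol(x),
                           " columns but beta has length ", p)
    drop(x %*% effect$beta)
  } else {
    if (length(x) != p) stop("marker vector has length ", length(x),
                             " but beta has length ", p)
    sum(effect$beta * x)
  }
}

#' Conditional survival and hazard given markers
#'
#' Under PH: `S(t|x) = S0(t)^theta`, `h(t|x) = theta * h0(t)`.
#' Under AFT: `S(t|x) = S0(theta * t)`, `h(t|x) = theta * h0(theta * t)`,
#' with acceleration factor `theta = exp(beta' x)`.
#'
#' @param dist A `baseline_dist`.
#' @param effect A [covariate_effect()].
#' @param x Marker vector for one subject (length = `length(beta)`).
#' @param t Vector of ages (years).
#' @return A list with components `survival` and `hazard`, each aligned with `t`.
#' @export
cond_survival <- function(dist, effect, x, t) {
  .check_age(t)
  theta <- exp(.linear_predictor(effect, x))
  if (effect$assumption == "PH") {
    list(survival = exp(-theta * base_cumhaz(dist, t)),
         hazard = theta * base_hazard(dist, t))
  } else {
    list(survival = exp(-base_cumhaz(dist, theta * t)),
         hazard = theta * base_hazard(dist, theta * t))
  }
}

# Conditional cumulative hazard at age t for a vector of acceleration factors
# theta (one per subject); closed forms for both assumptions.
.cond_cumhaz <- function(dist, theta, assumption, t) {
  if (assumption == "PH") theta * base_cumhaz(dist, t)
  else base_cumhaz(dist, theta * t)
}

# Inverse of the conditional cumulative hazard; both assumptions invert in
# closed form through inv_cumhaz.
.cond_inv_cumhaz <- function(dist, theta, assumption, x) {
  if (assumption == "PH") inv_cumhaz(dist, x / theta)
  else inv_cumhaz(dist, x) / theta
}

#' Conditional median residual life in closed form
#'
#' For a subject alive at age `c` with acceleration/hazard factor
#' `theta = exp(beta' x)`, the median residual life solves
#' `S(c + m | x) = S(c | x) / 2`, i.e. `H(c + m | x) = H(c | x) + log 2`.
#' Both the Gompertz and Weibull conditional laws invert in closed form, so no
#' root finding is needed. Vectorized over `c` and `theta`.
#'
#' @param dist A `baseline_dist`.
#' @param theta Acceleration (AFT) or hazard-ratio (PH) factors, > 0.
#' @param assumption `"PH"` or `"AFT"`.
#' @param c Current ages in years.
#' @return Median residual life in years, same length as `c`.
#' @export
cond_medrl <- function(dist, theta, assumption = c("AFT", "PH"), c) {
  assumption <- match.arg(assumption)
  .check_age(c)
  target <- .cond_cumhaz(dist, theta, assumption, c) + log(2)
  .cond_inv_cumhaz(dist, theta, assumption, target) - c
}
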