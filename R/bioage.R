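#' Two-step biological age prediction
#'
#' Step 1 predicts each subject's conditional residual life from the fitted
#' survival model at their current age and marker values. Step 2 looks up the
#' chronological age in the reference life table whose residual life equals
#' that prediction: that age is the biological age. With a sex-stratified
#' table, subjects are inverted against their own stratum, so two subjects
#' with the same predicted residual life can receive different biological ages
#' (the longer-lived stratum maps to a higher age).
#'
#' Subjects whose residual-life prediction falls outside the range spanned by
#' the table are flagged (`flag = TRUE`, `bioage_hat = NA`) rather than
#' clipped to the table bounds or dropped: clipping would silently distort
#' downstream calibration. The age acceleration `delta` is the residual of an
#' ordinary least squares regression of predicted biological age on
#' chronological age, computed over the non-flagged subjects of this sample.
#'
#' @param fit A `gompertz_aft_fit` or `cox_age_fit`.
#' @param table A `life_table`, or a named list of them matching the cohort's
#'   stratum labels.
#' @param data A [survival_data()] cohort.
#' @param kind `"median"` (default) or `"mean"` residual life.
#' @return A data frame of class `bioage_predictions` with columns `id`,
#'   `entry_age`, `residual_life_hat`, `bioage_hat`, `delta`, `flag`;
#'   attributes `predictor`, `kind`, `n_flagged`.
#' @export
predict_bioage <- function(fit, table, data, kind = c("median", "mean")) {
  kind <- match.arg(kind)
  stopifnot(inherits(data, "survival_data"))
  n <- n_subjects(data)
  # subjects whose residual life is unsupported by the fit (Cox tail) come
  # back NA and are flagged alongside out-of-range inversions
  m_hat <- conditional_residual_life(fit, data$entry_age, data$markers, kind,
                                     strict = FALSE)
  b_hat <- rep(NA_real_, n)
  if (inherits(table, "life_table")) {
    got <- !is.na(m_hat)
    b_hat[got] <- invert_residual_life(table, m_hat[got], kind, strict = FALSE)
  } else {
    if (is.null(data$stratum))
      stop("stratified life tables require a stratum label per subject")
    miss <- setdiff(unique(data$stratum), names(table))
    if (length(miss))
      stop("no life table for stratum/strata: ", paste(miss, collapse = ", "))
    for (s in unique(data$stratum)) {
      idx <- which(data$stratum == s & !is.na(m_hat))
      if (length(idx))
        b_hat[idx] <- invert_residual_life(table[[s]], m_hat[idx], kind,
                                           strict = FALSE)
    }
  }
  flag <- is.na(b_hat)
  .finish_predictions(data, m_hat, b_hat, flag,
                      predictor = class(fit)[1], kind = kind)
}

.finish_predictions <- function(data, m_hat, b_hat, flag, predictor, kind) {
  n <- n_subjects(data)
  delta <- rep(NA_real_, n)
  ok <- !flag
  if (sum(ok) >= 3 && stats::sd(data$entry_age[ok]) > 0)
    delta[ok] <- age_acceleration(b_hat[ok], data$entry_age[ok])
  out <- data.frame(id = seq_len(n), entry_age = data$entry_age,
                    residual_life_hat = m_hat, bioage_hat = b_hat,
                    delta = delta, flag = flag)
  structure(out, predictor = predictor, kind = kind, n_flagged = sum(flag),
            class = c("bioage_predictions", "data.frame"))
}

#' Predict biological age with a GrimAge-style fit
#'
#' The affine rescaling `B = age_mean + age_sd * (lp - lp_mean) / lp_sd`
#' applied to the subject's full Cox linear predictor (entry age included).
#' No residual-life prediction is produced: this predictor has no survival-law
#' interpretation that translates to residual life, so `residual_life_hat` is
#' `NA` throughout.
#'
#' @param fit A `grimage_fit`.
#' @param data A [survival_data()] cohort.
#' @return A `bioage_predictions` data frame (see [predict_bioage()]).
#' @export
predict_grimage <- function(fit, data) {
  stopifnot(inherits(fit, "grimage_fit"), inherits(data, "survival_data"))
  p <- length(fit$beta_hat) - 1L
  if (ncol(data$markers) != p)
    stop("marker dimension mismatch: fit expects ", p, " markers")
  lp <- drop(cbind(data$entry_age, data$markers) %*% fit$beta_hat)
  b_hat <- fit$age_mean + fit$age_sd * (lp - fit$lp_mean) / fit$lp_sd
  .finish_predictions(data, rep(NA_real_, n_subjects(data)), b_hat,
                      flag = rep(FALSE, n_subjects(data)),
                      predictor = "grimage_fit", kind = "none")
}

#' @export
print.bioage_predictions <- function(x, ...) {
  cat(sprintf("Biological age predictions (%s, residual-life kind: %s)\n",
              attr(x, "predictor"), attr(x, "kind")))
  cat(sprintf("  n = %d, flagged out-of-range: %d\n", nrow(x),
              attr(x, "n_flagged")))
  ok <- !x$flag
  if (any(ok))
    cat(sprintf("  bioage: mean %.1f y (sd %.1f); delta sd %.2f y\n",
                mean(x$bioage_hat[ok]), stats::sd(x$bioage_hat[ok]),
                stats::sd(x$delta[ok])))
  invisible(x)
}

#' Age acceleration: the age-independent part of a biological age prediction
#'
#' Residuals of the ordinary least squares regression of predicted biological
#' age on chronological age (intercept included). Any affine dependence of the
#' prediction on chronological age is absorbed, leaving the component of the
#' clock orthogonal to age.
#'
#' @param bioage_hat Predicted biological ages.
#' @param entry_age Chronological ages, same length (must not be constant).
#' @return Residual vector with mean zero.
#' @export
age_acceleration <- function(bioage_hat, entry_age) {
  if (length(bioage_hat) != length(entry_age))
    stop("bioage_hat and entry_age must have the same length")
  if (length(bioage_hat) < 3) stop("need at least 3 subjects")
  if (stats::sd(entry_age) == 0)
    stop("chronological age is constant; age acceleration undefined")
  unname(stats::residuals(stats::lm(bioage_hat ~ entry_age)))
}

#' Write biological age predictions as delimited text
#'
#' @param preds A `bioage_predictions` data frame.
#' @param path Output CSV path.
#' @export
write_predictions <- function(preds, path) {
  utils::write.csv(as.data.frame(preds), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
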