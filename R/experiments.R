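#' Grid specification for the simulation experiment
#'
#' Crosses data-generating mechanisms with training-set sizes and predictors:
#' per replicate, a training cohort and an independent test cohort are drawn,
#' each predictor is fitted on the training data, biological ages are
#' predicted on the test data, and the RMSE against the known true biological
#' ages is recorded. Residual-life predictors invert the true-mechanism
#' marginal life table (so the comparison isolates model-fit error, not
#' life-table estimation error); the GrimAge-style predictor needs no table.
#'
#' @param mechanisms Character vector of mechanisms (see [sim_config()]).
#' @param n_obs_list Training sizes.
#' @param n_sim Replicates per cell (default 20).
#' @param n_test Test-set size (default 5000).
#' @param predictors Subset of `"aft_gompertz"`, `"ph_semipar"`,
#'   `"grimage_type"`.
#' @param seed Root seed; replicate seeds are spawned by [child_seed()].
#' @return Object of class `experiment_grid`.
#' @export
experiment_grid <- function(mechanisms = c("gompertz_aft", "gompertz_ph",
                                           "weibull_ph"),
                            n_obs_list = c(500, 2500, 5000),
                            n_sim = 20, n_test = 5000,
                            predictors = c("aft_gompertz", "ph_semipar",
                                           "grimage_type"),
                            seed = 1L) {
  predictors <- match.arg(predictors, several.ok = TRUE)
  stopifnot(all(n_obs_list > 0), n_sim > 0, n_test > 0)
  structure(list(mechanisms = mechanisms, n_obs_list = n_obs_list,
                 n_sim = as.integer(n_sim), n_test = as.integer(n_test),
                 predictors = predictors, seed = as.integer(seed)),
            class = "experiment_grid")
}

.fit_predictor <- function(predictor, data) {
  switch(predictor,
         aft_gompertz = fit_gompertz_aft(data),
         ph_semipar = fit_cox_age(data),
         grimage_type = fit_grimage_type(data),
         stop("unknown predictor: ", predictor))
}

.predict_predictor <- function(predictor, fit, table, data, kind) {
  if (predictor == "grimage_type") predict_grimage(fit, data)
  else predict_bioage(fit, table, data, kind)
}

#' Run the simulation experiment
#'
#' @param grid An [experiment_grid()].
#' @param kind Residual-life kind for the residual-life predictors
#'   (default `"median"`).
#' @param verbose Print per-cell progress.
#' @return Data frame of class `experiment_result`: one row per
#'   (mechanism, n_obs, predictor) with `mean_rmse`, `sd_rmse`, `n_completed`,
#'   `n_failed`. Failed fits are excluded from the aggregates and counted.
#' @export
run_experiment <- function(grid, kind = "median", verbose = FALSE) {
  stopifnot(inherits(grid, "experiment_grid"))
  rows <- list()
  for (mech in grid$mechanisms) {
    table <- true_lifetable(sim_config(mechanism = mech), mode = "marginal")
    for (n_obs in grid$n_obs_list) {
      per_pred <- stats::setNames(
        replicate(length(grid$predictors), numeric(0), simplify = FALSE),
        grid$predictors)
      failed <- stats::setNames(integer(length(grid$predictors)),
                                grid$predictors)
      for (r in seq_len(grid$n_sim)) {
        seed_tr <- child_seed(grid$seed, 2L * r - 1L)
        seed_te <- child_seed(grid$seed, 2L * r)
        train <- draw_cohort(sim_config(mechanism = mech, n_obs = n_obs,
                                        seed = seed_tr))
        test <- draw_cohort(sim_config(mechanism = mech, n_obs = grid$n_test,
                                       seed = seed_te))
        # subjects whose true residual life exceeds the table's range (extreme
        # decelerated agers) have no defined truth; exclude, never clip
        b_true <- true_bioage(test, table, kind = kind, strict = FALSE)
        for (pred in grid$predictors) {
          res <- tryCatch({
            fit <- .fit_predictor(pred, train$data)
            pr <- .predict_predictor(pred, fit, table, test$data, kind)
            ok <- !pr$flag & !is.na(b_true)
            rmse(pr$bioage_hat[ok], b_true[ok])
          }, error = function(e) e)
          if (inherits(res, "error")) failed[pred] <- failed[pred] + 1L
          else per_pred[[pred]] <- c(per_pred[[pred]], res)
        }
      }
      for (pred in grid$predictors) {
        v <- per_pred[[pred]]
        if (!length(v))
          warning("all fits failed for ", pred, " under ", mech,
                  " at n_obs = ", n_obs)
        rows[[length(rows) + 1L]] <- data.frame(
          mechanism = mech, n_obs = n_obs, predictor = pred,
          mean_rmse = if (length(v)) mean(v) else NA_real_,
          sd_rmse = if (length(v) > 1) stats::sd(v) else NA_real_,
          n_completed = length(v), n_failed = failed[[pred]])
        if (verbose)
          message(sprintf("%s n_obs=%d %s: mean RMSE %.3f (%d/%d ok)",
                          mech, n_obs, pred,
                          if (length(v)) mean(v) else NA, length(v),
                          grid$n_sim))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("experiment_result", "data.frame")
  out
}
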