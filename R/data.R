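#' Left-truncated, right-censored cohort data
#'
#' The observational unit of a prospective cohort on the age timescale: each
#' subject enters the study alive at `entry_age` (left truncation: people who
#' died earlier are never observed), is followed until `exit_age`, and
#' `status` records whether exit was death (1) or censoring (0). Markers are
#' subject-level covariates assumed constant over life.
#'
#' @param entry_age Age at study entry, years.
#' @param exit_age Age at death or censoring, years; must exceed `entry_age`.
#' @param status Event indicator, 0 (censored) or 1 (died).
#' @param markers Numeric matrix (subjects x markers) or data frame; no
#'   missing values.
#' @param stratum Optional per-subject stratum label (e.g. sex).
#' @return An object of class `survival_data`.
#' @export
survival_data <- function(entry_age, exit_age, status, markers,
                          stratum = NULL) {
  n <- length(entry_age)
  markers <- as.matrix(markers)
  storage.mode(markers) <- "double"
  if (is.null(colnames(markers)))
    colnames(markers) <- paste0("x", seq_len(ncol(markers)))
  if (length(exit_age) != n || length(status) != n || nrow(markers) != n)
    stop("entry_age, exit_age, status and markers must have matching lengths")
  if (any(!is.finite(entry_age)) || any(!is.finite(exit_age)))
    stop("ages must be finite")
  bad <- which(exit_age <= entry_age)
  if (length(bad))
    stop("exit_age must exceed entry_age; first offending subject: row ",
         bad[1])
  if (!all(status %in% c(0, 1)))
    stop("status must be 0 or 1; first offending subject: row ",
         which(!status %in% c(0, 1))[1])
  if (anyNA(markers))
    stop("markers contain missing values; first offending subject: row ",
         which(rowSums(is.na(markers)) > 0)[1])
  if (!is.null(stratum) && length(stratum) != n)
    stop("stratum must have one label per subject")
  structure(list(entry_age = as.numeric(entry_age),
                 exit_age = as.numeric(exit_age),
                 status = as.integer(status),
                 markers = markers,
                 stratum = stratum),
            class = "survival_data")
}

#' @export
print.survival_data <- function(x, ...) {
  cat(sprintf(paste0("Cohort: %d subjects, %d events (%.1f%%), %d marker(s)\n",
                     "  entry age %.1f-%.1f y, exit age %.1f-%.1f y\n"),
              n_subjects(x), sum(x$status), 100 * mean(x$status),
              ncol(x$markers), min(x$entry_age), max(x$entry_age),
              min(x$exit_age), max(x$exit_age)))
  invisible(x)
}

#' @rdname survival_data
#' @param data A `survival_data` object.
#' @export
n_subjects <- function(data) length(data$entry_age)

#' @rdname survival_data
#' @export
time_on_study <- function(data) data$exit_age - data$entry_age

#' Read / write a cohort as delimited text
#'
#' Cohort files are comma-separated with header columns `entry_age`,
#' `exit_age`, `status`, marker columns `x1..xp`, and an optional `stratum`
#' column. Ages are years as decimals; time-on-study is always derived, never
#' stored.
#'
#' @param path CSV path.
#' @return [read_cohort()] returns a [survival_data()]; [write_cohort()]
#'   returns `path` invisibly.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("entry_age", "exit_age", "status")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("cohort file ", path, " lacks column(s): ", paste(miss, collapse = ", "))
  xcols <- grep("^x[0-9]+$", names(df), value = TRUE)
  if (!length(xcols)) stop("cohort file ", path, " has no marker columns x1..xp")
  xcols <- xcols[order(as.integer(sub("^x", "", xcols)))]
  survival_data(df$entry_age, df$exit_age, df$status,
                as.matrix(df[xcols]),
                stratum = if ("stratum" %in% names(df)) df$stratum else NULL)
}

#' @rdname read_cohort
#' @param data A `survival_data` cohort.
#' @export
write_cohort <- function(data, path) {
  df <- data.frame(entry_age = data$entry_age, exit_age = data$exit_age,
                   status = data$status)
  df <- cbind(df, as.data.frame(data$markers))
  if (!is.null(data$stratum)) df$stratum <- data$stratum
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
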