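#' Read a life table from delimited text
#'
#' Accepts the three dialects in which life tables circulate: a direct
#' survival column, national-statistics style `lx` (survivors out of a birth
#' cohort; normalized by `lx` at the first age) and `qx` (one-year death
#' probabilities; accumulated as `S(t) = prod(1 - qx)`). Files must be
#' comma-separated with a header containing an `age` column and the dialect
#' column; an optional stratum column (e.g. sex) yields one table per stratum.
#'
#' If the file's ages form a regular grid it is adopted as the table grid;
#' otherwise survival is interpolated onto the default grid.
#'
#' @param path Path to a CSV file.
#' @param dialect One of `"survival"`, `"lx"`, `"qx"`.
#' @param stratum_col Optional name of a stratum column.
#' @return A `life_table`, or a named list of them when `stratum_col` is given.
#' @export
read_lifetable <- function(path, dialect = c("survival", "lx", "qx"),
                           stratum_col = NULL) {
  dialect <- match.arg(dialect)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"age" %in% names(df))
    stop("life-table file ", path, " lacks an 'age' column")
  if (!dialect %in% names(df))
    stop("life-table file ", path, " lacks the '", dialect, "' column")
  build_one <- function(sub, stratum, offset) {
    o <- order(sub$age)
    if (any(o != seq_along(o))) {
      bad <- which(o != seq_along(o))[1]
      stop("non-monotone ages in ", path, " at line ", offset + bad + 1)
    }
    age <- sub$age
    val <- sub[[dialect]]
    s <- switch(dialect,
      survival = {
        inc <- which(diff(val) > 1e-9)
        if (length(inc))
          stop("survival increases in ", path, " at line ", offset + inc[1] + 2)
        val
      },
      lx = val / val[1],
      qx = cumprod(c(1, 1 - val[-length(val)]))
    )
    steps <- diff(age)
    regular <- length(steps) >= 2 && max(steps) - min(steps) < 1e-8
    if (regular) {
      new_life_table(age, s, stratum = stratum, provenance = "file")
    } else {
      grid <- seq(0, max(.default_t_max, max(age)), by = .default_step)
      sg <- stats::approx(age, s, xout = grid, rule = 2)$y
      new_life_table(grid, sg, stratum = stratum, provenance = "file")
    }
  }
  if (is.null(stratum_col)) return(build_one(df, NULL, 0))
  if (!stratum_col %in% names(df))
    stop("life-table file ", path, " lacks stratum column '", stratum_col, "'")
  strata <- split(seq_len(nrow(df)), df[[stratum_col]])
  out <- lapply(names(strata), function(sname) {
    idx <- strata[[sname]]
    build_one(df[idx, , drop = FALSE], sname, idx[1] - 1)
  })
  names(out) <- names(strata)
  out
}

#' Write a life table as delimited text (survival dialect)
#'
#' @param table A `life_table` or a named list of them (strata).
#' @param path Output CSV path.
#' @export
write_lifetable <- function(table, path) {
  if (inherits(table, "life_table")) table <- list(table)
  rows <- lapply(table, function(tb) {
    df <- data.frame(age = tb$ages, survival = tb$survival)
    if (!is.null(tb$stratum)) df$stratum <- tb$stratum
    df
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
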