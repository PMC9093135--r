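# Age-dependent background mortality from an annual life table.

#' Construct a life table
#'
#' @param age integer ages in years, strictly increasing and contiguous.
#' @param qx annual probability of death at each age, in `[0, 1]`.
#'   Lookups above the last tabulated age reuse the last `qx`.
#' @return an object of class `life_table`.
#' @export
life_table <- function(age, qx) {
  age <- as.integer(age); qx <- as.numeric(qx)
  if (length(age) != length(qx) || length(age) == 0) {
    stop("`age` and `qx` must be non-empty and of equal length", call. = FALSE)
  }
  if (any(diff(age) != 1L)) {
    stop("ages must be strictly increasing and contiguous", call. = FALSE)
  }
  if (any(qx < 0) || any(qx > 1)) stop("`qx` must be in [0, 1]", call. = FALSE)
  structure(list(age = age, qx = qx), class = "life_table")
}

#' @export
print.life_table <- function(x, ...) {
  cat(sprintf("<life_table> ages %d-%d, qx in [%.3g, %.3g]\n",
              min(x$age), max(x$age), min(x$qx), max(x$qx)))
  invisible(x)
}

# annual qx at (floored) age; ages above the table reuse the last entry
qx_at <- function(table, age_years) {
  stopifnot(inherits(table, "life_table"))
  a <- floor(age_years)
  if (any(a < table$age[1])) {
    stop(sprintf("age %g below the life table's first age (%d)",
                 min(age_years), table$age[1]), call. = FALSE)
  }
  idx <- pmin(a - table$age[1] + 1, length(table$qx))
  table$qx[idx]
}

#' Monthly background mortality from an annual life table
#'
#' Converts the annual death probability `qx` at the (floored) current age
#' to a monthly probability under a constant within-year hazard:
#' `1 - (1 - qx)^(1/12)`.  Compounding the result 12 times reproduces `qx`
#' exactly.
#'
#' @param table a [life_table].
#' @param age_years current age (may be fractional); must not fall below
#'   the table's first age.
#' @param months length of the model cycle in months (default 1).
#' @return the per-cycle background death probability.
#' @examples
#' lt <- make_life_table_fixture()
#' monthly_background_mortality(lt, 68)
#' @export
monthly_background_mortality <- function(table, age_years, months = 1) {
  q <- qx_at(table, age_years)
  1 - (1 - q)^(months / 12)
}

#' Read a life table from CSV
#'
#' Expected columns: `age`, `qx`.
#'
#' @param path CSV file path.
#' @return a [life_table].
#' @export
read_life_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("age", "qx") %in% names(df))) {
    stop("life-table CSV must have columns: age, qx", call. = FALSE)
  }
  df <- df[order(df$age), ]
  life_table(df$age, df$qx)
}
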