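#' Construct and validate an age-indexed life table
#'
#' A life table supplies the background mortality that drives transitions to
#' the death states: all-cause and cardiovascular (CV) mortality rates per
#' person-year in 1-year age bins. Non-CV mortality is obtained inside the
#' engine by subtraction, so the CV rate may never exceed the all-cause rate.
#'
#' @param age Integer vector of ages (years); must be contiguous.
#' @param all_cause_rate All-cause mortality rate per person-year, by age.
#' @param cv_rate Cardiovascular mortality rate per person-year, by age.
#' @return A `data.frame` of class `cua_life_table` with columns
#'   `age`, `all_cause_rate`, `cv_rate`.
#' @export
life_table <- function(age, all_cause_rate, cv_rate) {
  lt <- data.frame(age = as.integer(age),
                   all_cause_rate = as.numeric(all_cause_rate),
                   cv_rate = as.numeric(cv_rate))
  class(lt) <- c("cua_life_table", "data.frame")
  validate_life_table(lt)
}

#' @rdname life_table
#' @param lt A candidate life table.
#' @export
validate_life_table <- function(lt) {
  req <- c("age", "all_cause_rate", "cv_rate")
  missing_cols <- setdiff(req, names(lt))
  if (length(missing_cols) > 0L)
    stop("life table is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(lt) == 0L) stop("life table has no rows")
  if (any(diff(lt$age) != 1L))
    stop("life table ages must be contiguous 1-year bins")
  if (any(lt$all_cause_rate < 0) || any(lt$cv_rate < 0))
    stop("life table rates must be non-negative")
  bad <- which(lt$cv_rate > lt$all_cause_rate)
  if (length(bad) > 0L)
    stop("cv_rate exceeds all_cause_rate at age(s): ",
         paste(lt$age[bad], collapse = ", "))
  if (!inherits(lt, "cua_life_table")) class(lt) <- c("cua_life_table", class(lt))
  lt
}

#' Read / write a life table as CSV
#'
#' The on-disk format is a plain CSV with columns `age`, `all_cause_rate`,
#' `cv_rate` (rates per person-year, 1-year age bins), the same format the
#' synthetic generator emits.
#'
#' @param path Path to a CSV file.
#' @return `read_life_table()` returns a validated `cua_life_table`;
#'   `write_life_table()` returns `path` invisibly.
#' @export
read_life_table <- function(path) {
  if (!file.exists(path)) stop("life table file not found: ", path)
  lt <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_life_table(lt)
}

#' @rdname read_life_table
#' @param lt A `cua_life_table`.
#' @export
write_life_table <- function(lt, path) {
  lt <- validate_life_table(lt)
  utils::write.csv(as.data.frame(lt)[, c("age", "all_cause_rate", "cv_rate")],
                   path, row.names = FALSE)
  invisible(path)
}

# Look up mortality at a (possibly fractional) age: floor() the age and clamp
# to the table's range so a cohort older than the last row reuses that row.
.life_table_lookup <- function(lt, age) {
  a <- floor(age)
  a <- pmin(pmax(a, lt$age[1L]), lt$age[nrow(lt)])
  i <- a - lt$age[1L] + 1L
  list(all_cause = lt$all_cause_rate[i], cv = lt$cv_rate[i])
}
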