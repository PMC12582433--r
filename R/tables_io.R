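#' Construct and validate an aggregated age-group table
#'
#' Registry sources publish incidence, mortality and prevalence aggregated into
#' age groups (typically five-year groups up to 84 plus one open group pooling
#' all ages 85 and older).  An `age_group_table` holds such rows in a validated
#' long format, one row per (year, sex, age group).
#'
#' @param year integer calendar years.
#' @param sex `"female"` or `"male"` per row.
#' @param age_low integer lower age bound of the group (inclusive).
#' @param age_high integer upper age bound (inclusive); a negative value or
#'   `NA` marks an open-ended top group (for example 85+).
#' @param value non-negative rate per person-year (`kind = "rate"`) or a
#'   proportion in `[0, 1)` (`kind = "proportion"`).
#' @param kind `"rate"` or `"proportion"`; controls the upper-bound check.
#'
#' @return A data frame of class `age_group_table` with columns `year`, `sex`,
#'   `age_low`, `age_high`, `open`, `value` and attribute `kind`.  Within each
#'   (year, sex) stratum the closed groups must be non-overlapping and
#'   contiguous, and an open group (if any) must sit above every closed group.
#' @seealso [read_age_group_table()], [rate_surface()]
#' @export
age_group_table <- function(year, sex, age_low, age_high, value,
                            kind = c("rate", "proportion")) {
  kind <- match.arg(kind)
  open <- is.na(age_high) | age_high < 0
  df <- data.frame(
    year = as.integer(year),
    sex = as.character(sex),
    age_low = as.integer(age_low),
    age_high = ifelse(open, NA_integer_, suppressWarnings(as.integer(age_high))),
    open = open,
    value = as.numeric(value),
    stringsAsFactors = FALSE
  )
  validate_age_group_table(df, kind)
  structure(df, class = c("age_group_table", "data.frame"), kind = kind)
}

validate_age_group_table <- function(df, kind) {
  if (nrow(df) == 0L) stop("age group table has no rows")
  bad <- which(!df$sex %in% c("female", "male"))
  if (length(bad)) {
    stop("invalid sex value in row(s) ", paste(bad, collapse = ", "),
         " (must be 'female' or 'male')")
  }
  bad <- which(!is.finite(df$value) | df$value < 0)
  if (length(bad)) {
    stop("negative or non-finite value in row(s) ", paste(bad, collapse = ", "))
  }
  if (kind == "proportion") {
    bad <- which(df$value >= 1)
    if (length(bad)) {
      stop("proportion >= 1 in row(s) ", paste(bad, collapse = ", "))
    }
  }
  bad <- which(!df$open & df$age_low > df$age_high)
  if (length(bad)) {
    stop("age_low > age_high in row(s) ", paste(bad, collapse = ", "))
  }
  for (key in split(seq_len(nrow(df)), list(df$year, df$sex), drop = TRUE)) {
    rows <- df[key, , drop = FALSE]
    if (sum(rows$open) > 1L) {
      stop("more than one open age group in stratum (", rows$year[1], ", ",
           rows$sex[1], ")")
    }
    closed <- rows[!rows$open, , drop = FALSE]
    if (nrow(closed) > 1L) {
      o <- order(closed$age_low)
      lo <- closed$age_low[o]
      hi <- closed$age_high[o]
      if (any(lo[-1] <= hi[-length(hi)])) {
        stop("overlapping age groups in stratum (", rows$year[1], ", ",
             rows$sex[1], ")")
      }
      if (any(lo[-1] != hi[-length(hi)] + 1L)) {
        stop("non-contiguous age coverage in stratum (", rows$year[1], ", ",
             rows$sex[1], ")")
      }
    }
    if (any(rows$open) && nrow(closed)) {
      if (rows$age_low[rows$open] <= max(closed$age_high)) {
        stop("open age group overlaps closed groups in stratum (",
             rows$year[1], ", ", rows$sex[1], ")")
      }
    }
  }
  invisible(df)
}

#' Read an aggregated age-group table from CSV
#'
#' Expects a UTF-8 comma-separated file with mandatory header
#' `year,sex,age_low,age_high,value`.  An open-ended top age group (85+) is
#' encoded in files as `age_high = -1`.
#'
#' @param path path to the CSV file.
#' @inheritParams age_group_table
#' @return A validated [age_group_table].
#' @export
read_age_group_table <- function(path, kind = c("rate", "proportion")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("year", "sex", "age_low", "age_high", "value")
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  }
  if (nrow(df) == 0L) stop("no rows in ", path)
  age_group_table(df$year, df$sex, df$age_low, df$age_high, df$value, kind = kind)
}

#' Construct and validate a single-age population table
#'
#' @param year integer calendar years.
#' @param sex `"female"` or `"male"`.
#' @param age integer single year of age.
#' @param count non-negative person count.
#' @return A data frame of class `population_table` with unique
#'   (year, sex, age) keys.
#' @export
population_table <- function(year, sex, age, count) {
  df <- data.frame(
    year = as.integer(year),
    sex = as.character(sex),
    age = as.integer(age),
    count = as.numeric(count),
    stringsAsFactors = FALSE
  )
  if (nrow(df) == 0L) stop("population table has no rows")
  bad <- which(!df$sex %in% c("female", "male"))
  if (length(bad)) stop("invalid sex value in row(s) ", paste(bad, collapse = ", "))
  bad <- which(!is.finite(df$count) | df$count < 0)
  if (length(bad)) stop("negative or non-finite count in row(s) ", paste(bad, collapse = ", "))
  key <- paste(df$year, df$sex, df$age)
  if (anyDuplicated(key)) {
    stop("duplicate (year, sex, age) key: ", key[which(duplicated(key))[1]])
  }
  structure(df, class = c("population_table", "data.frame"))
}

#' Read a population table from CSV
#'
#' Expects header `year,sex,age,count` with one row per (year, sex, single
#' year of age).
#'
#' @param path path to the CSV file.
#' @return A validated [population_table].
#' @export
read_population <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("year", "sex", "age", "count")
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  }
  if (nrow(df) == 0L) stop("no rows in ", path)
  population_table(df$year, df$sex, df$age, df$count)
}

#' Write a surface or table to long-format CSV
#'
#' Writes `year,sex,age,value` rows sorted by (sex, year, age).  Values are
#' serialised with 17 significant digits so that reading the file back
#' reproduces each double bit-exactly.
#'
#' @param x an [idm_prevalence] fit, a [survivors()] table, or a data frame
#'   with columns `year`, `sex`, `age`, `value`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_surface <- function(x, path) UseMethod("write_surface")

#' @export
write_surface.idm_prevalence <- function(x, path) {
  df <- as.data.frame(x)
  names(df)[names(df) == "prevalence"] <- "value"
  write_surface(df[c("year", "sex", "age", "value")], path)
}

#' @export
write_surface.survivor_table <- function(x, path) {
  df <- data.frame(year = x$year, sex = x$sex, age = x$age, value = x$survivors)
  write_surface(df, path)
}

#' @export
write_surface.data.frame <- function(x, path) {
  required <- c("year", "sex", "age", "value")
  miss <- setdiff(required, names(x))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  o <- order(x$sex, x$year, x$age)
  x <- x[o, required, drop = FALSE]
  lines <- c(
    "year,sex,age,value",
    sprintf("%d,%s,%d,%.17g", as.integer(x$year), x$sex, as.integer(x$age), x$value)
  )
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read back a long-format surface CSV written by [write_surface()]
#'
#' @param path file path.
#' @return Data frame with columns `year`, `sex`, `age`, `value`.
#' @export
read_surface <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("year", "sex", "age", "value")
  miss <- setdiff(required, names(df))
  if (length(miss)) stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  df
}
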