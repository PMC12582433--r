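#' Absolute survivor counts from a prevalence fit and population counts
#'
#' Multiplies the fitted prevalence surface cell-wise with population counts
#' to obtain the absolute number of people alive with a prior diagnosis.
#' Counts are kept as reals; rounding happens only in printed reports, so
#' totals do not accumulate rounding error.
#'
#' @param object an [idm_prevalence] fit.
#' @param population a [population_table] covering every (year, sex, age)
#'   cell of the fit.
#' @param ... unused.
#' @return A data frame of class `survivor_table` with columns `year`, `sex`,
#'   `age`, `prevalence`, `population`, `survivors`.
#' @export
survivors <- function(object, population, ...) UseMethod("survivors")

#' @rdname survivors
#' @export
survivors.idm_prevalence <- function(object, population, ...) {
  if (!inherits(population, "population_table")) {
    stop("'population' must be a population_table")
  }
  df <- object$prevalence
  key <- paste(df$year, df$sex, df$age)
  pkey <- paste(population$year, population$sex, population$age)
  idx <- match(key, pkey)
  if (anyNA(idx)) {
    missing_cell <- key[which(is.na(idx))[1]]
    stop("population table missing cell (year sex age): ", missing_cell)
  }
  out <- data.frame(
    year = df$year, sex = df$sex, age = df$age,
    prevalence = df$prevalence,
    population = population$count[idx],
    survivors = df$prevalence * population$count[idx],
    stringsAsFactors = FALSE
  )
  structure(out, class = c("survivor_table", "data.frame"))
}

#' Summarise a survivor table
#'
#' Aggregates survivor counts to totals per (year, sex), both-sex totals per
#' year, and reports the age of maximum prevalence per (year, sex), with ties
#' broken toward the older age (prevalence typically peaks at the oldest
#' ages).
#'
#' @param object a `survivor_table`.
#' @param ... unused.
#' @return List of class `summary.survivor_table` with data frames `by_sex`
#'   (`year`, `sex`, `total`, `age_max_prevalence`) and `combined`
#'   (`year`, `total`).
#' @export
summary.survivor_table <- function(object, ...) {
  strata <- unique(object[c("year", "sex")])
  by_sex <- do.call(rbind, lapply(seq_len(nrow(strata)), function(k) {
    sel <- object$year == strata$year[k] & object$sex == strata$sex[k]
    rows <- object[sel, ]
    data.frame(
      year = strata$year[k], sex = strata$sex[k],
      total = sum(rows$survivors),
      age_max_prevalence = max(rows$age[rows$prevalence == max(rows$prevalence)]),
      stringsAsFactors = FALSE
    )
  }))
  by_sex <- by_sex[order(by_sex$sex, by_sex$year), ]
  rownames(by_sex) <- NULL
  combined <- stats::aggregate(total ~ year, data = by_sex, FUN = sum)
  structure(list(by_sex = by_sex, combined = combined),
            class = "summary.survivor_table")
}

#' @export
print.summary.survivor_table <- function(x, ...) {
  cat("Survivors by year and sex:\n")
  df <- x$by_sex
  df$total <- round(df$total)
  print(df, row.names = FALSE)
  cat("\nBoth sexes combined:\n")
  cb <- x$combined
  cb$total <- round(cb$total)
  print(cb, row.names = FALSE)
  invisible(x)
}
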