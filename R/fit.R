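#' Estimate lifetime prevalence from aggregated registry tables
#'
#' Fits the illness-death-model prevalence equation
#' \deqn{(\partial_t + \partial_a)\, p = (1-p)\, i - p\,(m_1 - m)}
#' to aggregated inputs: an age-group incidence table, a general-population
#' mortality table, a mortality input for the diseased (either directly as
#' `diseased_mortality`, or derived from population-level cause-specific
#' mortality, see [m1_from_cause_specific()]), and an initial prevalence
#' profile for the first year.  Tables are interpolated into continuous rate
#' surfaces ([rate_surface()]) and the PDE is integrated along characteristic
#' lines ([solve_surface()]), independently per sex.
#'
#' @param incidence [age_group_table] (or CSV path) of incidence rates.
#' @param mortality [age_group_table] (or path) of general-population
#'   all-cause mortality rates.
#' @param prevalence_start [age_group_table] (or path, `kind = "proportion"`)
#'   with the initial prevalence profile; evaluated at the first output year.
#' @param cause_mortality [age_group_table] (or path) of population-level
#'   cause-specific mortality rates; required for
#'   `mortality_mode = "cause_specific"` (the default, matching what
#'   cause-of-death statistics publish).
#' @param diseased_mortality [age_group_table] (or path) of all-cause
#'   mortality among the diseased; required for `mortality_mode = "direct"`.
#' @param years `c(t0, t1)` output year range; defaults to the year range of
#'   the incidence table.
#' @param max_age last supported age (default 85, the open-group boundary of
#'   typical registry tables).
#' @param mortality_mode `"cause_specific"` (derive `m1` from `mu_c` and `m`
#'   at the current prevalence) or `"direct"` (use `diseased_mortality`).
#' @param anchor_prevalence_at_birth anchor the initial prevalence profile
#'   linearly to 0 at age 0 below its youngest data age (healthy-at-birth
#'   assumption); default `TRUE`.
#' @param sexes which strata to fit; defaults to the sexes present in the
#'   incidence table.
#' @param control a [solver_settings()] object.
#'
#' @return An object of class `idm_prevalence`: list with
#'   \item{prevalence}{long data frame `(year, sex, age, prevalence)`}
#'   \item{surfaces}{named list of per-sex `prevalence_surface` objects}
#'   \item{warnings}{per-sex clamp / negative-excess counters}
#'   plus the call, year/age grid and settings.  Methods: `print`, `summary`,
#'   `predict`, `plot`, `as.data.frame`, [survivors()].
#'
#' @examples
#' sc <- idm_scenario(t1 = 2012)
#' tr <- build_truth(sc, step = 0.01)
#' tabs <- aggregate_to_groups(tr)
#' fit <- idm_prevalence(tabs$incidence, tabs$mortality, tabs$prevalence,
#'                       cause_mortality = tabs$cause_mortality)
#' fit
#' @export
idm_prevalence <- function(incidence, mortality, prevalence_start,
                           cause_mortality = NULL, diseased_mortality = NULL,
                           years = NULL, max_age = 85,
                           mortality_mode = c("cause_specific", "direct"),
                           anchor_prevalence_at_birth = TRUE,
                           sexes = NULL,
                           control = solver_settings()) {
  mortality_mode <- match.arg(mortality_mode)
  as_table <- function(x, kind) {
    if (is.character(x)) read_age_group_table(x, kind = kind) else x
  }
  incidence <- as_table(incidence, "rate")
  mortality <- as_table(mortality, "rate")
  prevalence_start <- as_table(prevalence_start, "proportion")
  if (mortality_mode == "cause_specific") {
    if (is.null(cause_mortality)) {
      stop("mortality_mode = 'cause_specific' requires 'cause_mortality'")
    }
    cause_mortality <- as_table(cause_mortality, "rate")
  } else {
    if (is.null(diseased_mortality)) {
      stop("mortality_mode = 'direct' requires 'diseased_mortality'")
    }
    diseased_mortality <- as_table(diseased_mortality, "rate")
  }
  if (is.null(years)) years <- range(incidence$year)
  if (is.null(sexes)) sexes <- sort(unique(incidence$sex))
  if (max_age > 85) stop("max_age must not exceed 85 (no anchor beyond the open group)")

  surfaces <- list()
  warn <- list()
  for (sx in sexes) {
    i_s <- rate_surface(incidence, sx, "incidence")
    m_s <- rate_surface(mortality, sx, "general_mortality")
    p0_s <- rate_surface(prevalence_start, sx, "initial_prevalence",
                         anchor_zero_at_birth = anchor_prevalence_at_birth)
    rates <- if (mortality_mode == "cause_specific") {
      list(i = i_s, mu_c = rate_surface(cause_mortality, sx,
                                        "cause_specific_mortality"),
           m = m_s)
    } else {
      list(i = i_s, m1 = rate_surface(diseased_mortality, sx,
                                      "diseased_mortality"),
           m = m_s)
    }
    surfaces[[sx]] <- solve_surface(
      p0 = p0_s, rates = rates, years = years, ages = c(0, max_age),
      settings = control, mortality_mode = mortality_mode, sex = sx
    )
    warn[[sx]] <- surfaces[[sx]]$warnings
  }

  prev <- do.call(rbind, lapply(sexes, function(sx) {
    s <- surfaces[[sx]]
    data.frame(
      year = rep(s$years, times = length(s$ages)),
      sex = sx,
      age = rep(s$ages, each = length(s$years)),
      prevalence = as.vector(s$values),
      stringsAsFactors = FALSE
    )
  }))
  prev <- prev[order(prev$sex, prev$year, prev$age), ]
  rownames(prev) <- NULL

  structure(
    list(prevalence = prev, surfaces = surfaces, warnings = warn,
         years = years[1]:years[2], ages = 0:max_age, sexes = sexes,
         mortality_mode = mortality_mode, control = control,
         call = match.call()),
    class = "idm_prevalence"
  )
}

#' @export
print.idm_prevalence <- function(x, ...) {
  cat("Illness-death model prevalence estimate\n")
  cat("  years ", min(x$years), "-", max(x$years), ", ages ",
      min(x$ages), "-", max(x$ages), ", sexes: ",
      paste(x$sexes, collapse = ", "), "\n", sep = "")
  cat("  mortality mode: ", x$mortality_mode, "; scheme ",
      x$control$scheme, ", step ", x$control$step_size, " yr\n", sep = "")
  for (sx in x$sexes) {
    v <- x$surfaces[[sx]]$values
    cat(sprintf("  %-6s max prevalence %.4f (age %d, year %d)\n", sx,
                max(v),
                x$ages[which(v == max(v), arr.ind = TRUE)[1, 2]],
                x$years[which(v == max(v), arr.ind = TRUE)[1, 1]]))
  }
  invisible(x)
}

#' @export
summary.idm_prevalence <- function(object, ...) {
  rows <- do.call(rbind, lapply(object$sexes, function(sx) {
    s <- object$surfaces[[sx]]
    do.call(rbind, lapply(seq_along(s$years), function(k) {
      v <- s$values[k, ]
      peak <- max(s$ages[v == max(v)])  # ties broken toward the older age
      data.frame(year = s$years[k], sex = sx,
                 max_prevalence = max(v), age_at_max = peak,
                 stringsAsFactors = FALSE)
    }))
  }))
  out <- list(by_year = rows, warnings = object$warnings,
              years = object$years, sexes = object$sexes)
  class(out) <- "summary.idm_prevalence"
  out
}

#' @export
print.summary.idm_prevalence <- function(x, ...) {
  cat("Peak prevalence by year and sex:\n")
  print(x$by_year, row.names = FALSE)
  for (sx in x$sexes) {
    w <- x$warnings[[sx]]
    if (w$clamped > 0 || w$negative_excess > 0) {
      cat(sx, ": ", w$clamped, " clamp events, ", w$negative_excess,
          " negative-excess evaluations\n", sep = "")
    }
  }
  invisible(x)
}

#' Predict prevalence at arbitrary (year, age, sex) points
#'
#' Bilinear interpolation on the fitted surface; points outside the fitted
#' grid take the nearest grid value.
#'
#' @param object an `idm_prevalence` fit.
#' @param newdata data frame with columns `year`, `age`, `sex`.
#' @param ... unused.
#' @return Numeric vector of prevalence values.
#' @export
predict.idm_prevalence <- function(object, newdata, ...) {
  required <- c("year", "age", "sex")
  miss <- setdiff(required, names(newdata))
  if (length(miss)) stop("newdata must have columns: ", paste(miss, collapse = ", "))
  out <- numeric(nrow(newdata))
  for (sx in unique(newdata$sex)) {
    if (!sx %in% object$sexes) stop("no fitted surface for sex '", sx, "'")
    s <- object$surfaces[[sx]]
    surf <- rate_surface_grid(s$years, s$ages, s$values, sx, "prevalence")
    sel <- newdata$sex == sx
    out[sel] <- surface_value(surf, newdata$year[sel], newdata$age[sel])
  }
  out
}

#' @export
as.data.frame.idm_prevalence <- function(x, ...) x$prevalence

#' Plot fitted prevalence against age, one curve per year
#'
#' @param x an `idm_prevalence` fit.
#' @param sexes which panels to draw (default: all fitted).
#' @param ... passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.idm_prevalence <- function(x, sexes = x$sexes, ...) {
  old <- graphics::par(mfrow = c(1, length(sexes)))
  on.exit(graphics::par(old))
  cols <- grDevices::hcl.colors(length(x$years), "viridis")
  for (sx in sexes) {
    s <- x$surfaces[[sx]]
    graphics::matplot(s$ages, t(s$values), type = "l", lty = 1, col = cols,
                      xlab = "age (years)", ylab = "lifetime prevalence",
                      main = sx, ...)
    graphics::legend("topleft", legend = range(x$years), col = cols[c(1, length(cols))],
                     lty = 1, bty = "n", title = "year")
  }
  invisible(x)
}
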