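#' Interpolate an age-group table into a continuous rate surface
#'
#' Each closed five-year group `[L, H]` is anchored at its continuous-age
#' midpoint `(L + H + 1) / 2` (so 80--84 sits at 82.5), the standard
#' demographic convention for rates tabulated over `[L, H + 1)`.  Node values
#' are interpolated bilinearly in (calendar year, age) inside the grid hull and
#' extrapolated as constants outside it.  An open top group (85+) contributes
#' no node: there is no anchor point beyond the oldest midpoint, which is why
#' analyses based on such tables stop at age 85.
#'
#' @param table an [age_group_table].
#' @param sex which stratum to interpolate (`"female"` or `"male"`).
#' @param quantity free-text label for the rate carried by the surface, e.g.
#'   `"incidence"`, `"general_mortality"`, `"diseased_mortality"`,
#'   `"cause_specific_mortality"` or `"initial_prevalence"`.
#' @param anchor_zero_at_birth if `TRUE`, adds a node (age 0, value 0) to every
#'   year, so values below the youngest midpoint fall linearly to zero at
#'   birth.  Used for prevalence profiles under the healthy-at-birth
#'   assumption; without it, values below the youngest midpoint are constant.
#' @return An object of class `rate_surface` with fields `sex`, `quantity`,
#'   `years`, `ages`, `values` (matrix years x ages).
#' @examples
#' tab <- age_group_table(
#'   year = 2010, sex = "female", age_low = c(50, 55),
#'   age_high = c(54, 59), value = c(0.010, 0.020)
#' )
#' s <- rate_surface(tab, "female")
#' surface_value(s, 2010, 55)  # halfway between midpoints 52.5 and 57.5
#' @export
rate_surface <- function(table, sex, quantity = "rate",
                         anchor_zero_at_birth = FALSE) {
  if (!inherits(table, "age_group_table")) {
    stop("'table' must be an age_group_table")
  }
  rows <- table[table$sex == sex & !table$open, , drop = FALSE]
  if (!nrow(rows)) stop("no closed age groups for sex '", sex, "'")
  years <- sort(unique(rows$year))
  mids <- sort(unique((rows$age_low + rows$age_high + 1) / 2))
  V <- matrix(NA_real_, length(years), length(mids))
  for (k in seq_along(years)) {
    yr <- rows[rows$year == years[k], , drop = FALSE]
    if (nrow(yr) < 2L) {
      stop("stratum (", years[k], ", ", sex, ") has fewer than 2 closed age groups")
    }
    m <- (yr$age_low + yr$age_high + 1) / 2
    idx <- match(m, mids)
    V[k, idx] <- yr$value
  }
  if (anyNA(V)) stop("age groups differ across years for sex '", sex, "'")
  if (anchor_zero_at_birth && mids[1] > 0) {
    mids <- c(0, mids)
    V <- cbind(0, V)
  }
  structure(
    list(sex = sex, quantity = quantity, years = years, ages = mids, values = V),
    class = "rate_surface"
  )
}

#' Build a rate surface directly from grid values
#'
#' Used for surfaces that are already on a rectangular (year, age) grid, such
#' as consistent mortality surfaces produced by [build_truth()].
#'
#' @param years ordered grid years.
#' @param ages ordered grid ages.
#' @param values matrix `length(years)` x `length(ages)`.
#' @inheritParams rate_surface
#' @return A `rate_surface`.
#' @export
rate_surface_grid <- function(years, ages, values, sex = NA_character_,
                              quantity = "rate") {
  values <- as.matrix(values)
  if (nrow(values) != length(years) || ncol(values) != length(ages)) {
    stop("values must be a length(years) x length(ages) matrix")
  }
  if (any(!is.finite(values))) stop("non-finite values in grid")
  structure(
    list(sex = sex, quantity = quantity, years = as.numeric(years),
         ages = as.numeric(ages), values = values),
    class = "rate_surface"
  )
}

#' Evaluate a rate surface
#'
#' Bilinear interpolation inside the grid hull; nearest-value (constant)
#' extrapolation outside.  Evaluation at a grid node returns the stored value
#' exactly.
#'
#' @param surface a `rate_surface`.
#' @param year,age numeric vectors (recycled to a common length).
#' @return Numeric vector of interpolated values.
#' @export
surface_value <- function(surface, year, age) {
  n <- max(length(year), length(age))
  t <- rep_len(as.numeric(year), n)
  a <- rep_len(as.numeric(age), n)
  ty <- surface$years
  ta <- surface$ages
  V <- surface$values
  t <- pmin(pmax(t, ty[1]), ty[length(ty)])
  a <- pmin(pmax(a, ta[1]), ta[length(ta)])
  if (length(ty) == 1L) {
    iy <- rep_len(1L, n); iy2 <- iy; wy <- rep_len(0, n)
  } else {
    iy <- pmin(pmax(findInterval(t, ty), 1L), length(ty) - 1L)
    iy2 <- iy + 1L
    wy <- (t - ty[iy]) / (ty[iy2] - ty[iy])
  }
  if (length(ta) == 1L) {
    ia <- rep_len(1L, n); ia2 <- ia; wa <- rep_len(0, n)
  } else {
    ia <- pmin(pmax(findInterval(a, ta), 1L), length(ta) - 1L)
    ia2 <- ia + 1L
    wa <- (a - ta[ia]) / (ta[ia2] - ta[ia])
  }
  (1 - wy) * (1 - wa) * V[cbind(iy, ia)] +
    (1 - wy) * wa * V[cbind(iy, ia2)] +
    wy * (1 - wa) * V[cbind(iy2, ia)] +
    wy * wa * V[cbind(iy2, ia2)]
}

#' @export
print.rate_surface <- function(x, ...) {
  cat("Rate surface:", x$quantity,
      if (!is.na(x$sex)) paste0("(", x$sex, ")"), "\n")
  cat("  years:", min(x$years), "-", max(x$years),
      " ages:", min(x$ages), "-", max(x$ages),
      " nodes:", length(x$years), "x", length(x$ages), "\n")
  cat("  value range: [", format(min(x$values)), ",", format(max(x$values)), "]\n")
  invisible(x)
}

#' Derive the mortality of the diseased from cause-specific mortality
#'
#' Cause-of-death statistics report the population-level rate of deaths
#' attributed to the disease, `mu_c`, not the all-cause mortality `m1` of the
#' diseased that the illness-death model needs.  Under two assumptions --
#' (i) every cause-specific death occurs in a diseased person, and (ii) the
#' diseased die of other causes at the same rate as the non-diseased
#' (`m0 = m - mu_c`) -- the unique `m1` consistent with the mixing relation
#' `m = p * m1 + (1 - p) * m0` is
#' \deqn{m_1 = \mu_c / p + m - \mu_c.}
#'
#' @param mu_c cause-specific mortality rate (per person-year) in the total
#'   population.
#' @param m all-cause mortality rate of the general population.
#' @param p prevalence, strictly inside (0, 1).
#' @return The derived `m1` (vectorised over the inputs).  If `mu_c > m`
#'   anywhere, a warning flags the data inconsistency but the value is still
#'   returned.
#' @examples
#' m1_from_cause_specific(0.001, 0.02, 0.1)  # 0.029
#' @export
m1_from_cause_specific <- function(mu_c, m, p) {
  if (any(p <= 0 | p >= 1)) stop("p must lie strictly inside (0, 1)")
  if (any(mu_c > m)) {
    warning("cause-specific mortality exceeds general mortality somewhere ",
            "(inconsistent inputs); value computed anyway")
  }
  mu_c / p + m - mu_c
}

#' Excess-mortality contribution to the prevalence equation
#'
#' Returns `p * (m1 - m)`, the term by which mortality differences between the
#' diseased and the general population deplete (or, if `m1 < m`, inflate)
#' prevalence.  A negative excess is legal -- noisy inputs can produce it --
#' and is deliberately not clamped, since silent clamping would bias
#' prevalence upward.
#'
#' @param p prevalence in `[0, 1)`.
#' @param m1 all-cause mortality of the diseased.
#' @param m all-cause mortality of the general population.
#' @return `p * (m1 - m)`.
#' @export
excess_term <- function(p, m1, m) {
  if (any(p < 0 | p >= 1)) stop("p must lie in [0, 1)")
  p * (m1 - m)
}
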