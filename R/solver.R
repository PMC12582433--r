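#' Solver settings for the characteristic integrator
#'
#' @param step_size integration step in years; a small integer multiple of it
#'   must land on whole years (e.g. 0.5, 0.4, 0.25, 0.1), so that trajectories
#'   can be sampled on integer ages.  Steps that do not divide 1 evenly (such
#'   as 0.4) record only at the integer ages they actually hit.
#' @param scheme `"rk4"` (default, 4th order) or `"euler"` (1st order).
#' @param clamp_epsilon output prevalence is clamped into
#'   `[0, 1 - clamp_epsilon]`; must lie in `(0, 1e-6]`.  Clamping happens only
#'   at output and every clamp event is counted, because prevalence leaving
#'   `[0, 1)` signals a data problem rather than numerical noise.
#' @return A list of class `solver_settings`.
#' @export
solver_settings <- function(step_size = 0.1, scheme = c("rk4", "euler"),
                            clamp_epsilon = 1e-9) {
  scheme <- match.arg(scheme)
  if (!is.numeric(step_size) || length(step_size) != 1L || step_size <= 0 ||
      step_size > 1) {
    stop("step_size must be a positive number of at most 1 year")
  }
  if (is.null(step_alignment(step_size))) {
    stop("step_size must be a simple fraction of a year (k * step_size a ",
         "whole number of years for some small k), e.g. 0.5, 0.4, 0.25, 0.1")
  }
  if (!is.numeric(clamp_epsilon) || clamp_epsilon <= 0 || clamp_epsilon > 1e-6) {
    stop("clamp_epsilon must lie in (0, 1e-6]")
  }
  structure(
    list(step_size = step_size, scheme = scheme, clamp_epsilon = clamp_epsilon),
    class = "solver_settings"
  )
}

#' Right-hand side of the illness-death prevalence equation
#'
#' Along characteristic lines (constant age minus calendar time) the
#' illness-death-model PDE
#' \deqn{(\partial_t + \partial_a)\, p = (1-p)\, i - p\,(m_1 - m)}
#' reduces to an ODE with this right-hand side, where `i` is the incidence
#' rate, `m1` the all-cause mortality of the diseased and `m` the general
#' population mortality linked to the unknown `m0` by
#' `m = p * m1 + (1 - p) * m0`.
#'
#' @param p prevalence in `[0, 1)`.
#' @param i incidence rate (per person-year).
#' @param m1 mortality of the diseased.
#' @param m general-population mortality.
#' @return Rate of change of prevalence per year.
#' @examples
#' pde_rhs(0.2, 0.01, 0.05, 0.03)  # 0.8*0.01 - 0.2*0.02 = 0.004
#' @export
pde_rhs <- function(p, i, m1, m) {
  if (any(p < 0 | p >= 1)) stop("p must lie in [0, 1)")
  (1 - p) * i - p * (m1 - m)
}

#' Exact prevalence under constant incidence and no excess mortality
#'
#' When `m1 = m0` (mortality does not depend on disease status) and the
#' incidence `i` is constant, the healthy-at-birth solution is
#' `p(a) = 1 - exp(-i * a)`.  Used as an analytic oracle for the solver.
#'
#' @param i constant incidence rate.
#' @param a age (years).
#' @return `1 - exp(-i * a)`.
#' @export
closed_form_constant_rates <- function(i, a) {
  if (any(i < 0) || any(a < 0)) stop("i and a must be non-negative")
  1 - exp(-i * a)
}

# Normalise a rate input (rate_surface, function of (t, a) or (t, a, p), or a
# single constant) into a vectorised function(t, a, p).
as_rate_fun <- function(x, what = "rate") {
  if (inherits(x, "rate_surface")) {
    function(t, a, p) surface_value(x, t, a)
  } else if (is.function(x)) {
    if (length(formals(x)) >= 3L) x else function(t, a, p) x(t, a)
  } else if (is.numeric(x) && length(x) == 1L) {
    function(t, a, p) rep_len(as.numeric(x), max(length(t), length(a)))
  } else {
    stop(what, " must be a rate_surface, a function(t, a[, p]) or a single number")
  }
}

# Excess-term evaluator for the two mortality modes.  `counter` is an
# environment with fields `negative_excess` (evaluations with m1 < m).
# Mode "direct":          excess = p * (m1 - m)
# Mode "cause_specific":  m1 is derived from (mu_c, m) at the current p via
#   m1 = mu_c / p + m - mu_c and substituted; at p = 0 the limit of
#   p * (m1 - m) is mu_c, which closes the expression continuously.
make_excess_fun <- function(mortality_mode, rates, counter) {
  mfun <- as_rate_fun(rates$m, "m")
  if (mortality_mode == "direct") {
    m1fun <- as_rate_fun(rates$m1, "m1")
    function(p, t, a) {
      m1 <- m1fun(t, a, p)
      m <- mfun(t, a, p)
      counter$negative_excess <- counter$negative_excess + sum(m1 < m)
      p * (m1 - m)
    }
  } else {
    mufun <- as_rate_fun(rates$mu_c, "mu_c")
    function(p, t, a) {
      mu <- rep_len(mufun(t, a, p), length(p))
      m <- rep_len(mfun(t, a, p), length(p))
      ex <- mu
      pos <- p > 0
      if (any(pos)) {
        m1 <- mu[pos] / p[pos] + m[pos] - mu[pos]
        ex[pos] <- p[pos] * (m1 - m[pos])
      }
      counter$negative_excess <- counter$negative_excess + sum(ex < 0)
      ex
    }
  }
}

# Smallest k such that k * h is (numerically) a whole number of years;
# returns list(stride = k, years = k * h) or NULL if none up to k = 1000.
step_alignment <- function(h) {
  k1 <- round(1 / h)
  if (abs(k1 * h - 1) < 1e-9) {
    return(list(stride = as.integer(k1), years = 1L))
  }
  for (k in seq_len(1000L)) {
    if (abs(k * h - round(k * h)) < 1e-9 && round(k * h) >= 1) {
      return(list(stride = k, years = as.integer(round(k * h))))
    }
  }
  NULL
}

# Integrate a batch of characteristics simultaneously.
#
# Characteristic k starts at (t0s[k], a0s[k]) with prevalence p0s[k] and runs
# until age a0s[k] + spans[k] (spans are non-negative integers).  All
# characteristics advance with the common step h; prevalence is recorded at
# every integer age offset that a step lands on exactly (every age for steps
# dividing 1; every `align$years`-th age otherwise).  Returns a
# K x (max(spans) + 1) matrix of recordings (NA where nothing was recorded).
run_characteristics <- function(t0s, a0s, p0s, spans, ifun, exfun, settings) {
  h <- settings$step_size
  align <- step_alignment(h)
  K <- length(t0s)
  maxspan <- max(spans)
  rec <- matrix(NA_real_, K, maxspan + 1L)
  rec[, 1L] <- p0s
  if (maxspan == 0L) return(rec)
  bad <- which((spans %% align$years) != 0L)
  if (length(bad)) {
    stop("characteristic span ", spans[bad[1]], " is not a multiple of ",
         align$years, " years, the recording interval of step_size ", h)
  }
  p <- p0s
  nsteps_k <- as.integer(round(spans / h))
  rk4 <- settings$scheme == "rk4"
  for (j in seq_len(as.integer(round(maxspan / h)))) {
    act <- which(nsteps_k >= j)
    s <- (j - 1) * h
    t <- t0s[act] + s
    a <- a0s[act] + s
    pa <- p[act]
    if (rk4) {
      k1 <- (1 - pa) * ifun(t, a, pa) - exfun(pa, t, a)
      p2 <- pa + (h / 2) * k1
      k2 <- (1 - p2) * ifun(t + h / 2, a + h / 2, p2) - exfun(p2, t + h / 2, a + h / 2)
      p3 <- pa + (h / 2) * k2
      k3 <- (1 - p3) * ifun(t + h / 2, a + h / 2, p3) - exfun(p3, t + h / 2, a + h / 2)
      p4 <- pa + h * k3
      k4 <- (1 - p4) * ifun(t + h, a + h, p4) - exfun(p4, t + h, a + h)
      p[act] <- pa + (h / 6) * (k1 + 2 * k2 + 2 * k3 + k4)
    } else {
      p[act] <- pa + h * ((1 - pa) * ifun(t, a, pa) - exfun(pa, t, a))
    }
    if (any(!is.finite(p[act]))) {
      bad <- act[which(!is.finite(p[act]))[1]]
      stop("non-finite prevalence during integration at (t = ",
           t0s[bad] + j * h, ", a = ", a0s[bad] + j * h, ")")
    }
    if (j %% align$stride == 0L) {
      col <- (j %/% align$stride) * align$years + 1L
      rec[cbind(act, col)] <- p[act]
    }
  }
  rec
}

#' Integrate the prevalence ODE along one characteristic line
#'
#' Follows the line `(t + s, a + s)` from a starting point, integrating
#' `dp/ds = (1 - p) i - p (m1 - m)` with the chosen scheme, and returns the
#' trajectory sampled at integer ages.
#'
#' @param p_start prevalence at the starting point, in `[0, 1)`.
#' @param year,age starting calendar year and age.
#' @param end_age final age (integer offset from `age`).
#' @param rates named list of rate inputs: either `i`, `m1`, `m`
#'   (`mortality_mode = "direct"`) or `i`, `mu_c`, `m`
#'   (`mortality_mode = "cause_specific"`); each a [rate_surface], a
#'   function `(t, a)` or `(t, a, p)`, or a constant.
#' @param settings a [solver_settings()] object.
#' @param mortality_mode see [idm_prevalence()].
#' @return Data frame `(year, age, p)` at integer ages, with attribute
#'   `warnings` holding the clamp and negative-excess counters.
#' @export
solve_characteristic <- function(p_start, year, age, end_age, rates,
                                 settings = solver_settings(),
                                 mortality_mode = c("direct", "cause_specific")) {
  mortality_mode <- match.arg(mortality_mode)
  if (p_start < 0 || p_start >= 1) stop("p_start must lie in [0, 1)")
  span <- end_age - age
  if (span < 0) stop("end_age must be >= age")
  if (abs(span - round(span)) > 1e-9) stop("end_age - age must be an integer")
  counter <- new.env(parent = emptyenv())
  counter$negative_excess <- 0L
  ifun <- as_rate_fun(rates$i, "i")
  exfun <- make_excess_fun(mortality_mode, rates, counter)
  rec <- run_characteristics(year, age, p_start, as.integer(round(span)),
                             ifun, exfun, settings)
  p <- drop(rec)
  hi <- 1 - settings$clamp_epsilon
  clamped <- sum(p < 0 | p > hi, na.rm = TRUE)
  p <- pmin(pmax(p, 0), hi)
  out <- data.frame(
    year = year + seq_along(p) - 1,
    age = age + seq_along(p) - 1,
    p = p
  )
  out <- out[!is.na(out$p), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "warnings") <- list(clamped = clamped,
                                negative_excess = counter$negative_excess)
  out
}

#' Solve the prevalence surface on a (year, age) grid
#'
#' Every output cell `(t, a)` lies on exactly one characteristic line.  Cells
#' whose characteristic crosses the initial year `t0` at a non-negative age
#' are seeded from the initial prevalence profile `p0`; cells on cohorts born
#' after `t0` are seeded with prevalence 0 at birth (healthy-at-birth
#' boundary).  Characteristics are mutually independent, so the surface is a
#' deterministic function of the inputs.
#'
#' @param p0 initial prevalence at `t0`: a [rate_surface] (evaluated at
#'   `(t0, age)`), a function of age, or a numeric vector over the output ages.
#' @param rates as in [solve_characteristic()].
#' @param years length-2 vector `c(t0, t1)` of first and last output year.
#' @param ages length-2 vector `c(0, max_age)`; the lower bound must be 0.
#' @inheritParams solve_characteristic
#' @return An object of class `prevalence_surface`: list with `years`, `ages`,
#'   `values` (matrix years x ages, each value in `[0, 1)`), `settings`,
#'   `warnings` (clamp and negative-excess counters) and `sex` label.
#' @export
solve_surface <- function(p0, rates, years, ages = c(0, 85),
                          settings = solver_settings(),
                          mortality_mode = c("direct", "cause_specific"),
                          sex = NA_character_) {
  mortality_mode <- match.arg(mortality_mode)
  t0 <- years[1]; t1 <- years[2]
  if (t1 < t0) stop("years must be c(t0, t1) with t0 <= t1")
  if (ages[1] != 0) stop("age range must start at 0 (healthy-at-birth boundary)")
  amax <- ages[2]
  yrs <- t0:t1
  ags <- 0:amax
  p0v <- if (inherits(p0, "rate_surface")) {
    surface_value(p0, t0, ags)
  } else if (is.function(p0)) {
    rep_len(p0(ags), length(ags))
  } else {
    if (length(p0) == 1L) rep_len(as.numeric(p0), length(ags)) else as.numeric(p0)
  }
  if (length(p0v) != length(ags)) {
    stop("p0 must provide one value per output age (", length(ags), ")")
  }
  if (any(p0v < 0 | p0v >= 1)) stop("initial prevalence must lie in [0, 1)")

  # characteristics: initial profile at t0 (ages 0..amax) + later birth cohorts
  t0s <- c(rep(t0, length(ags)), if (t1 > t0) (t0 + 1):t1)
  a0s <- c(ags, rep(0L, max(t1 - t0, 0L)))
  p0s <- c(p0v, rep(0, max(t1 - t0, 0L)))
  spans <- pmin(amax - a0s, t1 - t0s)

  counter <- new.env(parent = emptyenv())
  counter$negative_excess <- 0L
  ifun <- as_rate_fun(rates$i, "i")
  exfun <- make_excess_fun(mortality_mode, rates, counter)
  rec <- run_characteristics(t0s, a0s, p0s, spans, ifun, exfun, settings)

  P <- matrix(NA_real_, length(yrs), length(ags),
              dimnames = list(yrs, ags))
  for (k in seq_along(t0s)) {
    off <- 0:spans[k]
    P[cbind(t0s[k] - t0 + 1L + off, a0s[k] + 1L + off)] <- rec[k, off + 1L]
  }
  hi <- 1 - settings$clamp_epsilon
  clamped <- sum(P < 0 | P > hi, na.rm = TRUE)
  P <- pmin(pmax(P, 0), hi)
  structure(
    list(sex = sex, years = yrs, ages = ags, values = P,
         settings = settings, mortality_mode = mortality_mode,
         warnings = list(clamped = clamped,
                         negative_excess = counter$negative_excess)),
    class = "prevalence_surface"
  )
}

#' @export
print.prevalence_surface <- function(x, ...) {
  cat("Prevalence surface",
      if (!is.na(x$sex)) paste0("(", x$sex, ")"), "\n")
  cat("  years ", min(x$years), "-", max(x$years),
      ", ages ", min(x$ages), "-", max(x$ages), "\n", sep = "")
  cat("  scheme ", x$settings$scheme, ", step ", x$settings$step_size,
      " yr, mode ", x$mortality_mode, "\n", sep = "")
  cat("  prevalence range: [", format(min(x$values)), ", ",
      format(max(x$values)), "]\n", sep = "")
  if (x$warnings$clamped > 0 || x$warnings$negative_excess > 0) {
    cat("  warnings: ", x$warnings$clamped, " clamp events, ",
        x$warnings$negative_excess, " negative-excess evaluations\n", sep = "")
  }
  invisible(x)
}
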