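#' Define a parametric synthetic scenario
#'
#' A scenario fixes smooth, fully known transition rates for a two-sex
#' population over a study decade, emulating the statistical structure of
#' registry inputs (incidence and cause-specific mortality by calendar year,
#' Gompertz background mortality, an initial prevalence profile):
#' \itemize{
#'   \item incidence `i(t, a) = alpha * f_sex * exp(beta * a) * max(0, 1 + gamma * (t - t0))`
#'     -- exponential in age with a linear secular trend (clamped at zero in
#'     the remote past so historical cohort rates stay non-negative);
#'   \item non-diseased mortality `m0(a) = gompertz_a * exp(gompertz_b * a)`;
#'   \item diseased mortality `m1 = m0 + delta(a) * max(0, 1 - excess_trend * (t - t0))`
#'     with a configurable non-negative excess `delta`.
#' }
#' Because the rates are known in closed form, the implied true prevalence can
#' be computed to arbitrary accuracy ([build_truth()]) and every downstream
#' pipeline stage is testable without external data.
#'
#' @param alpha incidence level at age 0 (per person-year).  The default
#'   `1e-5` with `beta = 0.09` gives about 0.02 per person-year at age 85,
#'   the magnitude cancer registries report, and a lifetime prevalence of
#'   roughly 0.2--0.35 at the oldest ages.
#' @param beta exponential age slope of incidence (per year of age).
#' @param gamma linear secular trend of incidence (per calendar year).
#' @param gompertz_a,gompertz_b Gompertz parameters of non-diseased mortality.
#' @param excess excess mortality of the diseased: a non-negative constant or
#'   a function of age (per person-year).
#' @param excess_trend linear decline of the excess per calendar year
#'   (0 = constant excess).
#' @param male_incidence_factor multiplier on male incidence (default 1.3,
#'   males typically carry higher cancer incidence).
#' @param t0,t1 first and last calendar year of the study window.
#' @param max_age oldest supported age (85).
#' @param seed integer seed used by default in the microsimulation.
#' @return An object of class `idm_scenario`.
#' @export
idm_scenario <- function(alpha = 1e-5, beta = 0.09, gamma = 0.02,
                         gompertz_a = 2e-5, gompertz_b = 0.095,
                         excess = 0.02, excess_trend = 0,
                         male_incidence_factor = 1.3,
                         t0 = 2010, t1 = 2019, max_age = 85, seed = 1L) {
  if (t1 <= t0) stop("t1 must be greater than t0")
  if (max_age <= 0 || max_age > 85) stop("max_age must lie in (0, 85]")
  excess_fun <- if (is.function(excess)) excess else {
    if (excess < 0) stop("excess must be non-negative")
    function(a) rep_len(excess, length(a))
  }
  structure(
    list(alpha = alpha, beta = beta, gamma = gamma,
         gompertz_a = gompertz_a, gompertz_b = gompertz_b,
         excess_fun = excess_fun, excess_trend = excess_trend,
         male_incidence_factor = male_incidence_factor,
         t0 = t0, t1 = t1, max_age = max_age, seed = as.integer(seed),
         sexes = c("female", "male")),
    class = "idm_scenario"
  )
}

#' @export
print.idm_scenario <- function(x, ...) {
  cat("Synthetic illness-death scenario, years ", x$t0, "-", x$t1,
      ", ages 0-", x$max_age, "\n", sep = "")
  cat(sprintf("  incidence: %.3g * exp(%.3g a) * (1 + %.3g (t - %d)), male x %.2f\n",
              x$alpha, x$beta, x$gamma, x$t0, x$male_incidence_factor))
  cat(sprintf("  m0: Gompertz %.3g * exp(%.3g a); excess trend %.3g / yr; seed %d\n",
              x$gompertz_a, x$gompertz_b, x$excess_trend, x$seed))
  invisible(x)
}

#' True transition-rate functions of a scenario
#'
#' @param scenario an [idm_scenario].
#' @param sex `"female"` or `"male"`.
#' @return Named list of vectorised functions `i(t, a)`, `m0(t, a)`,
#'   `m1(t, a)`.
#' @export
scenario_rates <- function(scenario, sex) {
  sc <- scenario
  fac <- if (sex == "male") sc$male_incidence_factor else 1
  list(
    i = function(t, a) {
      n <- max(length(t), length(a))
      rep_len(sc$alpha * fac * exp(sc$beta * a) *
                pmax(0, 1 + sc$gamma * (t - sc$t0)), n)
    },
    m0 = function(t, a) {
      n <- max(length(t), length(a))
      rep_len(sc$gompertz_a * exp(sc$gompertz_b * a) + 0 * t, n)
    },
    m1 = function(t, a) {
      n <- max(length(t), length(a))
      rep_len(sc$gompertz_a * exp(sc$gompertz_b * a) +
                sc$excess_fun(a) * pmax(0, 1 - sc$excess_trend * (t - sc$t0)), n)
    }
  )
}

# Reference integration of the cohort ODE system, vectorised over birth
# cohorts.  Along a cohort born in year b the prevalence obeys
#   dp/da = (1 - p) i(b + a, a) - p (1 - p) (m1 - m0),
# which is the characteristic form of the PDE rewritten with m0/m1 instead of
# the population mixture m -- an independent route from the production solver.
# Optionally tracks the cumulative all-cause hazard H(a) = int_0^a m da with
# m = p m1 + (1 - p) m0, giving the cohort survivorship exp(-H).
#
# births: vector of birth years; a_end: per-cohort final age (multiples of
# record_da); returns p (and H) matrices K x (max records + 1), recorded at
# ages 0, record_da, 2*record_da, ...
integrate_cohorts <- function(births, a_end, rates, step = 1e-3,
                              record_da = 1, track_hazard = FALSE) {
  nsub <- round(record_da / step)
  if (abs(nsub * step - record_da) > 1e-9) {
    stop("step must divide record_da evenly")
  }
  nrec_k <- as.integer(round(a_end / record_da))
  if (any(abs(a_end / record_da - nrec_k) > 1e-9)) {
    stop("a_end must be multiples of record_da")
  }
  K <- length(births)
  maxrec <- max(nrec_k)
  P <- matrix(NA_real_, K, maxrec + 1L)
  P[, 1L] <- 0
  H <- if (track_hazard) matrix(NA_real_, K, maxrec + 1L) else NULL
  if (track_hazard) H[, 1L] <- 0
  p <- numeric(K)
  hz <- numeric(K)
  ifun <- rates$i; m0fun <- rates$m0; m1fun <- rates$m1
  deriv <- function(pp, t, a) {
    m0 <- m0fun(t, a)
    m1 <- m1fun(t, a)
    dp <- (1 - pp) * ifun(t, a) - pp * (1 - pp) * (m1 - m0)
    dh <- if (track_hazard) pp * m1 + (1 - pp) * m0 else NULL
    list(dp = dp, dh = dh)
  }
  h <- step
  for (j in seq_len(maxrec * nsub)) {
    act <- which(nrec_k * nsub >= j)
    a <- (j - 1) * h
    t <- births[act] + a
    pa <- p[act]
    k1 <- deriv(pa, t, a)
    p2 <- pa + (h / 2) * k1$dp
    k2 <- deriv(p2, t + h / 2, a + h / 2)
    p3 <- pa + (h / 2) * k2$dp
    k3 <- deriv(p3, t + h / 2, a + h / 2)
    p4 <- pa + h * k3$dp
    k4 <- deriv(p4, t + h, a + h)
    p[act] <- pa + (h / 6) * (k1$dp + 2 * k2$dp + 2 * k3$dp + k4$dp)
    if (track_hazard) {
      hz[act] <- hz[act] + (h / 6) * (k1$dh + 2 * k2$dh + 2 * k3$dh + k4$dh)
    }
    if (j %% nsub == 0L) {
      col <- j %/% nsub + 1L
      P[cbind(act, col)] <- p[act]
      if (track_hazard) H[cbind(act, col)] <- hz[act]
    }
  }
  list(p = P, H = H, births = births,
       ages = seq(0, maxrec * record_da, by = record_da))
}

#' Compute the exact truth implied by a scenario
#'
#' Reference-integrates the cohort ODE system along characteristic lines at
#' high resolution for every birth cohort reaching the output grid, assuming
#' all cohorts start healthy at birth.  Emits, per sex, the true prevalence
#' `p*(t, a)` together with the consistent general mortality
#' `m = p* m1 + (1 - p*) m0` and cause-specific mortality
#' `mu_c = p* (m1 - m0)`, so the mixing relation holds at every grid node by
#' construction.
#'
#' @param scenario an [idm_scenario].
#' @param step integration step in years (default `1e-3`).
#' @param ages integer output ages.
#' @return Object of class `idm_truth`: list with `scenario`, `years`, `ages`,
#'   `step` and per-sex element `surfaces[[sex]]` holding matrices `p_star`,
#'   `m`, `mu_c` (years x ages).
#' @export
build_truth <- function(scenario, step = 1e-3, ages = 0:scenario$max_age) {
  years <- scenario$t0:scenario$t1
  amax <- max(ages)
  births <- (min(years) - amax):max(years)
  a_end <- pmin(amax, max(years) - births)
  surfaces <- list()
  for (sx in scenario$sexes) {
    rates <- scenario_rates(scenario, sx)
    ref <- integrate_cohorts(births, a_end, rates, step = step, record_da = 1)
    P <- matrix(NA_real_, length(years), length(ages),
                dimnames = list(years, ages))
    for (ri in seq_along(years)) {
      for (ci in seq_along(ages)) {
        b <- years[ri] - ages[ci]
        P[ri, ci] <- ref$p[match(b, births), ages[ci] + 1L]
      }
    }
    bad <- !is.finite(P) | P >= 1
    if (any(bad)) {
      loc <- which(bad, arr.ind = TRUE)[1, ]
      stop("scenario produces prevalence >= 1 (or non-finite) at (year ",
           years[loc[1]], ", age ", ages[loc[2]], ")")
    }
    tm <- matrix(rep(years, times = length(ages)), length(years))
    am <- matrix(rep(ages, each = length(years)), length(years))
    m0v <- matrix(rates$m0(as.vector(tm), as.vector(am)), length(years))
    m1v <- matrix(rates$m1(as.vector(tm), as.vector(am)), length(years))
    surfaces[[sx]] <- list(
      p_star = P,
      m = P * m1v + (1 - P) * m0v,
      mu_c = P * (m1v - m0v)
    )
  }
  structure(
    list(scenario = scenario, years = years, ages = ages, step = step,
         surfaces = surfaces),
    class = "idm_truth"
  )
}

#' @export
print.idm_truth <- function(x, ...) {
  cat("Scenario truth bundle, years ", min(x$years), "-", max(x$years),
      ", ages ", min(x$ages), "-", max(x$ages),
      ", reference step ", x$step, " yr\n", sep = "")
  for (sx in names(x$surfaces)) {
    cat(sprintf("  %-6s max true prevalence %.4f\n", sx,
                max(x$surfaces[[sx]]$p_star)))
  }
  invisible(x)
}

#' Aggregate scenario truth into registry-style age-group tables
#'
#' Collapses the smooth truth into five-year age groups 0--84 plus an open
#' 85+ group, the schema registries publish.  Group values are person-time
#' weighted averages of the truth over the group's age span, with weights
#' given by the scenario's implied cohort survivorship -- mimicking how
#' registries compute rates (events over person-years), which is exactly the
#' aggregation the midpoint interpolation later has to undo.
#'
#' @param truth an [build_truth()] result.
#' @param group_width width of the closed age groups (5).
#' @param open_from lower bound of the open top group (85).
#' @param open_upper age at which the open group's person-time integral is
#'   truncated (survivorship beyond is negligible).
#' @param da fine age resolution of the person-time integrals.
#' @param step ODE step used for the fine truth evaluation.
#' @return Named list of [age_group_table]s covering both sexes:
#'   `incidence`, `mortality` (general), `cause_mortality`, and `prevalence`
#'   (first year only, `kind = "proportion"`), in the exact input schema the
#'   readers and [idm_prevalence()] expect.
#' @export
aggregate_to_groups <- function(truth, group_width = 5, open_from = 85,
                                open_upper = 95, da = 0.25, step = 0.01) {
  sc <- truth$scenario
  years <- truth$years
  afine <- seq(0, open_upper, by = da)
  births <- seq(min(years) - open_upper, max(years), by = da)
  a_end <- pmin(open_upper, max(years) - births)
  a_end <- floor(a_end / da + 1e-9) * da
  lows <- seq(0, open_from - group_width, by = group_width)
  rows <- list()
  for (sx in sc$sexes) {
    rates <- scenario_rates(sc, sx)
    ref <- integrate_cohorts(births, a_end, rates, step = step,
                             record_da = da, track_hazard = TRUE)
    lookup <- function(t, a) {
      ib <- round((t - a - births[1]) / da) + 1L
      ia <- round(a / da) + 1L
      cbind(ib, ia)
    }
    for (t in years) {
      idx <- lookup(t, afine)
      p_f <- ref$p[idx]
      S_f <- exp(-ref$H[idx])
      m0_f <- rates$m0(t, afine)
      m1_f <- rates$m1(t, afine)
      i_f <- rates$i(t, afine)
      m_f <- p_f * m1_f + (1 - p_f) * m0_f
      mu_f <- p_f * (m1_f - m0_f)
      group_avg <- function(v, lo, hi) {
        sel <- which(afine >= lo - 1e-9 & afine <= hi + 1e-9)
        w <- rep(1, length(sel)); w[1] <- 0.5; w[length(w)] <- 0.5
        w <- w * S_f[sel]
        sum(w * v[sel]) / sum(w)
      }
      spans <- rbind(cbind(lows, lows + group_width),
                     c(open_from, open_upper))
      for (g in seq_len(nrow(spans))) {
        lo <- spans[g, 1]; hi <- spans[g, 2]
        open <- lo >= open_from
        rows[[length(rows) + 1L]] <- data.frame(
          year = t, sex = sx, age_low = lo,
          age_high = if (open) NA_integer_ else as.integer(hi - 1),
          i = group_avg(i_f, lo, hi),
          m = group_avg(m_f, lo, hi),
          mu = group_avg(mu_f, lo, hi),
          p = group_avg(p_f, lo, hi),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  df <- do.call(rbind, rows)
  first <- df[df$year == min(years), ]
  list(
    incidence = age_group_table(df$year, df$sex, df$age_low, df$age_high,
                                df$i, kind = "rate"),
    mortality = age_group_table(df$year, df$sex, df$age_low, df$age_high,
                                df$m, kind = "rate"),
    cause_mortality = age_group_table(df$year, df$sex, df$age_low, df$age_high,
                                      df$mu, kind = "rate"),
    prevalence = age_group_table(first$year, first$sex, first$age_low,
                                 first$age_high, first$p, kind = "proportion")
  )
}

#' Deterministic synthetic population consistent with a scenario
#'
#' Builds single-age population counts whose survivorship follows the
#' scenario's all-cause mortality `m = p* m1 + (1 - p*) m0` along each birth
#' cohort, with an optional Gaussian birth-cohort bump mimicking the post-war
#' baby boom that shapes real population pyramids.
#'
#' @param scenario an [idm_scenario].
#' @param base_cohort births per cohort year (default 800000, a realistic
#'   national birth-cohort size).
#' @param boom_year center of the optional birth bump (`NULL` = no bump).
#' @param boom_amp relative amplitude of the bump.
#' @param boom_width Gaussian width (years) of the bump.
#' @param step ODE step for the survivorship integration.
#' @return A [population_table] covering years `t0..t1`, ages `0..max_age`,
#'   both sexes.
#' @export
make_population <- function(scenario, base_cohort = 8e5, boom_year = NULL,
                            boom_amp = 0.3, boom_width = 6, step = 0.01) {
  if (base_cohort <= 0) stop("base_cohort must be positive")
  sc <- scenario
  years <- sc$t0:sc$t1
  amax <- sc$max_age
  births <- (min(years) - amax):max(years)
  a_end <- pmin(amax, max(years) - births)
  size <- rep(base_cohort, length(births))
  if (!is.null(boom_year)) {
    size <- size * (1 + boom_amp * exp(-0.5 * ((births - boom_year) / boom_width)^2))
  }
  out <- list()
  for (sx in sc$sexes) {
    rates <- scenario_rates(sc, sx)
    ref <- integrate_cohorts(births, a_end, rates, step = step,
                             record_da = 1, track_hazard = TRUE)
    for (ri in seq_along(years)) {
      t <- years[ri]
      a <- 0:amax
      ib <- match(t - a, births)
      cnt <- size[ib] * exp(-ref$H[cbind(ib, a + 1L)])
      out[[length(out) + 1L]] <- data.frame(
        year = t, sex = sx, age = a, count = cnt, stringsAsFactors = FALSE
      )
    }
  }
  df <- do.call(rbind, out)
  population_table(df$year, df$sex, df$age, df$count)
}
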