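test_that("pde_rhs matches the illness-death prevalence equation", {
  expect_equal(pde_rhs(0, 0.02, 0.5, 0.1), 0.02)   # empty-prevalence limit
  expect_equal(pde_rhs(0.5, 0, 0.03, 0.03), 0)     # equilibrium
  expect_equal(pde_rhs(0.2, 0.01, 0.05, 0.03), 0.004)
  expect_error(pde_rhs(1, 0.01, 0.05, 0.03), "\\[0, 1\\)")
  expect_error(pde_rhs(-0.1, 0.01, 0.05, 0.03), "\\[0, 1\\)")
})

test_that("closed-form constant-rate prevalence is 1 - exp(-i a)", {
  expect_equal(closed_form_constant_rates(0, 0:85), rep(0, 86))
  expect_equal(closed_form_constant_rates(0.01, 50), 0.3934693, tolerance = 1e-6)
  expect_equal(closed_form_constant_rates(0.1, 10), 0.6321206, tolerance = 1e-6)
})

test_that("characteristic integration reproduces analytic limits", {
  # constant incidence, no excess mortality: exponential limit
  tr <- solve_characteristic(0, 2010, 0, 85,
                             list(i = 0.01, m1 = 0.02, m = 0.02))
  expect_lt(max(abs(tr$p - closed_form_constant_rates(0.01, tr$age))), 1e-6)
  expect_equal(tr$age, 0:85)
  expect_equal(tr$year, 2010:2095)

  # no incidence, no excess: prevalence is conserved
  tr <- solve_characteristic(0.3, 2010, 20, 60,
                             list(i = 0, m1 = 0.05, m = 0.05))
  expect_equal(tr$p, rep(0.3, 41), tolerance = 1e-14)

  # pure excess decay: dp/ds = -p (m1 - m), exponential in the m-form
  tr <- solve_characteristic(0.3, 2010, 50, 60,
                             list(i = 0, m1 = 0.04, m = 0.02))
  expect_equal(tr$p[11], 0.3 * exp(-0.02 * 10), tolerance = 1e-9)
})

test_that("trajectories agree with an independent ODE solver", {
  ifun <- function(t, a) 1e-4 * exp(0.08 * a) * (1 + 0.01 * (t - 2010))
  m1fun <- function(t, a) 2e-5 * exp(0.09 * a) + 0.03
  mfun <- function(t, a) 2e-5 * exp(0.09 * a) + 0.005
  tr <- solve_characteristic(0.01, 2010, 0, 80,
                             list(i = ifun, m1 = m1fun, m = mfun))
  ref <- deSolve::ode(
    y = c(p = 0.01), times = 0:80,
    func = function(s, y, parms) {
      list((1 - y) * ifun(2010 + s, s) - y * (m1fun(2010 + s, s) - mfun(2010 + s, s)))
    },
    rtol = 1e-12, atol = 1e-12
  )
  expect_lt(max(abs(tr$p - ref[, "p"])), 1e-8)
})

test_that("surface solve honours boundaries and the initial profile", {
  # null scenario: everything zero
  fit <- solve_surface(0, list(i = 0, m1 = 0, m = 0), c(2010, 2019))
  expect_true(all(fit$values == 0))

  # constant incidence, p0 = 0: each cell depends only on time in the domain
  fit <- solve_surface(0, list(i = 0.02, m1 = 0.01, m = 0.01), c(2010, 2019))
  for (cell in list(c(2012, 0), c(2015, 5), c(2010, 40), c(2019, 85))) {
    t <- cell[1]; a <- cell[2]
    expect_equal(fit$values[as.character(t), as.character(a)],
                 1 - exp(-0.02 * min(a, t - 2010)), tolerance = 1e-9,
                 label = paste("cell", t, a))
  }
  # healthy-at-birth boundary and initial profile
  p0 <- 0.001 * (0:85)
  fit <- solve_surface(p0, list(i = 0.01, m1 = 0.02, m = 0.015), c(2010, 2019))
  expect_equal(unname(fit$values[1, ]), p0)
  expect_true(all(fit$values[-1, 1] == 0))
})

test_that("solution stays in [0, 1) for random non-negative rate fields", {
  set.seed(99)
  for (rep in 1:10) {
    years <- 2010:2014
    ages <- seq(0, 85, by = 5)
    rand <- function(scale) {
      matrix(runif(length(years) * length(ages), 0, scale), length(years))
    }
    # consistent mortality pair: diseased mortality at least the population's
    mv <- rand(0.4)
    fit <- solve_surface(
      runif(86, 0, 0.5),
      list(i = rate_surface_grid(years, ages, rand(0.8)),
           m1 = rate_surface_grid(years, ages, mv + rand(0.4)),
           m = rate_surface_grid(years, ages, mv)),
      c(2010, 2014),
      settings = solver_settings(step_size = 0.25)  # <= 0.25 / max rate
    )
    expect_equal(fit$warnings$clamped, 0)
    expect_true(all(fit$values >= 0 & fit$values < 1))
  }
})

test_that("cells are independent across characteristics", {
  rates <- list(i = function(t, a) 1e-4 * exp(0.07 * a), m1 = 0.03, m = 0.02)
  p0 <- 0.002 * (0:85)
  fit <- solve_surface(p0, rates, c(2010, 2019))
  # re-solve individual cells from their own characteristic start
  for (cell in list(c(2013, 20), c(2019, 85), c(2015, 3), c(2011, 84))) {
    t <- cell[1]; a <- cell[2]
    if (a - (t - 2010) >= 0) {
      a0 <- a - (t - 2010)
      tr <- solve_characteristic(p0[a0 + 1], 2010, a0, a, rates)
    } else {
      tr <- solve_characteristic(0, t - a, 0, a, rates)
    }
    expect_equal(fit$values[as.character(t), as.character(a)],
                 tr$p[nrow(tr)], tolerance = 1e-14,
                 label = paste("cell", t, a))
  }
})

test_that("prevalence increases with age when incidence is positive and excess zero", {
  tr <- solve_characteristic(0, 2010, 0, 85,
                             list(i = function(t, a) 1e-4 * exp(0.06 * a),
                                  m1 = function(t, a) 1e-5 * exp(0.09 * a),
                                  m = function(t, a) 1e-5 * exp(0.09 * a)))
  expect_true(all(diff(tr$p) > 0))
})

test_that("cause-specific mode equals the derived-m1 substitution", {
  tru <- build_truth(idm_scenario(t1 = 2014), step = 0.01)
  s <- tru$surfaces$female
  mu_s <- rate_surface_grid(tru$years, tru$ages, s$mu_c)
  m_s <- rate_surface_grid(tru$years, tru$ages, s$m)
  ifun <- scenario_rates(tru$scenario, "female")$i
  modeB <- solve_surface(s$p_star[1, ], list(i = ifun, mu_c = mu_s, m = m_s),
                         range(tru$years), mortality_mode = "cause_specific")
  # independent route: the simplified algebra (1-p)(i - mu_c) expressed as a
  # direct-mode solve with shifted incidence and zero excess
  simplified <- solve_surface(
    s$p_star[1, ],
    list(i = function(t, a) ifun(t, a) - surface_value(mu_s, t, a),
         m1 = m_s, m = m_s),
    range(tru$years), mortality_mode = "direct"
  )
  expect_lt(max(abs(modeB$values - simplified$values)), 1e-13)
  # and the explicit m1(t, a, p) substitution through the direct-mode path
  m1fun <- function(t, a, p) {
    mu <- surface_value(mu_s, t, a); m <- surface_value(m_s, t, a)
    ifelse(p > 0, mu / p + m - mu, m)
  }
  # at p = 0 the excess term vanishes either way, so the two paths agree
  derived <- solve_surface(s$p_star[1, ],
                           list(i = ifun, m1 = m1fun, m = m_s),
                           range(tru$years), mortality_mode = "direct")
  expect_lt(max(abs(modeB$values - derived$values)), 1e-12)
})

test_that("solver settings validate step and clamp parameters", {
  expect_error(solver_settings(step_size = 0), "positive")
  expect_error(solver_settings(step_size = 0.3001), "fraction")
  expect_error(solver_settings(clamp_epsilon = 1e-3), "clamp_epsilon")
  expect_silent(solver_settings(step_size = 0.4))
  # a 0.4 step records every second age, so odd spans are rejected
  expect_error(
    solve_characteristic(0, 2010, 0, 5, list(i = 0.01, m1 = 0, m = 0),
                         solver_settings(0.4)),
    "multiple"
  )
  tr <- solve_characteristic(0, 2010, 0, 6, list(i = 0.01, m1 = 0, m = 0),
                             solver_settings(0.4))
  expect_equal(tr$age, seq(0, 6, by = 2))
})

test_that("clamp events are counted, not hidden", {
  # m1 < m inflates prevalence; an extreme negative excess pushes p toward 1
  fit <- solve_surface(0.9, list(i = 2, m1 = 0, m = 5), c(2010, 2012),
                       settings = solver_settings(step_size = 0.05))
  expect_gt(fit$warnings$clamped, 0)
  expect_true(all(fit$values < 1))
  expect_gt(fit$warnings$negative_excess, 0)
})
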