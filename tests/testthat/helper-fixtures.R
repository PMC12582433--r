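# Shared fixtures built in code (no data files).

# Five-year age-group table over a rectangular (year, sex) design with values
# supplied by a function f(year, sex, mid).
make_group_table <- function(years, sexes = c("female", "male"),
                             lows = seq(0, 80, by = 5), f,
                             kind = "rate", open85 = TRUE) {
  rows <- expand.grid(year = years, sex = sexes, low = lows,
                      stringsAsFactors = FALSE)
  rows$high <- rows$low + 4L
  rows$value <- f(rows$year, rows$sex, (rows$low + rows$high + 1) / 2)
  if (open85) {
    op <- expand.grid(year = years, sex = sexes, stringsAsFactors = FALSE)
    op$low <- 85L; op$high <- NA_integer_
    op$value <- f(op$year, op$sex, 87.5)
    rows <- rbind(rows, op)
  }
  age_group_table(rows$year, rows$sex, rows$low, rows$high, rows$value,
                  kind = kind)
}

# Lazy cache for the expensive default-scenario reference computations shared
# by the acceptance checks.
.accept_cache <- new.env(parent = emptyenv())

default_truth <- function() {
  if (is.null(.accept_cache$truth)) {
    .accept_cache$truth <- build_truth(idm_scenario(), step = 1e-3)
  }
  .accept_cache$truth
}

# Production-path (cause-specific mode) solve from the truth's consistent
# surfaces for one sex.
solve_from_truth <- function(truth, sx, settings = solver_settings()) {
  s <- truth$surfaces[[sx]]
  solve_surface(
    p0 = s$p_star[1, ],
    rates = list(
      i = scenario_rates(truth$scenario, sx)$i,
      mu_c = rate_surface_grid(truth$years, truth$ages, s$mu_c, sx),
      m = rate_surface_grid(truth$years, truth$ages, s$m, sx)
    ),
    years = range(truth$years), ages = c(0, max(truth$ages)),
    settings = settings, mortality_mode = "cause_specific", sex = sx
  )
}
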