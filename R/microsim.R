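#' Stochastic three-state cohort microsimulation
#'
#' Simulates individuals through the illness-death model (healthy -> ill,
#' healthy -> dead, ill -> dead; no remission) in discrete time under the
#' scenario's true rates, as an oracle that is statistically -- not
#' numerically -- tied to the PDE solution.  Individuals are allocated evenly
#' across birth cohorts so that every (year, age) cell of the study window is
#' observed; each is stepped from birth with per-step exit probabilities
#' `1 - exp(-rate * dt)` evaluated at the current (calendar time, age), with a
#' healthy individual's exit allocated between illness and death in
#' proportion to the competing rates.
#'
#' @param scenario an [idm_scenario].
#' @param n_per_sex individuals simulated per sex.
#' @param seed RNG seed (defaults to the scenario's stored seed); a single
#'   shared stream makes runs exactly reproducible.
#' @param dt time step in years; must divide 1 evenly and be at most 0.1.
#' @param sexes strata to simulate.
#' @param births birth-cohort years; defaults to every cohort reaching the
#'   study window (`t0 - max_age` through `t1`).
#' @return A data frame of class `idm_microsim` with columns `sex`, `year`,
#'   `age`, `healthy`, `ill`, `dead` -- the state occupancy of the simulated
#'   cohorts at each integer (year, age) cell of the study window.
#' @export
simulate_cohort <- function(scenario, n_per_sex = 200000,
                            seed = scenario$seed, dt = 0.05,
                            sexes = scenario$sexes, births = NULL) {
  sc <- scenario
  if (dt > 0.1 + 1e-12) stop("dt must be at most 0.1")
  nsub <- round(1 / dt)
  if (abs(nsub * dt - 1) > 1e-9) stop("dt must divide 1.0 evenly")
  if (n_per_sex < 1) stop("n_per_sex must be at least 1")
  if (is.null(births)) births <- (sc$t0 - sc$max_age):sc$t1
  set.seed(seed)
  years <- sc$t0:sc$t1
  nyears <- length(years)
  amax <- sc$max_age
  out <- list()
  for (sx in sexes) {
    rates <- scenario_rates(sc, sx)
    nb <- diff(round(seq(0, n_per_sex, length.out = length(births) + 1)))
    birth <- rep(births, nb)
    n <- length(birth)
    state <- integer(n)  # 0 healthy, 1 ill, 2 dead
    counts <- array(0L, dim = c(nyears, amax + 1L, 3L))
    for (j in 0:(amax * nsub)) {
      a <- j * dt
      if (j %% nsub == 0L) {
        a_int <- j %/% nsub
        yy <- birth + a_int
        sel <- which(yy >= sc$t0 & yy <= sc$t1)
        if (length(sel)) {
          yi <- yy[sel] - sc$t0 + 1L
          st <- state[sel]
          for (s in 0:2) {
            tb <- tabulate(yi[st == s], nbins = nyears)
            counts[, a_int + 1L, s + 1L] <- counts[, a_int + 1L, s + 1L] + tb
          }
        }
        if (a_int == amax) break
      }
      ih <- which(state == 0L)
      if (length(ih)) {
        t <- birth[ih] + a
        iv <- rates$i(t, a)
        m0v <- rates$m0(t, a)
        tot <- iv + m0v
        u <- stats::runif(length(ih))
        leave <- which(tot > 0 & u < 1 - exp(-tot * dt))
        if (length(leave)) {
          to_ill <- stats::runif(length(leave)) < iv[leave] / tot[leave]
          state[ih[leave[to_ill]]] <- 1L
          state[ih[leave[!to_ill]]] <- 2L
        }
      }
      ii <- which(state == 1L)
      if (length(ii)) {
        t <- birth[ii] + a
        m1v <- rates$m1(t, a)
        u <- stats::runif(length(ii))
        state[ii[u < 1 - exp(-m1v * dt)]] <- 2L
      }
    }
    out[[sx]] <- data.frame(
      sex = sx,
      year = rep(years, times = amax + 1L),
      age = rep(0:amax, each = nyears),
      healthy = as.vector(counts[, , 1L]),
      ill = as.vector(counts[, , 2L]),
      dead = as.vector(counts[, , 3L]),
      stringsAsFactors = FALSE
    )
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  structure(df, class = c("idm_microsim", "data.frame"),
            n_per_sex = n_per_sex, dt = dt, seed = seed)
}

#' Simulate a scenario (microsimulation oracle)
#'
#' `simulate()` method wrapping [simulate_cohort()].
#'
#' @param object an [idm_scenario].
#' @param nsim must be 1 (one occupancy table per call).
#' @param seed RNG seed.
#' @param ... passed to [simulate_cohort()].
#' @return See [simulate_cohort()].
#' @export
simulate.idm_scenario <- function(object, nsim = 1, seed = object$seed, ...) {
  if (nsim != 1) stop("nsim must be 1")
  simulate_cohort(object, seed = seed, ...)
}

#' Prevalence estimates from microsimulation occupancy counts
#'
#' @param counts an [simulate_cohort()] result.
#' @return Data frame `sex, year, age, alive, p_hat, se`; cells with nobody
#'   alive are flagged missing (`NA`), not zero.  `p_hat = ill / alive` among
#'   the alive, `se = sqrt(p_hat (1 - p_hat) / alive)`.
#' @export
estimate_prevalence <- function(counts) {
  alive <- counts$healthy + counts$ill
  p_hat <- ifelse(alive > 0, counts$ill / alive, NA_real_)
  se <- ifelse(alive > 0, sqrt(p_hat * (1 - p_hat) / alive), NA_real_)
  data.frame(
    sex = counts$sex, year = counts$year, age = counts$age,
    alive = alive, p_hat = p_hat, se = se,
    stringsAsFactors = FALSE
  )
}

#' Compare the PDE solution against the microsimulation oracle
#'
#' Solves the prevalence surface from the scenario's consistent rate surfaces
#' (cause-specific mode, the production path), runs the microsimulation at
#' the same conditions, and checks cell-wise agreement within
#' `3 * SE + allowance`, where the allowance absorbs the discretisation bias
#' of both the solver and the discrete-time simulation.
#'
#' @param scenario an [idm_scenario].
#' @param n_per_sex,seed,dt microsimulation size, seed and step.
#' @param settings solver settings for the PDE side.
#' @param allowance additive discretisation allowance (default 0.002).
#' @param truth optionally a precomputed [build_truth()] bundle (reused to
#'   avoid re-integrating the reference).
#' @return List of class `idm_validation`: cell-wise comparison data frame,
#'   the fraction of cells within bounds, the maximum absolute difference,
#'   and a pass verdict (`frac_within >= 0.99`).
#' @export
oracle_comparison <- function(scenario, n_per_sex = 200000,
                              seed = scenario$seed, dt = 0.05,
                              settings = solver_settings(),
                              allowance = 0.002, truth = NULL) {
  if (is.null(truth)) truth <- build_truth(scenario)
  sim <- simulate_cohort(scenario, n_per_sex = n_per_sex, seed = seed, dt = dt)
  est <- estimate_prevalence(sim)
  cells <- list()
  for (sx in scenario$sexes) {
    tr <- truth$surfaces[[sx]]
    fit <- solve_surface(
      p0 = tr$p_star[1, ],
      rates = list(
        i = scenario_rates(scenario, sx)$i,
        mu_c = rate_surface_grid(truth$years, truth$ages, tr$mu_c, sx,
                                 "cause_specific_mortality"),
        m = rate_surface_grid(truth$years, truth$ages, tr$m, sx,
                              "general_mortality")
      ),
      years = range(truth$years), ages = c(0, max(truth$ages)),
      settings = settings, mortality_mode = "cause_specific", sex = sx
    )
    e <- est[est$sex == sx, ]
    p_pde <- fit$values[cbind(match(e$year, fit$years), match(e$age, fit$ages))]
    cells[[sx]] <- data.frame(
      sex = sx, year = e$year, age = e$age,
      p_pde = p_pde, p_sim = e$p_hat, se = e$se,
      within = abs(p_pde - e$p_hat) <= 3 * e$se + allowance,
      stringsAsFactors = FALSE
    )
  }
  cells <- do.call(rbind, cells)
  rownames(cells) <- NULL
  ok <- cells$within[!is.na(cells$within)]
  res <- list(
    cells = cells,
    n_cells = length(ok),
    frac_within = mean(ok),
    max_abs_diff = max(abs(cells$p_pde - cells$p_sim), na.rm = TRUE),
    n_per_sex = n_per_sex, dt = dt, seed = seed, allowance = allowance,
    pass = mean(ok) >= 0.99
  )
  class(res) <- "idm_validation"
  res
}

#' @export
print.idm_validation <- function(x, ...) {
  cat("PDE vs microsimulation oracle (n per sex = ", x$n_per_sex,
      ", dt = ", x$dt, ", seed = ", x$seed, ")\n", sep = "")
  cat(sprintf("  cells within 3 SE + %.3g: %.2f%% of %d\n",
              x$allowance, 100 * x$frac_within, x$n_cells))
  cat(sprintf("  max |p_PDE - p_sim| = %.5f\n", x$max_abs_diff))
  cat("  verdict:", if (x$pass) "PASS" else "FAIL", "\n")
  invisible(x)
}
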