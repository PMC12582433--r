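test_that("truth reduces to the exponential limit without excess mortality", {
  # constant incidence, delta = 0: p*(a) = 1 - exp(-i a) regardless of m0
  sc <- idm_scenario(alpha = 0.01, beta = 0, gamma = 0, excess = 0,
                     male_incidence_factor = 1, t1 = 2012, seed = 5)
  tru <- build_truth(sc, step = 0.005)
  for (sx in c("female", "male")) {
    p <- tru$surfaces[[sx]]$p_star
    expect_equal(as.vector(p),
                 as.vector(outer(rep(1, 3), 1 - exp(-0.01 * (0:85)))),
                 tolerance = 1e-8)
    expect_equal(max(abs(tru$surfaces[[sx]]$mu_c)), 0)
  }
})

test_that("zero incidence gives zero prevalence and cause-specific mortality", {
  sc <- idm_scenario(alpha = 0, t1 = 2012)
  tru <- build_truth(sc, step = 0.01)
  expect_true(all(tru$surfaces$male$p_star == 0))
  expect_true(all(tru$surfaces$male$mu_c == 0))
  # general mortality then equals the Gompertz background
  expect_equal(unname(tru$surfaces$male$m[1, ]), 2e-5 * exp(0.095 * (0:85)),
               tolerance = 1e-12)
})

test_that("truth bundle is internally consistent", {
  sc <- idm_scenario(t1 = 2013)
  tru <- build_truth(sc, step = 0.01)
  for (sx in sc$sexes) {
    s <- tru$surfaces[[sx]]
    expect_true(all(s$p_star >= 0 & s$p_star < 1))
    expect_true(all(s$mu_c <= s$m + 1e-15))  # cause deaths subset of all deaths
    expect_true(all(s$mu_c >= 0))
    rates <- scenario_rates(sc, sx)
    # with m = p m1 + (1-p) m0 and mu_c = p (m1 - m0), non-cause mortality
    # in the whole population is exactly the background rate: m - mu_c = m0
    for (cell in list(c(1, 41), c(3, 86), c(2, 1))) {
      t <- tru$years[cell[1]]; a <- tru$ages[cell[2]]
      expect_equal(s$m[cell[1], cell[2]] - s$mu_c[cell[1], cell[2]],
                   rates$m0(t, a), tolerance = 1e-14)
    }
  }
  # male incidence factor lifts male prevalence
  expect_true(all(tru$surfaces$male$p_star[, -1] >
                    tru$surfaces$female$p_star[, -1]))
  # regeneration is bit-identical (fully deterministic generator)
  expect_identical(tru$surfaces, build_truth(sc, step = 0.01)$surfaces)
})

test_that("scenario rejects rates that break the prevalence bound", {
  sc <- idm_scenario(alpha = 1, beta = 0.12, t1 = 2012)
  expect_error(build_truth(sc, step = 0.05), "prevalence")
})

test_that("aggregation reproduces person-time-weighted group averages", {
  sc <- idm_scenario(t1 = 2012)
  tru <- build_truth(sc, step = 0.01)
  tabs <- aggregate_to_groups(tru, step = 0.025)
  # schema closure: every emitted table passes tables_io validation
  expect_s3_class(tabs$incidence, "age_group_table")
  expect_s3_class(tabs$prevalence, "age_group_table")
  expect_identical(attr(tabs$prevalence, "kind"), "proportion")
  expect_true(any(tabs$incidence$open))
  expect_equal(sort(unique(tabs$incidence$year)), 2010:2012)
  expect_equal(unique(tabs$prevalence$year), 2010)

  # independent oracle for one closed group: trapezoid person-time average
  # of the true incidence over [50, 55] with survivorship weights
  rates <- scenario_rates(sc, "female")
  da <- 0.05
  ag <- seq(0, 55, by = da)
  m_approx <- rates$m0(2011, ag)  # p* tiny at these ages; m ~ m0
  S <- exp(-cumsum(c(0, (m_approx[-1] + m_approx[-length(ag)]) / 2 * da)))
  sel <- ag >= 50
  w <- rep(1, sum(sel)); w[1] <- 0.5; w[length(w)] <- 0.5
  expected <- sum(w * S[sel] * rates$i(2011, ag[sel])) / sum(w * S[sel])
  got <- tabs$incidence$value[tabs$incidence$year == 2011 &
                                tabs$incidence$sex == "female" &
                                !tabs$incidence$open &
                                tabs$incidence$age_low == 50]
  expect_equal(got, expected, tolerance = 1e-3)

  # truth constant in age: group averages equal the constant
  scc <- idm_scenario(alpha = 0.005, beta = 0, gamma = 0, excess = 0,
                      male_incidence_factor = 1, t1 = 2012)
  tabsc <- aggregate_to_groups(build_truth(scc, step = 0.01), step = 0.025)
  expect_equal(tabsc$incidence$value, rep(0.005, nrow(tabsc$incidence)),
               tolerance = 1e-12)
})

test_that("synthetic population follows the implied survivorship", {
  # zero mortality: flat population at base_cohort for every age
  sc0 <- idm_scenario(alpha = 0.001, beta = 0, gamma = 0, excess = 0,
                      gompertz_a = 0, t1 = 2012)
  pop0 <- make_population(sc0, base_cohort = 1000, step = 0.05)
  expect_true(all(pop0$count == 1000))
  expect_equal(nrow(pop0), 3 * 86 * 2)

  # doubling the cohort size doubles every count
  sc <- idm_scenario(t1 = 2012)
  p1 <- make_population(sc, base_cohort = 1e5, step = 0.05)
  p2 <- make_population(sc, base_cohort = 2e5, step = 0.05)
  expect_equal(p2$count, 2 * p1$count, tolerance = 1e-12)

  # Gompertz mortality: counts strictly decrease with age within a year
  for (t in 2010:2012) {
    cnt <- p1$count[p1$year == t & p1$sex == "female"]
    expect_true(all(diff(cnt) < 0))
  }

  # baby-boom bump shows up as a local maximum around the boom cohort
  pb <- make_population(sc, base_cohort = 1e5, boom_year = 1964,
                        boom_amp = 0.5, step = 0.05)
  cnt <- pb$count[pb$year == 2010 & pb$sex == "male"]
  age_at_boom <- 2010 - 1964
  expect_gt(cnt[age_at_boom + 1], cnt[age_at_boom - 7])
})
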