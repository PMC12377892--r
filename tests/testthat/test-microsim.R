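test_that("a cycle with zero hazards only ages the individual", {
  m <- toy_model(inc = 0, mort = 0, cf = 0, bg = 0)
  ind <- list(id = 1L, sex = "male", current_age = 50,
              smoking_state = "current", disease_history = NULL, alive = TRUE)
  out <- step_individual(ind, m, year = 1,
                         draws = list(u_smoke = 0.99, u_event = 0.5,
                                      u_bg = 0.5))
  expect_equal(out$current_age, 51)
  expect_true(out$alive)
  expect_equal(out$smoking_state, "current")
  expect_null(out$disease_history)
})

test_that("forced outcomes propagate: certain event with certain case fatality kills", {
  m <- toy_model(inc = 1e6, cf = 1, bg = 0)  # hazard so large p -> 1
  ind <- list(id = 1L, sex = "female", current_age = 40,
              smoking_state = "never", disease_history = NULL, alive = TRUE)
  out <- step_individual(ind, m, year = 3,
                         draws = list(u_smoke = 0.5, u_event = 0.9999,
                                      u_bg = 0.99))
  expect_false(out$alive)
  expect_equal(out$cause_of_death, "ami")
  expect_equal(out$disease_history$ami, 3)
})

test_that("per-cycle event probability follows the hazard-RR identity", {
  h <- 0.01
  m <- toy_model(inc = h, rr_current = 2, cf = 0, bg = 0,
                 prev_current = 1, prev_former = 0)
  s <- simulate_population(m, 200000, 31, "factual", horizon = 1)
  p_hat <- sum(s$events) / s$n
  p_theory <- 1 - exp(-2 * h)
  se <- sqrt(p_theory * (1 - p_theory) / s$n)
  expect_lt(abs(p_hat - p_theory), 3 * se)
})

test_that("identical (model, n, seed) reproduce bit-identical results", {
  m <- peru_like_model()
  a <- simulate_population(m, 2000, 17, "factual", horizon = 5)
  b <- simulate_population(m, 2000, 17, "factual", horizon = 5)
  expect_identical(a, b)
})

test_that("with all RRs at 1 the factual and counterfactual aggregates coincide", {
  m <- toy_model(rr_current = 1, rr_former = 1, cessation = 0)
  f <- simulate_population(m, 20000, 4, "factual", horizon = 10)
  cf <- simulate_population(m, 20000, 4, "never_smoker", horizon = 10)
  expect_identical(f$deaths, cf$deaths)
  expect_identical(f$events, cf$events)
})

test_that("common random numbers make smoking harm sign-definite", {
  # with all RRs >= 1 and shared uniforms, every counterfactual death is
  # also a factual death and every counterfactual acute event is also a
  # factual event; chronic incident events are masked by the (larger)
  # factual prevalent pool and attributable cells are floored instead
  m <- peru_like_model()
  for (seed in 1:4) {
    f <- simulate_population(m, 4000, seed, "factual", horizon = 1)
    cf <- simulate_population(m, 4000, seed, "never_smoker", horizon = 1)
    expect_gte(sum(f$deaths), sum(cf$deaths))
    acute <- which(f$acute)
    expect_true(all(f$events[acute, , , ] - cf$events[acute, , , ] >= 0))
    ac <- attributable_counts(f, cf)
    expect_true(all(ac$attr_deaths >= 0) && all(ac$attr_events >= 0))
  }
})

test_that("person-years are conserved and bounded by simulated years", {
  m <- peru_like_model()
  s <- simulate_population(m, 3000, 8, "factual", horizon = 7)
  expect_equal(s$person_years, sum(s$py_state))
  expect_lte(s$person_years, 3000 * 7)
  # one person-year per individual alive at each cycle start
  s1 <- simulate_population(m, 3000, 8, "factual", horizon = 1)
  expect_equal(s1$person_years, 3000)
})

test_that("deaths never exceed the number simulated and everyone dies in a lifetime run", {
  m <- toy_model()
  s <- simulate_population(m, 5000, 12, "factual", "lifetime")
  expect_equal(sum(s$deaths), 5000)
  expect_lte(max(s$deaths), 5000)
})

test_that("mean age at death matches the geometric-lifetime oracle under constant hazard", {
  mu <- 0.2
  m <- toy_model(inc = 0, cf = 0, mort = 0, bg = mu,
                 prev_current = 0.3, prev_former = 0.2)
  s <- simulate_population(m, 40000, 21, "factual", "lifetime")
  # numeric oracle: start age uniform on 35..104, death in year t w.p.
  # (1-p)^(t-1) p, forced at 104; age at death = a + t - 1
  p <- 1 - exp(-mu)
  ages <- 35:104
  e_age <- mean(vapply(ages, function(a) {
    tmax <- 104 - a + 1
    t <- seq_len(tmax)
    pr <- (1 - p)^(t - 1) * p
    pr[tmax] <- pr[tmax] + (1 - p)^tmax  # forced terminal death
    sum((a + t - 1) * pr) / sum(pr)
  }, 0))
  got <- life_expectancy(s, "male", "never")
  # uniform start ages dominate the variance: sd ~ 20y, 3 SE ~ 0.45
  expect_lt(abs(got - e_age), 0.45)
  # no smoking effect: states agree within Monte-Carlo error
  expect_lt(abs(life_expectancy(s, "male", "current") -
                  life_expectancy(s, "male", "never")), 0.8)
})

test_that("life expectancy orders never > former > current on the fixture", {
  m <- peru_like_model()
  s <- simulate_population(m, 40000, 6, "factual", "lifetime")
  for (sx in c("male", "female")) {
    le_n <- life_expectancy(s, sx, "never")
    le_f <- life_expectancy(s, sx, "former")
    le_c <- life_expectancy(s, sx, "current")
    expect_gt(le_n, le_f)
    expect_gt(le_f, le_c)
  }
  expect_error(life_expectancy(s, "male", "no-such-state"))
  s1 <- simulate_population(m, 100, 6, "factual", horizon = 1)
  expect_error(life_expectancy(s1, "male", "never"), "lifetime")
})

test_that("argument validation rejects empty cohorts and bad modes", {
  m <- toy_model()
  expect_error(simulate_population(m, 0, 1), "positive")
  expect_error(simulate_population(m, 10, 1, "smoke-sometimes"))
  expect_error(simulate_population(m, 10, 1, horizon = -3), "horizon")
})
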