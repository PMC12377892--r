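test_that("post-policy prevalence equals prev * (1 - Em * Ip) to machine precision", {
  expect_equal(post_policy_prevalence(0.10, 0.20, 0.5), 0.09)
  expect_equal(post_policy_prevalence(0.071, 0, 0.5), 0.071)
  expect_equal(post_policy_prevalence(0.071, 1, 1), 0)
  grid <- expand.grid(prev = seq(0, 1, by = 0.1),
                      em = seq(0, 1, by = 0.25),
                      ip = seq(0, 1, by = 0.25))
  got <- with(grid, post_policy_prevalence(prev, em, ip))
  expect_equal(got, with(grid, prev * (1 - em * ip)), tolerance = 1e-15)
  expect_true(all(got >= 0))
  expect_error(post_policy_prevalence(1.2, 0.5, 0.5), "\\[0,1\\]")
})

test_that("tax effect follows the constant-elasticity approximation", {
  expect_equal(tax_effect(0.50, -0.4), 0.20)
  expect_equal(tax_effect(0, -0.4), 0)
  expect_equal(tax_effect(10, -0.4), 1)  # capped
  ems <- tax_effect(c(0.25, 0.50, 0.75), -0.4)
  expect_true(all(diff(ems) > 0))
  expect_error(tax_effect(-0.1, -0.4), ">= 0")
  expect_error(tax_effect(0.5, 0.4), "<= 0")
})

test_that("tax revenue change follows the absorption algebra", {
  # no price change -> no revenue change
  expect_equal(tax_revenue_change(0, -0.4, 1e6, 0.733, 10), 0)
  # zero elasticity -> revenue grows exactly by the added tax
  expect_equal(tax_revenue_change(0.25, 0, 1e6, 0.733, 10),
               0.25 * 10 * 1e6)
  # inelastic demand on a realistic grid keeps the change positive
  for (e in c(-0.2, -0.4, -0.6)) for (pi in c(0.25, 0.5, 0.75)) {
    expect_gt(tax_revenue_change(pi, e, 1e6, 0.733, 10), 0)
  }
  # oracle: direct evaluation of new tax x remaining demand - old tax
  pi <- 0.5; e <- -0.4; c0 <- 2e6; ts <- 0.7; p <- 12
  em <- abs(e) * pi
  expect_equal(tax_revenue_change(pi, e, c0, ts, p),
               (ts * p + pi * p) * c0 * (1 - em) - ts * p * c0)
})

test_that("scenario construction derives Em for taxes and checks ranges", {
  sc <- policy_scenario("tax50", "tax", price_increase = 0.5,
                        elasticity = -0.4)
  expect_equal(sc$effectiveness_Em, 0.2)
  expect_error(policy_scenario("tax", "tax"), "price_increase")
  expect_error(policy_scenario("x", "packaging"), "effectiveness_Em")
  expect_error(policy_scenario("x", "packaging", effectiveness_Em = 0.1,
                               horizon_years = 0), "horizon")
})

test_that("a zero-effect scenario reproduces the base case bit-exactly", {
  m <- peru_like_model()
  r <- run_scenario(m, policy_scenario("null", "packaging",
                                       effectiveness_Em = 0), 3000, 5)
  expect_true(all(unlist(r$avoided) == 0))
  expect_true(all(r$by_group$avoided_deaths == 0))
  expect_true(all(r$by_group$avoided_cost == 0))
})

test_that("avoided burden is monotone in effectiveness at matched seeds", {
  m <- peru_like_model()
  run_em <- function(em, n = 8000) run_scenario(
    m, policy_scenario(paste0("em", em), "packaging",
                       effectiveness_Em = em), n, 23)
  r1 <- run_em(0.1); r2 <- run_em(0.3); r3 <- run_em(0.6)
  avoided <- c(r1$avoided$deaths, r2$avoided$deaths, r3$avoided$deaths)
  expect_true(all(diff(avoided) > 0))
  expect_true(all(avoided >= 0))
  # approximate proportionality: doubling Em roughly doubles avoided
  # deaths (mild saturation and Monte-Carlo error allowed for)
  ra <- run_em(0.4, 20000); rb <- run_em(0.8, 20000)
  expect_gt(rb$avoided$deaths / ra$avoided$deaths, 1.4)
  expect_lt(rb$avoided$deaths / ra$avoided$deaths, 2.6)
})

test_that("smoke-free scenarios scale the secondhand-smoke row", {
  m <- peru_like_model()
  base <- run_scenario(m, policy_scenario("sf0", "smokefree",
                                          effectiveness_Em = 0.05,
                                          shs_risk_reduction = 0),
                       4000, 31)
  red <- run_scenario(m, policy_scenario("sf", "smokefree",
                                         effectiveness_Em = 0.05,
                                         shs_risk_reduction = 0.5),
                      4000, 31)
  g0 <- base$by_group[base$by_group$group == "shs_other", ]
  g1 <- red$by_group[red$by_group$group == "shs_other", ]
  expect_gt(g1$avoided_deaths, g0$avoided_deaths)
  expect_equal(g1$deaths_base, g0$deaths_base)
})

test_that("scenario tables order bounds around the point estimate", {
  m <- peru_like_model()
  r <- run_scenario(m, policy_scenario("pp", "packaging",
                                       effectiveness_Em = 0.1,
                                       em_range = c(0.05, 0.2)),
                    4000, 13)
  expect_false(is.null(r$bounds))
  expect_lte(r$bounds$lo$deaths, r$avoided$deaths)
  expect_lte(r$avoided$deaths, r$bounds$hi$deaths)
  tab <- scenario_table(list(r))
  expect_true(all(tab$avoided_deaths_total_lo <= tab$avoided_deaths_total_hi))
  # point scenario: bounds equal the point estimate
  rp <- run_scenario(m, policy_scenario("pt", "packaging",
                                        effectiveness_Em = 0.1), 4000, 13)
  tp <- scenario_table(list(rp))
  expect_equal(tp$avoided_deaths_total_lo, tp$avoided_deaths_total_hi)
  # cost savings decompose into the four categories
  expect_equal(sum(rp$cost_savings_by_category), rp$cost_savings_total,
               tolerance = 1e-10)
})
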