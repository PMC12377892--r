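test_that("inflation and currency conversion follow the published constants", {
  expect_equal(adjust_inflation(100, 0.1047), 110.47)
  expect_equal(adjust_inflation(0, 0.1047), 0)
  expect_equal(adjust_inflation(250, 0), 250)
  expect_error(adjust_inflation(-5, 0.1), ">= 0")
  expect_equal(convert_currency(3.3, 3.3), 1)
  expect_equal(convert_currency(0, 3.3), 0)
  expect_equal(convert_currency(330, 3.3), 100)
  expect_error(convert_currency(10, 0), "> 0")
  # conversion and inflation commute (both multiplicative)
  expect_equal(convert_currency(adjust_inflation(500, 0.1047), 3.3),
               adjust_inflation(convert_currency(500, 3.3), 0.1047))
})

test_that("the Mincer wage equation evaluates its log-linear form", {
  ec <- econ_params(mincer = list(
    male = c(beta0 = 0, beta_edu = 0, beta_age = 0, beta_age2 = 0),
    female = c(beta0 = log(100), beta_edu = 0, beta_age = 0, beta_age2 = 0)))
  expect_equal(mincer_wage(40, "male", 11, ec), 1)
  expect_equal(mincer_wage(40, "female", 11, ec), 100)
  ec2 <- econ_params(mincer = list(
    male = c(beta0 = 9, beta_edu = 0.08, beta_age = 0.05,
             beta_age2 = -0.0005),
    female = c(beta0 = 9, beta_edu = 0.08, beta_age = 0.05,
               beta_age2 = -0.0005)))
  expect_equal(mincer_wage(40, "male", 11, ec2),
               exp(9 + 0.08 * 11 + 0.05 * 40 - 0.0005 * 1600))
})

test_that("present value of future income matches the geometric-series oracle", {
  const_wage <- function(a) 100
  ec <- econ_params(discount_rate = 0.05, wage_growth_rate = 0,
                    retirement_age = c(male = 65, female = 65))
  expect_equal(pv_future_income(63, "male", ec, const_wage),
               100 / 1.05 + 100 / 1.05^2, tolerance = 1e-10)
  # T = 0 and beyond retirement
  expect_equal(pv_future_income(65, "male", ec, const_wage), 0)
  expect_equal(pv_future_income(70, "male", ec, const_wage), 0)
  # g = r makes the discount factors cancel: w * T
  ec_eq <- econ_params(discount_rate = 0.05, wage_growth_rate = 0.05)
  expect_equal(pv_future_income(55, "male", ec_eq, const_wage), 100 * 10)
})

test_that("present value is monotone in discounting, growth and horizon", {
  w <- function(a) 120
  pv <- function(r, g, age) pv_future_income(
    age, "male", econ_params(discount_rate = r, wage_growth_rate = g), w)
  rs <- c(0.01, 0.03, 0.05, 0.08)
  expect_true(all(diff(vapply(rs, pv, 0, g = 0.02, age = 45)) < 0))
  gs <- c(0, 0.02, 0.04)
  expect_true(all(diff(vapply(gs, pv, 0, r = 0.05, age = 45)) > 0))
  ages <- c(60, 55, 45, 40)
  expect_true(all(diff(vapply(ages, function(a) pv(0.05, 0.02, a), 0)) > 0))
})

test_that("presenteeism and informal care costs are proportional", {
  expect_equal(presenteeism_cost(0, 1, 1000), 0)
  expect_equal(presenteeism_cost(0.2, 1, 1000), 200)
  expect_equal(presenteeism_cost(0.4, 1, 1000),
               2 * presenteeism_cost(0.2, 1, 1000))
  expect_error(presenteeism_cost(1.2, 1, 1000))
  expect_equal(informal_care_cost(0, 5), 0)
  expect_equal(informal_care_cost(100, 5), 500)
  expect_equal(informal_care_cost(c(100, 50), 5), 750)
})

test_that("direct medical cost applies unit costs, inflation and conversion", {
  m <- toy_model(cost = 1000)
  ec <- m$econ
  got <- direct_medical_cost(
    data.frame(condition = "ami", case_years = 10), m$diseases, ec)
  expect_equal(got, 10 * 1000 * 1.1047 / 3.3)
  expect_equal(direct_medical_cost(
    data.frame(condition = "ami", case_years = 0), m$diseases, ec), 0)
  expect_error(direct_medical_cost(
    data.frame(condition = "gout", case_years = 1), m$diseases, ec),
    "gout")
})

test_that("cost shares reproduce the published category breakdown and GDP fractions", {
  fx <- printed_counts_fixture()
  sh <- cost_shares(fx$costs, gdp = 219039)
  expect_equal(unname(sh$shares), unname(fx$cost_shares_printed))
  expect_equal(sh$gdp_share_total_pct, 1.28)
  expect_equal(sh$gdp_share_direct_pct, 0.59)
  expect_equal(round_half_up(sh$total, 1), fx$grand_total, tolerance = 0.100001)
  # degenerate and single-category cases
  one <- cost_shares(c(direct_medical = 50, premature_mortality = 0,
                       disability = 0, informal_care = 0))
  expect_equal(unname(one$shares), c(100, 0, 0, 0))
  zero <- cost_shares(c(direct_medical = 0, premature_mortality = 0,
                        disability = 0, informal_care = 0))
  expect_true(all(is.na(zero$shares)))
})

test_that("the cost result conserves totals across groupings", {
  m <- peru_like_model()
  f <- simulate_population(m, 8000, 19, "factual", "lifetime")
  cf <- simulate_population(m, 8000, 19, "never_smoker", "lifetime")
  co <- compute_costs(attributable_counts(f, cf, years = 1), m)
  expect_equal(sum(co$category_totals), co$grand_total, tolerance = 1e-10)
  expect_equal(sum(co$group_totals), co$grand_total, tolerance = 1e-10)
  expect_equal(sum(co$cells$cost_musd), co$grand_total, tolerance = 1e-10)
  expect_true(all(co$cells$cost_musd >= 0))
  expect_equal(sum(co$shares), 100, tolerance = 0.2)
  # report table mirrors the cells
  tab <- cost_table(co)
  expect_equal(tab$total[tab$category == "total"],
               round_half_up(co$grand_total, 1), tolerance = 0.2)
})
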