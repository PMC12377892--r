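test_that("attributable fractions reproduce the published percentage cells", {
  fx <- printed_counts_fixture()
  d <- fx$deaths[fx$deaths$consistent, ]
  expect_equal(attributable_fraction(d$attributable, d$total), d$pct_printed)
  e <- fx$events[fx$events$consistent, ]
  expect_equal(attributable_fraction(e$attributable, e$total), e$pct_printed)
  # spot values: a fifth of AMI deaths, four fifths of lung-cancer deaths
  expect_equal(attributable_fraction(1303, 6348), 20.5)
  expect_equal(attributable_fraction(2420, 2910), 83.2)
  expect_equal(attributable_fraction(0, 6348), 0)
  expect_true(is.na(attributable_fraction(0, 0)))
  expect_error(attributable_fraction(10, 5), "attributable")
})

test_that("attributable counts are the floored factual-counterfactual difference", {
  m <- toy_model()
  f <- simulate_population(m, 5000, 3, "factual", horizon = 5)
  cf <- simulate_population(m, 5000, 3, "never_smoker", horizon = 5)
  ac <- attributable_counts(f, cf)
  expect_true(all(ac$attr_deaths >= 0))
  expect_true(all(ac$attr_deaths <= ac$total_deaths))
  expect_equal(ac$attr_deaths, pmax(ac$total_deaths - ac$cf_deaths, 0))
  # identical runs give zero attributable everywhere
  ac0 <- attributable_counts(f, f)
  expect_true(all(ac0$attr_deaths == 0) && all(ac0$attr_events == 0))
  # broken CRN contract
  cf2 <- simulate_population(m, 5000, 4, "never_smoker", horizon = 5)
  expect_error(attributable_counts(f, cf2), "seed")
  cf3 <- simulate_population(m, 4999, 3, "never_smoker", horizon = 5)
  expect_error(attributable_counts(f, cf3), "n, seed")
})

test_that("YLL is additive in deaths and anchored to the life table", {
  lt <- toy_life_table(rle = 10)
  lt$residual_le[] <- c(10, 5)  # male 10, female 5
  bands <- toy_bands
  expect_equal(compute_yll(data.frame(sex = "male", age = 50, n = 1),
                           lt, bands), 10)
  expect_equal(compute_yll(
    data.frame(sex = c("male", "female"), age = c(50, 70), n = c(1, 1)),
    lt, bands), 15)
  expect_equal(compute_yll(data.frame(sex = "male", age = 50, n = 0)[0, ],
                           lt, bands), 0)
  expect_error(compute_yll(data.frame(sex = "male", age = 120, n = 1),
                           lt, bands), "life table")
})

test_that("simulated YLL matches the survival-weighted numeric oracle", {
  mu <- 0.1
  rle <- 12
  m <- toy_model(inc = 0, cf = 0, mort = 0, bg = mu, rle = rle)
  s <- simulate_population(m, 30000, 9, "factual", "lifetime")
  # every death carries the single-band residual expectancy, and each
  # simulated person dies exactly once -> total YLL = n * rle
  d_by_sex <- apply(s$deaths, 2, sum)
  df <- data.frame(sex = names(d_by_sex), age = 50, n = unname(d_by_sex))
  expect_equal(compute_yll(df, m$life_table, model_bands(m)), 30000 * rle)
})

test_that("YLD is disability weight times years, additive over cases", {
  m <- peru_like_model()
  expect_equal(compute_yld(
    data.frame(condition = "copd", n = 1, years_in_state = 5), m$diseases),
    0.19 * 5)
  expect_equal(compute_yld(
    data.frame(condition = "stroke", n = 0, years_in_state = 5)[0, ],
    m$diseases), 0)
  zero_dw <- m$diseases
  zero_dw$copd$disability_weight <- 0
  expect_equal(compute_yld(
    data.frame(condition = "copd", n = 10, years_in_state = 5), zero_dw), 0)
  # partition by sex sums to the total
  b <- compute_burden(m, 4000, 2)
  tot_by_sex <- tapply(b$by_cs$yld, b$by_cs$sex, sum)
  expect_equal(sum(tot_by_sex), sum(b$by_cs$yld))
})

test_that("DALY = YLL + YLD holds exactly in every emitted report", {
  m <- peru_like_model()
  b <- compute_burden(m, 5000, 11)
  expect_equal(b$by_cs$daly, b$by_cs$yll + b$by_cs$yld)
  expect_equal(b$shs$daly, b$shs$yll + b$shs$yld)
  tot <- burden_totals(b)
  expect_equal(tot$daly, tot$yll + tot$yld)
})

test_that("secondhand-smoke uplift adds the documented sex-specific row", {
  m <- toy_model()
  f <- simulate_population(m, 5000, 3, "factual", horizon = 1)
  cf <- simulate_population(m, 5000, 3, "never_smoker", horizon = 1)
  b <- tobaccoburden:::burden_from_counts(attributable_counts(f, cf), m)
  b$by_cs$attr_deaths <- rep(100, nrow(b$by_cs))  # forced round numbers
  b$by_cs$yll <- b$by_cs$yld <- b$by_cs$daly <- rep(0, nrow(b$by_cs))
  up <- apply_shs_uplift(b, c(male = 0.136, female = 0.12))
  expect_equal(up$shs$attr_deaths[up$shs$sex == "male"], 13.6)
  expect_equal(up$shs$attr_deaths[up$shs$sex == "female"], 12)
  expect_equal(round_half_up(up$shs$attr_deaths[up$shs$sex == "male"]), 14)
  same <- apply_shs_uplift(b, c(male = 0, female = 0))
  expect_equal(sum(same$shs$attr_deaths), 0)
  expect_equal(same$by_cs, b$by_cs)
})

test_that("the burden table is internally consistent and flags non-computable events", {
  m <- peru_like_model()
  b <- compute_burden(m, 8000, 13)
  tab <- burden_table(b)
  # non-ischemic heart disease events are not applicable
  nihd <- tab[tab$condition == "heart_non_ischemic", ]
  expect_true(is.na(nihd$attr_events) && is.na(nihd$attr_events_pct))
  shs <- tab[tab$condition == "shs_other", ]
  expect_true(is.na(shs$total_events))
  expect_equal(shs$attr_deaths_pct, 100)
  # percentages recompute from the table's own counts (consistency)
  rows <- tab$condition %in% names(m$diseases) & tab$total_deaths > 0
  expect_equal(tab$attr_deaths_pct[rows],
               attributable_fraction(tab$attr_deaths[rows],
                                     tab$total_deaths[rows]),
               tolerance = 0.11)  # integer rounding of counts
  # all fractions inside [0, 100]
  pct <- unlist(tab[, grepl("_pct$", names(tab))])
  expect_true(all(pct[!is.na(pct)] >= 0 & pct[!is.na(pct)] <= 100))
})
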