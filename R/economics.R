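# Costing of the attributable burden: direct medical, premature mortality
# (human-capital present value of forgone labour income), disability /
# presenteeism, informal care. Unit medical costs enter in 2015 local
# currency and are inflated then converted; wages are reporting-year local
# currency and are converted only. Reports are in millions of 2020 USD.

#' Inflate an amount from the costing year to the reporting year
#' @param amount_2015 amount in costing-year currency (>= 0).
#' @param factor cumulative inflation fraction (e.g. 0.1047).
#' @return `amount_2015 * (1 + factor)`.
#' @export
adjust_inflation <- function(amount_2015, factor) {
  if (any(amount_2015 < 0)) stop_named("amount must be >= 0")
  stopifnot(factor >= 0)
  amount_2015 * (1 + factor)
}

#' Convert local currency to USD
#' @param amount_pen amount in local currency units.
#' @param rate local currency units per USD (> 0).
#' @return amount in USD.
#' @export
convert_currency <- function(amount_pen, rate) {
  if (rate <= 0) stop_named("exchange rate must be > 0")
  amount_pen / rate
}

#' Annual market wage from a Mincer log-wage equation
#'
#' `exp(beta0 + beta_edu * education + beta_age * age + beta_age2 * age^2)`
#' with sex-specific coefficients estimated from household-survey data.
#'
#' @param age years.
#' @param sex "male" or "female".
#' @param education years of schooling (defaults to the stratum mean).
#' @param econ an [econ_params()] object.
#' @return annual wage in reporting-year local currency.
#' @export
mincer_wage <- function(age, sex, education = NULL, econ = econ_params()) {
  b <- econ$mincer[[sex]]
  education <- education %||% econ$mean_education_years[[sex]]
  exp(b[["beta0"]] + b[["beta_edu"]] * education +
        b[["beta_age"]] * age + b[["beta_age2"]] * age^2)
}

#' Present value of future labour income
#'
#' Human-capital value of a death at `age`:
#' `sum_{t=1..T} wage(age + t) * (1+g)^t / (1+r)^t` with
#' `T = retirement_age - age`, `r` the discount rate and `g` wage growth.
#' Returns 0 at or beyond retirement (documented, not an error).
#'
#' @param age years at death.
#' @param sex "male" or "female".
#' @param econ an [econ_params()] object.
#' @param wage_fn function(age) -> annual wage; defaults to [mincer_wage()]
#'   at the stratum mean education.
#' @return present value, reporting-year local currency.
#' @export
pv_future_income <- function(age, sex, econ = econ_params(), wage_fn = NULL) {
  T_ <- floor(econ$retirement_age[[sex]] - age)
  if (T_ <= 0) return(0)
  wage_fn <- wage_fn %||% function(a) mincer_wage(a, sex, econ = econ)
  t <- seq_len(T_)
  w <- vapply(age + t, wage_fn, 0)
  sum(w * ((1 + econ$wage_growth_rate) / (1 + econ$discount_rate))^t)
}

#' Direct medical cost of attributable case-years
#'
#' Case-years x annual unit cost, inflated to the reporting year and
#' converted to USD.
#'
#' @param case_years data.frame with `condition` and `case_years`.
#' @param diseases list of `disease_spec` objects.
#' @param econ an [econ_params()] object.
#' @return total cost in USD.
#' @export
direct_medical_cost <- function(case_years, diseases, econ = econ_params()) {
  if (!nrow(case_years)) return(0)
  k <- match(case_years$condition, names(diseases))
  if (anyNA(k)) stop_named("unit cost missing for condition '%s'",
                           case_years$condition[which(is.na(k))[1]])
  unit <- vapply(diseases, `[[`, 0, "annual_direct_cost")[k]
  pen2020 <- adjust_inflation(sum(case_years$case_years * unit),
                              econ$inflation_factor)
  convert_currency(pen2020, econ$exchange_rate_pen_per_usd)
}

#' Presenteeism (disability) cost
#'
#' Productivity lost while working ill, proportional to the quality-of-life
#' decrement: `wage * decrement * years`.
#'
#' @param qol_decrement utility loss in `[0,1]`.
#' @param years_in_state years spent in the disease state while working.
#' @param wage annual wage.
#' @return cost, same currency as `wage`.
#' @export
presenteeism_cost <- function(qol_decrement, years_in_state, wage) {
  stopifnot(all(qol_decrement >= 0 & qol_decrement <= 1))
  sum(wage * qol_decrement * years_in_state)
}

#' Informal care cost
#'
#' Unpaid caregiving hours valued at a care-worker hourly wage (the
#' opportunity-cost proxy).
#'
#' @param hours caregiving hours.
#' @param caregiver_wage currency per hour.
#' @return cost.
#' @export
informal_care_cost <- function(hours, caregiver_wage) {
  stopifnot(all(hours >= 0), caregiver_wage >= 0)
  sum(hours * caregiver_wage)
}

COST_CATEGORIES <- c("direct_medical", "premature_mortality",
                     "disability", "informal_care")

#' Cost the attributable burden
#'
#' Builds the condition-group x cost-category x sex cost table (millions of
#' 2020 USD) from band-resolved attributable counts. Case-years are incident
#' cases x mean state duration; premature-mortality costs count only deaths
#' before retirement age (the present value is zero afterwards);
#' presenteeism is restricted to working ages and to state-years before
#' retirement. The secondhand-smoke/other group is a fixed sex-specific
#' uplift on the sum of the condition groups.
#'
#' @param ac an `attr_counts` object from [attributable_counts()].
#' @param model the `country_model` the runs came from.
#' @param gdp_usd_millions optional GDP for share-of-GDP reporting (defaults
#'   to the model's economic parameters).
#' @return object of class `cost_result`: `cells` (group, category, sex,
#'   cost_musd), `category_totals`, `group_totals`, `grand_total`, `shares`,
#'   `gdp_share_total_pct`, `gdp_share_direct_pct`.
#' @export
compute_costs <- function(ac, model, gdp_usd_millions = NULL) {
  stopifnot(inherits(ac, "attr_counts"))
  econ <- model$econ
  gdp <- gdp_usd_millions %||% econ$gdp_usd_millions
  ids <- ac$conditions
  K <- length(ids)
  mid <- band_mid(ac$bands)
  ds <- model$diseases
  dw <- vapply(ds, `[[`, 0, "disability_weight")[ids]
  dur <- vapply(ds, `[[`, 0, "mean_duration_years")[ids]
  unit <- vapply(ds, `[[`, 0, "annual_direct_cost")[ids]
  hours <- vapply(ds, `[[`, 0, "informal_care_hours_per_year")[ids]
  fx <- econ$exchange_rate_pen_per_usd

  pv_by_band <- function(sx) vapply(mid, function(a)
    pv_future_income(a, sx, econ), 0)
  pv_tab <- cbind(male = pv_by_band("male"), female = pv_by_band("female"))
  wage_tab <- cbind(male = mincer_wage(mid, "male", econ = econ),
                    female = mincer_wage(mid, "female", econ = econ))

  rows <- list()
  for (k in seq_len(K)) for (s in 1:2) {
    sx <- MODEL_SEXES[s]
    cases_b <- ac$attr_events[k, s, ] * ac$scale
    deaths_b <- ac$attr_deaths[k, s, ] * ac$scale
    retire <- econ$retirement_age[[sx]]
    work_years <- pmax(pmin(dur[k], retire - mid), 0)

    direct <- direct_medical_cost(
      data.frame(condition = ids[k], case_years = sum(cases_b) * dur[k]),
      ds, econ)
    mortality <- convert_currency(sum(deaths_b * pv_tab[, s]), fx)
    disability <- convert_currency(
      presenteeism_cost(dw[k], cases_b * work_years, wage_tab[, s]), fx)
    informal <- convert_currency(
      informal_care_cost(sum(cases_b) * dur[k] * hours[k],
                         econ$caregiver_hourly_wage), fx)
    rows[[length(rows) + 1]] <- data.frame(
      group = ac$groups[k], sex = sx,
      direct_medical = direct / 1e6, premature_mortality = mortality / 1e6,
      disability = disability / 1e6, informal_care = informal / 1e6,
      stringsAsFactors = FALSE)
  }
  by_ks <- do.call(rbind, rows)
  cells <- stats::aggregate(
    cbind(direct_medical, premature_mortality, disability, informal_care) ~
      group + sex, data = by_ks, FUN = sum)

  # SHS/other group: sex-specific uplift on the sum of condition groups
  shs <- do.call(rbind, lapply(MODEL_SEXES, function(sx) {
    d <- cells[cells$sex == sx, COST_CATEGORIES, drop = FALSE]
    u <- model$shs_uplift[[sx]]
    data.frame(group = "shs_other", sex = sx, as.list(colSums(d) * u),
               stringsAsFactors = FALSE)
  }))
  cells <- rbind(cells, shs)

  long <- stats::reshape(
    cells, direction = "long", varying = COST_CATEGORIES,
    v.names = "cost_musd", times = COST_CATEGORIES, timevar = "category",
    idvar = c("group", "sex"))
  rownames(long) <- NULL
  long$group <- factor(long$group, levels = condition_groups())
  long <- long[order(long$group, long$category, long$sex), ]
  long$group <- as.character(long$group)

  category_totals <- tapply(long$cost_musd, long$category, sum)[COST_CATEGORIES]
  group_totals <- tapply(long$cost_musd, long$group, sum)[condition_groups()]
  group_totals[is.na(group_totals)] <- 0
  names(group_totals) <- condition_groups()
  grand <- sum(long$cost_musd)
  sh <- cost_shares(category_totals, gdp = gdp)

  structure(list(
    cells = long, category_totals = category_totals,
    group_totals = group_totals, grand_total = grand,
    shares = sh$shares,
    gdp_share_total_pct = sh$gdp_share_total_pct,
    gdp_share_direct_pct = sh$gdp_share_direct_pct,
    gdp_usd_millions = gdp
  ), class = "cost_result")
}

#' Cost-category shares and GDP fractions
#'
#' @param categories named numeric vector of category totals (millions of
#'   USD; name `direct_medical` identifies the direct component) or a
#'   `cost_result`.
#' @param gdp optional GDP in the same units.
#' @return list: `shares` (percent of the grand total, 1 decimal),
#'   `total`, `gdp_share_total_pct` and `gdp_share_direct_pct` (2 decimals,
#'   NULL without `gdp`).
#' @export
cost_shares <- function(categories, gdp = NULL) {
  if (inherits(categories, "cost_result")) {
    gdp <- gdp %||% categories$gdp_usd_millions
    categories <- categories$category_totals
  }
  total <- sum(categories)
  if (total <= 0) return(list(shares = categories * NA_real_, total = total,
                              gdp_share_total_pct = NULL,
                              gdp_share_direct_pct = NULL))
  out <- list(shares = round_half_up(100 * categories / total, 1),
              total = total)
  if (!is.null(gdp)) {
    out$gdp_share_total_pct <- round_half_up(100 * total / gdp, 2)
    direct <- if ("direct_medical" %in% names(categories))
      categories[["direct_medical"]] else NA_real_
    out$gdp_share_direct_pct <- round_half_up(100 * direct / gdp, 2)
  }
  out
}

#' Report-shaped cost table
#'
#' Category x group x sex cells with row/column totals, millions of 2020
#' USD, mirroring the published annual economic-burden table.
#'
#' @param costs a `cost_result`.
#' @param digits decimals for report rounding (default 1).
#' @return data.frame, one row per category x sex plus totals.
#' @export
cost_table <- function(costs, digits = 1) {
  lv <- condition_groups()
  wide <- stats::reshape(
    costs$cells, direction = "wide", idvar = c("category", "sex"),
    timevar = "group")
  names(wide) <- sub("^cost_musd\\.", "", names(wide))
  for (g in setdiff(lv, names(wide))) wide[[g]] <- 0
  wide <- wide[, c("category", "sex", lv)]
  wide$total <- rowSums(wide[, lv])
  tot <- data.frame(category = "total", sex = "all",
                    as.list(colSums(wide[, c(lv, "total")])),
                    check.names = FALSE)
  out <- rbind(wide, tot)
  out[, c(lv, "total")] <- round_half_up(as.matrix(out[, c(lv, "total")]),
                                         digits)
  rownames(out) <- NULL
  out
}
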