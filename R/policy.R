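# Ten-year policy projection engine: plain packaging, smoke-free
# enforcement, TAPS bans and tax-driven price increases, all acting through
# a reduction Em of tobacco consumption of which a share Ip lowers smoker
# prevalence. Steady state: population, unit costs and wages are held fixed;
# the cumulative effect is the sum of annual differences over the horizon.

#' Define a policy scenario
#'
#' @param name scenario label.
#' @param kind one of "packaging", "smokefree", "taps_ban", "tax".
#' @param effectiveness_Em relative reduction in tobacco consumption in
#'   `[0,1]`. For `kind = "tax"` it is derived from `price_increase` and
#'   `elasticity` via [tax_effect()] and must not be supplied.
#' @param Ip share of the consumption reduction expressed as lower smoker
#'   prevalence (default 0.5).
#' @param price_increase fraction increase in the retail price (tax only).
#' @param elasticity price elasticity of demand, negative (tax only).
#' @param shs_risk_reduction extra relative reduction of the
#'   secondhand-smoke burden row (smoke-free enforcement only).
#' @param horizon_years projection horizon (default 10).
#' @param em_range optional c(lo, hi) effectiveness range for uncertainty
#'   bounds.
#' @return list of class `policy_scenario`.
#' @export
policy_scenario <- function(name, kind = c("packaging", "smokefree",
                                           "taps_ban", "tax"),
                            effectiveness_Em = NULL, Ip = 0.5,
                            price_increase = NULL, elasticity = -0.4,
                            shs_risk_reduction = 0, horizon_years = 10,
                            em_range = NULL) {
  kind <- match.arg(kind)
  if (horizon_years < 1) stop_named("horizon_years must be >= 1")
  if (kind == "tax") {
    if (is.null(price_increase)) stop_named("tax scenarios need price_increase")
    effectiveness_Em <- tax_effect(price_increase, elasticity)
  }
  if (is.null(effectiveness_Em))
    stop_named("effectiveness_Em is required for non-tax scenarios")
  stopifnot(effectiveness_Em >= 0, effectiveness_Em <= 1, Ip >= 0, Ip <= 1,
            shs_risk_reduction >= 0, shs_risk_reduction <= 1)
  structure(list(name = name, kind = kind,
                 effectiveness_Em = effectiveness_Em, Ip = Ip,
                 price_increase = price_increase, elasticity = elasticity,
                 shs_risk_reduction = shs_risk_reduction,
                 horizon_years = as.integer(horizon_years),
                 em_range = em_range), class = "policy_scenario")
}

#' Smoker prevalence after an intervention
#'
#' `prev_post = prev_pre - Em * Ip * prev_pre = prev_pre * (1 - Em * Ip)`:
#' the intervention reduces consumption by Em, of which the share Ip is a
#' prevalence reduction (the rest is lower consumption among continuing
#' smokers, which this burden model does not track).
#'
#' @param prev_pre pre-intervention smoker prevalence in `[0,1]`.
#' @param Em intervention effectiveness in `[0,1]`.
#' @param Ip prevalence-impact share in `[0,1]`.
#' @return post-intervention prevalence.
#' @export
post_policy_prevalence <- function(prev_pre, Em, Ip) {
  if (any(prev_pre < 0 | prev_pre > 1) || any(Em < 0 | Em > 1) ||
      any(Ip < 0 | Ip > 1))
    stop_named("prev_pre, Em and Ip must lie in [0,1]")
  prev_pre * (1 - Em * Ip)
}

#' Consumption reduction induced by a price increase
#'
#' Constant-elasticity approximation: `Em = min(1, |elasticity| *
#' price_increase)`, the relative reduction in cigarette consumption.
#'
#' @param price_increase fraction increase in retail price (>= 0).
#' @param elasticity price elasticity of demand (<= 0).
#' @return effectiveness Em in `[0,1]`.
#' @export
tax_effect <- function(price_increase, elasticity) {
  if (any(price_increase < 0)) stop_named("price_increase must be >= 0")
  if (any(elasticity > 0)) stop_named("elasticity must be <= 0")
  pmin(1, abs(elasticity) * price_increase)
}

#' Change in annual tax revenue from a price increase
#'
#' The tax absorbs the price increase: the per-pack tax rises from
#' `tax_share * price` to `tax_share * price + price_increase * price`,
#' while consumption falls by Em = |elasticity| x price_increase.
#'
#' @param price_increase fraction increase in retail price.
#' @param elasticity price elasticity of demand (<= 0).
#' @param baseline_consumption packs per year.
#' @param tax_share tax share of the retail price in `[0,1]`.
#' @param price retail price per pack, local currency.
#' @return revenue change per year, local currency.
#' @export
tax_revenue_change <- function(price_increase, elasticity,
                               baseline_consumption, tax_share, price) {
  stopifnot(tax_share >= 0, tax_share <= 1)
  em <- tax_effect(price_increase, elasticity)
  old_tax <- tax_share * price
  new_tax <- old_tax + price_increase * price
  new_tax * baseline_consumption * (1 - em) -
    old_tax * baseline_consumption
}

#' Project a policy scenario over its horizon
#'
#' Simulates three arms at a common seed and horizon: the base case (current
#' prevalence), the scenario (current smokers reassigned to former with
#' probability Em x Ip, i.e. quitting, not history erasure) and the
#' never-smoker counterfactual that defines attributable burden. Avoided
#' burden is base minus scenario summed over the horizon years; costs come
#' from costing the attributable counts of each arm. Smoke-free scenarios
#' additionally scale the scenario's secondhand-smoke row by
#' `1 - shs_risk_reduction`.
#'
#' @param model a validated `country_model`.
#' @param scenario a [policy_scenario()].
#' @param n simulated individuals per arm.
#' @param seed common master seed.
#' @return object of class `scenario_result` with per-group base-case and
#'   avoided deaths, events, DALYs and cost savings by category; tax
#'   scenarios add the cumulative tax-revenue change; `bounds` holds lo/hi
#'   totals when the scenario carries an `em_range`.
#' @export
run_scenario <- function(model, scenario, n, seed) {
  stopifnot(inherits(scenario, "policy_scenario"))
  H <- scenario$horizon_years
  base <- simulate_population(model, n, seed, "factual", horizon = H)
  cf <- simulate_population(model, n, seed, "never_smoker", horizon = H)

  arm <- function(em) {
    qf <- em * scenario$Ip
    scen <- if (qf > 0)
      simulate_population(model, n, seed, "factual", horizon = H,
                          quit_fraction = qf)
    else base
    shs_scale <- if (scenario$kind == "smokefree")
      1 - scenario$shs_risk_reduction else 1
    summarise_arm(scen, cf, model, shs_scale)
  }
  base_sum <- summarise_arm(base, cf, model, 1)
  scen_sum <- arm(scenario$effectiveness_Em)

  by_group <- merge(base_sum$by_group, scen_sum$by_group, by = "group",
                    suffixes = c("_base", "_scen"))
  for (q in c("deaths", "events", "daly", "cost")) {
    by_group[[paste0("avoided_", q)]] <-
      by_group[[paste0(q, "_base")]] - by_group[[paste0(q, "_scen")]]
  }
  by_group$group <- as.character(by_group$group)
  by_group <- by_group[order(match(by_group$group, condition_groups())), ]
  rownames(by_group) <- NULL

  savings_by_cat <- base_sum$cost_by_cat - scen_sum$cost_by_cat
  out <- list(
    scenario = scenario, n = n, seed = seed, horizon = H,
    by_group = by_group,
    base_totals = base_sum$totals, scen_totals = scen_sum$totals,
    avoided = mapply(`-`, base_sum$totals, scen_sum$totals, SIMPLIFY = FALSE),
    cost_savings_by_category = savings_by_cat,
    cost_savings_total = sum(savings_by_cat))
  if (scenario$kind == "tax") {
    out$tax_revenue_change_musd <- convert_currency(
      tax_revenue_change(scenario$price_increase, scenario$elasticity,
                         model$econ$annual_consumption_packs,
                         model$econ$tax_share,
                         model$econ$cigarette_price_pen) * H,
      model$econ$exchange_rate_pen_per_usd) / 1e6
    out$total_economic_benefit_musd <-
      out$cost_savings_total + out$tax_revenue_change_musd
  }
  if (!is.null(scenario$em_range)) {
    lo <- arm(scenario$em_range[1]); hi <- arm(scenario$em_range[2])
    out$bounds <- list(
      lo = mapply(`-`, base_sum$totals, lo$totals, SIMPLIFY = FALSE),
      hi = mapply(`-`, base_sum$totals, hi$totals, SIMPLIFY = FALSE))
  }
  structure(out, class = "scenario_result")
}

# attributable burden + costs of one arm, by condition group, over all
# simulated years; shs_scale rescales the secondhand-smoke row
summarise_arm <- function(scen, cf, model, shs_scale = 1) {
  ac <- attributable_counts(scen, cf)
  burden <- apply_shs_uplift(burden_from_counts(ac, model),
                             model$shs_uplift * shs_scale)
  costs <- compute_costs(ac, model)
  b <- burden$by_cs
  b$group <- ac$groups[match(b$condition, ac$conditions)]
  g <- stats::aggregate(cbind(attr_deaths, attr_events, daly) ~ group,
                        data = b, FUN = sum)
  shs_g <- data.frame(group = "shs_other",
                      attr_deaths = sum(burden$shs$attr_deaths),
                      attr_events = 0,
                      daly = sum(burden$shs$daly))
  g <- rbind(g, shs_g)
  cost_g <- costs$group_totals
  if (shs_scale != 1) {
    cost_g[["shs_other"]] <- cost_g[["shs_other"]] * shs_scale
  }
  g$cost <- unname(cost_g[g$group])
  names(g) <- c("group", "deaths", "events", "daly", "cost")
  cost_by_cat <- costs$category_totals
  if (shs_scale != 1) {
    shs_cells <- costs$cells[costs$cells$group == "shs_other", ]
    adj <- tapply(shs_cells$cost_musd, shs_cells$category, sum)[COST_CATEGORIES]
    cost_by_cat <- cost_by_cat - (1 - shs_scale) * adj
  }
  list(by_group = g,
       totals = list(deaths = sum(g$deaths), events = sum(g$events),
                     daly = sum(g$daly), cost = sum(g$cost)),
       cost_by_cat = cost_by_cat)
}

#' Scenario comparison table
#'
#' Per scenario and condition group: base-case attributable burden and the
#' estimated reduction over the horizon, with lower/upper bounds where an
#' effectiveness range was run (bounds equal the point estimate otherwise).
#'
#' @param results list of `scenario_result` objects sharing a horizon.
#' @return data.frame shaped like the published ten-year scenario table.
#' @export
scenario_table <- function(results) {
  if (inherits(results, "scenario_result")) results <- list(results)
  H <- unique(vapply(results, `[[`, 0L, "horizon"))
  if (length(H) != 1) stop_named("scenario results must share a horizon")
  do.call(rbind, lapply(results, function(r) {
    bg <- r$by_group
    lo <- r$bounds$lo$deaths %||% r$avoided$deaths
    hi <- r$bounds$hi$deaths %||% r$avoided$deaths
    data.frame(
      scenario = r$scenario$name, group = bg$group,
      base_deaths = round_half_up(bg$deaths_base),
      avoided_deaths = round_half_up(bg$avoided_deaths),
      base_events = round_half_up(bg$events_base),
      avoided_events = round_half_up(bg$avoided_events),
      base_cost_musd = round_half_up(bg$cost_base, 2),
      avoided_cost_musd = round_half_up(bg$avoided_cost, 2),
      avoided_deaths_total_lo = round_half_up(min(lo, hi)),
      avoided_deaths_total_hi = round_half_up(max(lo, hi)),
      stringsAsFactors = FALSE)
  }))
}
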