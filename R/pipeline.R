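# End-to-end orchestration: simulate (factual + counterfactual) -> annual
# burden -> costs -> policy scenarios, written as diffable CSV tables plus
# JSON headline summaries and a run manifest.

#' Run the full burden pipeline
#'
#' @param model a `country_model`, or the path of a parameter bundle to load.
#' @param n simulated individuals per arm.
#' @param seed master seed for every stage.
#' @param scenarios list of [policy_scenario()] objects (possibly empty,
#'   in which case only the burden and cost tables are produced).
#' @param out optional directory; when given, writes `table_burden.csv`,
#'   `table_costs.csv`, `table_scenarios.csv` (if any scenarios),
#'   `summary.json` and `manifest.json` there. Reruns from the manifest's
#'   (n, seed, scenarios) are bit-identical.
#' @return list of class `pipeline_result`: `burden` (`burden_result`),
#'   `costs` (`cost_result`), `scenarios` (list of `scenario_result`),
#'   `tables` (the emitted data.frames), `summary`, `manifest`.
#' @export
run_pipeline <- function(model, n, seed, scenarios = list(), out = NULL) {
  if (is.character(model)) model <- load_country(model)
  issues <- validate_model(model)
  if (length(issues))
    stop_named("pipeline aborted at validation:\n%s",
               paste("-", issues, collapse = "\n"))

  f <- simulate_population(model, n, seed, "factual", "lifetime")
  cf <- simulate_population(model, n, seed, "never_smoker", "lifetime")
  ac <- attributable_counts(f, cf, years = 1)
  burden <- apply_shs_uplift(burden_from_counts(ac, model), model$shs_uplift)
  costs <- compute_costs(ac, model)
  scen_results <- lapply(scenarios, function(sc)
    run_scenario(model, sc, n, seed))

  tables <- list(burden = burden_table(burden), costs = cost_table(costs))
  if (length(scen_results)) tables$scenarios <- scenario_table(scen_results)

  manifest <- list(
    package_version = as.character(utils::packageVersion("tobaccoburden")),
    n = n, seed = seed, population = f$pop_total,
    monetary_units = "millions of 2020 USD",
    scenarios = lapply(scenarios, function(sc)
      sc[c("name", "kind", "effectiveness_Em", "Ip", "price_increase",
           "elasticity", "shs_risk_reduction", "horizon_years")]),
    non_default_notes = "elasticity and scenario Em values are scenario inputs, not registry estimates",
    timestamp = format(Sys.time(), tz = "UTC"))

  result <- structure(list(
    burden = burden, costs = costs, scenarios = scen_results,
    tables = tables, manifest = manifest,
    summary = summarize_reports(burden, costs, scen_results)
  ), class = "pipeline_result")

  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    ok <- FALSE
    written <- character()
    on.exit(if (!ok) unlink(written), add = TRUE)
    wr <- function(df, file) {
      p <- file.path(out, file)
      utils::write.csv(df, p, row.names = FALSE)
      written <<- c(written, p)
    }
    wr(tables$burden, "table_burden.csv")
    wr(tables$costs, "table_costs.csv")
    if (!is.null(tables$scenarios)) wr(tables$scenarios, "table_scenarios.csv")
    jsonlite::write_json(result$summary, file.path(out, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    ok <- TRUE
  }
  result
}

summarize_reports <- function(burden, costs, scenarios = list()) {
  tot <- burden_totals(burden)
  out <- list(
    attributable_deaths = tot$attr_deaths,
    attributable_events = tot$attr_events,
    yll = tot$yll, yld = tot$yld, daly = tot$daly,
    total_cost_musd = costs$grand_total,
    cost_category_shares_pct = as.list(costs$shares),
    gdp_share_total_pct = costs$gdp_share_total_pct,
    gdp_share_direct_pct = costs$gdp_share_direct_pct)
  if (length(scenarios)) {
    out$scenarios <- lapply(scenarios, function(r) {
      s <- list(name = r$scenario$name,
                avoided_deaths = r$avoided$deaths,
                avoided_events = r$avoided$events,
                avoided_daly = r$avoided$daly,
                cost_savings_musd = r$cost_savings_total)
      if (!is.null(r$tax_revenue_change_musd)) {
        s$tax_revenue_change_musd <- r$tax_revenue_change_musd
        s$total_economic_benefit_musd <- r$total_economic_benefit_musd
      }
      s
    })
  }
  out
}

#' Headline summary of a pipeline run
#'
#' @param result a `pipeline_result`.
#' @return named list of headline aggregates: attributable deaths, events,
#'   YLL/YLD/DALY, total cost and GDP shares, plus per-scenario avoided
#'   burden. `daly` always equals `yll + yld`, and the total cost equals the
#'   cost table's grand total.
#' @export
summarize <- function(result) {
  stopifnot(inherits(result, "pipeline_result"))
  result$summary
}
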