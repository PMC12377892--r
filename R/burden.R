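# Attributable burden accounting: factual minus never-smoker counterfactual
# under common random numbers, then YLL/YLD/DALY and Table-style reports.

#' Attributable counts from a factual/counterfactual pair
#'
#' Per condition x sex x age-band cell: total = factual count, attributable =
#' factual - counterfactual floored at zero. Both runs must share model
#' population, n, seed and horizon, otherwise the common-random-numbers
#' contract is broken and an error is raised.
#'
#' @param factual,counterfactual `sim_result` objects from
#'   [simulate_population()] at a common seed (`factual` and `never_smoker`
#'   mode, or two factual runs under different policy prevalences).
#' @param years integer vector of simulation years to accumulate (default
#'   all simulated years; use `1` for the annual-snapshot tables).
#' @return object of class `attr_counts` holding total/attributable death
#'   and event arrays (condition x sex x band, simulation units) plus the
#'   population scale factor.
#' @export
attributable_counts <- function(factual, counterfactual, years = NULL) {
  stopifnot(inherits(factual, "sim_result"),
            inherits(counterfactual, "sim_result"))
  if (factual$n != counterfactual$n || factual$seed != counterfactual$seed ||
      !identical(factual$horizon, counterfactual$horizon))
    stop_named("factual and counterfactual runs must share n, seed and horizon (common random numbers)")
  if (!identical(factual$conditions, counterfactual$conditions))
    stop_named("runs were produced from different disease sets")
  years <- years %||% seq_len(factual$years)
  K <- length(factual$conditions)

  sum_years <- function(a, causes = seq_len(K)) {
    x <- a[causes, , , years, drop = FALSE]
    apply(x, c(1, 2, 3), sum)
  }
  f_d <- sum_years(factual$deaths)
  c_d <- sum_years(counterfactual$deaths)
  f_e <- sum_years(factual$events)
  c_e <- sum_years(counterfactual$events)

  structure(list(
    conditions = factual$conditions, eac = factual$eac,
    groups = factual$groups, acute = factual$acute,
    bands = factual$bands,
    total_deaths = f_d, attr_deaths = pmax(f_d - c_d, 0),
    total_events = f_e, attr_events = pmax(f_e - c_e, 0),
    cf_deaths = c_d, cf_events = c_e,
    scale = factual$scale_factor, n = factual$n, seed = factual$seed,
    years = years
  ), class = "attr_counts")
}

#' Attributable fraction as a report percentage
#'
#' 100 x attributable / total, rounded half-up to one decimal, the
#' percentage printed next to each count in the burden tables.
#'
#' @param attributable,total counts with `0 <= attributable <= total`.
#' @return percentage (1 decimal); `NA` where `total` is 0.
#' @export
attributable_fraction <- function(attributable, total) {
  out <- ifelse(total > 0, round_half_up(100 * attributable / total, 1), NA_real_)
  bad <- total > 0 & (attributable < 0 | attributable > total)
  if (any(bad, na.rm = TRUE))
    stop_named("attributable must lie in [0, total]")
  out
}

#' Years of life lost for a set of deaths
#'
#' Sum of residual life expectancy at the age band of death, from a period
#' life table; undiscounted and without age weighting.
#'
#' @param deaths data.frame with `sex`, `age` (years at death) and `n`
#'   (death count, default 1 per row).
#' @param life_table list with matrix `residual_le` (bands x male/female).
#' @param bands data.frame `age_lo`, `age_hi` matching the life table rows.
#' @return total YLL in years.
#' @export
compute_yll <- function(deaths, life_table, bands) {
  if (!nrow(deaths)) return(0)
  n <- deaths$n %||% rep(1, nrow(deaths))
  b <- findInterval(deaths$age, bands$age_lo)
  if (any(b < 1) || any(deaths$age > max(bands$age_hi)))
    stop_named("death age outside the life table range")
  sx <- match(deaths$sex, MODEL_SEXES)
  sum(n * life_table$residual_le[cbind(b, sx)])
}

#' Years lived with disability for a set of cases
#'
#' Sum over cases of disability weight x years lived in the disease state.
#' When `years_in_state` is absent, each condition's mean state duration is
#' used (steady-state incidence-prevalence identity).
#'
#' @param cases data.frame with `condition`, `n` (case count) and optionally
#'   `years_in_state`.
#' @param diseases list of `disease_spec` objects (e.g. `model$diseases`).
#' @return total YLD in years.
#' @export
compute_yld <- function(cases, diseases) {
  if (!nrow(cases)) return(0)
  dw <- vapply(diseases, `[[`, 0, "disability_weight")
  dur <- vapply(diseases, `[[`, 0, "mean_duration_years")
  k <- match(cases$condition, names(diseases))
  if (anyNA(k)) stop_named("unknown condition in YLD input")
  yrs <- cases$years_in_state %||% dur[k]
  sum((cases$n %||% rep(1, nrow(cases))) * dw[k] * yrs)
}

band_mid <- function(bands) (bands$age_lo + pmin(bands$age_hi, 99)) / 2

#' Build a burden result from attributable counts
#'
#' Turns band-resolved attributable counts into the condition x sex burden
#' table in population units: YLL from residual life expectancy at the age
#' band of death (factual minus counterfactual, floored at zero), YLD from
#' attributable incident cases x disability weight x mean state duration.
#'
#' @param ac an `attr_counts` object from [attributable_counts()].
#' @param model the `country_model` the runs came from.
#' @return a `burden_result` without the SHS row (add it with
#'   [apply_shs_uplift()]).
#' @export
burden_from_counts <- function(ac, model) {
  stopifnot(inherits(ac, "attr_counts"))
  ids <- ac$conditions
  K <- length(ids)
  rle <- model$life_table$residual_le
  dw <- vapply(model$diseases, `[[`, 0, "disability_weight")[ids]
  dur <- vapply(model$diseases, `[[`, 0, "mean_duration_years")[ids]

  rows <- list()
  for (k in seq_len(K)) for (s in 1:2) {
    yll_f <- sum(ac$total_deaths[k, s, ] * rle[, s])
    yll_c <- sum(ac$cf_deaths[k, s, ] * rle[, s])
    attr_ev <- sum(ac$attr_events[k, s, ])
    rows[[length(rows) + 1]] <- data.frame(
      condition = ids[k], sex = MODEL_SEXES[s],
      total_deaths = sum(ac$total_deaths[k, s, ]) * ac$scale,
      attr_deaths = sum(ac$attr_deaths[k, s, ]) * ac$scale,
      total_events = sum(ac$total_events[k, s, ]) * ac$scale,
      attr_events = attr_ev * ac$scale,
      yll = max(yll_f - yll_c, 0) * ac$scale,
      yld = attr_ev * dw[k] * dur[k] * ac$scale,
      event_af_computable = ac$eac[k],
      stringsAsFactors = FALSE)
  }
  by_cs <- do.call(rbind, rows)
  by_cs$daly <- by_cs$yll + by_cs$yld
  structure(list(by_cs = by_cs, shs = NULL, scale = ac$scale,
                 n = ac$n, seed = ac$seed),
            class = "burden_result")
}

#' Add the secondhand-smoke / other-causes row to a burden result
#'
#' The modelled conditions exclude perinatal effects and environmental
#' tobacco smoke; these are represented as a fixed proportional uplift on the
#' sex-specific attributable totals (deaths, YLL, YLD, DALY), appended as an
#' "exposure to environmental smoke and other causes" row. Condition-specific
#' events receive no uplift (their report cells stay NA).
#'
#' @param burden a `burden_result`.
#' @param uplift named fractions c(male, female), e.g. c(0.136, 0.12).
#' @return the `burden_result` with its `shs` component filled.
#' @export
apply_shs_uplift <- function(burden, uplift) {
  stopifnot(inherits(burden, "burden_result"), all(uplift >= 0))
  agg <- stats::aggregate(
    cbind(attr_deaths, yll, yld, daly) ~ sex, data = burden$by_cs, FUN = sum)
  u <- unname(uplift[agg$sex])
  burden$shs <- data.frame(
    sex = agg$sex,
    attr_deaths = agg$attr_deaths * u,
    yll = agg$yll * u, yld = agg$yld * u, daly = agg$daly * u,
    stringsAsFactors = FALSE)
  burden
}

#' Grand totals of a burden result
#' @param burden a `burden_result` (SHS row included when present).
#' @return named list: attributable deaths, events, YLL, YLD, DALY.
#' @export
burden_totals <- function(burden) {
  b <- burden$by_cs
  tot <- list(
    attr_deaths = sum(b$attr_deaths),
    attr_events = sum(b$attr_events[b$event_af_computable]),
    total_deaths = sum(b$total_deaths),
    total_events = sum(b$total_events[b$event_af_computable]),
    yll = sum(b$yll), yld = sum(b$yld), daly = sum(b$daly))
  if (!is.null(burden$shs)) {
    tot$attr_deaths <- tot$attr_deaths + sum(burden$shs$attr_deaths)
    tot$total_deaths <- tot$total_deaths + sum(burden$shs$attr_deaths)
    tot$yll <- tot$yll + sum(burden$shs$yll)
    tot$yld <- tot$yld + sum(burden$shs$yld)
    tot$daly <- tot$daly + sum(burden$shs$daly)
  }
  tot
}

#' Annual attributable burden of a model
#'
#' Runs the factual and never-smoker counterfactual simulations at a common
#' seed, takes year-1 outcomes of the population snapshot as the annual
#' burden, accrues YLL over the full residual life expectancy of each
#' attributable death and YLD over the full mean duration of each
#' attributable case, and applies the secondhand-smoke uplift.
#'
#' @param model a validated `country_model`.
#' @param n simulated individuals per arm.
#' @param seed master seed shared by both arms.
#' @param years simulation years to count as the reporting window (default 1).
#' @param horizon passed to [simulate_population()] (default `"lifetime"`,
#'   only the reporting window is tabulated but deaths can then be compared
#'   across the whole lifespan by other tools).
#' @return a `burden_result` in population units, SHS row included.
#' @export
compute_burden <- function(model, n, seed, years = 1, horizon = "lifetime") {
  f <- simulate_population(model, n, seed, "factual", horizon)
  cf <- simulate_population(model, n, seed, "never_smoker", horizon)
  ac <- attributable_counts(f, cf, years = seq_len(years))
  burden <- burden_from_counts(ac, model)
  apply_shs_uplift(burden, model$shs_uplift)
}

#' Report-shaped annual burden table
#'
#' One row per condition with rounded counts and attributable-fraction
#' percentage columns by sex, plus the SHS row (deaths only) and a totals
#' row. Event cells are NA for conditions whose attributable events cannot
#' be computed.
#'
#' @param burden a `burden_result`.
#' @return data.frame shaped like the published annual burden table.
#' @export
burden_table <- function(burden) {
  b <- burden$by_cs
  conds <- unique(b$condition)
  reg <- condition_registry()
  row_for <- function(cond) {
    d <- b[b$condition == cond, ]
    m <- d[d$sex == "male", ]; w <- d[d$sex == "female", ]
    td <- sum(d$total_deaths); ad <- sum(d$attr_deaths)
    te <- sum(d$total_events); ae <- sum(d$attr_events)
    eac <- d$event_af_computable[1]
    data.frame(
      condition = cond,
      label = if (cond %in% reg$condition_id)
        reg$label[match(cond, reg$condition_id)] else cond,
      total_deaths = round_half_up(td),
      attr_deaths = round_half_up(ad),
      attr_deaths_pct = attributable_fraction(ad, td),
      attr_deaths_men = round_half_up(m$attr_deaths),
      attr_deaths_men_pct = attributable_fraction(m$attr_deaths, m$total_deaths),
      attr_deaths_women = round_half_up(w$attr_deaths),
      attr_deaths_women_pct = attributable_fraction(w$attr_deaths, w$total_deaths),
      total_events = if (eac) round_half_up(te) else NA_real_,
      attr_events = if (eac) round_half_up(ae) else NA_real_,
      attr_events_pct = if (eac) attributable_fraction(ae, te) else NA_real_,
      daly = round_half_up(sum(d$daly)),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(conds, row_for))
  if (!is.null(burden$shs)) {
    s <- burden$shs
    m <- s[s$sex == "male", ]; w <- s[s$sex == "female", ]
    ad <- sum(s$attr_deaths)
    out <- rbind(out, data.frame(
      condition = "shs_other",
      label = group_labels()[["shs_other"]],
      total_deaths = round_half_up(ad), attr_deaths = round_half_up(ad),
      attr_deaths_pct = 100,
      attr_deaths_men = round_half_up(m$attr_deaths),
      attr_deaths_men_pct = 100,
      attr_deaths_women = round_half_up(w$attr_deaths),
      attr_deaths_women_pct = 100,
      total_events = NA_real_, attr_events = NA_real_,
      attr_events_pct = NA_real_,
      daly = round_half_up(sum(s$daly)), stringsAsFactors = FALSE))
  }
  tot <- burden_totals(burden)
  out <- rbind(out, data.frame(
    condition = "total", label = "Total",
    total_deaths = round_half_up(tot$total_deaths),
    attr_deaths = round_half_up(tot$attr_deaths),
    attr_deaths_pct = attributable_fraction(tot$attr_deaths, tot$total_deaths),
    attr_deaths_men = NA_real_, attr_deaths_men_pct = NA_real_,
    attr_deaths_women = NA_real_, attr_deaths_women_pct = NA_real_,
    total_events = round_half_up(tot$total_events),
    attr_events = round_half_up(tot$attr_events),
    attr_events_pct = attributable_fraction(tot$attr_events, tot$total_events),
    daly = round_half_up(tot$daly), stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}
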