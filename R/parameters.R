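MODEL_SEXES <- c("male", "female")
SMOKING_STATES <- c("never", "current", "former")

#' Construct one condition's parameter set
#'
#' @param condition_id identifier, ideally one of [condition_registry()].
#' @param bands data.frame with `age_lo`, `age_hi` rows defining age bands.
#' @param incidence_never matrix (bands x sex, columns male/female) of
#'   per-person-year never-smoker event (acute) or onset (chronic) hazards.
#' @param mortality_never matrix of per-person-year hazards: in-state
#'   mortality for chronic conditions; ignored for acute conditions, whose
#'   deaths arise through `case_fatality`.
#' @param rr_current,rr_former relative risks versus never smokers (>= 0).
#' @param case_fatality probability of death at an acute event, in `[0,1]`.
#' @param disability_weight utility decrement in `[0,1]`.
#' @param mean_duration_years mean years lived in the disease state (> 0);
#'   used for YLD and case-year costing under the steady-state
#'   incidence-prevalence identity.
#' @param annual_direct_cost direct medical cost per case-year, 2015 local
#'   currency.
#' @param informal_care_hours_per_year unpaid caregiving hours per case-year.
#' @param label,group,acute,event_af_computable,icd10 metadata; defaults are
#'   taken from [condition_registry()] when `condition_id` is canonical.
#' @param mortality_scale per-sex multiplicative calibration factor on the
#'   mortality-producing pathway: case fatality for acute conditions, the
#'   baseline onset hazard for chronic ones (named c(male, female),
#'   default 1).
#' @return list of class `disease_spec`.
#' @export
disease_spec <- function(condition_id, bands, incidence_never, mortality_never,
                         rr_current, rr_former, case_fatality = 0,
                         disability_weight = 0, mean_duration_years = 1,
                         annual_direct_cost = 0,
                         informal_care_hours_per_year = 0,
                         label = NULL, group = NULL, acute = NULL,
                         event_af_computable = NULL, icd10 = "",
                         mortality_scale = c(male = 1, female = 1)) {
  reg <- condition_registry()
  hit <- match(condition_id, reg$condition_id)
  if (!is.na(hit)) {
    label <- label %||% reg$label[hit]
    group <- group %||% reg$group[hit]
    acute <- acute %||% reg$acute[hit]
    event_af_computable <- event_af_computable %||% reg$event_af_computable[hit]
    if (!nzchar(icd10)) icd10 <- reg$icd10[hit]
  } else {
    label <- label %||% condition_id
    group <- group %||% "other_cancers"
    acute <- acute %||% FALSE
    event_af_computable <- event_af_computable %||% TRUE
  }
  as_rate_matrix <- function(m) {
    m <- as.matrix(m)
    if (ncol(m) == 1) m <- cbind(m, m)
    dimnames(m) <- list(NULL, MODEL_SEXES)
    m
  }
  structure(list(
    condition_id = condition_id, label = label, group = group,
    acute = acute, event_af_computable = event_af_computable, icd10 = icd10,
    rr_current = rr_current, rr_former = rr_former,
    case_fatality = case_fatality, disability_weight = disability_weight,
    mean_duration_years = mean_duration_years,
    annual_direct_cost = annual_direct_cost,
    informal_care_hours_per_year = informal_care_hours_per_year,
    incidence_never = as_rate_matrix(incidence_never),
    mortality_never = as_rate_matrix(mortality_never),
    mortality_scale = mortality_scale
  ), class = "disease_spec")
}

#' Economic parameter set
#'
#' Defaults mirror the Peru 2020 setting: 10.47% cumulative inflation
#' 2015-2020, PEN 3.3 per USD (January 2020), a 5% discount rate on monetary
#' streams, and half of any consumption change expressed as lower smoker
#' prevalence.
#'
#' @param exchange_rate_pen_per_usd local currency units per USD.
#' @param inflation_factor cumulative inflation from the costing year to the
#'   reporting year (fraction, e.g. 0.1047).
#' @param discount_rate annual discount rate for monetary streams.
#' @param wage_growth_rate expected real annual wage growth.
#' @param retirement_age named vector c(male, female), years.
#' @param mincer per-sex list of log-wage coefficients
#'   `beta0 + beta_edu*edu + beta_age*age + beta_age2*age^2`.
#' @param mean_education_years named vector c(male, female).
#' @param caregiver_hourly_wage local currency per hour (reporting-year
#'   prices), the opportunity-cost proxy for informal care.
#' @param prevalence_impact_share share Ip of a consumption reduction that
#'   lowers smoker prevalence (default 0.5).
#' @param elasticity default price elasticity of cigarette demand (negative).
#'   Not a value reported by the modelled study; a typical LMIC figure.
#' @param gdp_usd_millions GDP in millions of USD, for GDP-share reporting.
#' @param cigarette_price_pen,tax_share,annual_consumption_packs retail price
#'   per pack (local currency), tax share of price, packs sold per year;
#'   drive tax-revenue projections.
#' @return list of class `econ_params`.
#' @export
econ_params <- function(exchange_rate_pen_per_usd = 3.3,
                        inflation_factor = 0.1047,
                        discount_rate = 0.05,
                        wage_growth_rate = 0.02,
                        retirement_age = c(male = 65, female = 65),
                        mincer = list(
                          male = c(beta0 = 7.1, beta_edu = 0.09,
                                   beta_age = 0.055, beta_age2 = -0.00055),
                          female = c(beta0 = 6.9, beta_edu = 0.09,
                                     beta_age = 0.055, beta_age2 = -0.00055)),
                        mean_education_years = c(male = 10.5, female = 9.8),
                        caregiver_hourly_wage = 9,
                        prevalence_impact_share = 0.5,
                        elasticity = -0.4,
                        gdp_usd_millions = 219039,
                        cigarette_price_pen = 12,
                        tax_share = 0.733,
                        annual_consumption_packs = 1.3e8) {
  structure(as.list(environment()), class = "econ_params")
}

#' Assemble a country parameter bundle
#'
#' @param strata data.frame `sex`, `age_lo`, `age_hi`, `population` with
#'   identical, disjoint, contiguous bands per sex.
#' @param smoking list with `prev` (data.frame `sex`, `age_lo`, `age_hi`,
#'   `prev_current`, `prev_former`, `prev_never` summing to 1 per stratum),
#'   scalar `cessation_prob`, `initiation_prob`, `adult_age`.
#' @param diseases list of [disease_spec()] objects.
#' @param life_table list with matrices `hazard` and `residual_le`
#'   (bands x sex): background (non-modelled-cause) mortality hazard and
#'   residual life expectancy used for YLL.
#' @param econ an [econ_params()] object.
#' @param shs_uplift named vector of secondhand-smoke/other-causes uplift
#'   fractions, default c(male = 0.136, female = 0.12).
#' @param validate if TRUE (default), stop listing all invariant violations.
#' @return list of class `country_model`.
#' @export
country_model <- function(strata, smoking, diseases, life_table, econ,
                          shs_uplift = c(male = 0.136, female = 0.12),
                          validate = TRUE) {
  names(diseases) <- vapply(diseases, `[[`, "", "condition_id")
  model <- structure(list(
    strata = strata, smoking = smoking, diseases = diseases,
    life_table = life_table, econ = econ, shs_uplift = shs_uplift
  ), class = "country_model")
  if (validate) {
    issues <- validate_model(model)
    if (length(issues))
      stop_named("invalid country model:\n%s",
                 paste("-", issues, collapse = "\n"))
  }
  model
}

#' Age bands of a model
#' @param model a `country_model`.
#' @return data.frame `age_lo`, `age_hi` in ascending order.
#' @export
model_bands <- function(model) {
  s <- model$strata[model$strata$sex == "male", , drop = FALSE]
  s <- s[order(s$age_lo), c("age_lo", "age_hi")]
  rownames(s) <- NULL
  s
}

#' Validate a country model
#'
#' Checks every type invariant and returns all violations as a character
#' vector, each naming the stratum or condition and the rule broken. Never
#' raises; an empty return means the model is valid.
#'
#' @param model a `country_model`.
#' @return character vector of issues (empty if valid).
#' @export
validate_model <- function(model) {
  issues <- character()
  add <- function(...) issues <<- c(issues, sprintf(...))

  st <- model$strata
  for (sx in MODEL_SEXES) {
    b <- st[st$sex == sx, , drop = FALSE]
    if (!nrow(b)) { add("strata: sex '%s' missing", sx); next }
    b <- b[order(b$age_lo), ]
    if (any(b$population < 0))
      add("strata[%s]: population_count must be >= 0", sx)
    if (any(b$age_hi < b$age_lo))
      add("strata[%s]: band with age_hi < age_lo", sx)
    if (nrow(b) > 1) {
      gaps <- b$age_lo[-1] - b$age_hi[-nrow(b)]
      if (any(gaps < 1)) add("strata[%s]: overlapping age bands", sx)
      if (any(gaps > 1)) add("strata[%s]: non-contiguous age bands", sx)
    }
  }
  bands <- model_bands(model)
  B <- nrow(bands)

  pv <- model$smoking$prev
  for (i in seq_len(nrow(pv))) {
    p <- unlist(pv[i, c("prev_current", "prev_former", "prev_never")])
    who <- sprintf("smoking[%s %d-%d]", pv$sex[i], pv$age_lo[i], pv$age_hi[i])
    if (any(p < 0 | p > 1)) add("%s: prevalence outside [0,1]", who)
    if (abs(sum(p) - 1) > 1e-9) add("%s: prevalences sum to %.6f, not 1", who, sum(p))
  }
  for (fld in c("cessation_prob", "initiation_prob")) {
    v <- model$smoking[[fld]]
    if (is.null(v) || v < 0 || v > 1) add("smoking: %s outside [0,1]", fld)
  }

  for (d in model$diseases) {
    id <- d$condition_id
    for (fld in c("incidence_never", "mortality_never")) {
      m <- d[[fld]]
      if (!is.matrix(m) || nrow(m) != B || ncol(m) != 2)
        add("%s: %s must be a bands x sex matrix (%d x 2)", id, fld, B)
      else if (any(!is.finite(m)) || any(m < 0))
        add("%s: %s hazards must be finite and >= 0", id, fld)
    }
    if (d$rr_current < 0) add("%s: rr_current must be >= 0", id)
    if (d$rr_former < 0) add("%s: rr_former must be >= 0", id)
    if (d$rr_current > 1 && d$rr_former > 1 && d$rr_former > d$rr_current)
      add("%s: rr_former must be <= rr_current when both exceed 1", id)
    if (d$case_fatality < 0 || d$case_fatality > 1)
      add("%s: case_fatality outside [0,1]", id)
    if (d$disability_weight < 0 || d$disability_weight > 1)
      add("%s: disability_weight outside [0,1]", id)
    if (d$mean_duration_years <= 0) add("%s: mean_duration_years must be > 0", id)
    if (d$annual_direct_cost < 0) add("%s: annual_direct_cost must be >= 0", id)
    if (d$informal_care_hours_per_year < 0)
      add("%s: informal_care_hours_per_year must be >= 0", id)
    if (any(d$mortality_scale < 0)) add("%s: mortality_scale must be >= 0", id)
  }
  ids <- names(model$diseases)
  if (anyDuplicated(ids)) add("diseases: duplicated condition_id")

  lt <- model$life_table
  for (fld in c("hazard", "residual_le")) {
    m <- lt[[fld]]
    if (!is.matrix(m) || nrow(m) != B || ncol(m) != 2)
      add("life_table: %s must be a bands x sex matrix", fld)
  }
  if (is.matrix(lt$hazard) && any(lt$hazard < 0))
    add("life_table: hazards must be >= 0")
  if (is.matrix(lt$residual_le) && nrow(lt$residual_le) == B)
    for (j in 1:2)
      if (any(diff(lt$residual_le[, j]) >= 0))
        add("life_table[%s]: residual life expectancy must strictly decrease with age",
            MODEL_SEXES[j])

  ec <- model$econ
  if (ec$exchange_rate_pen_per_usd <= 0) add("econ: exchange rate must be > 0")
  for (fld in c("inflation_factor", "discount_rate", "wage_growth_rate",
                "prevalence_impact_share"))
    if (ec[[fld]] < 0 || ec[[fld]] >= 1) add("econ: %s outside [0,1)", fld)
  if (any(ec$retirement_age <= 35)) add("econ: retirement_age must exceed 35")
  if (any(model$shs_uplift < 0)) add("shs_uplift: must be >= 0")

  issues
}

# ---- bundle I/O ------------------------------------------------------------

BUNDLE_FILES <- c("strata.csv", "smoking.csv", "diseases.csv",
                  "disease_rates.csv", "life_table.csv", "config.yaml")

#' Write a country model as a plain-text parameter bundle
#'
#' One delimited table per entity (strata, smoking prevalence, disease
#' scalars, disease rate curves, life table) plus a YAML config for scalars;
#' the layout [load_country()] reads.
#'
#' @param model a `country_model`.
#' @param path directory to create/write into.
#' @return `path`, invisibly.
#' @export
save_country <- function(model, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, file)
    utils::write.csv(df, file.path(path, file), row.names = FALSE)
  w(model$strata, "strata.csv")
  w(model$smoking$prev, "smoking.csv")

  ds <- model$diseases
  meta <- do.call(rbind, lapply(ds, function(d) data.frame(
    condition_id = d$condition_id, label = d$label, group = d$group,
    acute = d$acute, event_af_computable = d$event_af_computable,
    icd10 = d$icd10, rr_current = d$rr_current, rr_former = d$rr_former,
    case_fatality = d$case_fatality, disability_weight = d$disability_weight,
    mean_duration_years = d$mean_duration_years,
    annual_direct_cost = d$annual_direct_cost,
    informal_care_hours_per_year = d$informal_care_hours_per_year,
    mortality_scale_male = d$mortality_scale[["male"]],
    mortality_scale_female = d$mortality_scale[["female"]],
    stringsAsFactors = FALSE)))
  w(meta, "diseases.csv")

  bands <- model_bands(model)
  rates <- do.call(rbind, lapply(ds, function(d) {
    do.call(rbind, lapply(1:2, function(j) data.frame(
      condition_id = d$condition_id, sex = MODEL_SEXES[j],
      age_lo = bands$age_lo, age_hi = bands$age_hi,
      incidence_never = d$incidence_never[, j],
      mortality_never = d$mortality_never[, j])))
  }))
  w(rates, "disease_rates.csv")

  lt <- do.call(rbind, lapply(1:2, function(j) data.frame(
    sex = MODEL_SEXES[j], age_lo = bands$age_lo, age_hi = bands$age_hi,
    hazard = model$life_table$hazard[, j],
    residual_le = model$life_table$residual_le[, j])))
  w(lt, "life_table.csv")

  cfg <- list(
    smoking = model$smoking[c("cessation_prob", "initiation_prob", "adult_age")],
    econ = unclass(model$econ),
    shs_uplift = as.list(model$shs_uplift)
  )
  cfg$econ$retirement_age <- as.list(model$econ$retirement_age)
  cfg$econ$mean_education_years <- as.list(model$econ$mean_education_years)
  cfg$econ$mincer <- lapply(model$econ$mincer, as.list)
  yaml::write_yaml(cfg, file.path(path, "config.yaml"), precision = 15)
  invisible(path)
}

#' Load a country parameter bundle
#'
#' @param path bundle directory written by [save_country()] (or by hand in
#'   the same layout).
#' @param require_complete if TRUE (default) every condition in
#'   [condition_registry()] must be present.
#' @return a validated `country_model`.
#' @export
load_country <- function(path, require_complete = TRUE) {
  for (f in BUNDLE_FILES)
    if (!file.exists(file.path(path, f)))
      stop_named("bundle at '%s' is missing required file '%s'", path, f)
  r <- function(f) utils::read.csv(file.path(path, f), stringsAsFactors = FALSE)

  strata <- r("strata.csv")
  need <- c("sex", "age_lo", "age_hi", "population")
  if (!all(need %in% names(strata)))
    stop_named("strata.csv: missing field(s) %s",
               paste(setdiff(need, names(strata)), collapse = ", "))
  smoking_prev <- r("smoking.csv")
  meta <- r("diseases.csv")
  rates <- r("disease_rates.csv")
  lt_df <- r("life_table.csv")
  cfg <- yaml::read_yaml(file.path(path, "config.yaml"))
  for (fld in c("smoking", "econ", "shs_uplift"))
    if (is.null(cfg[[fld]]))
      stop_named("config.yaml: missing field '%s'", fld)

  if (require_complete) {
    missing <- setdiff(condition_registry()$condition_id, meta$condition_id)
    if (length(missing))
      stop_named("bundle is missing condition(s): %s",
                 paste(missing, collapse = ", "))
  }

  bands <- strata[strata$sex == "male", c("age_lo", "age_hi")]
  bands <- bands[order(bands$age_lo), ]
  mat_from <- function(df, col) {
    m <- sapply(MODEL_SEXES, function(sx) {
      d <- df[df$sex == sx, ]
      d[order(d$age_lo), col]
    })
    dimnames(m) <- list(NULL, MODEL_SEXES)
    m
  }

  diseases <- lapply(seq_len(nrow(meta)), function(i) {
    m <- meta[i, ]
    rd <- rates[rates$condition_id == m$condition_id, ]
    if (!nrow(rd))
      stop_named("disease_rates.csv: no rates for condition '%s'", m$condition_id)
    disease_spec(
      condition_id = m$condition_id, bands = bands,
      incidence_never = mat_from(rd, "incidence_never"),
      mortality_never = mat_from(rd, "mortality_never"),
      rr_current = m$rr_current, rr_former = m$rr_former,
      case_fatality = m$case_fatality,
      disability_weight = m$disability_weight,
      mean_duration_years = m$mean_duration_years,
      annual_direct_cost = m$annual_direct_cost,
      informal_care_hours_per_year = m$informal_care_hours_per_year,
      label = m$label, group = m$group, acute = m$acute,
      event_af_computable = m$event_af_computable, icd10 = m$icd10,
      mortality_scale = c(male = m$mortality_scale_male,
                          female = m$mortality_scale_female))
  })

  ec_cfg <- cfg$econ
  ec_cfg$retirement_age <- unlist(ec_cfg$retirement_age)
  ec_cfg$mean_education_years <- unlist(ec_cfg$mean_education_years)
  ec_cfg$mincer <- lapply(ec_cfg$mincer, unlist)
  econ <- do.call(econ_params, ec_cfg)

  model <- country_model(
    strata = strata,
    smoking = list(prev = smoking_prev,
                   cessation_prob = cfg$smoking$cessation_prob,
                   initiation_prob = cfg$smoking$initiation_prob,
                   adult_age = cfg$smoking$adult_age %||% 25),
    diseases = diseases,
    life_table = list(hazard = mat_from(lt_df, "hazard"),
                      residual_le = mat_from(lt_df, "residual_le")),
    econ = econ,
    shs_uplift = c(male = cfg$shs_uplift$male, female = cfg$shs_uplift$female),
    validate = FALSE)
  issues <- validate_model(model)
  if (length(issues))
    stop_named("bundle at '%s' failed validation:\n%s", path,
               paste("-", issues, collapse = "\n"))
  model
}
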