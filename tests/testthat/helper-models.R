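# Toy single-stratum models and a deterministic transition-matrix oracle,
# independent of the microsimulation engine.

toy_bands <- data.frame(age_lo = 35, age_hi = 104)

toy_life_table <- function(bg = 0.01, rle = 20) {
  list(hazard = matrix(bg, 1, 2, dimnames = list(NULL, c("male", "female"))),
       residual_le = matrix(rle, 1, 2,
                            dimnames = list(NULL, c("male", "female"))))
}

# one-band, one-condition model with constant hazards
toy_model <- function(inc = 0.01, rr_current = 2, rr_former = 1.5,
                      cf = 0.2, mort = 0.1, acute = TRUE, bg = 0.01,
                      prev_current = 0.3, prev_former = 0.2,
                      cessation = 0, dur = 2, dw = 0.2,
                      cost = 1000, hours = 10, pop = 1e6, rle = 20) {
  strata <- data.frame(sex = rep(c("male", "female"), each = 1),
                       age_lo = 35, age_hi = 104, population = pop / 2)
  prev <- data.frame(sex = c("male", "female"), age_lo = 35, age_hi = 104,
                     prev_current = prev_current, prev_former = prev_former,
                     prev_never = 1 - prev_current - prev_former)
  d <- disease_spec(
    condition_id = if (acute) "ami" else "copd", bands = toy_bands,
    incidence_never = matrix(inc, 1, 2),
    mortality_never = matrix(mort, 1, 2),
    rr_current = rr_current, rr_former = rr_former, case_fatality = cf,
    disability_weight = dw, mean_duration_years = dur,
    annual_direct_cost = cost, informal_care_hours_per_year = hours,
    acute = acute)
  country_model(
    strata = strata,
    smoking = list(prev = prev, cessation_prob = cessation,
                   initiation_prob = 0, adult_age = 25),
    diseases = list(d),
    life_table = toy_life_table(bg, rle),
    econ = econ_params(),
    shs_uplift = c(male = 0, female = 0))
}

# Deterministic oracle: propagates per-(smoking state, start age) occupancy
# vectors over states (healthy, diseased, dead_disease, dead_background)
# with the engine's documented within-cycle order, by repeated
# matrix-vector products. Returns expected disease deaths, background
# deaths and events per simulated person over `horizon` cycles.
toy_chain_oracle <- function(model, horizon,
                             mode = c("factual", "never_smoker"),
                             quit_fraction = 0) {
  mode <- match.arg(mode)
  d <- model$diseases[[1]]
  inc <- d$incidence_never[1, 1]
  mort <- d$mortality_never[1, 1]
  bg <- model$life_table$hazard[1, 1]
  max_age <- 104
  p_bg <- 1 - exp(-bg)

  prev <- model$smoking$prev[1, ]
  w <- c(never = prev$prev_never, current = 0, former = 0)
  if (mode == "factual") {
    w["current"] <- prev$prev_current * (1 - quit_fraction)
    w["former"] <- prev$prev_former + prev$prev_current * quit_fraction
    w["never"] <- prev$prev_never
  } else w["never"] <- 1
  rrs <- c(never = 1, current = d$rr_current, former = d$rr_former)

  ages <- 35:104
  res <- c(dead_dis = 0, dead_bg = 0, events = 0)
  for (s in names(w)) {
    if (w[[s]] == 0) next
    rr <- rrs[[s]]
    p_ev <- 1 - exp(-inc * rr)
    p_de <- p_ev * min(1, d$case_fatality)
    p_d <- 1 - exp(-mort)
    prev0 <- if (d$acute) 0 else min(inc * rr * d$mean_duration_years, 0.95)
    for (a in ages) {
      occ <- c(healthy = 1 - prev0, diseased = prev0, dd = 0, db = 0)
      ev <- 0
      for (t in seq_len(horizon)) {
        forced <- (a + t - 1) >= max_age
        pb <- if (forced) 1 else p_bg
        if (d$acute) {
          ev <- ev + occ["healthy"] * p_ev
          dd <- occ["healthy"] * p_de
          db <- occ["healthy"] * (1 - p_de) * pb
          occ["dd"] <- occ["dd"] + dd
          occ["db"] <- occ["db"] + db
          occ["healthy"] <- occ["healthy"] - dd - db
        } else {
          onset <- occ["healthy"] * p_ev
          ev <- ev + onset
          dd <- occ["diseased"] * p_d
          db_d <- occ["diseased"] * (1 - p_d) * pb
          db_h <- occ["healthy"] * pb
          occ["dd"] <- occ["dd"] + dd
          occ["db"] <- occ["db"] + db_d + db_h
          occ["diseased"] <- occ["diseased"] - dd - db_d +
            onset * (1 - pb)
          occ["healthy"] <- (occ["healthy"] - onset) * (1 - pb)
        }
      }
      res <- res + w[[s]] / length(ages) *
        c(occ[["dd"]], occ[["db"]], ev)
    }
  }
  names(res) <- c("dead_dis", "dead_bg", "events")
  res
}
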