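# First-order Monte-Carlo Markov engine.
#
# Annual cycles, fixed event order within a cycle (smoking transition ->
# per-condition event draws -> acute case fatality -> chronic in-state
# mortality -> background mortality), no half-cycle correction. All uniforms
# for a cycle are drawn for every simulated individual (alive or dead) from a
# per-cycle seed derived from the master seed, so factual and counterfactual
# runs at the same seed traverse identical random streams: the common random
# numbers that make attributable differences low-variance and, with RRs >= 1,
# sign-definite. Death at an acute event and chronic in-state death reuse the
# condition's event uniform (u < p_event * case_fatality given u < p_event
# preserves the conditional probability), keeping draw counts fixed.

compile_model <- function(model) {
  bands <- model_bands(model)
  B <- nrow(bands)
  ds <- model$diseases
  K <- length(ds)
  arr <- function(fld) {
    a <- array(0, c(B, 2, K))
    for (k in seq_len(K)) a[, , k] <- ds[[k]][[fld]]
    a
  }
  prev <- model$smoking$prev
  pmat <- function(col) {
    m <- sapply(MODEL_SEXES, function(sx) {
      d <- prev[prev$sex == sx, ]
      d[order(d$age_lo), col]
    })
    matrix(m, nrow = B)
  }
  pop <- sapply(MODEL_SEXES, function(sx) {
    d <- model$strata[model$strata$sex == sx, ]
    d[order(d$age_lo), "population"]
  })
  list(
    band_lo = bands$age_lo, band_hi = bands$age_hi, B = B,
    K = K, ids = names(ds),
    acute = vapply(ds, `[[`, TRUE, "acute"),
    eac = vapply(ds, `[[`, TRUE, "event_af_computable"),
    groups = vapply(ds, `[[`, "", "group"),
    rr_c = vapply(ds, `[[`, 0, "rr_current"),
    rr_f = vapply(ds, `[[`, 0, "rr_former"),
    cf = vapply(ds, `[[`, 0, "case_fatality"),
    dw = vapply(ds, `[[`, 0, "disability_weight"),
    dur = vapply(ds, `[[`, 0, "mean_duration_years"),
    scale = t(vapply(ds, `[[`, c(male = 0, female = 0), "mortality_scale")),
    inc = arr("incidence_never"), mort = arr("mortality_never"),
    bg = model$life_table$hazard, rle = model$life_table$residual_le,
    prev_c = pmat("prev_current"), prev_f = pmat("prev_former"),
    cessation = model$smoking$cessation_prob,
    pop = matrix(pop, nrow = B), pop_total = sum(pop),
    max_age = max(bands$age_hi)
  )
}

# one annual cycle over a cohort state list; st fields: age, sex (1/2),
# state (1 never / 2 current / 3 former), alive, instate (n x K logical).
# draws: u_smoke (n), U (n x K), u_bg (n). Returns updated state plus the
# cycle's event matrix and death causes (0 none, K+1 background).
advance_cycle <- function(st, comp, draws, transitions = TRUE) {
  n <- length(st$age)
  K <- comp$K
  alive0 <- st$alive
  band <- pmin(findInterval(st$age, comp$band_lo), comp$B)
  ixbs <- cbind(band, st$sex)

  if (transitions && comp$cessation > 0) {
    quit <- alive0 & st$state == 2L & draws$u_smoke < comp$cessation
    st$state[quit] <- 3L
  }

  cause <- integer(n)
  ev_mat <- matrix(FALSE, n, K)
  scale_k <- comp$scale  # K x 2 (rows conditions)
  for (k in seq_len(K)) {
    rr <- c(1, comp$rr_c[k], comp$rr_f[k])[st$state]
    inc_k <- matrix(comp$inc[, , k], comp$B, 2L)
    u <- draws$U[, k]
    sc <- scale_k[k, st$sex]
    if (comp$acute[k]) {
      p <- -expm1(-inc_k[ixbs] * rr)
      ev <- alive0 & u < p
      die <- ev & u < p * pmin(1, comp$cf[k] * sc)
    } else {
      # calibration scales the onset pathway: deaths respond linearly
      # through the prevalent pool, so damped updates converge
      p <- -expm1(-inc_k[ixbs] * rr * sc)
      ink <- st$instate[, k]
      ev <- alive0 & !ink & u < p
      mort_k <- matrix(comp$mort[, , k], comp$B, 2L)
      pd <- -expm1(-mort_k[ixbs])
      die <- alive0 & ink & u < pd
      st$instate[ev, k] <- TRUE
    }
    ev_mat[, k] <- ev
    hit <- die & cause == 0L
    cause[hit] <- k
  }

  pbg <- -expm1(-comp$bg[ixbs])
  die_bg <- alive0 & cause == 0L &
    (draws$u_bg < pbg | st$age >= comp$max_age)
  cause[die_bg] <- K + 1L

  died <- cause > 0L
  st$alive <- st$alive & !died
  surv <- alive0 & !died
  st$age[surv] <- st$age[surv] + 1L
  list(st = st, events = ev_mat, cause = cause, band = band, alive0 = alive0)
}

cycle_draws <- function(seed, t, n, K) {
  set.seed(cycle_seed(seed, t))
  list(u_smoke = stats::runif(n),
       U = matrix(stats::runif(n * K), n, K),
       u_bg = stats::runif(n))
}

#' Simulate a population snapshot over annual cycles
#'
#' Samples `n` individuals from the model's age-sex structure (and smoking
#' profile when factual), then advances them in annual cycles until death or
#' the horizon. `never_smoker` mode forces every individual to the
#' never-smoker state but consumes the identical random streams, so the
#' factual/counterfactual difference at a common seed isolates the smoking
#' effect (common random numbers).
#'
#' @param model a validated `country_model`.
#' @param n number of simulated individuals (>= 1).
#' @param seed master seed; identical (model, n, seed, mode) give
#'   bit-identical results.
#' @param smoking_mode `"factual"` or `"never_smoker"`.
#' @param horizon `"lifetime"` or a positive integer number of years.
#' @param quit_fraction fraction of current smokers reassigned to former at
#'   baseline (policy counterfactuals; movers are the lowest-uniform current
#'   smokers so scenarios at increasing fractions are nested).
#' @return object of class `sim_result`: arrays of deaths
#'   (condition x sex x age band x year, cause `background` appended),
#'   events, person-years by smoking state and year, age-at-death
#'   accumulators by sex and baseline smoking state, and the scale factor
#'   from simulated individuals to the model population.
#' @export
simulate_population <- function(model, n, seed,
                                smoking_mode = c("factual", "never_smoker"),
                                horizon = "lifetime", quit_fraction = 0) {
  smoking_mode <- match.arg(smoking_mode)
  if (!is.numeric(n) || n < 1) stop_named("n must be a positive count")
  n <- as.integer(n)
  if (!(identical(horizon, "lifetime") ||
        (is.numeric(horizon) && horizon >= 1)))
    stop_named("horizon must be \"lifetime\" or a positive number of years")
  stopifnot(quit_fraction >= 0, quit_fraction <= 1)

  comp <- compile_model(model)
  B <- comp$B; K <- comp$K

  # --- baseline population (seeded; identical across modes) ---
  set.seed(as.integer(seed))
  p_male <- sum(comp$pop[, 1]) / comp$pop_total
  u_sex <- stats::runif(n)
  sex <- ifelse(u_sex < p_male, 1L, 2L)
  u_band <- stats::runif(n)
  band <- integer(n)
  for (j in 1:2) {
    cp <- cumsum(comp$pop[, j]) / sum(comp$pop[, j])
    sel <- sex == j
    band[sel] <- pmin(findInterval(u_band[sel], cp) + 1L, B)
  }
  u_age <- stats::runif(n)
  width <- comp$band_hi[band] - comp$band_lo[band] + 1L
  age <- comp$band_lo[band] + as.integer(floor(u_age * width))
  u_state <- stats::runif(n)
  pc <- comp$prev_c[cbind(band, sex)]
  pf <- comp$prev_f[cbind(band, sex)]
  state <- rep(1L, n)
  if (smoking_mode == "factual") {
    state[u_state < pc + pf] <- 3L
    state[u_state < pc * (1 - quit_fraction)] <- 2L
  }
  init_state <- state

  # baseline prevalent chronic cases: steady-state prevalence approximation
  # incidence x RR(state) x mean duration, one uniform per individual and
  # condition so that arms at a common seed have nested case sets
  u_prev <- matrix(stats::runif(n * K), n, K)
  instate <- matrix(FALSE, n, K)
  for (k in seq_len(K)) {
    if (comp$acute[k]) next
    rr <- c(1, comp$rr_c[k], comp$rr_f[k])[state]
    inc_k <- matrix(comp$inc[, , k], B, 2L)
    prev_k <- pmin(inc_k[cbind(band, sex)] * rr * comp$dur[k] *
                     comp$scale[k, sex], 0.95)
    instate[, k] <- u_prev[, k] < prev_k
  }

  st <- list(age = age, sex = sex, state = state,
             alive = rep(TRUE, n), instate = instate)

  TY <- if (identical(horizon, "lifetime")) comp$max_age - 35L + 1L
        else as.integer(horizon)
  deaths <- array(0, c(K + 1L, 2L, B, TY),
                  dimnames = list(c(comp$ids, "background"), MODEL_SEXES,
                                  NULL, NULL))
  events <- array(0, c(K, 2L, B, TY),
                  dimnames = list(comp$ids, MODEL_SEXES, NULL, NULL))
  py_state <- matrix(0, 3L, TY, dimnames = list(SMOKING_STATES, NULL))
  le_sum <- le_n <- matrix(0, 2L, 3L,
                           dimnames = list(MODEL_SEXES, SMOKING_STATES))
  py_total <- 0

  for (t in seq_len(TY)) {
    draws <- cycle_draws(seed, t, n, K)
    out <- advance_cycle(st, comp, draws,
                         transitions = smoking_mode == "factual")
    st <- out$st
    alive0 <- out$alive0
    py_total <- py_total + sum(alive0)
    py_state[, t] <- py_state[, t] + tabulate(st$state[alive0], 3L)

    bs <- (st$sex - 1L) * B + out$band
    for (k in seq_len(K)) {
      ev <- out$events[, k]
      if (any(ev))
        events[k, , , t] <- t(matrix(tabulate(bs[ev], 2L * B), B, 2L))
    }
    died <- out$cause > 0L
    if (any(died)) {
      idx <- (out$cause[died] - 1L) * 2L * B + bs[died]
      tab <- tabulate(idx, (K + 1L) * 2L * B)
      deaths[, , , t] <- aperm(array(tab, c(B, 2L, K + 1L)), c(3L, 2L, 1L))
      grp <- (init_state[died] - 1L) * 2L + st$sex[died]
      agd <- st$age[died]
      for (g in unique(grp)) {
        s <- (g - 1L) %/% 2L + 1L  # init state
        sx <- (g - 1L) %% 2L + 1L
        le_sum[sx, s] <- le_sum[sx, s] + sum(agd[grp == g])
        le_n[sx, s] <- le_n[sx, s] + sum(grp == g)
      }
    }
    if (!any(st$alive)) break
  }

  structure(list(
    n = n, seed = as.integer(seed), smoking_mode = smoking_mode,
    horizon = horizon, years = TY, quit_fraction = quit_fraction,
    conditions = comp$ids, acute = comp$acute, eac = comp$eac,
    groups = comp$groups, bands = data.frame(age_lo = comp$band_lo,
                                             age_hi = comp$band_hi),
    deaths = deaths, events = events,
    person_years = py_total, py_state = py_state,
    le_sum = le_sum, le_n = le_n,
    pop_total = comp$pop_total, scale_factor = comp$pop_total / n
  ), class = "sim_result")
}

#' Advance one individual by one annual cycle
#'
#' Single-individual view of the engine: applies, in the documented order,
#' the smoking-state transition, per-condition event draws with hazard x
#' RR(state), acute case fatality, chronic in-state mortality and background
#' mortality, then increments age. Dead individuals are returned unchanged.
#'
#' @param ind list with `sex` ("male"/"female"), `current_age`,
#'   `smoking_state` ("never"/"current"/"former"), optional
#'   `years_since_quit`, `disease_history` (named vector condition -> onset
#'   year), `alive`.
#' @param model a `country_model`.
#' @param year current simulation year (recorded in the disease history).
#' @param draws list of uniforms: `u_smoke` (scalar), `u_event` (one per
#'   condition, in model order), `u_bg` (scalar).
#' @return the updated individual, with `cause_of_death` set on death.
#' @export
step_individual <- function(ind, model, year, draws) {
  if (!isTRUE(ind$alive)) return(ind)
  comp <- compile_model(model)
  K <- comp$K
  st <- list(
    age = as.integer(ind$current_age),
    sex = match(ind$sex, MODEL_SEXES),
    state = match(ind$smoking_state, SMOKING_STATES),
    alive = TRUE,
    instate = matrix(FALSE, 1L, K))
  st$instate[1, ] <- comp$ids %in% names(ind$disease_history %||% list())
  st$instate[1, comp$acute] <- FALSE  # acute conditions never absorb
  d <- list(u_smoke = draws$u_smoke, U = matrix(draws$u_event, 1L, K),
            u_bg = draws$u_bg)
  out <- advance_cycle(st, comp, d)

  was_former <- ind$smoking_state == "former"
  ind$smoking_state <- SMOKING_STATES[out$st$state]
  if (ind$smoking_state == "former")
    ind$years_since_quit <- if (was_former) (ind$years_since_quit %||% 0) + 1 else 0
  new_ev <- comp$ids[out$events[1, ]]
  for (id in new_ev)
    if (!id %in% names(ind$disease_history))
      ind$disease_history[[id]] <- year
  if (out$cause[1] > 0L) {
    ind$alive <- FALSE
    ind$cause_of_death <- c(comp$ids, "background")[out$cause[1]]
  } else {
    ind$current_age <- out$st$age[1]
  }
  ind
}

#' Mean remaining-life summary by sex and baseline smoking state
#'
#' Mean age at death (from age 35) within a group of a lifetime simulation;
#' the gap between never and current smokers is the life-expectancy loss
#' attributable to smoking.
#'
#' @param result a `sim_result` simulated with `horizon = "lifetime"`.
#' @param sex "male" or "female".
#' @param smoking_state baseline state "never", "current" or "former".
#' @return mean age at death, years.
#' @export
life_expectancy <- function(result, sex, smoking_state) {
  stopifnot(inherits(result, "sim_result"))
  if (!identical(result$horizon, "lifetime"))
    stop_named("life_expectancy requires a lifetime simulation")
  n <- result$le_n[sex, smoking_state]
  if (is.na(n) || n == 0)
    stop_named("no deaths recorded for %s %s", sex, smoking_state)
  result$le_sum[sex, smoking_state] / n
}
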