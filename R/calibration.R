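# Calibration of cause-specific mortality against registry-style reference
# tables. Cells are condition x sex (age bands pooled so the stochastic
# target is estimated with workable Monte-Carlo precision); failing cells
# get a damped multiplicative update of the condition-sex calibration scale
# (case fatality for acute conditions, the baseline onset hazard for chronic
# ones, where deaths respond linearly through the prevalent pool). Relative
# risks are never touched, so the smoking effect survives calibration
# unchanged.

#' Relative deviation of a model prediction from a reference count
#' @param model_value predicted count.
#' @param reference_value reference count; `NA` returned where it is 0.
#' @return `(model - reference) / reference`.
#' @export
relative_deviation <- function(model_value, reference_value) {
  ifelse(reference_value > 0,
         (model_value - reference_value) / reference_value, NA_real_)
}

#' Cause- and sex-specific mortality of a simulation, as a reference table
#'
#' @param result a `sim_result` (lifetime horizon recommended).
#' @param source label recorded with the table.
#' @return data.frame of class `reference_mortality`: `condition`, `sex`,
#'   `deaths` (population units).
#' @export
reference_mortality <- function(result, source = "simulated") {
  stopifnot(inherits(result, "sim_result"))
  K <- length(result$conditions)
  d <- apply(result$deaths[seq_len(K), , , , drop = FALSE], c(1, 2), sum) *
    result$scale_factor
  out <- data.frame(
    condition = rep(result$conditions, 2),
    sex = rep(MODEL_SEXES, each = K),
    deaths = c(d[, 1], d[, 2]),
    stringsAsFactors = FALSE)
  attr(out, "source") <- source
  class(out) <- c("reference_mortality", "data.frame")
  out
}

#' Calibrate a model's cause-specific mortality to a reference table
#'
#' Iteratively simulates the factual arm, compares condition x sex death
#' counts to the reference, and multiplies each failing cell's calibration
#' scale by `(reference / model)^damping` until every cell with a nonzero
#' reference is within `tol` or `max_iter` is reached. Zero-reference cells
#' are marked not applicable and excluded. Non-convergence is reported in
#' the returned table's `pass` flags, never raised.
#'
#' @param model a validated `country_model`.
#' @param reference a [reference_mortality()] table covering the model's
#'   conditions.
#' @param n simulated individuals per iteration.
#' @param seed fixed seed for all calibration runs (validate at a different
#'   seed to detect overfitting to simulation noise).
#' @param max_iter iteration cap (default 10).
#' @param tol acceptance threshold on |relative deviation| (default 0.15).
#' @param damping exponent damping the multiplicative update (default 0.5).
#' @return list of class `calibration_result`: the adjusted `model`, the
#'   final `report` (condition, sex, model deaths, reference, deviation,
#'   pass), `iterations` used, `converged`, and the `factors` applied.
#' @export
calibrate <- function(model, reference, n, seed, max_iter = 10,
                      tol = 0.15, damping = 0.5) {
  stopifnot(inherits(reference, "reference_mortality") ||
              all(c("condition", "sex", "deaths") %in% names(reference)))
  ids <- names(model$diseases)
  missing <- setdiff(ids, unique(reference$condition))
  if (length(missing))
    stop_named("reference does not cover condition(s): %s",
               paste(missing, collapse = ", "))

  report <- NULL
  iterations <- 0
  factors <- stats::setNames(
    rep(list(c(male = 1, female = 1)), length(ids)), ids)

  for (it in seq_len(max_iter + 1)) {
    sim <- simulate_population(model, n, seed, "factual", "lifetime")
    pred <- reference_mortality(sim)
    m <- merge(pred, reference, by = c("condition", "sex"),
               suffixes = c("_model", "_reference"))
    m$deviation <- relative_deviation(m$deaths_model, m$deaths_reference)
    m$pass <- !is.na(m$deviation) & abs(m$deviation) <= tol
    m$pass[is.na(m$deviation)] <- NA  # zero-reference cells: excluded
    report <- m[order(m$condition, m$sex), ]
    rownames(report) <- NULL
    failing <- which(!is.na(m$pass) & !m$pass)
    if (!length(failing) || it > max_iter) break
    iterations <- it
    for (i in failing) {
      id <- m$condition[i]; sx <- m$sex[i]
      upd <- (m$deaths_reference[i] / max(m$deaths_model[i], 1e-9))^damping
      model$diseases[[id]]$mortality_scale[[sx]] <-
        model$diseases[[id]]$mortality_scale[[sx]] * upd
      factors[[id]][[sx]] <- factors[[id]][[sx]] * upd
    }
  }
  structure(list(
    model = model, report = report, iterations = iterations,
    converged = all(report$pass, na.rm = TRUE), factors = factors,
    n = n, seed = seed, tol = tol, damping = damping
  ), class = "calibration_result")
}
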