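# Survival machinery: lognormal AFT curves, hazard-ratio adjustment,
# life-table background mortality, and parametric fitting/selection from
# published Kaplan-Meier summaries.

#' Lognormal survivor function
#'
#' `S(t) = 1 - Phi((ln t - mu)/sigma)`, the accelerated-failure-time
#' parameterization used for the disease-free-survival and breast-cancer
#' mortality curves (`mu` is the published "intercept", `sigma` the exp of
#' the published "log(scale)").
#'
#' @param t Time in years (vectorized, `t >= 0`).
#' @param mu Location on the log-year scale.
#' @param sigma Positive scale.
#' @return Survival probabilities in \[0, 1\].
#' @examples
#' surv_lognormal(exp(3.28), 3.28, exp(0.61)) # median: 0.5
#' @export
surv_lognormal <- function(t, mu, sigma) {
  if (any(t < 0)) abort("t must be >= 0", class = "tdm_domain_error")
  if (sigma <= 0) abort("sigma must be > 0", class = "tdm_domain_error")
  plnorm(t, meanlog = mu, sdlog = sigma, lower.tail = FALSE)
}

#' Proportional-hazards adjustment of a survivor function
#'
#' Multiplying the cumulative hazard by `hr` transforms the survivor
#' probability to `s^hr`; for `hr < 1` survival improves.
#'
#' @param s Survivor probabilities in (0, 1\] (vectorized).
#' @param hr Hazard ratio, `> 0`.
#' @return `s^hr`.
#' @export
apply_hazard_ratio <- function(s, hr) {
  if (any(hr <= 0)) abort("hazard ratio must be > 0", class = "tdm_domain_error")
  if (any(s <= 0 | s > 1)) {
    abort("survivor probabilities must lie in (0, 1]", class = "tdm_domain_error")
  }
  s^hr
}

#' Construct / validate a life table
#'
#' @param age Integer ages (contiguous years).
#' @param qx Annual death probabilities, each in \[0, 1).
#' @return A tibble of class `tdm_life_table` with columns `age`, `qx`.
#' @export
life_table <- function(age, qx) {
  lt <- tibble(age = as.integer(age), qx = as.numeric(qx))
  validate_life_table(lt)
}

validate_life_table <- function(lt) {
  if (!all(c("age", "qx") %in% names(lt))) {
    abort("life table needs columns `age` and `qx`", class = "tdm_validation_error")
  }
  lt <- dplyr::arrange(as_tibble(lt), .data$age)
  if (nrow(lt) == 0) abort("life table is empty", class = "tdm_validation_error")
  if (any(diff(lt$age) != 1L)) {
    abort("life table ages must be contiguous", class = "tdm_validation_error")
  }
  if (any(lt$qx < 0 | lt$qx >= 1)) {
    abort("every qx must lie in [0, 1)", class = "tdm_validation_error")
  }
  class(lt) <- c("tdm_life_table", class(tibble()))
  lt
}

#' Read / write a life table CSV (`age,qx`)
#' @param path CSV path.
#' @return [read_life_table()]: a validated life-table tibble.
#' @export
read_life_table <- function(path) {
  validate_life_table(read.csv(path))
}

#' @rdname read_life_table
#' @param lt A life table.
#' @export
write_life_table <- function(lt, path) {
  write.csv(as.data.frame(validate_life_table(lt))[c("age", "qx")], path,
            row.names = FALSE)
  invisible(path)
}

#' Background (other-cause) survival from a life table
#'
#' Survival from `start_age` over `t` years as the product of annual
#' `(1 - qx)`, with fractional years under the constant-hazard-within-year
#' convention: surviving a fraction `f` of age `a` contributes
#' `exp(f * log(1 - q_a))`.
#'
#' @param lt A life table covering `[start_age, start_age + max(t)]`.
#' @param start_age Age in years at time 0 (integer).
#' @param t Elapsed years (vectorized, `>= 0`).
#' @return Survival probabilities.
#' @export
surv_background <- function(lt, start_age, t) {
  lt <- validate_life_table(lt)
  if (any(t < 0)) abort("t must be >= 0", class = "tdm_domain_error")
  idx0 <- match(as.integer(floor(start_age)), lt$age)
  if (is.na(idx0)) {
    abort("start_age not covered by the life table", class = "tdm_coverage_error")
  }
  max_age <- floor(start_age + max(t) - 1e-9)
  if (length(t) && max_age > max(lt$age)) {
    abort("life table does not cover start_age + t", class = "tdm_coverage_error")
  }
  loghaz_year <- log1p(-lt$qx[idx0:nrow(lt)])   # log annual survival, <= 0
  cum <- c(0, cumsum(loghaz_year))
  k <- floor(t)
  f <- t - k
  # ages beyond the table can only be reached with f == 0 handled above
  li <- pmin(k + 1L, length(loghaz_year))
  exp(cum[k + 1L] + f * loghaz_year[li])
}

#' Overall survival: disease-specific curve plus background mortality
#'
#' Independent competing hazards: `OS(t) = S_bc(t) * S_bg(t)` where `S_bc`
#' is the breast-cancer mortality curve and `S_bg` the life-table survival.
#'
#' @inheritParams surv_lognormal
#' @inheritParams surv_background
#' @return Survival probabilities.
#' @export
surv_overall <- function(t, mu, sigma, lt, start_age) {
  surv_lognormal(t, mu, sigma) * surv_background(lt, start_age, t)
}

#' Survivor function with a hazard switch at a fixed time
#'
#' Models a subcohort whose recurrence hazard drops to the high-exposure
#' level once dose escalation is confirmed: before `switch_time` the
#' low-exposure curve applies; from `switch_time` the hazard is multiplied
#' by `hr`, and (when `hr_duration` is finite) reverts to the low-exposure
#' hazard once treatment ends, retaining the survival advantage accrued in
#' between. `switch_time = 0` gives the hazard-ratio-adjusted curve from the
#' start, `switch_time = Inf` (or `>= hr_duration`) the low curve
#' everywhere.
#'
#' @inheritParams surv_lognormal
#' @param hr Hazard ratio applied after the switch.
#' @param switch_time Years, `>= 0` (may be `Inf`).
#' @param hr_duration Years from time 0 during which the hazard ratio acts
#'   (treatment duration); `Inf` applies it over the whole curve.
#' @return Survival probabilities, continuous at `switch_time` and
#'   `hr_duration`.
#' @export
surv_switched <- function(t, mu, sigma, hr, switch_time, hr_duration = Inf) {
  if (switch_time < 0) abort("switch_time must be >= 0", class = "tdm_domain_error")
  if (hr <= 0) abort("hazard ratio must be > 0", class = "tdm_domain_error")
  s_low <- surv_lognormal(t, mu, sigma)
  .hr_window_curve(t, s_low, mu, sigma, hr, switch_time, hr_duration)
}

# Survivor curve for a subcohort on the low-exposure lognormal whose hazard
# is multiplied by `hr` on the interval (switch_time, hr_duration]:
# S(t) = S_low(t) * (S_low(min(t, T)) / S_low(s))^(hr - 1) for t > s.
.hr_window_curve <- function(t, s_low, mu, sigma, hr, switch_time, hr_duration) {
  if (is.infinite(switch_time) || switch_time >= hr_duration || hr == 1) {
    return(s_low)
  }
  a <- if (switch_time == 0) 1 else plnorm(switch_time, mu, sigma, lower.tail = FALSE)
  s_min <- if (is.infinite(hr_duration)) {
    s_low
  } else {
    s_t <- plnorm(hr_duration, mu, sigma, lower.tail = FALSE)
    ifelse(t <= hr_duration, s_low, s_t)
  }
  ifelse(t <= switch_time, s_low, s_low * (s_min / a)^(hr - 1))
}

#' Reconstruct event and censoring counts from published KM summaries
#'
#' Given survival probabilities and numbers at risk at interval boundaries
#' (as read off a published Kaplan-Meier curve), back-calculates integer
#' events per interval from the survival drops (`d_i = round(n_i * (1 -
#' S_{i+1}/S_i))`) with censorings absorbing the remaining decline in the
#' at-risk count. Re-running the KM estimator on the counts reproduces the
#' input survival to within the rounding of a single patient.
#'
#' @param km A data frame with columns `time_years` (increasing boundaries),
#'   `survival` (non-increasing, starting at 1) and `n_risk` (non-increasing,
#'   positive at time 0).
#' @return A tibble with one row per interval: `interval_start`,
#'   `interval_end`, `n_risk`, `events`, `censored`; the number still at risk
#'   at the final boundary is kept in attribute `final_n_risk`.
#' @export
km_reconstruct <- function(km) {
  km <- as_tibble(km)
  need <- c("time_years", "survival", "n_risk")
  if (!all(need %in% names(km))) {
    abort("KM data needs columns time_years, survival, n_risk",
          class = "tdm_validation_error")
  }
  if (nrow(km) < 2) abort("need at least two boundaries", class = "tdm_data_error")
  if (any(diff(km$time_years) <= 0)) {
    abort("boundaries must be strictly increasing", class = "tdm_data_error")
  }
  if (km$survival[1] != 1) abort("survival must start at 1", class = "tdm_data_error")
  if (any(diff(km$survival) > 0)) {
    abort("survival must be non-increasing", class = "tdm_data_error")
  }
  if (any(diff(km$n_risk) > 0) || km$n_risk[1] <= 0) {
    abort("numbers at risk must be non-increasing and positive at time 0",
          class = "tdm_data_error")
  }
  m <- nrow(km)
  i <- seq_len(m - 1)
  drop_frac <- 1 - km$survival[i + 1] / km$survival[i]
  drop_frac[!is.finite(drop_frac)] <- 0 # survival already 0
  events <- floor(km$n_risk[i] * drop_frac + 0.5)
  censored <- km$n_risk[i] - km$n_risk[i + 1] - events
  if (any(censored < -0.5) || any(events < 0)) {
    abort("at-risk and survival sequences imply negative counts",
          class = "tdm_data_error")
  }
  censored <- pmax(censored, 0)
  out <- tibble(
    interval_start = km$time_years[i],
    interval_end   = km$time_years[i + 1],
    n_risk         = km$n_risk[i],
    events         = as.integer(events),
    censored       = as.integer(censored)
  )
  attr(out, "final_n_risk") <- km$n_risk[m]
  out
}

#' Expand reconstructed counts to interval-censored pseudo patient data
#'
#' Events become interval-censored observations on `(interval_start,
#' interval_end]`, within-interval censorings right-censored at the interval
#' start, and survivors at the last boundary right-censored there.
#'
#' @param counts Output of [km_reconstruct()].
#' @return A tibble with columns `lower`, `upper` (`Inf` = right-censored).
#' @export
km_pseudo_ipd <- function(counts) {
  stopifnot(all(c("interval_start", "interval_end", "events", "censored") %in%
                  names(counts)))
  rows <- purrr::pmap(counts, function(interval_start, interval_end, n_risk,
                                       events, censored, ...) {
    tibble(
      lower = c(rep(interval_start, events), rep(interval_start, censored)),
      upper = c(rep(interval_end, events), rep(Inf, censored))
    )
  })
  out <- bind_rows(rows)
  fin <- attr(counts, "final_n_risk") %||% 0
  if (fin > 0) {
    out <- bind_rows(out, tibble(lower = rep(max(counts$interval_end), fin),
                                 upper = Inf))
  }
  out
}

#' Fit a parametric survival model
#'
#' Maximum-likelihood fit of one of the four candidate extrapolation
#' families (exponential, Weibull, lognormal, log-logistic) to exact or
#' interval-censored data, via [survival::survreg()]. Exact data use columns
#' `time` (> 0) and `status` (1 event, 0 right-censored); interval data (as
#' produced by [km_pseudo_ipd()]) use columns `lower`, `upper` with
#' `upper = Inf` for right censoring.
#'
#' @param data A data frame as described above.
#' @param family One of `"exponential"`, `"weibull"`, `"lognormal"`,
#'   `"loglogistic"`.
#' @return An object of class `tdm_survfit`: a list with the family, natural
#'   parameters, location-scale coefficients, `log_likelihood`, `aic`,
#'   `bic`, the coefficient covariance (on the (location, log scale) scale)
#'   and the underlying `survreg` fit.
#' @export
fit_parametric <- function(data,
                           family = c("exponential", "weibull", "lognormal",
                                      "loglogistic")) {
  family <- match.arg(family)
  data <- as.data.frame(data)
  if (all(c("time", "status") %in% names(data))) {
    if (sum(data$status == 1) < 1) {
      abort("need at least one event", class = "tdm_fit_error")
    }
    srv <- survival::Surv(data$time, data$status)
    n <- nrow(data)
  } else if (all(c("lower", "upper") %in% names(data))) {
    ev <- is.finite(data$upper)
    if (sum(ev) < 1) abort("need at least one event", class = "tdm_fit_error")
    lo <- data$lower
    up <- data$upper
    up[!ev] <- NA # right-censored at lower
    lo[ev & lo <= 0] <- NA # first interval starts at 0: left-censored at upper
    srv <- survival::Surv(time = lo, time2 = up, type = "interval2")
    n <- nrow(data)
  } else {
    abort("data must have columns (time, status) or (lower, upper)",
          class = "tdm_validation_error")
  }
  fit <- tryCatch(
    suppressWarnings(survival::survreg(srv ~ 1, dist = family)),
    error = function(e) abort(paste0("fit failed (", family, "): ",
                                     conditionMessage(e)),
                              class = "tdm_fit_error")
  )
  ll <- fit$loglik[length(fit$loglik)]
  k <- sum(fit$df)
  if (!is.finite(ll)) abort("fit did not converge", class = "tdm_fit_error")
  mu <- unname(coef(fit)[1])
  scl <- fit$scale
  params <- switch(family,
    exponential = c(rate = exp(-mu)),
    weibull     = c(shape = 1 / scl, scale = exp(mu)),
    lognormal   = c(mu = mu, sigma = scl),
    loglogistic = c(alpha = exp(mu), beta = 1 / scl)
  )
  V <- vcov(fit)
  structure(list(
    family = family,
    params = params,
    coef = c(location = mu,
             log_scale = if (family == "exponential") 0 else log(scl)),
    log_likelihood = ll,
    aic = 2 * k - 2 * ll,
    bic = k * log(n) - 2 * ll,
    n_params = k,
    nobs = n,
    vcov = V,
    fit = fit
  ), class = "tdm_survfit")
}

#' @export
print.tdm_survfit <- function(x, ...) {
  cat("<tdm_survfit>", x$family, "\n")
  print(round(x$params, 5))
  cat(sprintf("  logLik %.3f  AIC %.3f  BIC %.3f  (n = %d)\n",
              x$log_likelihood, x$aic, x$bic, x$nobs))
  invisible(x)
}

#' @export
tidy.tdm_survfit <- function(x, ...) {
  se <- sqrt(diag(x$vcov))[seq_along(x$coef)]
  tibble(term = names(x$coef), estimate = unname(x$coef),
         std.error = unname(se))
}

#' @export
glance.tdm_survfit <- function(x, ...) {
  tibble(family = x$family, logLik = x$log_likelihood, AIC = x$aic,
         BIC = x$bic, df = x$n_params, nobs = x$nobs)
}

#' Select the best-fitting parametric family
#'
#' Minimum AIC, ties broken by minimum BIC, then by fewer parameters.
#'
#' @param fits A non-empty list of [fit_parametric()] results.
#' @return The selected `tdm_survfit`.
#' @export
select_best <- function(fits) {
  if (!length(fits)) abort("empty list of fits", class = "tdm_argument_error")
  aic <- vapply(fits, function(f) f$aic, numeric(1))
  bic <- vapply(fits, function(f) f$bic, numeric(1))
  k <- vapply(fits, function(f) f$n_params, numeric(1))
  fits[[order(aic, bic, k)[1]]]
}
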