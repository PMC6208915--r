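# Partitioned-survival cohort model: strategy construction, per-cycle
# traces, and economic summaries.
#
# State occupancy is read directly from the survival curves each cycle:
# OS(t) = S_bcmort(t) * S_bg(t) is identical for both strategies, DFS is a
# weighted mixture of subcohort curves depleted by background mortality and
# capped at OS within each subcohort, and RD = OS - DFS.

.make_grid <- function(p, lt) {
  n_cycles <- floor((p$horizon_age - p$start_age) * 365.25 / p$cycle_length)
  t_days <- (0:n_cycles) * p$cycle_length
  t_years <- t_days / 365.25
  bg <- surv_background(lt, p$start_age, t_years)
  t_mid <- (t_years[-1] + t_years[-length(t_years)]) / 2
  list(
    n_cycles = n_cycles,
    t_days = t_days,
    t_years = t_years,
    bg = bg,
    dt_years = p$cycle_length / 365.25,
    disc_cost = (1 + p$discount_rate_costs)^(-t_mid),
    disc_eff  = (1 + p$discount_rate_effects)^(-t_mid)
  )
}

# Shared engine behind run_trace(), the PSA and the DSA. `pv` is a plain
# list of parameter values (possibly one PSA draw layered over the
# structural settings). Returns either full per-cycle components or just
# discounted totals.
.trace_core <- function(pv, strategy, grid, totals_only = FALSE) {
  n <- grid$n_cycles
  t <- grid$t_years
  sig_d <- exp(pv$dfs_low_log_scale)
  s_low <- plnorm(t, pv$dfs_low_intercept, sig_d, lower.tail = FALSE)
  os <- plnorm(t, pv$bcmort_intercept, exp(pv$bcmort_log_scale),
               lower.tail = FALSE) * grid$bg
  dfs <- numeric(length(t))
  sc <- strategy$subcohorts
  for (j in seq_along(sc$weight)) {
    w <- sc$weight[j]
    if (w == 0) next
    s_j <- .hr_window_curve(t, s_low, pv$dfs_low_intercept, sig_d,
                            pv$hr_high_vs_low, sc$switch_time[j],
                            pv$treatment_duration)
    dfs <- dfs + w * pmin(s_j * grid$bg, os)
  }
  rd <- pmax(os - dfs, 0)
  dead <- 1 - os

  avg_dfs <- (dfs[-1] + dfs[-(n + 1)]) / 2
  avg_rd <- (rd[-1] + rd[-(n + 1)]) / 2
  new_deaths <- dead[-1] - dead[-(n + 1)]
  dt <- grid$dt_years
  cost_state <- (pv$cost_dfs_annual * avg_dfs + pv$cost_rd_annual * avg_rd) * dt
  qaly <- (pv$utility_dfs * avg_dfs + pv$utility_rd * avg_rd) * dt
  cost_death <- pv$cost_death_once * new_deaths
  cost_test <- numeric(n)
  ts <- strategy$test_schedule
  if (length(ts$time_days)) {
    if (max(ts$time_days) > grid$t_days[n + 1]) {
      abort("model horizon is shorter than the test schedule",
            class = "tdm_config_error")
    }
    for (j in seq_along(ts$time_days)) {
      k <- min(max(round(ts$time_days[j] / pv$cycle_length), 0), n - 1)
      cost_test[k + 1] <- cost_test[k + 1] +
        ts$fraction[j] * pv$cost_test * os[k + 1]
    }
  }
  disc_cost <- (cost_state + cost_death + cost_test) * grid$disc_cost
  disc_qaly <- qaly * grid$disc_eff
  if (totals_only) {
    return(c(cost = sum(disc_cost), qalys = sum(disc_qaly)))
  }
  list(dfs = dfs, rd = rd, dead = dead, new_deaths = new_deaths,
       cost_state = cost_state, cost_test = cost_test,
       cost_death = cost_death, qaly = qaly,
       disc_cost = disc_cost, disc_qaly = disc_qaly)
}

#' Build the comparator and intervention strategies
#'
#' The comparator ("no TDM") is a mixture of a high-exposure subcohort
#' (weight `p_high_start`, hazard-ratio-adjusted curve during treatment)
#' and a low-exposure subcohort, with no testing. Under monitoring ("TDM")
#' every patient is tested at `first_test_time`; low patients (fraction
#' `1 - p_high_start`) have the tamoxifen dose doubled and are retested at
#' `second_test_time`. `p_high_after_escalation` is the share of the whole
#' cohort with adequate levels once escalation is complete, so the
#' subcohort that converts to the high-exposure hazard has weight
#' `p_high_after_escalation - p_high_start` (floored at zero: reverting to
#' low exposure is modelled as impossible) and the remainder stays low
#' forever.
#'
#' @param p A [tdm_parameters()] object.
#' @return A named list with `tdm_strategy` objects `no_tdm` and `tdm`.
#' @export
build_strategies <- function(p) {
  validate_parameters(p)
  light <- .strategies_light(p)
  wrap <- function(name, tdm_enabled, s, labels) {
    stopifnot(abs(sum(s$subcohorts$weight) - 1) < 1e-9,
              all(s$subcohorts$weight >= 0),
              all(s$test_schedule$fraction >= 0 & s$test_schedule$fraction <= 1))
    structure(list(name = name, tdm_enabled = tdm_enabled,
                   subcohorts = tibble(label = labels,
                                       weight = s$subcohorts$weight,
                                       switch_time = s$subcohorts$switch_time),
                   test_schedule = tibble(time_days = s$test_schedule$time_days,
                                          fraction = s$test_schedule$fraction)),
              class = "tdm_strategy")
  }
  list(
    no_tdm = wrap("no_tdm", FALSE, light$no_tdm,
                  c("high_from_start", "low_forever")),
    tdm = wrap("tdm", TRUE, light$tdm,
               c("high_from_start", "low_then_high", "low_forever"))
  )
}

# Minimal strategy structures (plain lists) shared by build_strategies()
# and the per-trial PSA loop.
.strategies_light <- function(pv) {
  ph <- pv$p_high_start
  q <- pv$p_high_after_escalation
  st_years <- (if (isTRUE(pv$benefit_at_first_test)) pv$first_test_time
               else pv$second_test_time) / 365.25
  # q is the share of ALL patients with adequate levels once the escalation
  # phase is over, so the converting subcohort has weight q - ph (never
  # negative: reverting to low exposure is modelled as impossible).
  w_convert <- max(q - ph, 0)
  list(
    no_tdm = list(
      subcohorts = list(weight = c(ph, 1 - ph), switch_time = c(0, Inf)),
      test_schedule = list(time_days = numeric(), fraction = numeric())
    ),
    tdm = list(
      subcohorts = list(weight = c(ph, w_convert, 1 - ph - w_convert),
                        switch_time = c(0, st_years, Inf)),
      test_schedule = list(time_days = c(pv$first_test_time,
                                         pv$second_test_time),
                           fraction = c(1, 1 - ph))
    )
  )
}

#' @export
print.tdm_strategy <- function(x, ...) {
  cat("<tdm_strategy>", x$name, if (x$tdm_enabled) "(monitoring)" else "", "\n")
  print(x$subcohorts)
  if (nrow(x$test_schedule)) print(x$test_schedule)
  invisible(x)
}

#' Run the cohort trace for one strategy
#'
#' Evaluates state occupancy at every 28-day cycle boundary and accrues
#' costs and QALYs with trapezoidal (half-cycle-corrected) occupancy,
#' prorating annual state costs and utilities by the cycle length. The
#' one-off death cost applies to the deaths of each cycle; testing costs
#' apply at their scheduled cycle to the fraction of the cohort tested and
#' still alive. Discounting uses the cycle midpoint at the cost and effect
#' rates respectively.
#'
#' @param p A [tdm_parameters()] object.
#' @param strategy A `tdm_strategy` from [build_strategies()].
#' @param lt A life table covering `[start_age, horizon_age]`.
#' @return A tibble of class `tdm_trace`, one row per cycle boundary:
#'   occupancy (`dfs`, `rd`, `dead`) at the boundary and the accruals of the
#'   cycle that starts there (`new_deaths`, `cost_state`, `cost_test`,
#'   `cost_death`, `qaly`, `disc_cost`, `disc_qaly`; zero on the final row).
#' @export
run_trace <- function(p, strategy, lt) {
  validate_parameters(p)
  stopifnot(inherits(strategy, "tdm_strategy"))
  grid <- .make_grid(p, lt)
  comp <- .trace_core(p, strategy, grid)
  n <- grid$n_cycles
  pad <- function(x) c(x, 0)
  out <- tibble(
    cycle = 0:n,
    time_days = grid$t_days,
    dfs = comp$dfs, rd = comp$rd, dead = comp$dead,
    new_deaths = pad(comp$new_deaths),
    cost_state = pad(comp$cost_state),
    cost_test = pad(comp$cost_test),
    cost_death = pad(comp$cost_death),
    qaly = pad(comp$qaly),
    disc_cost = pad(comp$disc_cost),
    disc_qaly = pad(comp$disc_qaly)
  )
  class(out) <- c("tdm_trace", class(out))
  attr(out, "strategy") <- strategy$name
  out
}

#' Write a cohort trace to CSV
#' @param trace A `tdm_trace`.
#' @param path Output path.
#' @export
write_trace <- function(trace, path) {
  cols <- c("time_days", "dfs", "rd", "dead", "cost_state", "cost_test",
            "cost_death", "qaly", "disc_cost", "disc_qaly")
  write.csv(as.data.frame(trace)[cols], path, row.names = FALSE)
  invisible(path)
}

#' Total (discounted) costs and QALYs of a trace
#'
#' @param trace A `tdm_trace`.
#' @return A one-row tibble: `strategy`, `total_cost`, `total_qalys`
#'   (discounted) and their undiscounted counterparts.
#' @export
summarize_trace <- function(trace) {
  tibble(
    strategy = attr(trace, "strategy") %||% NA_character_,
    total_cost = sum(trace$disc_cost),
    total_qalys = sum(trace$disc_qaly),
    undisc_cost = sum(trace$cost_state + trace$cost_test + trace$cost_death),
    undisc_qalys = sum(trace$qaly)
  )
}

#' Incremental comparison of two strategy summaries
#'
#' `delta = intervention - comparator`; the ICER is `delta_cost /
#' delta_qalys` (undefined, `NA`, when `delta_qalys` is zero) and the net
#' monetary benefit is `wtp * delta_qalys - delta_cost`.
#'
#' @param intervention,comparator One-row tibbles from [summarize_trace()].
#' @param wtp Willingness to pay, EUR per QALY.
#' @return A one-row tibble with `delta_cost`, `delta_qalys`, `icer`,
#'   `dominance` ("dominant" if cheaper and more effective, "dominated" for
#'   the reverse, "undefined" when `delta_qalys = 0`, otherwise "tradeoff"),
#'   `wtp` and `nmb`.
#' @export
compare_strategies <- function(intervention, comparator, wtp = 20000) {
  dc <- intervention$total_cost - comparator$total_cost
  de <- intervention$total_qalys - comparator$total_qalys
  icer <- if (de == 0) NA_real_ else dc / de
  dominance <- if (de == 0) {
    "undefined"
  } else if (de > 0 && dc < 0) {
    "dominant"
  } else if (de < 0 && dc > 0) {
    "dominated"
  } else {
    "tradeoff"
  }
  tibble(delta_cost = dc, delta_qalys = de, icer = icer,
         dominance = dominance, wtp = wtp, nmb = wtp * de - dc)
}

#' Base-case analysis: both strategies, summaries and increments
#'
#' @param p A [tdm_parameters()] object.
#' @param lt A life table (default: the bundled synthetic Dutch-female
#'   stand-in from [synthetic_dutch_life_table()]).
#' @param wtp Willingness to pay, EUR per QALY.
#' @return A list of class `tdm_basecase`: `traces` (named list),
#'   `summaries` (two-row tibble) and `comparison` (one-row tibble,
#'   TDM versus no TDM).
#' @export
run_base_case <- function(p = tdm_parameters(),
                          lt = synthetic_dutch_life_table(), wtp = 20000) {
  strategies <- build_strategies(p)
  traces <- lapply(strategies, function(s) run_trace(p, s, lt))
  summaries <- bind_rows(lapply(traces, summarize_trace))
  comparison <- compare_strategies(summaries[summaries$strategy == "tdm", ],
                                   summaries[summaries$strategy == "no_tdm", ],
                                   wtp = wtp)
  structure(list(traces = traces, summaries = summaries,
                 comparison = comparison),
            class = "tdm_basecase")
}

#' @export
print.tdm_basecase <- function(x, ...) {
  cat("<tdm_basecase>\n")
  print(x$summaries)
  cat("\nTDM vs no TDM:\n")
  print(x$comparison)
  invisible(x)
}
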