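# Sensitivity analysis: one-way deterministic ranges (tornado) and
# probabilistic analysis (CE plane, CEAC, net monetary benefit).

#' One-way deterministic sensitivity analysis
#'
#' Re-evaluates the incremental comparison (TDM versus no TDM) with each
#' uncertain parameter set to its published low and high endpoint in turn,
#' all others held at base. Entries are sorted by the incremental-cost swing
#' `|delta_cost(high) - delta_cost(low)|`.
#'
#' @param p A [tdm_parameters()] object (base values).
#' @param lt A life table.
#' @param dists Distribution/range table from [parameter_distributions()].
#' @param wtp Willingness to pay for the net-monetary-benefit column.
#' @return A tibble of class `tdm_dsa`: `parameter`, `direction`, `value`,
#'   `delta_cost`, `delta_qalys`, `icer` (`NA` when `delta_qalys` is zero),
#'   `nmb`, `swing`.
#' @export
run_dsa <- function(p = tdm_parameters(), lt = synthetic_dutch_life_table(),
                    dists = parameter_distributions(p), wtp = 20000) {
  grid <- .make_grid(p, lt)
  eval_at <- function(name, value) {
    pv <- unclass(p)
    pv[[name]] <- value
    validate_parameters(pv)
    s <- .strategies_light(pv)
    tot_ref <- .trace_core(pv, s$no_tdm, grid, totals_only = TRUE)
    tot_int <- .trace_core(pv, s$tdm, grid, totals_only = TRUE)
    dc <- tot_int[["cost"]] - tot_ref[["cost"]]
    de <- tot_int[["qalys"]] - tot_ref[["qalys"]]
    tibble(parameter = name, value = value, delta_cost = dc,
           delta_qalys = de, icer = ifelse(de == 0, NA_real_, dc / de),
           nmb = wtp * de - dc)
  }
  rows <- purrr::map2(
    rep(dists$name, each = 2),
    as.vector(rbind(dists$low, dists$high)),
    eval_at
  )
  out <- bind_rows(rows)
  out$direction <- rep(c("low", "high"), nrow(dists))
  out <- out |>
    group_by(.data$parameter) |>
    mutate(swing = abs(diff(.data$delta_cost))) |>
    ungroup() |>
    arrange(dplyr::desc(.data$swing), .data$parameter, .data$direction) |>
    select("parameter", "direction", "value", "delta_cost", "delta_qalys",
           "icer", "nmb", "swing")
  class(out) <- c("tdm_dsa", class(out))
  out
}

#' Sample parameter sets for probabilistic sensitivity analysis
#'
#' Draws `n` parameter sets: beta proportions and utilities, gamma costs,
#' the hazard ratio as exp of a normal on the log scale, and the two
#' (intercept, log-scale) survival pairs jointly normal via the Cholesky
#' factor of their covariance (standard errors back-computed from the
#' published ranges as `(high - low)/3.92`; correlation configurable,
#' independent by default). Hazard-ratio draws are clipped at 1.00 and
#' recurrent-disease utility draws at the paired disease-free utility draw;
#' the resulting point masses are the "no benefit demonstrated" scenarios.
#'
#' @param p A [tdm_parameters()] object (structural settings and bases).
#' @param n Number of trials (`>= 1`).
#' @param seed Integer seed; draws are reproducible given the seed.
#' @param dists Distribution table from [parameter_distributions()].
#' @param survival_correlation Either a correlation scalar applied within
#'   each (intercept, log-scale) pair, or a named list of 2x2 covariance
#'   matrices (names `"dfs"`, `"bcmort"`) replacing the default.
#' @return A tibble of class `tdm_psa_draws` with one row per trial, one
#'   column per sampled parameter, and logical columns `hr_clipped` and
#'   `utility_rd_clipped`.
#' @export
sample_psa <- function(p = tdm_parameters(), n = 10000, seed = 1,
                       dists = parameter_distributions(p),
                       survival_correlation = 0) {
  if (n < 1) abort("n must be >= 1", class = "tdm_argument_error")
  draws <- withr::with_seed(as.integer(seed), {
    out <- list()
    for (i in seq_len(nrow(dists))) {
      d <- dists[i, ]
      out[[d$name]] <- switch(d$family,
        beta = rbeta(n, d$par1, d$par2),
        gamma = rgamma(n, shape = d$par1, scale = d$par2),
        normal_on_log = exp(rnorm(n, d$par1, d$par2)),
        correlated_lognormal_pair = rnorm(n) # standard normal, correlated below
      )
    }
    out
  })
  for (pair in unique(stats::na.omit(dists$pair))) {
    rows <- dists[!is.na(dists$pair) & dists$pair == pair, ]
    stopifnot(nrow(rows) == 2)
    if (is.matrix(survival_correlation) || is.list(survival_correlation)) {
      Sigma <- if (is.list(survival_correlation)) {
        survival_correlation[[pair]]
      } else {
        survival_correlation
      }
      if (is.null(Sigma)) Sigma <- diag(rows$par2^2)
    } else {
      rho <- survival_correlation
      Sigma <- diag(rows$par2) %*% matrix(c(1, rho, rho, 1), 2) %*%
        diag(rows$par2)
    }
    U <- tryCatch(chol(Sigma), error = function(e) {
      abort("survival covariance matrix is not positive definite",
            class = "tdm_argument_error")
    })
    z <- cbind(draws[[rows$name[1]]], draws[[rows$name[2]]]) %*% U
    draws[[rows$name[1]]] <- rows$par1[1] + z[, 1]
    draws[[rows$name[2]]] <- rows$par1[2] + z[, 2]
  }
  hr_clipped <- draws$hr_high_vs_low > 1
  draws$hr_high_vs_low <- pmin(draws$hr_high_vs_low, 1)
  urd_clipped <- draws$utility_rd > draws$utility_dfs
  draws$utility_rd <- pmin(draws$utility_rd, draws$utility_dfs)
  # trials where the drawn post-escalation share does not exceed the
  # starting share leave nobody to convert (no-benefit scenarios)
  conv_clipped <- draws$p_high_after_escalation <= draws$p_high_start
  out <- as_tibble(c(list(trial = seq_len(n)), draws,
                     list(hr_clipped = hr_clipped,
                          utility_rd_clipped = urd_clipped,
                          conversion_clipped = conv_clipped)))
  class(out) <- c("tdm_psa_draws", class(out))
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Run the probabilistic sensitivity analysis
#'
#' Evaluates both strategies on every drawn parameter set (identical draws
#' for both arms of a trial) and summarises the incremental cloud: the
#' cost-effectiveness acceptability curve `CEAC(wtp) = P(wtp * dQALY -
#' dCost > 0)` and the mean and 2.5/97.5 percentiles of the net monetary
#' benefit at each willingness-to-pay value.
#'
#' @param p A [tdm_parameters()] object (structural settings).
#' @param draws A `tdm_psa_draws` tibble from [sample_psa()].
#' @param lt A life table.
#' @param wtp_grid Non-empty vector of non-negative WTP values (EUR/QALY).
#' @return A list of class `tdm_psa`: `trials` (tibble with `trial`,
#'   `delta_cost`, `delta_qalys`), `ceac`, `nmb`, the `draws`, `wtp_grid`
#'   and `n_trials`.
#' @export
run_psa <- function(p = tdm_parameters(), draws, lt = synthetic_dutch_life_table(),
                    wtp_grid = c(0, 20000, 80000)) {
  if (!length(wtp_grid) || any(wtp_grid < 0)) {
    abort("wtp_grid must be non-empty and non-negative",
          class = "tdm_argument_error")
  }
  grid <- .make_grid(p, lt)
  sampled <- setdiff(names(draws), c("trial", "hr_clipped",
                                     "utility_rd_clipped", "conversion_clipped"))
  n <- nrow(draws)
  dc <- de <- numeric(n)
  base <- unclass(p)
  dm <- as.data.frame(draws[sampled])
  for (i in seq_len(n)) {
    pv <- base
    pv[sampled] <- dm[i, ]
    res <- tryCatch({
      s <- .strategies_light(pv)
      tot_ref <- .trace_core(pv, s$no_tdm, grid, totals_only = TRUE)
      tot_int <- .trace_core(pv, s$tdm, grid, totals_only = TRUE)
      c(tot_int[["cost"]] - tot_ref[["cost"]],
        tot_int[["qalys"]] - tot_ref[["qalys"]])
    }, error = function(e) {
      abort(paste0("PSA trial ", i, " failed: ", conditionMessage(e)),
            class = "tdm_psa_error")
    })
    dc[i] <- res[1]
    de[i] <- res[2]
  }
  nmb_mat <- outer(de, wtp_grid) - dc
  ceac <- tibble(wtp = wtp_grid,
                 probability = colMeans(nmb_mat > 0))
  nmb <- tibble(
    wtp = wtp_grid,
    mean = colMeans(nmb_mat),
    conf.low = apply(nmb_mat, 2, quantile, probs = 0.025, names = FALSE),
    conf.high = apply(nmb_mat, 2, quantile, probs = 0.975, names = FALSE)
  )
  structure(list(
    trials = tibble(trial = draws$trial, delta_cost = dc, delta_qalys = de),
    ceac = ceac,
    nmb = nmb,
    draws = draws,
    wtp_grid = wtp_grid,
    n_trials = n
  ), class = "tdm_psa")
}

#' @export
print.tdm_psa <- function(x, ...) {
  cat("<tdm_psa>", x$n_trials, "trials\n")
  cat(sprintf("  mean dCost %.1f EUR, mean dQALY %.5f\n",
              mean(x$trials$delta_cost), mean(x$trials$delta_qalys)))
  print(x$ceac)
  invisible(x)
}

#' @export
tidy.tdm_psa <- function(x, ...) x$trials

#' @export
glance.tdm_psa <- function(x, ...) {
  tibble(
    n_trials = x$n_trials,
    mean_delta_cost = mean(x$trials$delta_cost),
    mean_delta_qalys = mean(x$trials$delta_qalys),
    prob_cost_saving = mean(x$trials$delta_cost < 0),
    prob_no_benefit = mean(x$trials$delta_qalys == 0)
  )
}
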