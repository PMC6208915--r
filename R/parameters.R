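# Model inputs: point estimates, deterministic ranges and sampling
# distributions for the endoxifen-TDM cost-effectiveness model.

# Published point estimates and structural defaults. Survival intercepts and
# log(scale)s are on the log-year scale of an accelerated-failure-time
# lognormal; costs are euros; utilities are per year of state occupancy.
.tdm_defaults <- list(
  start_age                = 53,      # years at model entry
  cycle_length             = 28,      # days per model cycle
  horizon_age              = 100,     # effectively lifetime horizon
  discount_rate_costs      = 0.04,    # annual, Dutch guideline
  discount_rate_effects    = 0.015,   # annual
  dfs_low_intercept        = 3.28,    # lognormal mu, DFS with low endoxifen
  dfs_low_log_scale        = 0.61,    # log(sigma) of that curve
  hr_high_vs_low           = 0.74,    # recurrence hazard ratio, high vs low
  treatment_duration       = 5,       # years of adjuvant tamoxifen over which
                                      # the hazard ratio acts (Inf = lifelong)
  bcmort_intercept         = 3.71,    # lognormal mu, breast-cancer mortality
  bcmort_log_scale         = 0.40,
  p_high_start             = 0.76,    # share adequate at the first test
  p_high_after_escalation  = 0.94,    # share of the whole cohort adequate
                                      # once dose escalation is complete
  cost_dfs_annual          = 2872,    # EUR/year in DFS
  cost_rd_annual           = 16125,   # EUR/year in RD
  cost_death_once          = 8296,    # one-off end-of-life cost, EUR
  cost_test                = 113,     # EUR per serum endoxifen test
  utility_dfs              = 0.80,
  utility_rd               = 0.73,
  first_test_time          = 91,      # days; ~3 months after start
  second_test_time         = 182,     # days; retest ~3 months after escalation
  endoxifen_threshold      = 5.97,    # ng/mL, low/high cut-off
  benefit_at_first_test    = FALSE    # escalated patients adopt the high-level
                                      # hazard at the confirmatory (second) test
                                      # by default; TRUE moves it to the first
)

#' Model parameters for the endoxifen monitoring model
#'
#' Builds the full set of model inputs. Defaults are the published Dutch
#' base-case values: a cohort entering at age 53, 28-day cycles to age 100,
#' lognormal disease-free-survival and breast-cancer-mortality curves, the
#' recurrence hazard ratio 0.74 for adequate (>= 5.97 ng/mL) versus low
#' endoxifen exposure, the proportions reaching adequate levels at the first
#' test (76%) and after dose escalation (94%), Dutch state costs and
#' utilities, and annual discount rates of 4% (costs) and 1.5% (effects).
#'
#' @param ... Named overrides of any default, e.g. `hr_high_vs_low = 1`.
#'   Unknown names are rejected.
#' @return A named list of class `tdm_parameters`.
#' @examples
#' p <- tdm_parameters()
#' p$start_age
#' tdm_parameters(p_high_after_escalation = 0.664)$p_high_after_escalation
#' @export
tdm_parameters <- function(...) {
  overrides <- list(...)
  if (length(overrides) == 1L && is.null(names(overrides)) &&
      is.list(overrides[[1L]])) {
    overrides <- overrides[[1L]]
  }
  if (length(overrides) && (is.null(names(overrides)) ||
                            any(!nzchar(names(overrides))))) {
    abort("all parameter overrides must be named", class = "tdm_config_error")
  }
  unknown <- setdiff(names(overrides), names(.tdm_defaults))
  if (length(unknown)) {
    abort(paste0("unknown configuration key(s): ",
                 paste(unknown, collapse = ", ")),
          class = "tdm_config_error")
  }
  p <- utils::modifyList(.tdm_defaults, overrides)
  p <- p[names(.tdm_defaults)]
  validate_parameters(p)
  structure(p, class = c("tdm_parameters", "list"))
}

#' Validate a parameter set
#'
#' Checks the type invariants: proportions and utilities in \[0, 1\], costs
#' non-negative, positive cycle length, horizon beyond the start age, and
#' `utility_rd <= utility_dfs` (recurrent disease cannot carry more quality
#' of life than disease-free survival, mirroring the constraint imposed in
#' probabilistic analysis).
#'
#' @param p A list of parameter values.
#' @return `p`, invisibly, if valid; otherwise an error naming the field.
#' @export
validate_parameters <- function(p) {
  bad <- function(field, why) {
    abort(paste0("invalid parameter `", field, "`: ", why),
          class = "tdm_validation_error")
  }
  num1 <- function(field) {
    v <- p[[field]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      bad(field, "must be a single finite number")
    }
    v
  }
  for (f in c("p_high_start", "p_high_after_escalation",
              "utility_dfs", "utility_rd")) {
    v <- num1(f)
    if (v < 0 || v > 1) bad(f, "must lie in [0, 1]")
  }
  for (f in c("cost_dfs_annual", "cost_rd_annual", "cost_death_once",
              "cost_test")) {
    if (num1(f) < 0) bad(f, "costs must be >= 0")
  }
  if (num1("cycle_length") <= 0) bad("cycle_length", "must be > 0")
  if (num1("horizon_age") < num1("start_age")) {
    bad("horizon_age", "must be >= start_age")
  }
  if (num1("hr_high_vs_low") <= 0) bad("hr_high_vs_low", "must be > 0")
  td <- p$treatment_duration
  if (!is.numeric(td) || length(td) != 1L || is.na(td) || td <= 0) {
    bad("treatment_duration", "must be > 0 (Inf allowed)")
  }
  if (num1("endoxifen_threshold") < 0) bad("endoxifen_threshold", "must be >= 0")
  if (exp(num1("dfs_low_log_scale")) <= 0) bad("dfs_low_log_scale", "must be finite")
  for (f in c("discount_rate_costs", "discount_rate_effects")) {
    if (num1(f) < 0) bad(f, "must be >= 0")
  }
  for (f in c("first_test_time", "second_test_time")) {
    if (num1(f) < 0) bad(f, "must be >= 0")
  }
  if (p$utility_rd > p$utility_dfs) {
    bad("utility_rd", "must not exceed utility_dfs")
  }
  if (!is.logical(p$benefit_at_first_test) || length(p$benefit_at_first_test) != 1L) {
    bad("benefit_at_first_test", "must be a single logical")
  }
  invisible(p)
}

#' Load parameters (and their distributions) from a configuration file
#'
#' Reads a flat key-value YAML or JSON document whose keys are parameter
#' names; absent keys take the published defaults. An empty `config_source`
#' (`NULL`) returns the full default set.
#'
#' @param config_source Path to a `.yml`/`.yaml`/`.json` file, or `NULL`.
#' @return A list with elements `parameters` (a [tdm_parameters()] object)
#'   and `distributions` (the tibble from [parameter_distributions()]).
#' @export
load_parameters <- function(config_source = NULL) {
  if (is.null(config_source)) {
    p <- tdm_parameters()
  } else {
    if (!file.exists(config_source)) {
      abort(paste0("configuration file not found: ", config_source),
            class = "tdm_config_error")
    }
    cfg <- if (grepl("\\.json$", config_source, ignore.case = TRUE)) {
      jsonlite::read_json(config_source, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config_source)
    }
    if (is.null(cfg)) cfg <- list()
    p <- tdm_parameters(as.list(cfg))
  }
  list(parameters = p, distributions = parameter_distributions(p))
}

#' Write parameters to a YAML configuration file
#'
#' The written file round-trips through [load_parameters()] to identical
#' values.
#'
#' @param p A [tdm_parameters()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(p, path) {
  validate_parameters(p)
  yaml::write_yaml(unclass(p), path, precision = 15L)
  invisible(path)
}

#' Sampling distributions and deterministic ranges for every uncertain input
#'
#' One row per uncertain parameter, mirroring the published table: the two
#' correlated (intercept, log-scale) survival pairs, the hazard ratio
#' (normal on the log scale, mean -0.301, SE 0.153), two beta proportions,
#' four gamma costs and two beta utilities. `low`/`high` are the one-way
#' deterministic-sensitivity endpoints; `par1`/`par2` are the family-specific
#' sampling parameters (beta: alpha, beta; gamma: shape, scale; normal on
#' log: mean, SE; survival pairs: mean, SE with SE back-computed from the
#' published range as (high - low)/3.92).
#'
#' @param p A [tdm_parameters()] object supplying the base values.
#' @return A tibble with columns `name`, `family`, `par1`, `par2`, `low`,
#'   `high`, `base`, `pair`, `role`.
#' @export
parameter_distributions <- function(p = tdm_parameters()) {
  validate_parameters(p)
  d <- tibble::tribble(
    ~name,                     ~family,                     ~par1,   ~par2,  ~low,  ~high, ~pair,     ~role,
    "dfs_low_intercept",       "correlated_lognormal_pair", NA,      (3.37 - 3.20) / 3.92, 3.20, 3.37, "dfs",    "intercept",
    "dfs_low_log_scale",       "correlated_lognormal_pair", NA,      (0.64 - 0.57) / 3.92, 0.57, 0.64, "dfs",    "log_scale",
    "hr_high_vs_low",          "normal_on_log",             -0.301,  0.153,  0.55,  1.00,  NA,        NA,
    "bcmort_intercept",        "correlated_lognormal_pair", NA,      (3.76 - 3.66) / 3.92, 3.66, 3.76, "bcmort", "intercept",
    "bcmort_log_scale",        "correlated_lognormal_pair", NA,      (0.42 - 0.37) / 3.92, 0.37, 0.42, "bcmort", "log_scale",
    "p_high_start",            "beta",                      14.8,    4.7,    0.57,  0.94,  NA,        NA,
    "p_high_after_escalation", "beta",                      13.2,    0.8,    0.76,  1.00,  NA,        NA,
    "cost_dfs_annual",         "gamma",                     26.0,    110.4,  1769,  3975,  NA,        NA,
    "cost_rd_annual",          "gamma",                     26.5,    609.5,  9980,  22270, NA,        NA,
    "cost_death_once",         "gamma",                     61.5,    135.0,  6222,  10370, NA,        NA,
    "cost_test",               "gamma",                     61.5,    1.8,    85,    141,   NA,        NA,
    "utility_dfs",             "beta",                      99.55,   24.89,  0.73,  0.87,  NA,        NA,
    "utility_rd",              "beta",                      112.07,  41.45,  0.66,  0.80,  NA,        NA
  )
  d$base <- vapply(d$name, function(nm) p[[nm]], numeric(1))
  # survival pair draws are centred on the current base value
  d$par1[d$family == "correlated_lognormal_pair"] <-
    d$base[d$family == "correlated_lognormal_pair"]
  # deterministic endpoints always bracket the (possibly overridden) base
  d$low <- pmin(d$low, d$base)
  d$high <- pmax(d$high, d$base)
  d
}

#' Analytic mean of a sampling distribution
#'
#' beta(alpha, beta) -> alpha/(alpha + beta); gamma(shape, scale) ->
#' shape * scale; normal on the log scale -> the median exp(mean). Used to
#' check the internal consistency of the published table (each analytic mean
#' should reproduce the printed base value).
#'
#' @param dist One or more rows of [parameter_distributions()].
#' @return A numeric vector, one mean per row.
#' @export
distribution_mean <- function(dist) {
  stopifnot(is.data.frame(dist), all(c("family", "par1", "par2") %in% names(dist)))
  supported <- c("beta", "gamma", "normal_on_log")
  if (any(!dist$family %in% supported)) {
    abort(paste0("unsupported distribution family: ",
                 paste(unique(setdiff(dist$family, supported)), collapse = ", ")),
          class = "tdm_family_error")
  }
  ifelse(dist$family == "beta", dist$par1 / (dist$par1 + dist$par2),
    ifelse(dist$family == "gamma", dist$par1 * dist$par2, exp(dist$par1))
  )
}

#' @export
print.tdm_parameters <- function(x, ...) {
  cat("<tdm_parameters>\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
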