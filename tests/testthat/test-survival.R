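test_that("lognormal survivor function matches its closed form", {
  expect_equal(surv_lognormal(0, 3.28, exp(0.61)), 1)
  expect_equal(surv_lognormal(exp(3.28), 3.28, exp(0.61)), 0.5)
  # frozen from an independent erfc-based evaluation of Phi
  expect_equal(surv_lognormal(15, 3.28, exp(0.61)), 0.6220120408,
               tolerance = 1e-9)
  grid <- seq(0.01, 80, length.out = 400)
  s <- surv_lognormal(grid, 3.28, exp(0.61))
  expect_true(all(diff(s) < 0))
  expect_true(all(s >= 0 & s <= 1))
  expect_error(surv_lognormal(-1, 3.28, 1), class = "tdm_domain_error")
  expect_error(surv_lognormal(1, 3.28, 0), class = "tdm_domain_error")
})

test_that("hazard-ratio transform is s^hr and monotone in hr", {
  expect_equal(apply_hazard_ratio(0.5, 1), 0.5)
  expect_equal(apply_hazard_ratio(1, 0.3), 1)
  expect_equal(apply_hazard_ratio(0.5, 0.74), 0.5987393523, tolerance = 1e-9)
  s <- 0.37
  hrs <- seq(0.2, 2, by = 0.2)
  expect_true(all(diff(apply_hazard_ratio(s, hrs)) < 0))
  expect_true(all(apply_hazard_ratio(c(0.2, 0.9), 0.74) >= c(0.2, 0.9)))
  expect_error(apply_hazard_ratio(0.5, 0), class = "tdm_domain_error")
  expect_error(apply_hazard_ratio(0, 0.74), class = "tdm_domain_error")
})

test_that("background survival multiplies annual probabilities with fractional-year hazards", {
  lt <- flat_lt(0.1)
  expect_equal(surv_background(lt, 53, 0), 1)
  expect_equal(surv_background(lt, 53, 2), 0.81)
  expect_equal(surv_background(lt, 53, 1.5), 0.9^1.5, tolerance = 1e-12)
  expect_equal(surv_background(immortal_lt, 53, c(0, 10, 40)), c(1, 1, 1))
  expect_error(surv_background(lt, 300, 1), class = "tdm_coverage_error")
  expect_error(surv_background(lt, 53, 100), class = "tdm_coverage_error")
})

test_that("overall survival is the product of disease and background survival", {
  t <- c(0, 1, 5, 15, 30)
  lt <- flat_lt(0.02)
  expect_equal(surv_overall(t, 3.71, exp(0.40), lt, 53),
               surv_lognormal(t, 3.71, exp(0.40)) * surv_background(lt, 53, t))
  expect_equal(surv_overall(t, 3.71, exp(0.40), immortal_lt, 53),
               surv_lognormal(t, 3.71, exp(0.40)))
  expect_true(all(surv_overall(t, 3.71, exp(0.40), lt, 53) <=
                    pmin(surv_lognormal(t, 3.71, exp(0.40)),
                         surv_background(lt, 53, t)) + 1e-15))
})

test_that("switched survivor function is continuous and hits its limiting cases", {
  t <- seq(0, 40, by = 0.25)
  mu <- 3.28; sigma <- exp(0.61); hr <- 0.74
  expect_equal(surv_switched(t, mu, sigma, hr, 0),
               surv_lognormal(t, mu, sigma)^hr)
  expect_equal(surv_switched(t, mu, sigma, hr, Inf),
               surv_lognormal(t, mu, sigma))
  st <- 0.25
  eps <- 1e-9
  s_at <- surv_switched(st, mu, sigma, hr, st)
  expect_equal(s_at, surv_lognormal(st, mu, sigma))
  expect_equal(surv_switched(st + eps, mu, sigma, hr, st), s_at,
               tolerance = 1e-6)
  # switching after the hazard-ratio window ends has no effect
  expect_equal(surv_switched(t, mu, sigma, hr, 6, hr_duration = 5),
               surv_lognormal(t, mu, sigma))
  # once treatment ends the advantage is a constant survival ratio
  s_win <- surv_switched(t, mu, sigma, hr, st, hr_duration = 5)
  late <- t > 5
  ratio <- s_win[late] / surv_lognormal(t[late], mu, sigma)
  expect_true(all(abs(ratio - ratio[1]) < 1e-12))
  expect_true(all(ratio > 1))
})

test_that("event counts are reconstructed from published KM summaries", {
  km <- tibble::tibble(time_years = c(0, 1, 2), survival = c(1, 0.9, 0.8),
                       n_risk = c(100, 90, 80))
  rec <- km_reconstruct(km)
  expect_equal(rec$events, c(10L, 10L))
  expect_equal(rec$censored, c(0L, 0L))
  flat <- tibble::tibble(time_years = c(0, 1, 2), survival = c(1, 1, 1),
                         n_risk = c(100, 60, 30))
  rec2 <- km_reconstruct(flat)
  expect_equal(rec2$events, c(0L, 0L))
  expect_equal(rec2$censored, c(40L, 30L))
  bad <- tibble::tibble(time_years = c(0, 1), survival = c(1, 1.1),
                        n_risk = c(100, 90))
  expect_error(km_reconstruct(bad), class = "tdm_data_error")
  inconsistent <- tibble::tibble(time_years = c(0, 1), survival = c(1, 0.5),
                                 n_risk = c(100, 100))
  expect_error(km_reconstruct(inconsistent), "negative",
               class = "tdm_data_error")
})

test_that("reconstructed counts reproduce the KM curve within one patient", {
  set.seed(42)
  for (rep in 1:5) {
    n0 <- 400
    ev <- rlnorm(n0, 2.2, 0.9)
    cs <- runif(n0, 2, 25)
    time <- pmin(ev, cs)
    status <- as.integer(ev <= cs)
    bounds <- seq(0, 20, by = 2)
    km_fit <- survival::survfit(survival::Surv(time, status) ~ 1)
    sm <- summary(km_fit, times = bounds, extend = TRUE)
    km <- tibble::tibble(time_years = bounds, survival = sm$surv,
                         n_risk = sm$n.risk)
    rec <- km_reconstruct(km)
    s_hat <- cumprod(1 - rec$events / rec$n_risk)
    expect_true(all(abs(s_hat - km$survival[-1]) <= 1 / rec$n_risk + 1e-12))
    # pseudo-IPD accounts for every initial patient
    ipd <- km_pseudo_ipd(rec)
    expect_equal(nrow(ipd), km$n_risk[1])
  }
})

test_that("maximum-likelihood fits recover simulated parameters", {
  set.seed(7)
  x <- rlnorm(5000, 3.28, exp(0.61))
  dat <- tibble::tibble(time = x, status = 1L)
  fit <- fit_parametric(dat, "lognormal")
  td <- tidy(fit)
  mu_hat <- td$estimate[td$term == "location"]
  ls_hat <- td$estimate[td$term == "log_scale"]
  expect_lt(abs(mu_hat - 3.28), 3 * td$std.error[td$term == "location"])
  expect_lt(abs(ls_hat - 0.61), 3 * td$std.error[td$term == "log_scale"])
  expect_equal(fit$aic, 2 * 2 - 2 * fit$log_likelihood)

  # exponential closed form: rate = 1 / mean event time
  set.seed(8)
  y <- rexp(2000, rate = 0.3)
  efit <- fit_parametric(tibble::tibble(time = y, status = 1L), "exponential")
  expect_equal(unname(efit$params["rate"]), 1 / mean(y), tolerance = 1e-4)

  expect_error(fit_parametric(tibble::tibble(time = 1:3, status = 0L),
                              "weibull"), class = "tdm_fit_error")
})

test_that("interval-censored fits from reconstructed curves recover the truth", {
  set.seed(9)
  x <- rlnorm(3000, 3.28, exp(0.61))
  cs <- runif(3000, 5, 60)
  time <- pmin(x, cs)
  status <- as.integer(x <= cs)
  bounds <- seq(0, 40, by = 2.5)
  sm <- summary(survival::survfit(survival::Surv(time, status) ~ 1),
                times = bounds, extend = TRUE)
  km <- tibble::tibble(time_years = bounds, survival = sm$surv,
                       n_risk = sm$n.risk)
  ipd <- km_pseudo_ipd(km_reconstruct(km))
  fit <- fit_parametric(ipd, "lognormal")
  expect_lt(abs(fit$params["mu"] - 3.28), 0.15)
  expect_lt(abs(log(fit$params["sigma"]) - 0.61), 0.1)
})

test_that("AIC/BIC selection picks the generating family and applies tie rules", {
  set.seed(10)
  x <- rlnorm(4000, 3.28, exp(0.61))
  dat <- tibble::tibble(time = x, status = 1L)
  fits <- lapply(c("exponential", "weibull", "lognormal", "loglogistic"),
                 function(f) fit_parametric(dat, f))
  expect_equal(select_best(fits)$family, "lognormal")
  expect_identical(select_best(fits[2]), fits[[2]])
  # ties: equal AIC resolved by BIC, then by parameter count
  a <- list(family = "a", aic = 10, bic = 12, n_params = 2)
  b <- list(family = "b", aic = 10, bic = 11, n_params = 2)
  expect_equal(select_best(list(a, b))$family, "b")
  c3 <- list(family = "c", aic = 10, bic = 11, n_params = 1)
  expect_equal(select_best(list(b, c3))$family, "c")
  expect_error(select_best(list()), class = "tdm_argument_error")
})

test_that("Wald intervals for the lognormal location have near-nominal coverage", {
  set.seed(11)
  cover <- 0L
  for (i in 1:20) {
    x <- rlnorm(2000, 3.28, exp(0.61))
    fit <- fit_parametric(tibble::tibble(time = x, status = 1L), "lognormal")
    td <- tidy(fit)
    mu <- td$estimate[td$term == "location"]
    se <- td$std.error[td$term == "location"]
    cover <- cover + (abs(mu - 3.28) <= 1.96 * se)
  }
  expect_gte(cover, 16L) # >= 80% of 20 replicates
})

test_that("life tables round-trip through CSV", {
  lt <- flat_lt(0.05, 50:60)
  path <- withr::local_tempfile(fileext = ".csv")
  write_life_table(lt, path)
  expect_equal(as.data.frame(read_life_table(path)), as.data.frame(lt))
  expect_error(life_table(c(50, 52), c(0.1, 0.1)), "contiguous",
               class = "tdm_validation_error")
  expect_error(life_table(50:51, c(0.5, 1)), class = "tdm_validation_error")
})
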