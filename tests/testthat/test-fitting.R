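# One-compartment zero-order-input model: prediction, fitting, AUC,
# confidence intervals, acceptance verdicts, QC regression.

test_that("predicted concentration follows the multi-dose closed form", {
  sch <- data.frame(start = c(0, 8, 16), duration = 0.5, amount = 21600)
  k <- log(2); v <- 180
  # end of first infusion
  expect_equal(predict_concentration(k, v, sch, 0.5),
               21600 / (0.5 * v * k) * (1 - exp(-k * 0.5)),
               tolerance = 1e-12)
  expect_equal(predict_concentration(k, v, sch, 0.5), 101.4,
               tolerance = 1e-3)
  # zero before the first dose, vanishing at long times after the last
  expect_equal(predict_concentration(k, v, sch, -1e-9), 0)
  expect_lt(predict_concentration(k, v, sch, 120), 1e-12)
  # superposition: three doses = sum of three one-dose predictions
  tt <- seq(0, 24, by = 0.5)
  total <- Reduce(`+`, lapply(c(0, 8, 16), function(s)
    predict_concentration(k, v, data.frame(start = s, duration = 0.5,
                                           amount = 21600), tt)))
  expect_equal(predict_concentration(k, v, sch, tt), total,
               tolerance = 1e-12)
  # bolus limit
  expect_equal(predict_concentration(k, v, data.frame(start = 0, duration = 0,
                                                      amount = 1800), 1),
               10 * exp(-k), tolerance = 1e-12)
})

test_that("fitted model agrees with the design simulator at the peak", {
  d <- ref_design()
  sch <- ref_schedule(d)
  pr <- simulate_closed_form(d, sch, times = 0.5)
  pred <- predict_concentration(log(2), 180, sch, 0.5, drug = "meropenem")
  expect_equal(pr$meropenem$c_central, pred, tolerance = 1e-9)
})

test_that("noiseless fits recover the design parameters to 0.1%", {
  st <- generate_study(noise = noise_model(cv = 0, seed = 1), days = 1L)
  sch <- st$schedule
  truth <- c(meropenem = 1.0, ceftazidime = 2.5, ceftriaxone = 8.0)
  for (drug in names(truth)) {
    obs <- st$observations[st$observations$drug == drug, ]
    fit <- fit_one_compartment(obs, sch, drug = drug)
    expect_true(fit$converged)
    expect_equal(fit$half_life_est, unname(truth[drug]), tolerance = 1e-3)
    expect_equal(fit$v_est, 180, tolerance = 1e-3)
    expect_gte(fit$r2, 0.9999)
  }
})

test_that("uniform and proportional weighting agree exactly on clean data", {
  st <- generate_study(noise = noise_model(cv = 0, seed = 1), days = 1L)
  obs <- st$observations[st$observations$drug == "ceftazidime", ]
  f1 <- fit_one_compartment(obs, st$schedule, weighting = "proportional",
                            drug = "ceftazidime")
  f2 <- fit_one_compartment(obs, st$schedule, weighting = "uniform",
                            drug = "ceftazidime")
  expect_equal(f1$k_est, f2$k_est, tolerance = 1e-6)
  expect_equal(f1$v_est, f2$v_est, tolerance = 1e-6)
})

test_that("fits at 5% assay noise stay within 10% of the true half-life", {
  st <- generate_study(noise = noise_model(cv = 0.05, seed = 42))
  truth <- c(meropenem = 1.0, ceftazidime = 2.5, ceftriaxone = 8.0)
  for (drug in names(truth)) {
    obs <- st$observations[st$observations$drug == drug, ]
    fit <- fit_one_compartment(obs, st$schedule, drug = drug)
    expect_true(fit$converged)
    expect_lt(abs(fit$half_life_est / truth[drug] - 1), 0.10)
  }
})

test_that("analytic AUC24 matches trapezoidal integration of the fit", {
  sch <- data.frame(start = c(0, 8, 16), duration = 0.5, amount = 21600)
  fit <- list(k_est = log(2) / 2.5, v_est = 180, drug = NULL, schedule = sch)
  t <- seq(0, 24, by = 0.001)
  c_t <- predict_concentration(fit$k_est, fit$v_est, sch, t)
  trap <- sum(diff(t) * (utils::head(c_t, -1) + utils::tail(c_t, -1)) / 2)
  expect_equal(auc24_from_fit(fit), trap, tolerance = 1e-4)
})

test_that("single-bolus AUC24 has the (C0/k)(1 - exp(-24k)) closed form", {
  k <- log(2) / 8
  fit <- list(k_est = k, v_est = 180, drug = NULL,
              schedule = data.frame(start = 0, duration = 1e-9,
                                    amount = 30 * 180))
  expect_equal(auc24_from_fit(fit), 30 / k * (1 - exp(-24 * k)),
               tolerance = 1e-6)
  expect_equal(auc24_from_fit(fit), 303.0, tolerance = 1e-3)
  # truncation at 24 h equals the sum of per-dose truncated integrals
  fit3 <- list(k_est = k, v_est = 180, drug = NULL,
               schedule = data.frame(start = c(0, 8, 16), duration = 0.5,
                                     amount = 5400))
  parts <- vapply(c(0, 8, 16), function(s)
    auc24_from_fit(list(k_est = k, v_est = 180, drug = NULL,
                        schedule = data.frame(start = s, duration = 0.5,
                                              amount = 5400))), numeric(1))
  expect_equal(auc24_from_fit(fit3), sum(parts), tolerance = 1e-12)
})

test_that("half-life intervals pool per-day fits as an envelope", {
  st <- generate_study(noise = noise_model(cv = 0.05, seed = 3))
  obs <- st$observations[st$observations$drug == "meropenem", ]
  fits <- lapply(split(obs, obs$day), fit_one_compartment,
                 schedule = st$schedule, drug = "meropenem")
  ci <- halflife_confidence_interval(fits, level = 0.80)
  expect_lt(ci$lower, min(ci$estimates))
  expect_gt(ci$upper, max(ci$estimates))
  # a single exact fit gives a zero-width interval at its estimate
  exact <- list(k_est = log(2) / 8, se_k = 0, half_life_est = 8,
                n_obs = 10L, converged = TRUE)
  class(exact) <- "one_compartment_fit"
  ci0 <- halflife_confidence_interval(exact)
  expect_equal(ci0$lower, 8)
  expect_equal(ci0$upper, 8)
  # duplicating a fit does not change the envelope
  ci2 <- halflife_confidence_interval(list(exact, exact))
  expect_equal(c(ci2$lower, ci2$upper), c(ci0$lower, ci0$upper))
})

test_that("acceptance verdicts apply the 20% rule to both parameters", {
  tg <- drug_target("meropenem", 120, 1.0, 8)
  ok <- list(half_life_est = 1.0, cmax_est = 101.4)
  v <- acceptance_check(ok, tg)
  expect_true(v$pass)
  expect_equal(v$cmax_ratio, 101.4 / 120)
  low_cmax <- list(half_life_est = 1.0, cmax_est = 0.72 * 120)
  v2 <- acceptance_check(low_cmax, tg)
  expect_false(v2$pass)
  expect_true(v2$halflife_pass)
  expect_false(v2$cmax_pass)
  off_hl <- list(half_life_est = 1.3, cmax_est = 120)
  expect_false(acceptance_check(off_hl, tg)$pass)
})

test_that("target-vs-observed regression recovers known lines", {
  x <- c(1, 5, 20, 60, 120)
  r <- target_vs_observed_regression(x, x)
  expect_equal(r$slope, 1)
  expect_equal(r$intercept, 0, tolerance = 1e-12)
  expect_equal(r$r2, 1)
  expect_equal(r$ratio_pct$median, 100)
  r2 <- target_vs_observed_regression(x, 0.9 * x)
  expect_equal(r2$slope, 0.9)
  expect_equal(r2$intercept, 0, tolerance = 1e-12)
  expect_error(target_vs_observed_regression(c(1, 1, 1), c(1, 2, 3)),
               "constant")
  expect_error(target_vs_observed_regression(1:2, 1:2), "at least 3")
})

test_that("all-BLQ input and too-few observations are rejected", {
  sch <- data.frame(start = 0, duration = 0.5, amount = 21600)
  blq <- data.frame(time = c(1, 2, 3, 4), conc = c(0.1, 0.2, 0.05, 0.4))
  expect_error(fit_one_compartment(blq, sch), "at least 2")
})
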