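# Two-compartment simulator: schedules, closed form vs numeric, the
# mono-exponential design property, superposition, mass balance.

test_that("build_schedule lays out q8h and once-daily infusions", {
  d <- ref_design()
  sch <- ref_schedule(d)
  mem_c <- sch[sch$drug == "meropenem" & sch$compartment == "central", ]
  expect_equal(mem_c$start, c(0, 8, 16))
  expect_equal(mem_c$amount, rep(21600, 3))
  expect_equal(mem_c$duration, rep(0.5, 3))
  mem_s <- sch[sch$drug == "meropenem" & sch$compartment == "supplemental", ]
  expect_equal(mem_s$start, c(0, 8, 16))
  cro <- sch[sch$drug == "ceftriaxone", ]
  expect_equal(unique(cro$start), 0)
  # an 8 h horizon leaves exactly one dose per q8h drug
  sch8 <- build_schedule(d, horizon = 8)
  expect_equal(sum(sch8$drug == "ceftazidime" & sch8$compartment == "central"),
               1L)
  expect_error(build_schedule(d, horizon = 0), "positive")
})

test_that("closed-form and numeric integrators agree to 1e-6", {
  d <- ref_design()
  sch <- ref_schedule(d)
  times <- seq(0, 24, by = 0.1)
  cf <- simulate_closed_form(d, sch, times)
  nm <- simulate_numeric(d, sch, times)
  for (drug in names(cf)) {
    expect_lt(max_rel_dev(nm[[drug]]$c_central, cf[[drug]]$c_central,
                          floor = 1e-6), 1e-6)
    expect_lt(max_rel_dev(nm[[drug]]$c_supp, cf[[drug]]$c_supp,
                          floor = 1e-6), 1e-6)
  }
})

test_that("end of first infusion matches the one-compartment closed form", {
  d <- ref_design()
  sch <- ref_schedule(d)
  pr <- simulate_closed_form(d, sch, times = 0.5)
  # (D / (T Vc k)) (1 - exp(-k T)) with the design on the slow eigenvector
  for (drug in d$lines$drug) {
    ln <- design_line(d, drug)
    expected <- ln$central_dose / (0.5 * 180 * ln$k) * (1 - exp(-ln$k * 0.5))
    expect_equal(pr[[drug]]$c_central, expected, tolerance = 1e-12)
  }
  expect_equal(pr$meropenem$c_central, 101.4, tolerance = 1e-3)
})

test_that("post-dose central decline is mono-exponential at each drug's rate", {
  d <- ref_design()
  pr <- simulate_closed_form(d, ref_schedule(d), seq(0, 24, by = 0.05))
  windows <- list(meropenem = c(1, 7.9), ceftazidime = c(1, 7.9),
                  ceftriaxone = c(1, 24))
  for (drug in names(windows)) {
    ln <- design_line(d, drug)
    sl <- log_linear_slope(pr[[drug]], windows[[drug]])
    expect_equal(sl$k, ln$k, tolerance = 1e-6)
    expect_gte(sl$r2, 1 - 1e-9)
  }
})

test_that("single-dose decline ratios follow the target half-life", {
  d <- ref_design()
  one <- single_dose_schedule(d, "ceftriaxone", horizon = 24)
  pr <- simulate_closed_form(d, one, times = c(8, 24))
  # post-infusion window: c(24)/c(8) = exp(-ln2 * 16 / 8) = 1/4
  expect_equal(pr$ceftriaxone$c_central[2] / pr$ceftriaxone$c_central[1],
               0.25, tolerance = 1e-9)
})

test_that("a lone central bolus with no supplemental dose decays at k_total", {
  hw <- hardware_config(100, 1, 1)                # k_total = 0.6 /h
  tg <- drug_target("d", 10, log(2) / 0.6, 24)    # k = k_total
  d <- design_parallel(list(tg), hw)
  expect_equal(d$lines$supp_dose, 0)
  sch <- dose_schedule(data.frame(drug = "d", compartment = "central",
                                  start = 0, duration = 0, amount = 1000),
                       horizon = 24)
  t <- seq(0, 12, by = 0.5)
  pr <- simulate_closed_form(d, sch, t)
  expect_equal(pr$d$c_central, 10 * exp(-0.6 * t), tolerance = 1e-12)
})

test_that("profiles superpose: n doses equal n shifted single doses", {
  d <- ref_design()
  full <- ref_schedule(d)
  t <- seq(0, 24, by = 0.25)
  pr_full <- simulate_closed_form(d, full, t)
  for (drug in c("meropenem", "ceftazidime")) {
    ev <- full[full$drug == drug, ]
    total <- numeric(length(t))
    for (s in unique(ev$start)) {
      one <- dose_schedule(ev[ev$start == s, ], horizon = 24)
      total <- total + simulate_closed_form(d, one, t)[[drug]]$c_central
    }
    expect_equal(total, pr_full[[drug]]$c_central, tolerance = 1e-9)
  }
})

test_that("two half-life design declines at -ln2/4 per hour on log scale", {
  # independent check of the design equations by brute-force simulation
  # two lines whose combined hourly flow is Vc ln2, so k_total = ln2 /h
  hw <- hardware_config(v_central = 100,
                        flow_ml_min = 100 * log(2) / 2 / 60, n_lines = 2)
  expect_equal(system_turnover(hw), log(2))
  tg <- list(drug_target("one_h", 10, 1, 24),
             drug_target("four_h", 10, 4, 24))
  d <- design_parallel(tg, hw)
  expect_equal(design_line(d, "one_h")$supp_dose, 0)  # k == k_total
  sch <- build_schedule(d, horizon = 24)
  pr <- simulate_numeric(d, sch, seq(0, 24, by = 0.1))
  sl <- log_linear_slope(pr$four_h, c(1, 24))
  expect_equal(sl$k, log(2) / 4, tolerance = 1e-6)
})

test_that("mass leaving the central vessel equals the total dose", {
  d <- ref_design()
  for (drug in d$lines$drug) {
    ln <- design_line(d, drug)
    horizon <- 40 / ln$k   # far past 7 half-lives; exact segment integrals
    one <- single_dose_schedule(d, drug, horizon = horizon)
    auc <- profile_auc(d, one, drug, horizon)
    eliminated <- d$k_total * d$hardware$v_central * auc
    expect_equal(eliminated, ln$central_dose + ln$supp_dose,
                 tolerance = 1e-3)
  }
})

test_that("exact AUC matches fine-grid trapezoidal integration", {
  d <- ref_design()
  sch <- ref_schedule(d)
  t <- seq(0, 24, by = 0.005)
  pr <- simulate_closed_form(d, sch, t)
  for (drug in c("meropenem", "ceftriaxone")) {
    trap <- sum(diff(t) * (utils::head(pr[[drug]]$c_central, -1) +
                           utils::tail(pr[[drug]]$c_central, -1)) / 2)
    expect_equal(profile_auc(d, sch, drug, 24), trap, tolerance = 1e-4)
  }
})

test_that("zero-dose schedules give identically zero profiles", {
  d <- ref_design()
  sch <- dose_schedule(data.frame(drug = "meropenem", compartment = "central",
                                  start = 0, duration = 0.5, amount = 0),
                       horizon = 24)
  pr <- simulate_closed_form(d, sch, seq(0, 24, by = 1))
  expect_true(all(pr$meropenem$c_central == 0))
  expect_true(all(pr$ceftriaxone$c_central == 0))
})

test_that("concentrations are never negative at solver output points", {
  d <- ref_design()
  sch <- ref_schedule(d)
  for (pr in list(simulate_closed_form(d, sch), simulate_numeric(d, sch))) {
    for (p in pr) {
      expect_true(all(p$c_central >= 0))
      expect_true(all(p$c_supp >= 0))
    }
  }
})

test_that("pre-dose evaluation takes the left limit at bolus boundaries", {
  hw <- hardware_config(100, 1, 1)
  tg <- drug_target("d", 10, log(2) / 0.6, 24)
  d <- design_parallel(list(tg), hw)
  sch <- dose_schedule(data.frame(drug = "d", compartment = "central",
                                  start = c(0, 8), duration = 0,
                                  amount = 1000), horizon = 24)
  at8 <- simulate_closed_form(d, sch, times = c(8, 8),
                              pre_dose = c(TRUE, FALSE))
  trough <- 10 * exp(-0.6 * 8)
  expect_equal(at8$d$c_central[1], trough, tolerance = 1e-12)
  expect_equal(at8$d$c_central[2], trough + 10, tolerance = 1e-12)
})
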