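set_pv <- function(ps, ...) {
  vals <- list(...)
  for (nm in names(vals)) ps <- sarcscreen:::set_param_value(ps, nm, vals[[nm]])
  ps
}

# a deathless, event-free configuration with unit utilities
immortal_params <- function() {
  bands <- data.frame(age_low = c(60, 70), age_high = c(69, 120))
  sched <- rbind(
    data.frame(disease = "CVD", bands, incidence = 0, prevalence = 0.5, mortality = 0),
    data.frame(disease = "fall", bands, incidence = 0, prevalence = 0.5, mortality = 0))
  ps <- default_parameters(schedules = sched)
  u_names <- grep("^u_", required_parameter_names(), value = TRUE)
  do.call(set_pv, c(list(ps), setNames(as.list(rep(1, length(u_names))), u_names),
                    list(p_death_background = 0)))
}

test_that("fatality rate is mortality over prevalence, clamped with a warning", {
  expect_equal(fatality_rate(0.02, 0.10), 0.2)
  expect_equal(fatality_rate(0, 0.10), 0)
  expect_warning(r <- fatality_rate(0.15, 0.10), "clamped")
  expect_equal(r, 1)
  expect_error(fatality_rate(0.1, 0), "prevalence")
})

test_that("event probabilities compose the schedules with the relative risks", {
  ps <- toy_parameter_set()
  ns <- annual_event_probs(60, "NS", ps)
  s <- annual_event_probs(60, "S", ps)
  expect_equal(ns$p_fracture, ns$p_fall * 0.26, tolerance = 1e-12)
  expect_equal(s$p_fall / ns$p_fall, 1.89, tolerance = 1e-12)
  expect_equal(s$p_cvd_onset / ns$p_cvd_onset, 1.33, tolerance = 1e-12)
  expect_equal(annual_event_probs(60, "C", ps)$p_cvd_onset, 0)
  # background-only death when disease mortalities are zero
  ps0 <- immortal_params()
  ps0 <- set_pv(ps0, p_death_background = 0.09)
  expect_equal(annual_event_probs(65, "NS", ps0)$p_death, 0.09, tolerance = 1e-12)
  expect_equal(annual_event_probs(65, "S", ps0)$p_death, 0.18, tolerance = 1e-12)
})

test_that("sarcopenia dynamics follow the age bands and intervention effects", {
  ps <- default_parameters()
  expect_equal(unname(sarcopenia_dynamics(65, FALSE, ps)), c(0.04, 0.16))
  expect_equal(sarcopenia_dynamics(75, TRUE, ps)[["p_incidence"]], 0.12 * 0.45)
  expect_equal(sarcopenia_dynamics(65, TRUE, ps)[["p_recovery"]], 0.16 * 3.61)
  expect_equal(sarcopenia_dynamics(85, FALSE, ps)[["p_incidence"]], 0.17)
})

test_that("transition matrices are row-stochastic with absorbing death and irreversible CVD", {
  ps <- default_parameters()
  labs <- stratum_labels()
  for (age in c(60, 72, 84)) {
    M <- build_transition_matrix(age, ps)
    expect_equal(unname(rowSums(M)), rep(1, 9), tolerance = 1e-10)
    expect_equal(M["dead", "dead"], 1)
    expect_true(all(M >= 0 & M <= 1))
    expect_equal(M["cvd", "no_sarc"], 0)
    expect_equal(M["sarc_cvd", "sarc"], 0)
    # intervention flag only changes through screening, never in transition
    expect_equal(sum(M[1:4, 5:8]), 0)
    expect_equal(sum(M[5:8, 1:4]), 0)
  }
})

test_that("cohort trace conserves occupancy and death is monotone", {
  ps <- default_parameters()
  tr <- run_cohort(screening_strategies(ps)[[10]], ps)
  expect_equal(unname(rowSums(tr$occupancy)), rep(1, 25), tolerance = 1e-12)
  expect_true(all(diff(tr$occupancy[, "dead"]) >= 0))
  expect_true(all(tr$cycles$fractures >= 0))
  expect_true(all(tr$cycles$cvd_entrants >= 0))
})

test_that("immortal unit-utility cohort accrues exactly one QALY per cycle", {
  ps <- immortal_params()
  tr <- run_cohort(screening_strategies(ps)[[1]], ps)
  expect_equal(accumulate(tr, 0)$total_qaly, 25, tolerance = 1e-12)
  expect_equal(healthy_life_expectancy(tr), 85, tolerance = 1e-12)
})

test_that("a costless perfect test with a neutral intervention replicates no screening", {
  ps <- toy_parameter_set()
  cost_zero <- grep("^cost_", required_parameter_names(), value = TRUE)
  ps <- do.call(set_pv, c(list(ps),
    setNames(as.list(rep(0, length(cost_zero))), cost_zero),
    list(intervention_rr_incidence = 1, intervention_rr_recovery = 1)))
  base <- accumulate(run_cohort(screening_strategies(ps)[[1]], ps, totals_only = TRUE), 0.03)
  for (s in screening_strategies(ps)[-1]) {
    a <- accumulate(run_cohort(s, ps, totals_only = TRUE), 0.03)
    expect_equal(a$total_qaly, base$total_qaly, tolerance = 1e-12, info = s$label)
    expect_equal(a$total_cost, base$total_cost, tolerance = 1e-12, info = s$label)
  }
})

test_that("the toy cohort reproduces the independently computed worksheet values", {
  ps <- toy_parameter_set()
  st <- screening_strategies(ps)
  lab <- vapply(st, `[[`, "", "label")
  # frozen straight-line oracle values for the no-screening toy run
  tr <- run_cohort(st[[1]], ps)
  a <- accumulate(tr, 0.03)
  expect_equal(a$total_cost, 1226.93844792, tolerance = 1e-8)
  expect_equal(a$total_qaly, 1.94644558, tolerance = 1e-8)
  expect_equal(sum(tr$cycles$alive), 2.70045628, tolerance = 1e-8)
  # live oracle comparison for screening strategies, including the two-step tool
  o <- toy_oracle(sens = 0.34, spec = 0.90, unit_cost = 0.71, interval = 1)
  a <- accumulate(run_cohort(st[[match("SARC-F annual", lab)]], ps, totals_only = TRUE), 0.03)
  expect_equal(a$total_cost, o$cost, tolerance = 1e-9)
  expect_equal(a$total_qaly, o$qaly, tolerance = 1e-9)
  o <- toy_oracle(sens = 1, spec = 1, interval = 2, two_step = TRUE)
  a <- accumulate(run_cohort(st[[match("AWGS 2019 biennial", lab)]], ps, totals_only = TRUE), 0.03)
  expect_equal(a$total_cost, o$cost, tolerance = 1e-9)
  expect_equal(a$total_qaly, o$qaly, tolerance = 1e-9)
})

test_that("raising sarcopenia prevalence weakly lowers no-screening QALYs", {
  ps <- default_parameters()
  q <- vapply(c(0.05, 0.12, 0.25, 0.40), function(p) {
    psx <- set_pv(ps, sarcopenia_prevalence = p)
    accumulate(run_cohort(screening_strategies(psx)[[1]], psx, totals_only = TRUE), 0.03)$total_qaly
  }, 0)
  expect_true(all(diff(q) <= 0))
})

test_that("microsimulation oracle agrees with the cohort engine on the toy set", {
  ps <- toy_parameter_set()
  st <- screening_strategies(ps)
  s <- st[[match("AWGS 2019 annual", vapply(st, `[[`, "", "label"))]]
  a <- accumulate(run_cohort(s, ps, totals_only = TRUE), 0.03)
  ms <- microsim_oracle(s, ps, n_individuals = 50000, seed = 11)
  expect_lt(abs(ms$mean_qaly - a$total_qaly), 3 * ms$se_qaly)
  expect_lt(abs(ms$mean_cost - a$total_cost), 3 * ms$se_cost)
  # seed reproducibility
  ms2 <- microsim_oracle(s, ps, n_individuals = 1000, seed = 5)
  ms3 <- microsim_oracle(s, ps, n_individuals = 1000, seed = 5)
  expect_identical(ms2, ms3)
})
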