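test_that("packaged defaults validate and carry the published point values", {
  ps <- default_parameters()
  expect_s3_class(ps, "sarc_params")
  expect_equal(param_value(ps, "sarcopenia_prevalence"), 0.12)
  expect_equal(param_value(ps, "cost_dxa"), 42.86)
  expect_equal(param_value(ps, "sens_awgs2019"), 1.00)
  expect_equal(ps$settings$cohort_size, 1000L)
  expect_equal(ps$settings$n_cycles, 25L)
  expect_setequal(names(ps$params), required_parameter_names())
})

test_that("the packaged example configuration loads and matches the defaults", {
  f <- system.file("extdata", "default_config.yaml", package = "sarcscreen")
  expect_true(nzchar(f))
  ps <- load_parameters(f)
  ps0 <- default_parameters()
  for (nm in required_parameter_names())
    expect_equal(param_value(ps, nm), param_value(ps0, nm), info = nm)
})

test_that("config round-trip preserves values; bad configs are rejected by name", {
  cfg <- withr::local_tempfile(fileext = ".yaml")
  write_default_config(cfg)
  ps <- load_parameters(cfg)
  ps0 <- default_parameters()
  for (nm in required_parameter_names())
    expect_equal(param_value(ps, nm), param_value(ps0, nm), info = nm)

  # out-of-range probability
  bad <- yaml::read_yaml(cfg)
  bad$transition$sarcopenia_prevalence$value <- 1.5
  bad$transition$sarcopenia_prevalence$high <- 2.0
  f1 <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(bad, f1)
  expect_error(load_parameters(f1), "sarcopenia_prevalence")

  # omitted required parameter
  bad2 <- yaml::read_yaml(cfg)
  bad2$transition$sarcopenia_recovery_rate <- NULL
  f2 <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(bad2, f2)
  expect_error(load_parameters(f2), "sarcopenia_recovery_rate")
})

test_that("PSA sampling is reproducible, leaves fixed rows alone, and respects scales", {
  ps <- default_parameters()
  a <- sample_parameter_set(ps, 1L)
  b <- sample_parameter_set(ps, 1L)
  expect_identical(vapply(a$params, `[[`, 0, "value"),
                   vapply(b$params, `[[`, 0, "value"))
  expect_equal(param_value(a, "sens_awgs2019"), 1.00)
  expect_equal(param_value(a, "spec_sarcf_msra7"), 1.00)
  expect_equal(param_value(a, "sarc_incidence_70_79"), 0.12)
  expect_equal(param_value(a, "p_death_background"), 0.09)
  for (s in 1:20) {
    d <- sample_parameter_set(ps, s)
    for (p in d$params) {
      if (p$kind %in% c("probability", "utility"))
        expect_true(p$value >= 0 && p$value <= 1, info = p$name)
      if (p$kind == "cost") expect_gte(p$value, 0)
      if (p$kind == "rr") expect_gt(p$value, 0)
    }
  }
})

test_that("per-parameter substreams are independent of the rest of the set", {
  ps <- default_parameters()
  full <- sample_parameter_set(ps, 7L)
  # fixing one parameter must not perturb any other parameter's draw
  ps2 <- ps
  ps2$params[["cost_dxa"]]$dist <- "fixed"
  part <- sample_parameter_set(ps2, 7L)
  for (nm in setdiff(required_parameter_names(), "cost_dxa"))
    expect_equal(param_value(part, nm), param_value(full, nm), info = nm)
})

test_that("Monte Carlo draws reproduce the intervention cost mean within 3 SE", {
  spec <- param_distribution(default_parameters()$params[["cost_intervention"]])
  set.seed(99)
  x <- rgamma(10000, shape = spec$shape, scale = spec$scale)
  se <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - 1119.05), 3 * se)
})

test_that("DSA ranges follow their rules", {
  ps <- default_parameters()
  expect_equal(dsa_range(ps$params[["discount_rate"]]), c(0.01, 0.05))
  expect_equal(dsa_range(ps$params[["sarcopenia_recovery_rate"]]), c(0.14, 0.18))
  cost_p <- sarcscreen:::.param_row("c", 100, dist = "gamma", sd = 1,
                                    dsa = "pct10", kind = "cost")
  expect_equal(dsa_range(cost_p), c(90, 110))
  # probabilities clamp at 1
  u_p <- sarcscreen:::.param_row("u", 0.95, dsa = "pct10", kind = "utility")
  expect_equal(dsa_range(u_p), c(0.855, 1))
  expect_error(dsa_range(ps$params[["gdp_per_capita"]]), "no DSA range")
})
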