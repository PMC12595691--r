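test_that("one-way DSA produces a coherent tornado", {
  ps <- toy_parameter_set()
  df <- one_way_dsa(ps, "AWGS 2019 annual", "no screening", 37654.49)
  expect_setequal(df$parameter, sarcscreen:::dsa_parameter_names(ps))
  expect_true(all(df$range >= 0))
  expect_equal(sum(df$influence_share), 1, tolerance = 1e-12)
  expect_true(all(diff(df$range) <= 1e-12))  # sorted descending
  disc <- df[df$parameter == "discount_rate", ]
  expect_equal(c(disc$low, disc$high), c(0.01, 0.05))
  # deterministic: identical rerun
  expect_equal(one_way_dsa(ps, "AWGS 2019 annual", "no screening", 37654.49), df)
  # a degenerate range produces a zero swing
  ps2 <- ps
  ps2$params[["sarcopenia_prevalence"]]$low <- 0.12
  ps2$params[["sarcopenia_prevalence"]]$high <- 0.12
  df2 <- one_way_dsa(ps2, "AWGS 2019 annual", "no screening", 37654.49)
  expect_equal(df2$range[df2$parameter == "sarcopenia_prevalence"], 0, tolerance = 1e-9)
  expect_error(one_way_dsa(ps, "nonexistent strategy"), "valid")
})

test_that("PSA draws are reproducible and complete", {
  ps <- toy_parameter_set()
  a <- run_psa(ps, n_draws = 3, seed = 42)
  b <- run_psa(ps, n_draws = 3, seed = 42)
  expect_identical(a, b)
  expect_equal(length(unique(a$strategy)), 21)
  expect_equal(nrow(a), 3 * 21)
  expect_true(all(table(a$draw) == 21))
  c2 <- run_psa(ps, n_draws = 3, seed = 43)
  expect_false(identical(a$cost, c2$cost))
})

test_that("with all distributions collapsed to points every draw is the base case", {
  ps <- toy_parameter_set()
  for (nm in names(ps$params)) ps$params[[nm]]$dist <- "fixed"
  psa <- run_psa(ps, n_draws = 2, seed = 1)
  tab <- cea_table(ps)
  for (s in tab$strategy) {
    expect_equal(unique(psa$cost[psa$strategy == s]), tab$cost[tab$strategy == s],
                 tolerance = 1e-12, info = s)
    expect_equal(unique(psa$qaly[psa$strategy == s]), tab$qaly[tab$strategy == s],
                 tolerance = 1e-12, info = s)
  }
})

test_that("CEAC probabilities partition unity and behave at the edges", {
  ps <- toy_parameter_set()
  psa <- run_psa(ps, n_draws = 10, seed = 7)
  grid <- seq(0, 40000, by = 2000)
  cc <- ceac(psa, grid)
  sums <- tapply(cc$probability, cc$wtp, sum)
  expect_equal(as.numeric(sums), rep(1, length(grid)), tolerance = 1e-12)
  # at WTP 0 the cheapest strategy wins every draw
  at0 <- cc[cc$wtp == 0, ]
  cheapest <- vapply(split(psa, psa$draw),
                     function(d) d$strategy[which.min(d$cost)], "")
  top <- at0$strategy[which.max(at0$probability)]
  expect_equal(at0$probability[at0$strategy == top],
               mean(cheapest == top), tolerance = 1e-12)
  # single draw: one strategy takes probability 1 at each WTP (no exact ties here)
  cc1 <- ceac(psa[psa$draw == 1, ], grid)
  expect_true(all(tapply(cc1$probability, cc1$wtp, max) == 1))
  # invariance to a constant cost shift across all strategies and draws
  psa_shift <- psa
  psa_shift$cost <- psa_shift$cost + 1000
  expect_equal(ceac(psa_shift, grid)$probability, cc$probability, tolerance = 1e-12)
})
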