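test_that("discounting follows the closed form and accumulation is linear", {
  expect_equal(discount_factor(0, 0.03), 1)
  expect_equal(discount_factor(1, 0.03), 0.970874, tolerance = 1e-6)
  expect_equal(discount_factor(2, 0.05), 0.907029, tolerance = 1e-6)
  ps <- toy_parameter_set()
  tr <- run_cohort(screening_strategies(ps)[[1]], ps)
  a0 <- accumulate(tr, 0)
  a3 <- accumulate(tr, 0.03)
  expect_lt(a3$total_cost, a0$total_cost)
  expect_lt(a3$total_qaly, a0$total_qaly)
  tr2 <- tr
  tr2$cycles$total_cost <- 2 * tr$cycles$total_cost
  expect_equal(accumulate(tr2, 0.03)$total_cost, 2 * a3$total_cost, tolerance = 1e-12)
})

test_that("ICER and threshold classification handle the standard and degenerate cases", {
  expect_equal(icer(11064.42, 9.4482, 10411.01, 9.0011), 653.41 / 0.4471,
               tolerance = 1e-12)
  expect_true(is.na(icer(100, 5, 50, 5)))
  expect_true(is.na(icer(100, 4, 50, 5)))
  gdp <- 12551.49
  expect_equal(classify_threshold(1461.52, gdp), "highly cost-effective")
  expect_equal(classify_threshold(20000, gdp), "cost-effective")
  expect_equal(classify_threshold(40000, gdp), "not cost-effective")
  expect_true(is.na(classify_threshold(NA_real_, gdp)))
})

test_that("net monetary benefit definition and its ICER crossing", {
  expect_equal(net_monetary_benefit(11904.95, 9.6186, 37654.49),
               9.6186 * 37654.49 - 11904.95)
  expect_equal(net_monetary_benefit(500, 2, 0), -500)
  # at WTP equal to the pairwise ICER, the two strategies' NMBs tie
  w <- icer(200, 6, 100, 5)
  expect_equal(net_monetary_benefit(200, 6, w), net_monetary_benefit(100, 5, w))
})

test_that("efficiency frontier removes dominance and keeps ties", {
  qaly <- c(1.0, 1.0, 0.9, 2.0, 1.5)
  cost <- c(10, 10, 20, 100, 30)
  on <- efficiency_frontier(qaly, cost)
  expect_true(on[1] && on[2])   # exact ties both retained
  expect_false(on[3])           # strictly dominated
  expect_true(on[4] && on[5])
  # extended dominance: middle point above the chord is pruned
  on2 <- efficiency_frontier(c(1, 2, 3), c(0, 90, 100))
  expect_equal(on2, c(TRUE, FALSE, TRUE))
})

test_that("the base-case table is internally consistent and NMB-coherent", {
  ps <- toy_parameter_set()
  tab <- cea_table(ps)
  expect_equal(nrow(tab), 21)
  expect_equal(tab$ce_ratio * tab$qaly, tab$cost, tolerance = 1e-9)
  i0 <- match("no screening", tab$strategy)
  expect_equal(tab$incr_cost[i0], 0)
  expect_equal(tab$incr_qaly[i0], 0)
  expect_equal(tab$incr_cost, tab$cost - tab$cost[i0], tolerance = 1e-12)
  # the max-NMB strategy at any WTP lies on the frontier
  for (w in c(0, 500, 5000, 50000)) {
    nmb <- net_monetary_benefit(tab$cost, tab$qaly, w)
    expect_true(tab$on_frontier[which.max(nmb)], info = paste("wtp", w))
  }
  # frontier table ICERs are increasing
  ft <- frontier_table(tab)
  expect_true(all(diff(ft$sequential_icer[-1]) >= 0 | is.na(diff(ft$sequential_icer[-1]))))
})
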