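test_that("base-case driver writes the canonical outputs with a manifest", {
  out <- withr::local_tempdir()
  ps <- toy_parameter_set()
  tab <- suppressMessages(run_base_case(ps, out))
  expect_true(file.exists(file.path(out, "cea_table.csv")))
  expect_true(file.exists(file.path(out, "frontier.csv")))
  expect_true(file.exists(file.path(out, "manifest.txt")))
  got <- read.csv(file.path(out, "cea_table.csv"))
  expect_equal(nrow(got), 21)
  expect_equal(got$cost, tab$cost, tolerance = 1e-9)
  expect_equal(sum(grepl("^trace_", list.files(out))), 21)
  # idempotent: rerun reproduces identical table bytes
  h1 <- unname(tools::md5sum(file.path(out, "cea_table.csv")))
  suppressMessages(run_base_case(ps, out))
  expect_identical(unname(tools::md5sum(file.path(out, "cea_table.csv"))), h1)
})

test_that("DSA driver writes one tornado row per varied parameter", {
  out <- withr::local_tempdir()
  ps <- toy_parameter_set()
  df <- suppressMessages(run_dsa(ps, out))
  got <- read.csv(file.path(out, "tornado.csv"))
  expect_equal(nrow(got), length(sarcscreen:::dsa_parameter_names(ps)))
  expect_equal(got$parameter, df$parameter)
})

test_that("PSA driver output is reproducible under a fixed seed", {
  ps <- toy_parameter_set()
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  suppressMessages(run_psa_report(ps, out1, n_draws = 5, seed = 9,
                                  wtp_grid = seq(0, 40000, 5000)))
  suppressMessages(run_psa_report(ps, out2, n_draws = 5, seed = 9,
                                  wtp_grid = seq(0, 40000, 5000)))
  expect_identical(unname(tools::md5sum(file.path(out1, "ceac.csv"))),
                   unname(tools::md5sum(file.path(out2, "ceac.csv"))))
  cc <- read.csv(file.path(out1, "ceac.csv"))
  sums <- tapply(cc$probability, cc$wtp, sum)
  expect_equal(as.numeric(sums), rep(1, length(unique(cc$wtp))), tolerance = 1e-12)
})

test_that("trace export is tidy, one row per cycle and stratum", {
  ps <- toy_parameter_set()
  tr <- run_cohort(screening_strategies(ps)[[2]], ps)
  df <- trace_to_df(tr)
  expect_equal(nrow(df), 3 * 9)
  expect_true(all(c("cycle", "stratum", "occupancy", "screening", "utility")
                  %in% names(df)))
  occ_sum <- tapply(df$occupancy, df$cycle, sum)
  expect_equal(as.numeric(occ_sum), rep(1, 3), tolerance = 1e-12)
})
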