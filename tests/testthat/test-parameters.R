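test_that("default parameter set carries the published base values and ranges", {
  ps <- default_parameters()
  rr <- ps$specs[["annual_recurrence_rate"]]
  expect_equal(c(rr$base, rr$low, rr$high), c(0.1219, 0.1163, 0.1276))
  gt <- ps$specs[["cost_genetic_testing"]]
  expect_equal(c(gt$base, gt$low, gt$high), c(1076.5, 861.2, 1291.8))
  ud <- ps$specs[["utility_death"]]
  expect_equal(c(ud$base, ud$low, ud$high), c(0, 0, 0))
  expect_identical(ud$dist, "fixed")
  expect_equal(ps$specs[["cost_annual_mrs35"]]$base, 13850.50)
  # duplicated printed cost row resolved as the ICH mRS 3-6 band
  expect_equal(ps$specs[["cost_hosp_ich_mrs36"]]$base, 18700.45)
  expect_equal(ps$structural$horizon_years, 30L)
  expect_equal(ps$structural$wtp_primary, 72100)
})

test_that("defaults validate cleanly and violations are reported by name", {
  ps <- default_parameters()
  expect_length(validate_parameters(ps), 0)

  bad <- set_param(ps, "utility_mrs02", 1.2)
  v <- validate_parameters(bad)
  expect_length(v, 1)
  expect_match(v, "utility_mrs02")

  bad2 <- ps
  bad2$specs[["discount_cost"]]$base <- -0.01
  bad2$specs[["discount_cost"]]$low <- -0.01
  v2 <- validate_parameters(bad2)
  expect_true(any(grepl("discount_cost", v2)))
})

test_that("config round-trips losslessly, including randomized sets", {
  for (seed in c(11L, 12L, 13L, 14L, 15L)) {
    ps <- random_ps(seed)
    path <- withr::local_tempfile(fileext = ".yaml")
    write_config(ps, path)
    back <- load_config(path)
    expect_equal(parameter_table(back), parameter_table(ps),
                 tolerance = 1e-12)
    expect_equal(unclass(back$structural), unclass(ps$structural))
  }
})

test_that("config loading: fallback, single-key override, strict errors", {
  empty <- withr::local_tempfile(fileext = ".yaml")
  writeLines(character(0), empty)
  expect_equal(parameter_table(load_config(empty)),
               parameter_table(default_parameters()))

  one <- withr::local_tempfile(fileext = ".yaml")
  writeLines("parameters:\n  cost_genetic_testing: 1291.8", one)
  got <- load_config(one)
  expect_equal(got$specs[["cost_genetic_testing"]]$base, 1291.8)
  others <- setdiff(names(got$specs), "cost_genetic_testing")
  expect_equal(parameter_table(got)[match(others, names(got$specs)), ],
               parameter_table(default_parameters())[
                 match(others, names(got$specs)), ])

  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("parameters:", "  utility_mrs5:", "    low: 0.5",
               "    high: 0.1"), bad)
  expect_error(load_config(bad), "utility_mrs5")

  unk <- withr::local_tempfile(fileext = ".yaml")
  writeLines("parameters:\n  not_a_parameter: 1", unk)
  expect_error(load_config(unk), "not_a_parameter")

  expect_error(load_config(file.path(tempdir(), "nope.yaml")), "not found")
})

test_that("parameter table export is complete", {
  ps <- default_parameters()
  path <- withr::local_tempfile(fileext = ".csv")
  export_parameters_csv(ps, path)
  tab <- read.csv(path)
  expect_setequal(names(tab),
                  c("name", "base", "low", "high", "dist", "units", "source"))
  expect_equal(nrow(tab), length(ps$specs))
})
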