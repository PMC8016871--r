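sched <- default_schedule()

test_that("tornado rows bracket the base case and sort by spread", {
  ps <- default_parameters()
  ow <- run_owsa(ps, sched)
  expect_s3_class(ow, "owsa_result")
  expect_true(all(diff(ow$spread) <= 1e-9))
  # inputs are the declared bounds
  i <- match("cost_genetic_testing", ow$parameter)
  expect_equal(c(ow$low_input[i], ow$high_input[i]), c(861.2, 1291.8))
  # a costlier assay can only worsen the ratio
  expect_gt(ow$icer_at_high[i], ow$icer_at_low[i])
})

test_that("collapsing every range onto base reproduces the base-case ICER", {
  ps <- collapse_ranges(default_parameters())
  base_icer <- run_base_case(ps, sched)$icer
  ow <- run_owsa(ps, sched)
  expect_true(all(abs(ow$icer_at_low - base_icer) < 1e-9))
  expect_true(all(abs(ow$icer_at_high - base_icer) < 1e-9))
})

test_that("triangular draws respect their support and mean", {
  withr::with_seed(99, {
    x <- pgxcea:::rtriangular(10000, 0.1163, 0.1219, 0.1276)
    expect_true(all(x >= 0.1163 & x <= 0.1276))
    tri_mean <- (0.1163 + 0.1219 + 0.1276) / 3
    expect_lt(abs(mean(x) - tri_mean), 3 * sd(x) / sqrt(length(x)))
  })
})

test_that("parameter sampling honours distribution tags and bounds", {
  ps <- collapse_ranges(default_parameters(), fix = TRUE)
  withr::with_seed(1, expect_equal(param_values(sample_parameter_set(ps)),
                                   param_values(ps)))
  ps2 <- default_parameters()
  withr::with_seed(2, {
    for (i in 1:20) {
      drawn <- sample_parameter_set(ps2)
      expect_length(validate_parameters(drawn), 0)
      for (nm in names(drawn$specs)) {
        sp <- drawn$specs[[nm]]
        ref <- ps2$specs[[nm]]
        expect_gte(sp$base, ref$low)
        expect_lte(sp$base, ref$high)
      }
    }
  })
  # discount rates are not part of the probabilistic draw
  withr::with_seed(3, {
    drawn <- sample_parameter_set(ps2)
    expect_equal(drawn$specs[["discount_cost"]]$base, 0.03)
    expect_equal(drawn$specs[["discount_outcome"]]$base, 0.03)
  })
})

test_that("PSA is reproducible under a fixed seed and collapses to base", {
  ps <- default_parameters()
  p1 <- run_psa(ps, n = 30, seed = 123, schedule = sched)
  p2 <- run_psa(ps, n = 30, seed = 123, schedule = sched)
  expect_identical(p1$samples, p2$samples)

  fixed <- collapse_ranges(ps, fix = TRUE)
  p3 <- run_psa(fixed, n = 1, seed = 5, schedule = sched)
  base <- run_base_case(ps, sched)
  expect_equal(p3$samples$d_cost, base$d_cost)
  expect_equal(p3$samples$d_qaly, base$d_qaly)
})

test_that("acceptability curve limits: cost-saving fraction and QALY fraction", {
  ps <- default_parameters()
  psa <- run_psa(ps, n = 200, seed = 11, schedule = sched)
  cc <- ceac(psa, c(0, 72100, 1e12))
  expect_equal(cc$probability[1], mean(psa$samples$d_cost < 0))
  expect_equal(cc$probability[3], mean(psa$samples$d_qaly > 0))
  # monotone in WTP when every sampled increment gains QALYs
  pos <- psa$samples$d_qaly > 0
  sub <- psa
  sub$samples <- psa$samples[pos, ]
  grid <- seq(0, 250000, by = 12500)
  expect_true(all(diff(ceac(sub, grid)$probability) >= 0))
})

test_that("scatter mean sits near the base point for symmetric distributions", {
  ps <- collapse_ranges(default_parameters(), fix = TRUE)
  sym <- c(cost_genetic_testing = 150, cost_annual_mrs02 = 1500,
           cost_annual_mrs35 = 1500, utility_mrs34 = 0.05)
  for (nm in names(sym)) {
    sp <- ps$specs[[nm]]
    sp$low <- sp$base - sym[[nm]]; sp$high <- sp$base + sym[[nm]]
    sp$dist <- "triangular"
    ps$specs[[nm]] <- sp
  }
  psa <- run_psa(ps, n = 400, seed = 21, schedule = sched)
  base <- run_base_case(ps, sched)
  se_c <- sd(psa$samples$d_cost) / sqrt(nrow(psa$samples))
  se_q <- sd(psa$samples$d_qaly) / sqrt(nrow(psa$samples))
  expect_lt(abs(mean(psa$samples$d_cost) - base$d_cost), 3 * se_c)
  expect_lt(abs(mean(psa$samples$d_qaly) - base$d_qaly),
            3 * se_q + 1e-12)
})
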