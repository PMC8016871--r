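test_that("90-day fraction of one-year events: trial values and limits", {
  expect_equal(round(proportion_within_90d(0.083, 0.103), 3), 0.806)
  expect_equal(proportion_within_90d(0.07, 0.07), 1)
  expect_equal(proportion_within_90d(0.05, 0.10), 0.5)
  expect_error(proportion_within_90d(0.2, 0.1), "inconsistent")
})

test_that("hazard ratios act multiplicatively on 90-day probabilities", {
  expect_equal(round(apply_hazard_ratio(0.0932, 0.78), 4), 0.0727)
  p <- c(0, 0.3, 1)
  expect_equal(apply_hazard_ratio(p, 1), p)
  expect_equal(apply_hazard_ratio(0, 0.5), 0)
  expect_error(apply_hazard_ratio(0.9, 1.2), "exceeds 1")
})

test_that("disability-rate adjustment follows the reallocation formula", {
  # C = 0: nobody switched, no adjustment
  expect_equal(adjusted_disability_rate(0.0527, 0.78, 0), 0.0527)
  expect_equal(adjusted_disability_rate(0, 0.78, 0.37), 0)
  # direct arithmetic: (0.0527 * (0.78 - 0.37) / 0.78) * (1 - 0.37)
  expect_equal(adjusted_disability_rate(0.0527, 0.78, 0.37), 0.01745181,
               tolerance = 1e-6)
  # alternative parenthesization is a different, selectable policy
  expect_equal(adjusted_disability_rate(0.0527, 0.78, 0.37, policy = "ratio"),
               0.0527 * ((0.78 - 0.37) / 0.78) / 0.63, tolerance = 1e-12)
  # B < C drives the adjusted rate negative: incompatible inputs
  expect_error(adjusted_disability_rate(0.5, 0.3, 0.4), "incompatible")
})

test_that("subgroup mixing is a proportion-weighted mean", {
  ps <- default_parameters()
  # single pooled subgroup: risks pass through unchanged
  nt <- mix_subgroups(strategy_arm("no_testing", ps))
  expect_equal(nt$recurrence_90d, 0.082)
  # mixture of equal risks is that risk
  eq <- ps
  for (nm in c("rec90_noncarrier", "rec90_carrier_high", "rec90_carrier_low"))
    eq <- set_param(eq, nm, 0.08)
  expect_equal(mix_subgroups(strategy_arm("genetic_testing", eq))$recurrence_90d,
               0.08)
  # weighted mean with the default split
  gt <- mix_subgroups(strategy_arm("genetic_testing", ps))
  expect_equal(gt$recurrence_90d,
               0.41 * 0.0717 + 0.22 * 0.0871 + 0.37 * 0.0727)
  # MI/ECH risks are common across subgroups
  expect_equal(gt$ech_90d, nt$ech_90d)
  expect_equal(gt$mi_90d, nt$mi_90d)
})

test_that("printed 90-day distributions are reproduced and conserve mass", {
  ps <- default_parameters()
  g <- ninety_day_distribution("genetic_testing", ps)
  expect_equal(as.numeric(g), c(0.9506, 0.0404, 0.0054, 0.0036),
               tolerance = 1e-12)
  n <- ninety_day_distribution("no_testing", ps)
  expect_equal(as.numeric(n), c(0.9376, 0.0527, 0.0058, 0.0039),
               tolerance = 1e-12)
  expect_equal(sum(g), 1)
  expect_equal(sum(n), 1)
  # distribution advantage of guided therapy, as observed
  expect_gte(g[["minor"]], n[["minor"]])
})

test_that("derived mode reproduces the pooled no-testing distribution", {
  ps <- default_parameters()
  d <- ninety_day_distribution("no_testing", ps, mode = "derived")
  p <- ninety_day_distribution("no_testing", ps, mode = "printed")
  expect_lt(max(abs(as.numeric(d) - as.numeric(p))), 0.005)
})

test_that("mass conservation and recurrence monotonicity hold over random sets", {
  for (seed in 1:10) {
    ps <- random_ps(seed)
    for (arm in c("genetic_testing", "no_testing")) {
      for (mode in c("printed", "derived"))
        expect_equal(sum(ninety_day_distribution(arm, ps, mode)), 1,
                     tolerance = 1e-9)
    }
    # raising one subgroup's 90-day recurrence never raises derived p_minor
    before <- ninety_day_distribution("genetic_testing", ps,
                                      mode = "derived")[["minor"]]
    bumped <- set_param(ps, "rec90_carrier_high",
                        min(1, ps$specs[["rec90_carrier_high"]]$base + 0.01))
    after <- ninety_day_distribution("genetic_testing", bumped,
                                     mode = "derived")[["minor"]]
    expect_lte(after, before)
  }
})

test_that("90-day costs and QALYs reduce to closed forms in degenerate cases", {
  # no events: cost is the 90-day therapy price alone
  ps0 <- zero_event_ps()
  out <- ninety_day_outcome("no_testing", ps0)
  expect_equal(out$cost_90d, 490.45)

  # the assay cost enters the tested arm additively
  ps <- default_parameters()
  with_test <- ninety_day_outcome("genetic_testing", ps)
  no_test_cost <- ninety_day_outcome("genetic_testing",
                                     set_param(ps, "cost_genetic_testing", 0))
  expect_equal(with_test$cost_90d - no_test_cost$cost_90d, 1076.5)

  # all-survivor all-minor outcome: utility x 90/365.25 years
  out2 <- ninety_day_outcome("no_testing", all_minor_ps())
  expect_equal(out2$qaly_90d, 0.75 * 90 / 365.25, tolerance = 1e-12)
  expect_lte(out2$qaly_90d, 90 / 365)
})
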