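cp_zero <- list(recurrence = 0, death_on_recurrence = 0, ech_rate = 0,
                ech_fatality = 0, mi_rate = 0, mi_fatality = 0,
                nonstroke_death = 0)

test_that("discount factors", {
  expect_equal(discount_factor(0.03, 0), 1)
  expect_equal(discount_factor(0.03, 1), 1 / 1.03)
  expect_equal(discount_factor(0, 0:10), rep(1, 11))
})

test_that("recurrence grows multiplicatively per cycle", {
  expect_equal(recurrence_at_cycle(0.1219, 1.017, 1), 0.1219)
  expect_equal(recurrence_at_cycle(0.1219, 1.017, 2), 0.1219 * 1.017)
  expect_equal(recurrence_at_cycle(0.07, 1, 1:30), rep(0.07, 30))
  expect_error(recurrence_at_cycle(0.9, 2, 3), "exceeds 1")
})

test_that("survivors are reallocated to equal-and-greater disability states", {
  expect_equal(redistribute_survivors("minor", 0.09), c(0.03, 0.03, 0.03, 0))
  expect_equal(redistribute_survivors("moderate", 0.10), c(0, 0.05, 0.05, 0))
  expect_equal(redistribute_survivors("severe", 0.2), c(0, 0, 0.2, 0))
  expect_error(redistribute_survivors("dead", 0.1))
})

test_that("cycle transition: identity, absorbing death, branch-tree example", {
  s <- c(0.6, 0.25, 0.1, 0.05)
  expect_equal(as.numeric(cycle_transition(s, cp_zero)$state), s)

  dead <- c(0, 0, 0, 1)
  cp <- cp_zero; cp$recurrence <- 0.3; cp$nonstroke_death <- 0.2
  expect_equal(as.numeric(cycle_transition(dead, cp)$state), dead)

  # enumerated branch tree from all-minor: recurrence 0.10, fatality 0.20
  cp2 <- cp_zero; cp2$recurrence <- 0.10; cp2$death_on_recurrence <- 0.20
  out <- cycle_transition(c(1, 0, 0, 0), cp2)
  expect_equal(as.numeric(out$state),
               c(0.90 + 0.08 / 3, 0.08 / 3, 0.08 / 3, 0.02),
               tolerance = 1e-12)
  expect_equal(out$events$recurrence, 0.10)
  expect_equal(out$events$recurrence_fatal, 0.02)
})

test_that("mass is conserved and death is monotone for random parameters", {
  withr::with_seed(42, {
    for (i in 1:25) {
      s <- runif(4); s <- s / sum(s)
      cp <- list(recurrence = runif(1, 0, 0.5),
                 death_on_recurrence = runif(1),
                 ech_rate = runif(1, 0, 0.1), ech_fatality = runif(1),
                 mi_rate = runif(1, 0, 0.1), mi_fatality = runif(1),
                 nonstroke_death = runif(1, 0, 0.3))
      cur <- s
      for (t in 1:5) {
        nxt <- cycle_transition(cur, cp)$state
        expect_equal(sum(nxt), 1, tolerance = 1e-9)
        expect_gte(nxt[["dead"]], cur[4] - 1e-12)
        cur <- as.numeric(nxt)
      }
    }
  })
})

test_that("cycle costs compose additively from care and event components", {
  pv <- param_values(default_parameters())
  minor <- c(1, 0, 0, 0)
  ev0 <- list(recurrence = 0, recurrence_fatal = 0, recurrence_to_minor = 0,
              ech = 0, mi = 0, ech_nonfatal = c(0, 0, 0),
              mi_nonfatal = c(0, 0, 0))
  expect_equal(cycle_cost(minor, ev0, pv), 8767.42)
  expect_equal(cycle_cost(c(0, 0, 0, 1), ev0, pv), 0)
  ev_mi <- ev0; ev_mi$mi <- 1; ev_mi$mi_nonfatal <- c(1, 0, 0)
  expect_equal(cycle_cost(minor, ev_mi, pv), 8767.42 + 21276.20)
})

test_that("cycle QALYs apply temporary-episode disutilities multiplicatively", {
  pv <- param_values(default_parameters())
  minor <- c(1, 0, 0, 0)
  ev0 <- list(recurrence = 0, recurrence_fatal = 0, recurrence_to_minor = 0,
              ech = 0, mi = 0, ech_nonfatal = c(0, 0, 0),
              mi_nonfatal = c(0, 0, 0))
  expect_equal(cycle_qaly(minor, ev0, pv), 0.75)
  expect_equal(cycle_qaly(c(0, 0, 0, 1), ev0, pv), 0)
  ev_mi <- ev0; ev_mi$mi <- 1; ev_mi$mi_nonfatal <- c(1, 0, 0)
  expect_equal(cycle_qaly(minor, ev_mi, pv),
               0.75 - (30 / 365.25) * 0.75 * (1 - 0.84), tolerance = 1e-12)
  expect_equal(cycle_qaly(minor, ev_mi, pv), 0.7401437, tolerance = 1e-6)
})

test_that("markov run: degenerate horizons, absorbing seed, discount ordering", {
  ps <- default_parameters()
  sched <- zero_schedule()
  seed <- state_distribution(0.9, 0.06, 0.03, 0.01)

  h0 <- run_markov(seed, ps, sched, horizon = 0)
  expect_equal(h0$cost, 0)
  expect_equal(h0$qaly, 0)
  expect_equal(nrow(h0$trace), 1L)

  dead <- state_distribution(0, 0, 0, 1)
  all_dead <- run_markov(dead, ps, sched)
  expect_equal(all_dead$cost, 0)
  expect_equal(all_dead$qaly, 0)

  r0 <- run_markov(seed, set_param(set_param(ps, "discount_cost", 0),
                                   "discount_outcome", 0), sched)
  r3 <- run_markov(seed, ps, sched)
  expect_lt(r3$qaly, r0$qaly)
  expect_lt(r3$cost, r0$cost)
  expect_equal(r3$undisc_qaly, r0$undisc_qaly)

  expect_error(run_markov(seed, ps, zero_schedule(10)), "shorter")
})

test_that("zero-event limit matches the closed-form annuity to 1e-9", {
  seed <- state_distribution(1, 0, 0, 0)
  sched <- zero_schedule()

  r0 <- run_markov(seed, all_minor_ps(discount = 0), sched)
  expect_equal(r0$undisc_qaly, 30 * 0.75, tolerance = 1e-9)

  r3 <- run_markov(seed, all_minor_ps(discount = 0.03), sched)
  expect_equal(r3$qaly, sum(0.75 * 1.03^-(1:30)), tolerance = 1e-9)
})

test_that("raising utilities raises QALYs; raising costs raises costs", {
  ps <- default_parameters()
  sched <- default_schedule()
  seed <- ninety_day_distribution("no_testing", ps)
  base <- run_markov(seed, ps, sched)
  for (nm in c("utility_mrs02", "utility_mrs34", "utility_mrs5")) {
    up <- run_markov(seed, set_param(ps, nm,
                                     min(1, ps$specs[[nm]]$base + 0.05)),
                     sched)
    expect_gte(up$qaly, base$qaly)
  }
  for (nm in c("cost_annual_mrs02", "cost_annual_mrs35",
               "cost_hosp_ischemic_mrs36", "cost_hosp_mi")) {
    up <- run_markov(seed, set_param(ps, nm, ps$specs[[nm]]$base * 1.1),
                     sched)
    expect_gte(up$cost, base$cost)
  }
})
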