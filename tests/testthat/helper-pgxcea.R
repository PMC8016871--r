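# shared fixtures, built in code

# parameter set with every stochastic event switched off (used for
# closed-form limits); discount rates configurable
zero_event_ps <- function(discount = 0) {
  ps <- default_parameters()
  for (nm in c("annual_recurrence_rate", "ech_rate_annual", "mi_rate_annual",
               "rec90_no_testing", "rec90_noncarrier", "rec90_carrier_high",
               "rec90_carrier_low", "ech_90d", "mi_90d"))
    ps <- set_param(ps, nm, 0)
  ps <- set_param(ps, "discount_cost", discount)
  ps <- set_param(ps, "discount_outcome", discount)
  ps
}

# all-survivor, all-minor 90-day outcome for the no-testing arm
all_minor_ps <- function(...) {
  ps <- zero_event_ps(...)
  ps <- set_param(ps, "p90_minor_no_testing", 1)
  ps <- set_param(ps, "p90_minor_genetic", 1)
  ps
}

zero_schedule <- function(horizon = 30) mortality_schedule(rep(0, horizon))

# a randomized valid parameter set (draws stay inside each printed range)
random_ps <- function(seed) {
  withr::with_seed(seed, sample_parameter_set(default_parameters()))
}

# collapse every parameter's range onto its base value
collapse_ranges <- function(ps, fix = FALSE) {
  for (nm in names(ps$specs)) {
    ps$specs[[nm]]$low <- ps$specs[[nm]]$base
    ps$specs[[nm]]$high <- ps$specs[[nm]]$base
    if (fix) ps$specs[[nm]]$dist <- "fixed"
  }
  ps
}
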