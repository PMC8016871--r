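#' Four-state health-state distribution
#'
#' Probability mass over the modified-Rankin-Scale bands used by the model:
#' minor/no disability (mRS 0-2), moderate disability (mRS 3-4), severe
#' disability (mRS 5) and death (mRS 6).
#'
#' @param minor,moderate,severe,dead Non-negative masses summing to 1
#'   (within 1e-9).
#' @return A named numeric vector of class `state_distribution`.
#' @export
state_distribution <- function(minor, moderate, severe, dead) {
  x <- c(minor = minor, moderate = moderate, severe = severe, dead = dead)
  if (any(x < -1e-12))
    stop("state distribution has negative mass", call. = FALSE)
  if (abs(sum(x) - 1) > 1e-9)
    stop(sprintf("state distribution sums to %.12f, not 1", sum(x)),
         call. = FALSE)
  structure(pmax(x, 0), class = "state_distribution")
}

#' Fraction of one-year events falling within the first 90 days
#'
#' Given a 90-day and a one-year cumulative risk of the same event, returns
#' the share of first-year events that occur within 90 days. With the trial's
#' clopidogrel-aspirin recurrence risks (0.083 at 90 days, 0.103 at one year)
#' this is 0.806.
#'
#' @param rate_90d 90-day cumulative probability, in (0, 1].
#' @param rate_1y One-year cumulative probability, `>= rate_90d`.
#' @return `rate_90d / rate_1y`.
#' @export
proportion_within_90d <- function(rate_90d, rate_1y) {
  if (any(rate_90d <= 0) || any(rate_1y > 1))
    stop("rates must satisfy 0 < rate_90d and rate_1y <= 1", call. = FALSE)
  if (any(rate_90d > rate_1y))
    stop("rate_90d > rate_1y: inconsistent inputs", call. = FALSE)
  rate_90d / rate_1y
}

#' Apply a hazard ratio on the 90-day probability scale
#'
#' The model applies treatment hazard ratios multiplicatively to short-horizon
#' probabilities (e.g. 0.0932 x 0.78 = 0.0727 for dipyridamole-aspirin versus
#' aspirin monotherapy), a close approximation at these event rates.
#'
#' @param p Baseline probability in \[0, 1\].
#' @param hr Positive hazard ratio.
#' @return `p * hr`.
#' @export
apply_hazard_ratio <- function(p, hr) {
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]", call. = FALSE)
  if (any(hr <= 0)) stop("hr must be positive", call. = FALSE)
  out <- p * hr
  if (any(out > 1))
    stop("p * hr exceeds 1: invalid combination", call. = FALSE)
  out
}

#' Moderate-disability rate after reallocating non-benefiting patients
#'
#' Adjusts the 90-day moderate-disability rate of the untested cohort for a
#' strategy in which the share `C` of patients who cannot benefit from
#' clopidogrel-aspirin (LoFA carriers with ESRS < 3) are switched to an
#' alternative therapy, with `B` the relative disability rate under dual
#' therapy versus aspirin.
#'
#' The printed formula `A*(B - C)/B*(1 - C)` is typographically ambiguous;
#' the default `policy = "left_to_right"` evaluates
#' `(A * (B - C) / B) * (1 - C)`, and `policy = "ratio"` evaluates
#' `A * ((B - C) / B) / (1 - C)`.
#'
#' @param A Moderate-disability rate in the untested group.
#' @param B Relative disability-rate ratio (DAPT vs aspirin), in (0, 1].
#' @param C Proportion of patients switched away from DAPT, in \[0, 1).
#' @param policy Parenthesization policy; see Details.
#' @return Adjusted disability rate, checked to lie in \[0, 1\].
#' @export
adjusted_disability_rate <- function(A, B, C,
                                     policy = c("left_to_right", "ratio")) {
  policy <- match.arg(policy)
  stopifnot(A >= 0, A <= 1, B > 0, C >= 0, C < 1)
  out <- switch(policy,
    left_to_right = (A * (B - C) / B) * (1 - C),
    ratio = A * ((B - C) / B) / (1 - C)
  )
  if (out < 0 || out > 1)
    stop("adjusted disability rate outside [0, 1]: incompatible inputs",
         call. = FALSE)
  out
}

#' Build a strategy arm of the 90-day decision tree
#'
#' The genetic-testing arm holds three genotype/ESRS subgroups (noncarriers
#' and high-ESRS carriers on clopidogrel-aspirin; low-ESRS carriers switched
#' to dipyridamole-aspirin). The no-testing arm is a single pooled subgroup on
#' clopidogrel-aspirin.
#'
#' @param name `"genetic_testing"` or `"no_testing"`.
#' @param ps A `parameter_set`.
#' @return A list of class `strategy_arm` with a `subgroups` data.frame
#'   (label, proportion, therapy, recurrence_90d, ich_prop, ech_90d, mi_90d).
#' @export
strategy_arm <- function(name = c("genetic_testing", "no_testing"), ps) {
  name <- match.arg(name)
  pv <- param_values(ps)
  sub <- if (name == "genetic_testing") {
    data.frame(
      label = c("noncarrier", "carrier_high_esrs", "carrier_low_esrs"),
      proportion = unname(pv[c("prop_noncarrier", "prop_carrier_high_esrs",
                               "prop_carrier_low_esrs")]),
      therapy = c("clopidogrel_aspirin", "clopidogrel_aspirin",
                  "dipyridamole_aspirin"),
      recurrence_90d = unname(pv[c("rec90_noncarrier", "rec90_carrier_high",
                                   "rec90_carrier_low")]),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(label = "pooled", proportion = 1,
               therapy = "clopidogrel_aspirin",
               recurrence_90d = unname(pv["rec90_no_testing"]),
               stringsAsFactors = FALSE)
  }
  # MI and major-ECH short-term risks are common to all subgroups
  sub$ich_prop <- pv[["prop_ich_90d"]]
  sub$ech_90d <- pv[["ech_90d"]]
  sub$mi_90d <- pv[["mi_90d"]]
  if (abs(sum(sub$proportion) - 1) > 1e-9)
    stop("subgroup proportions do not sum to 1", call. = FALSE)
  structure(list(name = name, subgroups = sub), class = "strategy_arm")
}

#' Pool subgroup event risks of a strategy arm
#'
#' Proportion-weighted mean of each 90-day event risk across the arm's
#' subgroups.
#'
#' @param arm A `strategy_arm`.
#' @return Named list: `recurrence_90d`, `ich_prop`, `ech_90d`, `mi_90d`,
#'   `drug_weight` (named therapy weights).
#' @export
mix_subgroups <- function(arm) {
  stopifnot(inherits(arm, "strategy_arm"))
  sub <- arm$subgroups
  if (abs(sum(sub$proportion) - 1) > 1e-9)
    stop("subgroup proportions do not sum to 1", call. = FALSE)
  wmean <- function(x) sum(sub$proportion * x)
  dw <- tapply(sub$proportion, sub$therapy, sum)
  list(recurrence_90d = wmean(sub$recurrence_90d),
       ich_prop = wmean(sub$ich_prop),
       ech_90d = wmean(sub$ech_90d),
       mi_90d = wmean(sub$mi_90d),
       drug_weight = dw)
}

#' 90-day health-state distribution of a strategy arm
#'
#' `mode = "printed"` (default) returns the observed 90-day mRS distribution
#' for the arm, taken from the parameter set (`p90_*`): the minor/no-disability
#' proportion is the sampled/overridden `p90_minor_*` value, the 90-day death
#' proportion is held at its own parameter value, and the remaining mass is
#' split across moderate and severe disability in their base-case ratio.
#' Holding death fixed keeps uncertainty in the *disability mix* from leaking
#' into observed 90-day mortality (otherwise a sensitivity run on the
#' disability proportion also perturbs survival, and the incremental QALY can
#' degenerate through zero). `mode = "derived"` reconstructs the
#' distribution from subgroup
#' recurrence risks and the disability-rate adjustment
#' ([adjusted_disability_rate()]); it is a secondary pathway used for
#' cross-checking.
#'
#' @param arm A `strategy_arm` or an arm name.
#' @param ps A `parameter_set`.
#' @param mode `"printed"` or `"derived"`.
#' @return A [state_distribution()].
#' @export
ninety_day_distribution <- function(arm, ps, mode = c("printed", "derived")) {
  mode <- match.arg(mode)
  if (is.character(arm)) arm <- strategy_arm(arm, ps)
  pv <- param_values(ps)
  key <- if (arm$name == "genetic_testing") "genetic" else "no_testing"
  if (mode == "printed") {
    p_minor <- pv[[paste0("p90_minor_", key)]]
    # death held at its own parameter, squeezed only if p_minor leaves no room
    p_dead <- min(pv[[paste0("p90_death_", key)]], 1 - p_minor)
    dis <- pv[paste0("p90_", c("moderate", "severe"), "_", key)]
    dis <- dis / sum(dis) * (1 - p_minor - p_dead)
    state_distribution(p_minor, dis[[1]], dis[[2]], p_dead)
  } else {
    mixed <- mix_subgroups(arm)
    r_ref <- pv[["rec90_no_testing"]]
    C <- if (arm$name == "genetic_testing") pv[["prop_carrier_low_esrs"]] else 0
    moderate <- adjusted_disability_rate(pv[["p90_moderate_no_testing"]],
                                         pv[["disability_rr_dapt"]], C)
    scale <- mixed$recurrence_90d / r_ref
    severe <- pv[["p90_severe_no_testing"]] * scale
    dead <- pv[["p90_death_no_testing"]] * scale
    state_distribution(1 - moderate - severe - dead, moderate, severe, dead)
  }
}

#' 90-day costs and QALYs of a strategy arm
#'
#' Cost: genotyping assay (genetic arm only) + proportion-weighted 90-day
#' drug price + expected event hospitalization costs. Recurrent strokes are
#' split ischemic/ICH by the 90-day ICH share and costed by the resulting mRS
#' band; the share of recurrences ending in mRS 3-6 is inferred from the
#' arm's 90-day distribution (all disability/death is attributed to
#' recurrence, since MI and ECH do not change disability status). ECH and MI
#' events are costed at their one-time hospitalization prices.
#'
#' QALYs: utility-weighted 90/365.25 years under the arm's 90-day
#' distribution, minus temporary-episode disutilities (2 weeks at the major
#' ECH episode utility, 30 days at the MI episode utility, multiplicative on
#' the state utility, for the nonfatal share of each event).
#'
#' @param arm A `strategy_arm` or an arm name.
#' @param ps A `parameter_set`.
#' @param mode Passed to [ninety_day_distribution()].
#' @return List of class `ninety_day_outcome`: `distribution`, `cost_90d`,
#'   `qaly_90d`, `events` (expected per-patient event masses).
#' @export
ninety_day_outcome <- function(arm, ps, mode = c("printed", "derived")) {
  mode <- match.arg(mode)
  if (is.character(arm)) arm <- strategy_arm(arm, ps)
  pv <- param_values(ps)
  mixed <- mix_subgroups(arm)
  dist <- ninety_day_distribution(arm, ps, mode)

  drug_price <- c(clopidogrel_aspirin = pv[["cost_drug_clop_asp_90d"]],
                  dipyridamole_aspirin = pv[["cost_drug_dipy_asp_90d"]])
  drug_cost <- sum(mixed$drug_weight *
                     drug_price[names(mixed$drug_weight)])
  test_cost <- if (arm$name == "genetic_testing") pv[["cost_genetic_testing"]] else 0

  r <- mixed$recurrence_90d
  frac36 <- if (r > 0) min(1, (1 - dist[["minor"]]) / r) else 0
  ich <- mixed$ich_prop
  hosp02 <- (1 - ich) * pv[["cost_hosp_ischemic_mrs02"]] +
    ich * pv[["cost_hosp_ich_mrs02"]]
  hosp36 <- (1 - ich) * pv[["cost_hosp_ischemic_mrs36"]] +
    ich * pv[["cost_hosp_ich_mrs36"]]
  event_cost <- r * ((1 - frac36) * hosp02 + frac36 * hosp36) +
    mixed$ech_90d * pv[["cost_hosp_ech"]] +
    mixed$mi_90d * pv[["cost_hosp_mi"]]

  u <- c(pv[["utility_mrs02"]], pv[["utility_mrs34"]], pv[["utility_mrs5"]],
         pv[["utility_death"]])
  qaly <- sum(dist * u) * (90 / 365.25)
  # temporary-episode disutility, booked against the entry-state (mRS 0-2)
  # utility: every patient enters the tree with minor/no disability
  qaly <- qaly -
    mixed$ech_90d * (1 - pv[["ech_fatality"]]) * (14 / 365.25) *
      u[1] * (1 - pv[["utility_ech"]]) -
    mixed$mi_90d * (1 - pv[["mi_fatality"]]) * (30 / 365.25) *
      u[1] * (1 - pv[["utility_mi"]])

  structure(
    list(arm = arm$name, distribution = dist,
         cost_90d = test_cost + drug_cost + event_cost,
         qaly_90d = qaly,
         events = c(recurrence = r, recurrence_mrs36 = r * frac36,
                    ech = mixed$ech_90d, mi = mixed$mi_90d)),
    class = "ninety_day_outcome"
  )
}
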