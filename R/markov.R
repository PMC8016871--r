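#' Discount factor
#'
#' @param r Annual discount rate, `>= 0`.
#' @param t Cycle index, `>= 0`.
#' @return `(1 + r)^(-t)`.
#' @export
discount_factor <- function(r, t) {
  stopifnot(all(r >= 0), all(t >= 0))
  (1 + r)^(-t)
}

#' Recurrence probability at a given cycle
#'
#' The annual stroke-recurrence probability grows multiplicatively with time
#' since the index event: `base_rate * rr^(t - 1)` at cycle `t` (cycle 1 is
#' the first post-90-day year and returns `base_rate`).
#'
#' @param base_rate First-cycle annual recurrence probability.
#' @param rr_per_year Yearly relative risk (default model value 1.017).
#' @param t Cycle index, `>= 1`.
#' @return Recurrence probability at cycle `t`; errors if it exceeds 1.
#' @export
recurrence_at_cycle <- function(base_rate, rr_per_year, t) {
  stopifnot(all(t >= 1))
  out <- base_rate * rr_per_year^(t - 1)
  if (any(out > 1))
    stop("recurrence probability exceeds 1 at cycle ", min(t[out > 1]),
         call. = FALSE)
  out
}

#' Redistribute survivors of a recurrent stroke
#'
#' Survivors of a recurrence are reallocated equally among the disability
#' states of equal and greater severity: from minor/no disability the mass is
#' split 1/3 each to minor, moderate and severe; from moderate, 1/2 each to
#' moderate and severe; from severe, all stays severe.
#'
#' @param origin `"minor"`, `"moderate"` or `"severe"`.
#' @param survivor_mass Probability mass of surviving recurrences.
#' @return Numeric vector of length 4 (minor, moderate, severe, dead).
#' @export
redistribute_survivors <- function(origin = c("minor", "moderate", "severe"),
                                   survivor_mass) {
  origin <- match.arg(origin)
  stopifnot(survivor_mass >= 0)
  switch(origin,
    minor = c(survivor_mass / 3, survivor_mass / 3, survivor_mass / 3, 0),
    moderate = c(0, survivor_mass / 2, survivor_mass / 2, 0),
    severe = c(0, 0, survivor_mass, 0)
  )
}

# Redistribution matrix: row = origin alive state, column = destination state.
REDISTRIBUTION <- rbind(minor = c(1, 1, 1, 0) / 3,
                        moderate = c(0, 1, 1, 0) / 2,
                        severe = c(0, 0, 1, 0))

#' One annual Markov cycle
#'
#' Applies the cycle's competing risks to each alive state as mutually
#' exclusive branches, in order, each on the residual mass of the previous:
#' recurrent stroke (fatal with probability `death_on_recurrence`, survivors
#' redistributed per [redistribute_survivors()]), major ECH (fatal with
#' `ech_fatality`, nonfatal episodes stay in state), MI (fatal with
#' `mi_fatality`), then non-stroke death. Death is absorbing.
#'
#' @param state Numeric length-4 state distribution (minor, moderate, severe,
#'   dead) at cycle start.
#' @param cp Named list of cycle parameters: `recurrence`,
#'   `death_on_recurrence`, `ech_rate`, `ech_fatality`, `mi_rate`,
#'   `mi_fatality`, `nonstroke_death`.
#' @return List: `state` (end-of-cycle distribution) and `events`, a list of
#'   per-origin-state expected masses (`recurrence`, `recurrence_fatal`,
#'   `recurrence_to_minor`, `ech_nonfatal`, `mi_nonfatal`, totals `ech`,
#'   `mi`).
#' @export
cycle_transition <- function(state, cp) {
  stopifnot(length(state) == 4L, all(state >= -1e-12))
  x <- pmax(as.numeric(state), 0)[1:3]             # alive states
  if (abs(sum(state) - 1) > 1e-9)
    stop("state mass does not sum to 1", call. = FALSE)

  rec <- cp$recurrence * x
  if (cp$recurrence > 1)
    stop("recurrence branch probability exceeds 1", call. = FALSE)
  rec_fatal <- rec * cp$death_on_recurrence
  rec_surv <- rec - rec_fatal
  resid <- x - rec
  ech <- resid * cp$ech_rate
  ech_fatal <- ech * cp$ech_fatality
  resid <- resid - ech
  mi <- resid * cp$mi_rate
  mi_fatal <- mi * cp$mi_fatality
  resid <- resid - mi
  ns_death <- resid * cp$nonstroke_death
  stay <- resid - ns_death + (ech - ech_fatal) + (mi - mi_fatal)

  out <- c(stay, state[4]) + drop(rec_surv %*% REDISTRIBUTION)
  out[4] <- out[4] + sum(rec_fatal) + sum(ech_fatal) + sum(mi_fatal) +
    sum(ns_death)
  if (abs(sum(out) - 1) > 1e-9)
    stop("internal error: state mass not conserved", call. = FALSE)

  list(
    state = structure(stats::setNames(out, c("minor", "moderate", "severe",
                                             "dead")),
                      class = "state_distribution"),
    events = list(recurrence = sum(rec),
                  recurrence_fatal = sum(rec_fatal),
                  recurrence_to_minor = rec_surv[1] / 3,
                  ech = sum(ech), mi = sum(mi),
                  ech_nonfatal = ech - ech_fatal,
                  mi_nonfatal = mi - mi_fatal)
  )
}

#' Cost accrued in one cycle
#'
#' Annual post-hospitalization care cost by end-of-cycle mRS band (mRS 0-2
#' versus mRS 3-5; the dead accrue nothing), plus one-time hospitalization
#' costs for the cycle's events: recurrent strokes split ischemic/ICH by the
#' long-term ICH share and costed by resulting band (survivors redistributed
#' to mRS 0-2 at the mRS 0-2 price; all other survivors and fatal recurrences
#' at the mRS 3-6 price), ECH and MI at their one-time prices.
#'
#' @param state_end End-of-cycle state distribution.
#' @param events Event masses as returned by [cycle_transition()].
#' @param pv Named numeric parameter values ([param_values()]).
#' @return Undiscounted cycle cost in CNY.
#' @export
cycle_cost <- function(state_end, events, pv) {
  annual <- state_end[[1]] * pv[["cost_annual_mrs02"]] +
    (state_end[[2]] + state_end[[3]]) * pv[["cost_annual_mrs35"]]
  ich <- pv[["prop_ich_recurrence"]]
  hosp02 <- (1 - ich) * pv[["cost_hosp_ischemic_mrs02"]] +
    ich * pv[["cost_hosp_ich_mrs02"]]
  hosp36 <- (1 - ich) * pv[["cost_hosp_ischemic_mrs36"]] +
    ich * pv[["cost_hosp_ich_mrs36"]]
  to_minor <- events$recurrence_to_minor
  annual + to_minor * hosp02 + (events$recurrence - to_minor) * hosp36 +
    events$ech * pv[["cost_hosp_ech"]] + events$mi * pv[["cost_hosp_mi"]]
}

#' Quality-adjusted life-years accrued in one cycle
#'
#' Utility-weighted end-of-cycle occupancy over one year, minus temporary
#' disutilities for nonfatal ECH (2 weeks) and MI (30 days) episodes: for the
#' episode duration the state utility is multiplied by the episode utility,
#' so the loss is `duration * u_state * (1 - u_episode)` per event.
#'
#' @inheritParams cycle_cost
#' @param state_start Start-of-cycle distribution (origin states for episode
#'   disutilities).
#' @return Undiscounted cycle QALYs.
#' @export
cycle_qaly <- function(state_end, events, pv, state_start = NULL) {
  u <- c(pv[["utility_mrs02"]], pv[["utility_mrs34"]], pv[["utility_mrs5"]])
  base <- sum(state_end[1:3] * u)
  dis <- sum(events$ech_nonfatal * u) * (14 / 365.25) *
    (1 - pv[["utility_ech"]]) +
    sum(events$mi_nonfatal * u) * (30 / 365.25) * (1 - pv[["utility_mi"]])
  base - dis
}

#' Run the 30-year Markov cohort projection
#'
#' Iterates [cycle_transition()] from the 90-day seed distribution for
#' `horizon` annual cycles, accruing per-cycle costs and QALYs discounted at
#' `(1 + r)^(-t)`. Cycle `t` uses recurrence
#' `annual_recurrence_rate * rr^(t-1)` and the `t`-th rate of the mortality
#' schedule. With half-cycle correction enabled, rewards are accrued on the
#' mean of start- and end-of-cycle occupancy.
#'
#' @param seed A [state_distribution()] seeding the model (the 90-day
#'   outcome distribution; any dead mass stays absorbed and accrues nothing).
#' @param ps A `parameter_set`.
#' @param schedule A [mortality_schedule()] at least as long as the horizon.
#' @param horizon Number of cycles; defaults to the structural setting.
#' @return A list of class `markov_trace`: `trace` data.frame (cycle, age,
#'   state masses, cost, disc_cost, qaly, disc_qaly) with cycle 0 holding the
#'   seed, and totals `cost`, `qaly`, `undisc_cost`, `undisc_qaly`.
#' @export
run_markov <- function(seed, ps, schedule, horizon = NULL) {
  pv <- param_values(ps)
  st <- ps$structural
  if (is.null(horizon)) horizon <- st$horizon_years
  if (horizon > length(schedule$rates))
    stop("mortality schedule shorter than horizon", call. = FALSE)
  rc <- pv[["discount_cost"]]
  ro <- pv[["discount_outcome"]]
  hcc <- st$half_cycle_correction

  cp <- list(death_on_recurrence = pv[["death_on_recurrence"]],
             ech_rate = pv[["ech_rate_annual"]],
             ech_fatality = pv[["ech_fatality"]],
             mi_rate = pv[["mi_rate_annual"]],
             mi_fatality = pv[["mi_fatality"]])

  n <- horizon + 1L
  states <- matrix(0, n, 4,
                   dimnames = list(NULL, c("minor", "moderate", "severe",
                                           "dead")))
  states[1L, ] <- as.numeric(seed)
  cost <- qaly <- dcost <- dqaly <- numeric(n)
  s <- as.numeric(seed)
  for (t in seq_len(horizon)) {
    r_t <- pv[["annual_recurrence_rate"]] *
      pv[["rr_recurrence_per_year"]]^(t - 1)
    if (r_t > 1) {
      warning("recurrence probability capped at 1 in cycle ", t)
      r_t <- 1
    }
    cp$recurrence <- r_t
    cp$nonstroke_death <- schedule$rates[t]
    step <- cycle_transition(s, cp)
    occ <- if (hcc) (s + as.numeric(step$state)) / 2 else
      as.numeric(step$state)
    c_t <- cycle_cost(occ, step$events, pv)
    q_t <- cycle_qaly(occ, step$events, pv)
    s <- as.numeric(step$state)
    states[t + 1L, ] <- s
    cost[t + 1L] <- c_t
    qaly[t + 1L] <- q_t
    dcost[t + 1L] <- c_t * discount_factor(rc, t)
    dqaly[t + 1L] <- q_t * discount_factor(ro, t)
  }
  trace <- data.frame(cycle = 0:horizon,
                      age = st$start_age + 0:horizon,
                      states, cost = cost, disc_cost = dcost,
                      qaly = qaly, disc_qaly = dqaly)
  structure(list(trace = trace,
                 cost = sum(dcost), qaly = sum(dqaly),
                 undisc_cost = sum(cost), undisc_qaly = sum(qaly)),
            class = "markov_trace")
}

#' @export
print.markov_trace <- function(x, ...) {
  h <- nrow(x$trace) - 1L
  cat(sprintf(paste0("<markov_trace> %d cycles | discounted cost %.2f CNY, ",
                     "%.4f QALYs | final survival %.4f\n"),
              h, x$cost, x$qaly, 1 - x$trace$dead[h + 1L]))
  invisible(x)
}

#' Write a per-cycle cohort trace as CSV
#'
#' @param trace A `markov_trace`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(trace$trace, path, row.names = FALSE)
  invisible(path)
}
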