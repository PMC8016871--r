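#' Individual-level microsimulation of one strategy arm
#'
#' Brute-force validation oracle for the cohort engine: simulates `n`
#' individuals through the identical event logic — a 90-day draw of outcome
#' state and (independently, as in the cohort expectation) of the 90-day
#' event branch, then per-cycle competing-risk draws in the same branch
#' order with the same redistribution rule, costs, utilities and
#' discounting. Means converge to the [run_strategy()] totals by
#' construction; standard errors quantify Monte-Carlo noise.
#'
#' @param arm `"genetic_testing"` or `"no_testing"`.
#' @param ps A `parameter_set`.
#' @param schedule A [mortality_schedule()].
#' @param n Number of simulated individuals.
#' @param seed Integer seed.
#' @param mode 90-day distribution mode.
#' @return List of class `microsim_result`: `mean_cost`, `mean_qaly`,
#'   `se_cost`, `se_qaly`, `n`, `arm`.
#' @export
run_microsim <- function(arm, ps, schedule = default_schedule(),
                         n = 10000L, seed = 1L,
                         mode = c("printed", "derived")) {
  mode <- match.arg(mode)
  stopifnot(n >= 1)
  pv <- param_values(ps)
  st <- ps$structural
  horizon <- st$horizon_years
  if (horizon > length(schedule$rates))
    stop("mortality schedule shorter than horizon", call. = FALSE)
  tree <- ninety_day_outcome(arm, ps, mode)
  mixed <- mix_subgroups(strategy_arm(arm, ps))
  u_state <- c(pv[["utility_mrs02"]], pv[["utility_mrs34"]],
               pv[["utility_mrs5"]], 0)
  rc <- pv[["discount_cost"]]; ro <- pv[["discount_outcome"]]

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  ## --- 90-day phase ---
  dist <- as.numeric(tree$distribution)
  state <- sample.int(4L, n, replace = TRUE, prob = dist)
  # fixed per-arm costs: assay + therapy (therapy drawn by subgroup weight)
  drug_price <- c(clopidogrel_aspirin = pv[["cost_drug_clop_asp_90d"]],
                  dipyridamole_aspirin = pv[["cost_drug_dipy_asp_90d"]])
  dw <- mixed$drug_weight
  therapy <- sample(names(dw), n, replace = TRUE, prob = as.numeric(dw))
  cost <- unname(drug_price[therapy]) +
    if (arm == "genetic_testing") pv[["cost_genetic_testing"]] else 0
  # mutually exclusive 90-day event branch
  r <- mixed$recurrence_90d
  ev <- stats::runif(n)
  had_rec <- ev < r
  had_ech <- !had_rec & ev < r + mixed$ech_90d
  had_mi <- !had_rec & !had_ech & ev < r + mixed$ech_90d + mixed$mi_90d
  frac36 <- if (r > 0) min(1, (1 - dist[1]) / r) else 0
  band36 <- had_rec & (stats::runif(n) < frac36)
  is_ich <- stats::runif(n) < mixed$ich_prop
  h02 <- ifelse(is_ich, pv[["cost_hosp_ich_mrs02"]],
                pv[["cost_hosp_ischemic_mrs02"]])
  h36 <- ifelse(is_ich, pv[["cost_hosp_ich_mrs36"]],
                pv[["cost_hosp_ischemic_mrs36"]])
  cost <- cost + had_rec * ifelse(band36, h36, h02) +
    had_ech * pv[["cost_hosp_ech"]] + had_mi * pv[["cost_hosp_mi"]]
  qaly <- u_state[state] * (90 / 365.25)
  ech_nonfatal <- had_ech & (stats::runif(n) >= pv[["ech_fatality"]])
  mi_nonfatal <- had_mi & (stats::runif(n) >= pv[["mi_fatality"]])
  qaly <- qaly -
    ech_nonfatal * (14 / 365.25) * u_state[1] * (1 - pv[["utility_ech"]]) -
    mi_nonfatal * (30 / 365.25) * u_state[1] * (1 - pv[["utility_mi"]])

  ## --- annual cycles ---
  ich_lt <- pv[["prop_ich_recurrence"]]
  for (t in seq_len(horizon)) {
    alive <- state < 4L
    if (!any(alive)) break
    r_t <- min(1, pv[["annual_recurrence_rate"]] *
                 pv[["rr_recurrence_per_year"]]^(t - 1))
    q_t <- schedule$rates[t]
    idx <- which(alive)
    m <- length(idx)
    u1 <- stats::runif(m)
    p_rec <- r_t
    p_ech <- (1 - r_t) * pv[["ech_rate_annual"]]
    p_mi <- (1 - r_t) * (1 - pv[["ech_rate_annual"]]) * pv[["mi_rate_annual"]]
    p_ns <- (1 - r_t) * (1 - pv[["ech_rate_annual"]]) *
      (1 - pv[["mi_rate_annual"]]) * q_t
    b_rec <- u1 < p_rec
    b_ech <- !b_rec & u1 < p_rec + p_ech
    b_mi <- !b_rec & !b_ech & u1 < p_rec + p_ech + p_mi
    b_ns <- !b_rec & !b_ech & !b_mi & u1 < p_rec + p_ech + p_mi + p_ns

    s_t <- state[idx]
    new_s <- s_t
    cyc_cost <- numeric(m)
    cyc_qaly <- numeric(m)

    if (any(b_rec)) {
      k <- which(b_rec)
      fatal <- stats::runif(length(k)) < pv[["death_on_recurrence"]]
      dest <- s_t[k]
      surv <- !fatal
      # equal reallocation among states of equal and greater disability
      from_minor <- surv & s_t[k] == 1L
      from_mod <- surv & s_t[k] == 2L
      dest[from_minor] <- sample.int(3L, sum(from_minor), replace = TRUE)
      dest[from_mod] <- sample(2:3, sum(from_mod), replace = TRUE)
      dest[surv & s_t[k] == 3L] <- 3L
      dest[fatal] <- 4L
      new_s[k] <- dest
      ich_k <- stats::runif(length(k)) < ich_lt
      to02 <- dest == 1L
      cyc_cost[k] <- cyc_cost[k] +
        ifelse(to02,
               ifelse(ich_k, pv[["cost_hosp_ich_mrs02"]],
                      pv[["cost_hosp_ischemic_mrs02"]]),
               ifelse(ich_k, pv[["cost_hosp_ich_mrs36"]],
                      pv[["cost_hosp_ischemic_mrs36"]]))
    }
    if (any(b_ech)) {
      k <- which(b_ech)
      fatal <- stats::runif(length(k)) < pv[["ech_fatality"]]
      new_s[k][fatal] <- 4L
      cyc_cost[k] <- cyc_cost[k] + pv[["cost_hosp_ech"]]
      kk <- k[!fatal]
      cyc_qaly[kk] <- cyc_qaly[kk] - (14 / 365.25) * u_state[s_t[kk]] *
        (1 - pv[["utility_ech"]])
    }
    if (any(b_mi)) {
      k <- which(b_mi)
      fatal <- stats::runif(length(k)) < pv[["mi_fatality"]]
      new_s[k][fatal] <- 4L
      cyc_cost[k] <- cyc_cost[k] + pv[["cost_hosp_mi"]]
      kk <- k[!fatal]
      cyc_qaly[kk] <- cyc_qaly[kk] - (30 / 365.25) * u_state[s_t[kk]] *
        (1 - pv[["utility_mi"]])
    }
    new_s[b_ns] <- 4L

    end_alive <- new_s < 4L
    cyc_cost[end_alive] <- cyc_cost[end_alive] +
      ifelse(new_s[end_alive] == 1L, pv[["cost_annual_mrs02"]],
             pv[["cost_annual_mrs35"]])
    cyc_qaly <- cyc_qaly + u_state[new_s]

    cost[idx] <- cost[idx] + cyc_cost * (1 + rc)^(-t)
    qaly[idx] <- qaly[idx] + cyc_qaly * (1 + ro)^(-t)
    state[idx] <- new_s
  }

  structure(list(arm = arm, n = n,
                 mean_cost = mean(cost), mean_qaly = mean(qaly),
                 se_cost = stats::sd(cost) / sqrt(n),
                 se_qaly = stats::sd(qaly) / sqrt(n)),
            class = "microsim_result")
}

#' @export
print.microsim_result <- function(x, ...) {
  cat(sprintf(paste0("<microsim_result> %s, n = %d\n  cost %.2f (SE %.2f) ",
                     "CNY\n  QALY %.4f (SE %.4f)\n"),
              x$arm, x$n, x$mean_cost, x$se_cost, x$mean_qaly, x$se_qaly))
  invisible(x)
}
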