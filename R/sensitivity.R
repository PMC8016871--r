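#' Deterministic one-way sensitivity analysis (tornado)
#'
#' For each non-fixed parameter, re-runs the full pipeline twice — once at
#' the parameter's low bound, once at its high bound, everything else at base
#' — and records both ICERs. Rows are sorted by decreasing ICER spread
#' (tornado order).
#'
#' Overrides of the 90-day minor/no-disability proportions follow the
#' package's renormalization policy (see [ninety_day_distribution()]): the
#' 90-day death proportion stays fixed and the moderate/severe split is
#' rescaled.
#'
#' @param ps A `parameter_set`.
#' @param schedule A [mortality_schedule()].
#' @param mode 90-day distribution mode.
#' @return A data.frame of class `owsa_result`: `parameter`, `low_input`,
#'   `high_input`, `icer_at_low`, `icer_at_high`, `spread`, plus the
#'   base-case ICER as attribute `"icer_base"`.
#' @export
run_owsa <- function(ps, schedule = default_schedule(),
                     mode = c("printed", "derived")) {
  mode <- match.arg(mode)
  base_res <- run_base_case(ps, schedule, mode)
  vary <- names(ps$specs)[vapply(ps$specs, function(s) s$dist != "fixed",
                                 logical(1))]
  icer_at <- function(name, value) {
    res <- tryCatch(
      run_base_case(set_param(ps, name, value), schedule, mode),
      error = function(e) stop("one-way sensitivity failed for '", name,
                               "' at ", value, ": ", conditionMessage(e),
                               call. = FALSE))
    res$icer
  }
  rows <- lapply(vary, function(nm) {
    sp <- ps$specs[[nm]]
    data.frame(parameter = nm, low_input = sp$low, high_input = sp$high,
               icer_at_low = icer_at(nm, sp$low),
               icer_at_high = icer_at(nm, sp$high),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$spread <- abs(out$icer_at_high - out$icer_at_low)
  out <- out[order(-out$spread), ]
  rownames(out) <- NULL
  attr(out, "icer_base") <- base_res$icer
  class(out) <- c("owsa_result", "data.frame")
  out
}

# inverse-CDF draw from a triangular(low, mode, high) distribution
rtriangular <- function(n, low, mode, high) {
  if (high <= low) return(rep(low, n))
  u <- stats::runif(n)
  fc <- (mode - low) / (high - low)
  ifelse(u < fc,
         low + sqrt(u * (high - low) * (mode - low)),
         high - sqrt((1 - u) * (high - low) * (high - mode)))
}

# one random draw for a single param_spec
draw_spec <- function(sp) {
  if (sp$dist == "fixed" || sp$high <= sp$low) return(sp$base)
  switch(sp$dist,
    triangular = rtriangular(1L, sp$low, sp$base, sp$high),
    normal = {
      # truncated normal via inverse CDF; sd set so (low, high) ~ central 95%
      sd <- (sp$high - sp$low) / (2 * 1.96)
      lo <- stats::pnorm(sp$low, sp$base, sd)
      hi <- stats::pnorm(sp$high, sp$base, sd)
      stats::qnorm(stats::runif(1L, lo, hi), sp$base, sd)
    },
    beta = {
      # scaled beta with mode at base, fixed concentration
      k <- 6
      m <- (sp$base - sp$low) / (sp$high - sp$low)
      sp$low + (sp$high - sp$low) * stats::rbeta(1L, 1 + k * m,
                                                 1 + k * (1 - m))
    })
}

#' Draw one probabilistic-sensitivity parameter set
#'
#' Every non-fixed parameter is drawn independently from its tagged
#' distribution over (low, base, high); structural settings are unchanged.
#' The two discount-rate parameters are not sampled (they are varied in the
#' one-way analysis only, as is conventional).
#'
#' @param ps A `parameter_set`.
#' @return A `parameter_set` with sampled base values (ranges kept).
#' @export
sample_parameter_set <- function(ps) {
  for (nm in names(ps$specs)) {
    if (nm %in% c("discount_cost", "discount_outcome")) next
    sp <- ps$specs[[nm]]
    if (sp$dist == "fixed") next
    sp$base <- draw_spec(sp)
    ps$specs[[nm]] <- sp
  }
  ps
}

#' Probabilistic sensitivity analysis
#'
#' Draws `n` independent parameter sets ([sample_parameter_set()]), evaluates
#' both strategy arms on each, and collects the incremental cost/effect
#' pairs. Reproducible for a fixed `seed`.
#'
#' @param ps A `parameter_set`.
#' @param n Number of Monte-Carlo iterations (default: the structural
#'   `psa_iterations`, 10,000).
#' @param seed Integer seed (default: structural `rng_seed`).
#' @param schedule A [mortality_schedule()].
#' @param mode 90-day distribution mode.
#' @return A list of class `psa_result`: `samples` (data.frame with
#'   `d_cost`, `d_qaly`, per-arm totals), `n`, `seed`, `base` (the base-case
#'   [ce_result()]).
#' @export
run_psa <- function(ps, n = NULL, seed = NULL,
                    schedule = default_schedule(),
                    mode = c("printed", "derived")) {
  mode <- match.arg(mode)
  st <- ps$structural
  if (is.null(n)) n <- st$psa_iterations
  if (is.null(seed)) seed <- st$rng_seed
  stopifnot(n >= 1)
  base_res <- run_base_case(ps, schedule, mode)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  cost_A <- qaly_A <- cost_B <- qaly_B <- numeric(n)
  for (i in seq_len(n)) {
    psi <- sample_parameter_set(ps)
    a <- run_strategy("genetic_testing", psi, schedule, mode)
    b <- run_strategy("no_testing", psi, schedule, mode)
    cost_A[i] <- a$cost; qaly_A[i] <- a$qaly
    cost_B[i] <- b$cost; qaly_B[i] <- b$qaly
  }
  samples <- data.frame(cost_A = cost_A, qaly_A = qaly_A,
                        cost_B = cost_B, qaly_B = qaly_B,
                        d_cost = cost_A - cost_B, d_qaly = qaly_A - qaly_B)
  structure(list(samples = samples, n = n, seed = seed, base = base_res),
            class = "psa_result")
}

#' Summarize PSA quadrant probabilities
#'
#' @param psa A `psa_result`.
#' @param wtp Willingness-to-pay for the cost-effectiveness probability
#'   (default 72,100 CNY/QALY).
#' @return Named list: `p_qaly_gain` (fraction with `d_qaly > 0`),
#'   `p_cost_effective` (fraction with positive net monetary benefit at
#'   `wtp`), `p_dominant` (fraction with `d_qaly > 0` and `d_cost < 0`).
#' @export
psa_summary <- function(psa, wtp = 72100) {
  s <- psa$samples
  list(p_qaly_gain = mean(s$d_qaly > 0),
       p_cost_effective = mean(nmb(s$d_cost, s$d_qaly, wtp) > 0),
       p_dominant = mean(s$d_qaly > 0 & s$d_cost < 0))
}

#' @export
print.psa_result <- function(x, ...) {
  sm <- psa_summary(x)
  cat(sprintf("<psa_result> %d iterations (seed %d)\n", x$n, x$seed))
  cat(sprintf("  P(QALY gain)                 %.4f\n", sm$p_qaly_gain))
  cat(sprintf("  P(cost-effective @ 72,100)   %.4f\n", sm$p_cost_effective))
  cat(sprintf("  P(dominant)                  %.4f\n", sm$p_dominant))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA samples with
#' positive net monetary benefit.
#'
#' @param psa A `psa_result`.
#' @param wtp_grid Thresholds in CNY/QALY (default 0 to 250,000 by 2,500,
#'   covering both decision thresholds 72,100 and 216,000).
#' @return Data.frame with columns `wtp`, `probability`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 250000, by = 2500)) {
  stopifnot(length(wtp_grid) >= 1)
  s <- psa$samples
  prob <- vapply(wtp_grid,
                 function(w) mean(nmb(s$d_cost, s$d_qaly, w) > 0),
                 numeric(1))
  data.frame(wtp = wtp_grid, probability = prob)
}
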