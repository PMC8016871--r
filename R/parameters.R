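#' Single model-parameter specification
#'
#' A parameter is described by its base-case value, the low/high range used in
#' sensitivity analyses, the sampling distribution used in probabilistic
#' sensitivity analysis, and a unit label. Units drive validation: probabilities
#' and utilities must stay within \[0, 1\], costs must be non-negative.
#'
#' @param name Parameter identifier (snake_case).
#' @param base Base-case value.
#' @param low,high Sensitivity range; must bracket `base`. Default to `base`
#'   (a fixed parameter).
#' @param dist Sampling distribution tag: one of `"triangular"`, `"normal"`,
#'   `"beta"`, `"fixed"`.
#' @param units One of `"CNY"`, `"probability"`, `"utility"`, `"rate"`,
#'   `"ratio"`, `"dimensionless"`.
#' @param source Free-text provenance note.
#' @return An object of class `param_spec`.
#' @export
param_spec <- function(name, base, low = base, high = base,
                       dist = if (low == high) "fixed" else "triangular",
                       units = "dimensionless", source = "") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  dist <- match.arg(dist, c("triangular", "normal", "beta", "fixed"))
  units <- match.arg(units, c("CNY", "probability", "utility", "rate",
                              "ratio", "dimensionless"))
  structure(
    list(name = name, base = as.numeric(base), low = as.numeric(low),
         high = as.numeric(high), dist = dist, units = units,
         source = source),
    class = "param_spec"
  )
}

# shorthand: +/- 20% range around base
spec_pm20 <- function(name, base, units, source = "") {
  param_spec(name, base, 0.8 * base, 1.2 * base, "triangular", units, source)
}

#' Structural model settings
#'
#' Settings that define the shape of the analysis rather than a sampled
#' quantity: time horizon, cycle length, cohort starting age,
#' willingness-to-pay thresholds, PSA iteration count, half-cycle correction
#' and the default random seed.
#'
#' @param horizon_years Number of annual Markov cycles (default 30).
#' @param cycle_length_years Cycle length; the model is annual (fixed at 1).
#' @param start_age Cohort age at model entry in years (default 62).
#' @param wtp_primary Primary willingness-to-pay threshold, CNY/QALY
#'   (default 72,100 = 2019 Chinese per-capita GDP).
#' @param wtp_upper Upper threshold, CNY/QALY (default 216,000, about 3x GDP).
#' @param psa_iterations Default Monte-Carlo iteration count (10,000).
#' @param half_cycle_correction Accrue rewards on mid-cycle occupancy?
#'   Default `FALSE`.
#' @param rng_seed Default random seed.
#' @return A list of class `structural_settings`.
#' @export
structural_settings <- function(horizon_years = 30L, cycle_length_years = 1,
                                start_age = 62, wtp_primary = 72100,
                                wtp_upper = 216000, psa_iterations = 10000L,
                                half_cycle_correction = FALSE,
                                rng_seed = 20190101L) {
  structure(
    list(horizon_years = as.integer(horizon_years),
         cycle_length_years = cycle_length_years,
         start_age = start_age,
         wtp_primary = wtp_primary,
         wtp_upper = wtp_upper,
         psa_iterations = as.integer(psa_iterations),
         half_cycle_correction = isTRUE(half_cycle_correction),
         rng_seed = as.integer(rng_seed)),
    class = "structural_settings"
  )
}

new_parameter_set <- function(specs, structural) {
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  structure(list(specs = specs, structural = structural),
            class = "parameter_set")
}

#' Default base-case parameter set
#'
#' The shipped base case: every event risk, 90-day outcome distribution, cost,
#' utility, long-term probability and discount rate of the model, each with its
#' sensitivity range and sampling distribution. Parameters whose range is
#' quoted as "+/- 20%" get `low = 0.8 * base`, `high = 1.2 * base`.
#'
#' Naming groups:
#' * `cost_hosp_*` — one-time hospitalization costs per event, by resulting
#'   mRS band (2019 CNY).
#' * `cost_annual_*` — annual post-hospitalization care costs by mRS band.
#' * `cost_drug_*`, `cost_genetic_testing` — 90-day drug prices and the
#'   genotyping assay cost.
#' * `utility_*` — health-state and temporary-event utilities.
#' * `rec90_*`, `prop_ich_90d`, `ech_90d`, `mi_90d` — 90-day event risks by
#'   genotype/ESRS subgroup.
#' * `p90_*` — 90-day mRS outcome distributions per strategy arm.
#' * long-term probabilities (`annual_recurrence_rate`,
#'   `rr_recurrence_per_year`, `death_on_recurrence`, `prop_ich_recurrence`,
#'   `ech_rate_annual`/`ech_fatality`, `mi_rate_annual`/`mi_fatality`).
#' * `discount_cost`, `discount_outcome` — annual discount rates.
#'
#' @return A `parameter_set`.
#' @examples
#' ps <- default_parameters()
#' ps$specs[["annual_recurrence_rate"]]$base  # 0.1219
#' validate_parameters(ps)                    # character(0)
#' @export
default_parameters <- function() {
  s <- list(
    ## one-time hospitalization costs (2019 CNY)
    param_spec("cost_hosp_ischemic_mrs02", 12499.91, 7021.54, 15861.18,
               "triangular", "CNY", "hospitalization, ischemic stroke, mRS 0-2"),
    param_spec("cost_hosp_ischemic_mrs36", 18700.45, 9711.31, 24627.33,
               "triangular", "CNY", "hospitalization, ischemic stroke, mRS 3-6"),
    param_spec("cost_hosp_ich_mrs02", 14086.15, 7515.65, 17613.39,
               "triangular", "CNY", "hospitalization, ICH, mRS 0-2"),
    param_spec("cost_hosp_ich_mrs36", 18700.45, 9711.31, 24627.33,
               "triangular", "CNY", "hospitalization, ICH, mRS 3-6"),
    param_spec("cost_hosp_ech", 9125.97, 5563.25, 18330.50,
               "triangular", "CNY", "hospitalization, major extracranial hemorrhage"),
    param_spec("cost_hosp_mi", 21276.20, 8292.31, 37291.96,
               "triangular", "CNY", "hospitalization, myocardial infarction"),
    ## annual post-hospitalization costs
    param_spec("cost_annual_mrs02", 8767.42, 2189.32, 10945.34,
               "triangular", "CNY", "annual care, mRS 0-2"),
    param_spec("cost_annual_mrs35", 13850.50, 4104.98, 18060.64,
               "triangular", "CNY", "annual care, mRS 3-5"),
    ## 90-day drug and testing costs
    spec_pm20("cost_drug_clop_asp_90d", 490.45, "CNY",
              "90-day clopidogrel-aspirin price"),
    spec_pm20("cost_drug_dipy_asp_90d", 504, "CNY",
              "90-day dipyridamole-aspirin price"),
    spec_pm20("cost_genetic_testing", 1076.5, "CNY", "CYP2C19 genotyping assay"),
    ## utilities
    param_spec("utility_mrs02", 0.75, 0.70, 0.90, "triangular", "utility",
               "minor or no disability"),
    param_spec("utility_mrs34", 0.39, 0.10, 0.50, "triangular", "utility",
               "moderate disability"),
    param_spec("utility_mrs5", 0.20, 0.00, 0.32, "triangular", "utility",
               "severe disability"),
    param_spec("utility_death", 0, 0, 0, "fixed", "utility", "death"),
    param_spec("utility_ech", 0.80, 0.79, 0.84, "triangular", "utility",
               "temporary, major ECH episode"),
    param_spec("utility_mi", 0.84, 0.67, 0.96, "triangular", "utility",
               "temporary, MI episode"),
    ## long-term probabilities
    param_spec("annual_recurrence_rate", 0.1219, 0.1163, 0.1276,
               "triangular", "probability", "stroke recurrence per patient-year"),
    param_spec("prop_ich_recurrence", 0.075, 0.075, 0.146,
               "triangular", "probability", "ICH share of recurrences, long term"),
    param_spec("death_on_recurrence", 0.1933, 0.1737, 0.2128,
               "triangular", "probability", "case fatality of recurrent stroke"),
    param_spec("rr_recurrence_per_year", 1.017, 1.013, 1.022,
               "triangular", "ratio", "annual multiplicative growth of recurrence"),
    param_spec("ech_rate_annual", 0.0038, 0.0030, 0.0048,
               "triangular", "probability", "annual major ECH rate"),
    spec_pm20("ech_fatality", 0.06, "probability", "major ECH case fatality"),
    param_spec("mi_rate_annual", 0.0085, 0.0060, 0.0114,
               "triangular", "probability", "annual MI rate"),
    param_spec("mi_fatality", 0.15, 0.103, 0.246,
               "triangular", "probability", "MI case fatality"),
    ## 90-day event risks by subgroup
    spec_pm20("rec90_noncarrier", 0.0717, "probability",
              "90-day recurrence, LoFA noncarrier, clopidogrel-aspirin"),
    spec_pm20("rec90_carrier_high", 0.0871, "probability",
              "90-day recurrence, carrier ESRS >= 3, clopidogrel-aspirin"),
    spec_pm20("rec90_carrier_low", 0.0727, "probability",
              "90-day recurrence, carrier ESRS < 3, dipyridamole-aspirin"),
    spec_pm20("rec90_no_testing", 0.082, "probability",
              "90-day recurrence, pooled no-testing arm"),
    spec_pm20("prop_ich_90d", 0.0377, "probability", "ICH share of 90-day recurrences"),
    spec_pm20("ech_90d", 0.0108, "probability", "90-day major ECH risk"),
    spec_pm20("mi_90d", 0.0012, "probability", "90-day MI risk"),
    ## 90-day outcome distributions (mRS bands) per arm
    param_spec("p90_minor_genetic", 0.9506, 0.939, 0.961,
               "triangular", "probability", "90-day mRS 0-2, genetic-testing arm"),
    param_spec("p90_moderate_genetic", 0.0404, units = "probability",
               source = "90-day mRS 3-4, genetic-testing arm"),
    param_spec("p90_severe_genetic", 0.0054, units = "probability",
               source = "90-day mRS 5, genetic-testing arm"),
    param_spec("p90_death_genetic", 0.0036, units = "probability",
               source = "90-day death, genetic-testing arm"),
    param_spec("p90_minor_no_testing", 0.9376, 0.9266, 0.9486,
               "triangular", "probability", "90-day mRS 0-2, no-testing arm"),
    param_spec("p90_moderate_no_testing", 0.0527, units = "probability",
               source = "90-day mRS 3-4, no-testing arm"),
    param_spec("p90_severe_no_testing", 0.0058, units = "probability",
               source = "90-day mRS 5, no-testing arm"),
    param_spec("p90_death_no_testing", 0.0039, units = "probability",
               source = "90-day death, no-testing arm"),
    ## genotype/ESRS subgroup mix of the tested arm
    param_spec("prop_noncarrier", 0.41, units = "probability",
               source = "LoFA noncarriers among tested patients"),
    param_spec("prop_carrier_high_esrs", 0.22, units = "probability",
               source = "LoFA carriers with ESRS >= 3"),
    param_spec("prop_carrier_low_esrs", 0.37, units = "probability",
               source = "LoFA carriers with ESRS < 3 (switched to dipyridamole-aspirin)"),
    ## effect ratios used by the derived 90-day pathway
    param_spec("hr_dipyridamole", 0.78, 0.68, 0.90, "triangular", "ratio",
               "dipyridamole-aspirin vs aspirin hazard ratio for recurrence"),
    param_spec("disability_rr_dapt", 0.78, 0.62, 0.99, "triangular", "ratio",
               "DAPT vs aspirin relative disability rate"),
    ## one-year / 90-day recurrence anchors for the closed-form derivations
    param_spec("rec90_clop_asp_trial", 0.083, units = "probability",
               source = "90-day recurrence, clopidogrel-aspirin trial arm"),
    param_spec("rec1y_clop_asp_trial", 0.103, units = "probability",
               source = "1-year recurrence, clopidogrel-aspirin trial arm"),
    param_spec("rec90_aspirin_mono", 0.0932, units = "probability",
               source = "90-day recurrence, aspirin monotherapy, carrier ESRS < 3"),
    ## discounting
    param_spec("discount_cost", 0.03, 0.03, 0.08, "triangular", "rate",
               "annual discount rate, costs"),
    param_spec("discount_outcome", 0.03, 0.024, 0.036, "triangular", "rate",
               "annual discount rate, outcomes")
  )
  new_parameter_set(s, structural_settings())
}

#' Validate a parameter set
#'
#' Checks every invariant and returns violations as a character vector rather
#' than raising: `low <= base <= high`; probabilities and utilities in
#' \[0, 1\]; costs non-negative; structural settings sane (horizon >= 1,
#' discount rates in \[0, 0.08\], positive WTP); subgroup proportions summing
#' to 1.
#'
#' @param ps A `parameter_set`.
#' @return Character vector of violation messages; `character(0)` if valid.
#' @export
validate_parameters <- function(ps) {
  stopifnot(inherits(ps, "parameter_set"))
  v <- character(0)
  for (sp in ps$specs) {
    if (!(sp$low <= sp$base && sp$base <= sp$high))
      v <- c(v, sprintf("%s: low <= base <= high violated (%g, %g, %g)",
                        sp$name, sp$low, sp$base, sp$high))
    if (sp$units %in% c("probability", "utility")) {
      if (sp$low < 0) v <- c(v, sprintf("%s: %s < 0", sp$name, sp$units))
      if (sp$high > 1) v <- c(v, sprintf("%s: %s > 1", sp$name, sp$units))
    }
    if (sp$units == "CNY" && sp$low < 0)
      v <- c(v, sprintf("%s: cost < 0", sp$name))
    if (sp$dist == "fixed" && !(sp$low == sp$base && sp$high == sp$base))
      v <- c(v, sprintf("%s: fixed parameter with non-degenerate range", sp$name))
  }
  st <- ps$structural
  if (st$horizon_years < 1L) v <- c(v, "structural: horizon_years < 1")
  for (dn in c("discount_cost", "discount_outcome")) {
    d <- ps$specs[[dn]]
    if (!is.null(d) && (d$base < 0 || d$base > 0.08))
      v <- c(v, sprintf("%s: discount rate outside [0, 0.08]", dn))
  }
  if (st$wtp_primary <= 0 || st$wtp_upper <= 0)
    v <- c(v, "structural: willingness-to-pay must be positive")
  w <- param_values(ps)[c("prop_noncarrier", "prop_carrier_high_esrs",
                          "prop_carrier_low_esrs")]
  if (all(!is.na(w)) && abs(sum(w) - 1) > 1e-9)
    v <- c(v, "subgroup proportions do not sum to 1")
  v
}

#' Extract base-case values as a named numeric vector
#'
#' @param ps A `parameter_set`.
#' @return Named numeric vector of base-case values.
#' @export
param_values <- function(ps) {
  vapply(ps$specs, `[[`, numeric(1), "base")
}

#' Set the base value of one parameter
#'
#' Used by one-way sensitivity analysis and scenario runs. The range is widened
#' if the new base falls outside it, so the result remains a valid set.
#'
#' @param ps A `parameter_set`.
#' @param name Parameter name.
#' @param value New base value.
#' @return The modified `parameter_set`.
#' @export
set_param <- function(ps, name, value) {
  if (!name %in% names(ps$specs))
    stop("unknown parameter: ", name, call. = FALSE)
  sp <- ps$specs[[name]]
  sp$base <- as.numeric(value)
  sp$low <- min(sp$low, sp$base)
  sp$high <- max(sp$high, sp$base)
  ps$specs[[name]] <- sp
  ps
}

#' @export
print.parameter_set <- function(x, ...) {
  cat(sprintf("<parameter_set> %d parameters, horizon %d y, start age %g\n",
              length(x$specs), x$structural$horizon_years,
              x$structural$start_age))
  nf <- sum(vapply(x$specs, function(s) s$dist != "fixed", logical(1)))
  cat(sprintf("  %d non-fixed (enter sensitivity analyses), %d fixed\n",
              nf, length(x$specs) - nf))
  invisible(x)
}

#' Tabulate a parameter set
#'
#' @param ps A `parameter_set`.
#' @return A data.frame with one row per parameter: name, base, low, high,
#'   dist, units, source.
#' @export
parameter_table <- function(ps) {
  data.frame(
    name = vapply(ps$specs, `[[`, character(1), "name"),
    base = vapply(ps$specs, `[[`, numeric(1), "base"),
    low = vapply(ps$specs, `[[`, numeric(1), "low"),
    high = vapply(ps$specs, `[[`, numeric(1), "high"),
    dist = vapply(ps$specs, `[[`, character(1), "dist"),
    units = vapply(ps$specs, `[[`, character(1), "units"),
    source = vapply(ps$specs, `[[`, character(1), "source"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Write the full parameter table as CSV
#'
#' @param ps A `parameter_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_parameters_csv <- function(ps, path) {
  utils::write.csv(parameter_table(ps), path, row.names = FALSE)
  invisible(path)
}

#' Serialize a parameter set to a YAML configuration file
#'
#' The written file round-trips losslessly through [load_config()].
#'
#' @param ps A `parameter_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(ps, path) {
  pars <- lapply(ps$specs, function(sp)
    list(base = sp$base, low = sp$low, high = sp$high, dist = sp$dist))
  st <- unclass(ps$structural)
  yaml::write_yaml(list(structural = st, parameters = pars), path,
                   precision = 15L)
  invisible(path)
}

#' Load a parameter configuration file
#'
#' Reads the YAML config dialect: optional top-level `structural:` and
#' `parameters:` blocks. A parameter entry is either a bare number (overrides
#' the base value) or a map with any of `base`, `low`, `high`, `dist`.
#' Parameters not mentioned keep their defaults; unknown keys are an error;
#' the resulting set must pass [validate_parameters()].
#'
#' @param path Path to a YAML config file. An empty file yields
#'   [default_parameters()].
#' @return A validated `parameter_set`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  ps <- default_parameters()
  if (is.null(cfg)) return(ps)
  if (!is.list(cfg)) stop("config must be a YAML mapping", call. = FALSE)
  unknown_top <- setdiff(names(cfg), c("structural", "parameters"))
  if (length(unknown_top))
    stop("unknown top-level config key(s): ",
         paste(unknown_top, collapse = ", "), call. = FALSE)
  if (!is.null(cfg$structural)) {
    st <- ps$structural
    unknown <- setdiff(names(cfg$structural), names(st))
    if (length(unknown))
      stop("unknown structural key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    for (k in names(cfg$structural)) st[[k]] <- cfg$structural[[k]]
    st$horizon_years <- as.integer(st$horizon_years)
    st$psa_iterations <- as.integer(st$psa_iterations)
    st$rng_seed <- as.integer(st$rng_seed)
    st$half_cycle_correction <- isTRUE(st$half_cycle_correction)
    ps$structural <- st
  }
  if (!is.null(cfg$parameters)) {
    unknown <- setdiff(names(cfg$parameters), names(ps$specs))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    for (k in names(cfg$parameters)) {
      entry <- cfg$parameters[[k]]
      sp <- ps$specs[[k]]
      if (is.numeric(entry) && length(entry) == 1L) {
        sp$base <- as.numeric(entry)
      } else if (is.list(entry)) {
        bad <- setdiff(names(entry), c("base", "low", "high", "dist"))
        if (length(bad))
          stop("parameter ", k, ": unknown field(s) ",
               paste(bad, collapse = ", "), call. = FALSE)
        for (f in intersect(names(entry), c("base", "low", "high")))
          sp[[f]] <- as.numeric(entry[[f]])
        if (!is.null(entry$dist))
          sp$dist <- match.arg(entry$dist,
                               c("triangular", "normal", "beta", "fixed"))
      } else {
        stop("parameter ", k, ": entry must be a number or a mapping",
             call. = FALSE)
      }
      ps$specs[[k]] <- sp
    }
  }
  viol <- validate_parameters(ps)
  if (length(viol))
    stop("invalid configuration:\n  ", paste(viol, collapse = "\n  "),
         call. = FALSE)
  ps
}
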