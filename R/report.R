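write_csv_plain <- function(df, path) {
  # '.' decimal separator, no thousands separators, regardless of locale
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  path
}

run_manifest <- function(out_dir, config, seed, files) {
  list(config = if (is.null(config)) "<defaults>" else config,
       seed = seed,
       package_version = as.character(utils::packageVersion("pgxcea")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       out_dir = out_dir,
       files = files)
}

resolve_config <- function(config) {
  if (is.null(config)) default_parameters() else load_config(config)
}

#' Write the base-case report
#'
#' Runs both strategy arms and writes a summary table (per-arm cost, QALYs,
#' ICER), per-cycle cohort traces, the 90-day block, and a JSON run manifest
#' listing every output file.
#'
#' @param config Path to a YAML config file, or `NULL` for defaults.
#' @param out_dir Output directory (created if missing).
#' @param schedule A [mortality_schedule()].
#' @return The [ce_result()], invisibly.
#' @export
write_base_case <- function(config = NULL, out_dir,
                            schedule = default_schedule()) {
  ps <- resolve_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- run_base_case(ps, schedule)
  files <- c("summary.csv", "ninety_day.csv",
             "trace_genetic_testing.csv", "trace_no_testing.csv",
             "manifest.json")
  write_csv_plain(as.data.frame(res), file.path(out_dir, "summary.csv"))
  nd <- do.call(rbind, lapply(res$arms, function(a)
    data.frame(arm = a$arm, cost_90d = a$cost_90d, qaly_90d = a$qaly_90d,
               t(as.numeric(a$distribution_90d)))))
  names(nd)[4:7] <- c("p_minor", "p_moderate", "p_severe", "p_dead")
  write_csv_plain(nd, file.path(out_dir, "ninety_day.csv"))
  write_trace_csv(res$arms$genetic_testing$markov,
                  file.path(out_dir, "trace_genetic_testing.csv"))
  write_trace_csv(res$arms$no_testing$markov,
                  file.path(out_dir, "trace_no_testing.csv"))
  jsonlite::write_json(run_manifest(out_dir, config, NA, files),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}

#' Write the one-way sensitivity (tornado) report
#'
#' @inheritParams write_base_case
#' @param top Number of leading rows in the tornado view (default 9).
#' @return The [run_owsa()] result, invisibly.
#' @export
write_owsa <- function(config = NULL, out_dir, schedule = default_schedule(),
                       top = 9L) {
  ps <- resolve_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ow <- run_owsa(ps, schedule)
  files <- c("tornado_full.csv", "tornado_top.csv", "manifest.json")
  write_csv_plain(as.data.frame(ow), file.path(out_dir, "tornado_full.csv"))
  write_csv_plain(utils::head(as.data.frame(ow), top),
                  file.path(out_dir, "tornado_top.csv"))
  jsonlite::write_json(run_manifest(out_dir, config, NA, files),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(ow)
}

#' Write the probabilistic sensitivity report
#'
#' Writes the incremental cost-effectiveness scatter (one row per iteration),
#' the acceptability curve, quadrant summary and manifest.
#'
#' @inheritParams write_base_case
#' @param n Iterations (default: structural setting).
#' @param seed Integer seed (default: structural setting).
#' @return The [run_psa()] result, invisibly.
#' @export
write_psa <- function(config = NULL, out_dir, n = NULL, seed = NULL,
                      schedule = default_schedule()) {
  ps <- resolve_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  psa <- run_psa(ps, n = n, seed = seed, schedule = schedule)
  sm <- psa_summary(psa, ps$structural$wtp_primary)
  files <- c("scatter.csv", "ceac.csv", "psa_summary.csv", "manifest.json")
  write_csv_plain(psa$samples[, c("d_cost", "d_qaly")],
                  file.path(out_dir, "scatter.csv"))
  write_csv_plain(ceac(psa), file.path(out_dir, "ceac.csv"))
  write_csv_plain(
    data.frame(metric = c("p_qaly_gain", "p_cost_effective", "p_dominant"),
               value = c(sm$p_qaly_gain, sm$p_cost_effective,
                         sm$p_dominant)),
    file.path(out_dir, "psa_summary.csv"))
  jsonlite::write_json(run_manifest(out_dir, config, psa$seed, files),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(psa)
}

#' Plot the cost-effectiveness plane
#'
#' @param psa A `psa_result`.
#' @param wtp Threshold line, CNY/QALY.
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(psa, wtp = 72100) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  ggplot2::ggplot(psa$samples, ggplot2::aes(x = d_qaly,
                                            y = d_cost)) +
    ggplot2::geom_point(alpha = 0.15, size = 0.4) +
    ggplot2::geom_abline(slope = wtp, intercept = 0, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.2) +
    ggplot2::annotate("point", x = psa$base$d_qaly, y = psa$base$d_cost,
                      shape = 22, fill = "white", size = 2) +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (CNY)")
}

#' Plot the cost-effectiveness acceptability curve
#'
#' @param psa A `psa_result`.
#' @param wtp_grid Thresholds passed to [ceac()].
#' @return A ggplot object.
#' @export
plot_ceac <- function(psa, wtp_grid = seq(0, 250000, by = 2500)) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  cc <- ceac(psa, wtp_grid)
  ggplot2::ggplot(cc, ggplot2::aes(x = wtp, y = probability)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = c(72100, 216000), linetype = "dashed") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Willingness to pay (CNY/QALY)",
                  y = "P(genetic testing cost-effective)")
}

#' Plot the tornado diagram
#'
#' @param owsa An `owsa_result`.
#' @param top Number of parameters shown (default 9).
#' @return A ggplot object.
#' @export
plot_tornado <- function(owsa, top = 9L) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  d <- utils::head(as.data.frame(owsa), top)
  d$parameter <- factor(d$parameter, levels = rev(d$parameter))
  base <- attr(owsa, "icer_base")
  ggplot2::ggplot(d) +
    ggplot2::geom_segment(ggplot2::aes(x = icer_at_low,
                                       xend = icer_at_high,
                                       y = parameter,
                                       yend = parameter),
                          linewidth = 4, colour = "grey60") +
    ggplot2::geom_vline(xintercept = base, linetype = "solid") +
    ggplot2::labs(x = "ICER (CNY/QALY)", y = NULL)
}
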