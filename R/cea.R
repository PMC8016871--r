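#' Incremental cost-effectiveness ratio with quadrant classification
#'
#' Computes `d_cost / d_qaly` and classifies the incremental point on the
#' cost-effectiveness plane. For dominance quadrants the ratio is not a
#' meaningful decision statistic and reports should show the class instead.
#'
#' @param d_cost Incremental cost (intervention minus comparator), CNY.
#' @param d_qaly Incremental effect, QALYs.
#' @return List: `icer` (numeric, `NA` when `d_qaly == 0`) and `dominance`,
#'   one of `"A_dominant"` (cheaper and more effective), `"B_dominant"`
#'   (costlier and less effective), `"tradeoff_NE"`, `"tradeoff_SW"`,
#'   `"tie"`.
#' @export
icer <- function(d_cost, d_qaly) {
  dominance <- if (d_qaly > 0 && d_cost < 0) "A_dominant"
  else if (d_qaly < 0 && d_cost > 0) "B_dominant"
  else if (d_qaly > 0) "tradeoff_NE"
  else if (d_qaly < 0) "tradeoff_SW"
  else if (d_cost < 0) "A_dominant"
  else if (d_cost > 0) "B_dominant"
  else "tie"
  list(icer = if (d_qaly != 0) d_cost / d_qaly else NA_real_,
       dominance = dominance)
}

#' Net monetary benefit
#'
#' `wtp * d_qaly - d_cost`; positive iff the intervention is cost-effective
#' at the threshold (for `d_qaly > 0`, equivalent to ICER < WTP).
#'
#' @param d_cost Incremental cost, CNY.
#' @param d_qaly Incremental effect, QALYs.
#' @param wtp Willingness-to-pay threshold, CNY/QALY, `>= 0`.
#' @return Net monetary benefit in CNY.
#' @export
nmb <- function(d_cost, d_qaly, wtp) {
  stopifnot(all(wtp >= 0))
  wtp * d_qaly - d_cost
}

#' WHO GDP-multiple cost-effectiveness classification
#'
#' ICER below one per-capita GDP: highly cost-effective; between one and
#' three (inclusive): acceptable; above three: not worthwhile.
#'
#' @param icer_value ICER in CNY/QALY.
#' @param gdp Per-capita GDP in CNY (default 72,100, China 2019).
#' @return `"highly_cost_effective"`, `"acceptable"` or `"not_worthwhile"`.
#' @export
who_class <- function(icer_value, gdp = 72100) {
  stopifnot(gdp > 0)
  ifelse(icer_value < gdp, "highly_cost_effective",
         ifelse(icer_value <= 3 * gdp, "acceptable", "not_worthwhile"))
}

#' Assemble an incremental cost-effectiveness result
#'
#' @param cost_A,qaly_A Totals of the intervention arm (genetic testing).
#' @param cost_B,qaly_B Totals of the comparator arm (no testing).
#' @param label_A,label_B Arm labels.
#' @return List of class `ce_result`: per-arm totals, `d_cost`, `d_qaly`,
#'   `icer`, `dominance`.
#' @export
ce_result <- function(cost_A, qaly_A, cost_B, qaly_B,
                      label_A = "genetic_testing", label_B = "no_testing") {
  d_cost <- cost_A - cost_B
  d_qaly <- qaly_A - qaly_B
  ic <- icer(d_cost, d_qaly)
  structure(list(label_A = label_A, label_B = label_B,
                 cost_A = cost_A, qaly_A = qaly_A,
                 cost_B = cost_B, qaly_B = qaly_B,
                 d_cost = d_cost, d_qaly = d_qaly,
                 icer = ic$icer, dominance = ic$dominance),
            class = "ce_result")
}

#' @export
print.ce_result <- function(x, ...) {
  cat("Incremental cost-effectiveness result\n")
  cat(sprintf("  %-18s cost %12.2f CNY   %8.4f QALYs\n", x$label_A,
              x$cost_A, x$qaly_A))
  cat(sprintf("  %-18s cost %12.2f CNY   %8.4f QALYs\n", x$label_B,
              x$cost_B, x$qaly_B))
  cat(sprintf("  incremental        cost %12.2f CNY   %8.4f QALYs\n",
              x$d_cost, x$d_qaly))
  if (x$dominance %in% c("tradeoff_NE", "tradeoff_SW"))
    cat(sprintf("  ICER %.2f CNY/QALY (%s)\n", x$icer,
                who_class(x$icer)))
  else
    cat(sprintf("  dominance: %s\n", x$dominance))
  invisible(x)
}

#' As a one-row data.frame (for CSV reports)
#'
#' @param x A `ce_result`.
#' @param ... Unused.
#' @return A data.frame mirroring the published summary-table columns.
#' @export
as.data.frame.ce_result <- function(x, ...) {
  data.frame(strategy = c(x$label_A, x$label_B),
             cost = c(x$cost_A, x$cost_B),
             qaly = c(x$qaly_A, x$qaly_B),
             icer = c(round(x$icer, 2), NA),
             dominance = c(x$dominance, NA),
             stringsAsFactors = FALSE)
}
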