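#' Incremental cost and effect
#'
#' @param intervention,comparator Lists (or `cohort_trace` objects) with
#'   `total_cost` and `total_qaly`.
#' @return List with `delta_cost` and `delta_qaly` (intervention minus
#'   comparator).
#' @export
incremental <- function(intervention, comparator) {
  list(delta_cost = intervention$total_cost - comparator$total_cost,
       delta_qaly = intervention$total_qaly - comparator$total_qaly)
}

#' Incremental cost-effectiveness ratio with dominance labelling
#'
#' Returns the ratio `delta_cost / delta_qaly` when it is meaningful, and a
#' dominance label otherwise. Negative ratios are never reported as numbers:
#' an intervention that saves money while gaining QALYs is `"dominant"`, one
#' that costs more while losing QALYs is `"dominated"`. A zero QALY
#' difference leaves the ratio undefined.
#'
#' @param delta_cost Incremental cost, USD.
#' @param delta_qaly Incremental QALYs.
#' @return List with `icer` (numeric or NA), `label` (one of
#'   `"cost_effective_ratio"`, `"dominant"`, `"dominated"`, `"undefined"`),
#'   and a `display` string (the number, or the capitalised label).
#' @export
icer <- function(delta_cost, delta_qaly) {
  if (delta_qaly == 0) {
    out <- list(icer = NA_real_, label = "undefined", display = "Undefined")
  } else if (delta_qaly > 0 && delta_cost < 0) {
    out <- list(icer = NA_real_, label = "dominant", display = "Dominant")
  } else if (delta_qaly < 0 && delta_cost > 0) {
    out <- list(icer = NA_real_, label = "dominated", display = "Dominated")
  } else {
    r <- delta_cost / delta_qaly
    out <- list(icer = r, label = "cost_effective_ratio",
                display = formatC(r, format = "f", digits = 0, big.mark = " "))
  }
  out
}

#' Net monetary benefit
#'
#' `NMB = delta_qaly * wtp - delta_cost`; positive values indicate
#' cost-effectiveness at the given willingness-to-pay threshold.
#'
#' @param delta_cost Incremental cost, USD.
#' @param delta_qaly Incremental QALYs.
#' @param wtp Willingness-to-pay threshold, USD per QALY (>= 0); vectorised.
#' @return NMB in USD.
#' @export
nmb <- function(delta_cost, delta_qaly, wtp) {
  if (any(wtp < 0)) stop("nmb: wtp must be >= 0")
  delta_qaly * wtp - delta_cost
}

#' Base-case cost-effectiveness table
#'
#' Runs both arms at every horizon and perspective and lays the results out
#' one row per horizon x perspective: per-arm discounted cost and QALYs,
#' incremental cost and QALYs, ICER (or dominance label), and NMB at the
#' requested thresholds.
#'
#' @param params A [model_params()] object.
#' @param horizons Horizons in months.
#' @param perspectives Character vector of perspectives.
#' @param wtp Willingness-to-pay thresholds for NMB columns.
#' @return Data frame (one row per horizon x perspective).
#' @export
cea_table <- function(params, horizons = c(3, 12, 24, 72, 120),
                      perspectives = c("health_system", "societal"),
                      wtp = c(50000, 100000, 150000)) {
  rows <- list()
  for (persp in perspectives) {
    tops <- run_cohort_horizons(params, "TOPS", horizons, persp)
    ctrl <- run_cohort_horizons(params, "TLIF", horizons, persp)
    for (i in seq_along(horizons)) {
      dc <- tops$total_cost[i] - ctrl$total_cost[i]
      dq <- tops$total_qaly[i] - ctrl$total_qaly[i]
      ic <- icer(dc, dq)
      row <- data.frame(perspective = persp, horizon_months = horizons[i],
                        cost_tops = tops$total_cost[i], qaly_tops = tops$total_qaly[i],
                        cost_control = ctrl$total_cost[i], qaly_control = ctrl$total_qaly[i],
                        delta_cost = dc, delta_qaly = dq,
                        icer = ic$icer, icer_label = ic$display,
                        stringsAsFactors = FALSE)
      for (w in wtp) row[[paste0("nmb_", format(w, scientific = FALSE))]] <- nmb(dc, dq, w)
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}
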