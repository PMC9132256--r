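#' Beta distribution from a point estimate and 95% CI
#'
#' Method-of-moments fit with mean `p` and SD `(hi - lo)/3.92`. Boundary
#' point estimates (0 or 1) are shifted by a continuity correction of half a
#' pseudo-event, `0.5/(n + 1)`, which requires the sample size `n`.
#'
#' @param p Point estimate in \[0, 1\].
#' @param lo,hi 95% confidence bounds, `0 <= lo <= p <= hi <= 1`, `hi > lo`.
#' @param n Sample size behind the estimate (needed only when `p` is 0 or 1).
#' @return Named vector `c(alpha, beta)`.
#' @export
beta_from_point_ci <- function(p, lo, hi, n = NULL) {
  if (lo > hi || hi <= lo) stop("beta_from_point_ci: inverted or empty interval")
  if (p < lo || p > hi || lo < 0 || hi > 1) {
    stop("beta_from_point_ci: need 0 <= lo <= p <= hi <= 1")
  }
  if (p == 0 || p == 1) {
    if (is.null(n)) stop("beta_from_point_ci: boundary point estimate needs n for the continuity correction")
    eps <- 0.5 / (n + 1)
    p <- if (p == 0) eps else 1 - eps
  }
  v <- ((hi - lo) / 3.92)^2
  ab <- p * (1 - p) / v - 1
  if (ab <= 0) stop("beta_from_point_ci: interval too wide for a valid beta fit")
  c(alpha = p * ab, beta = (1 - p) * ab)
}

#' Gamma distribution from mean and coefficient of variation
#'
#' `shape = 1/cv^2`, `scale = mean/shape`; the fitted mean and CV reproduce
#' the inputs exactly. The conventional cost CV is 0.153 (30%/1.96).
#'
#' @param mean Mean (> 0), e.g. a base-case cost in USD.
#' @param cv Coefficient of variation (> 0).
#' @return Named vector `c(shape, scale)`.
#' @export
gamma_from_mean_cv <- function(mean, cv = 0.153) {
  if (mean <= 0) stop("gamma_from_mean_cv: mean must be > 0")
  if (cv <= 0) stop("gamma_from_mean_cv: cv must be > 0")
  shape <- 1 / cv^2
  c(shape = shape, scale = mean / shape)
}

#' Default sensitivity-parameter registry
#'
#' The 39 perturbable inputs of the base-case model: 34 costs (the 21 fee
#' schedule items, 5 per-state direct costs, 5 per-state medication costs,
#' the annual wage, the device upcharge, and the supplemental-bundle scale)
#' and the 5 per-state utilities. Each entry carries accessors that read and
#' write the value inside a `model_params` object; utilities are clipped to
#' \[0, 1\] when written.
#'
#' @param params A [model_params()] object (supplies the cost-table layout).
#' @return Named list of entries, each with `id`, `kind` (`"cost"` or
#'   `"utility"`), `get(params)`, `set(params, value)`.
#' @export
default_owsa_parameters <- function(params) {
  entries <- list()
  add <- function(id, kind, get, set) {
    entries[[id]] <<- list(id = id, kind = kind, get = get, set = set)
  }
  tab <- params$cost_table
  for (i in seq_len(nrow(tab))) {
    local({
      row <- i
      id <- paste0("cost_", tab$category[row], "_", tab$code[row])
      add(id, "cost",
          function(p) p$cost_table$medicare[row],
          function(p, v) {
            ratio <- v / p$cost_table$medicare[row]
            p$cost_table$medicare[row] <- v
            p$cost_table$private[row] <- p$cost_table$private[row] * ratio
            p
          })
    })
  }
  for (s in 1:5) {
    local({
      si <- s
      add(paste0("state_cost_", health_states()[si]), "cost",
          function(p) p$state_costs[si],
          function(p, v) { p$state_costs[si] <- max(v, 0); p })
      add(paste0("medication_cost_", health_states()[si]), "cost",
          function(p) p$medication_costs[si],
          function(p, v) { p$medication_costs[si] <- max(v, 0); p })
      add(paste0("utility_", health_states()[si]), "utility",
          function(p) p$utilities[si],
          function(p, v) { p$utilities[si] <- min(max(v, 0), 1); p })
    })
  }
  add("annual_wage", "cost",
      function(p) p$indirect$annual_wage,
      function(p, v) { p$indirect$annual_wage <- max(v, 0); p })
  add("device_upcharge", "cost",
      function(p) p$upcharge,
      function(p, v) { p$upcharge <- max(v, 0); p })
  add("supplemental_bundle", "cost",
      function(p) p$supplemental_scale * supplemental_cost(p$mix, p$cost_table),
      function(p, v) {
        base <- supplemental_cost(p$mix, p$cost_table)
        p$supplemental_scale <- if (base > 0) max(v, 0) / base else 0
        p
      })
  entries
}

# Incremental outcome of TOPS vs TLIF for one parameter set.
eval_incremental <- function(params, horizon = 24, perspective = "health_system") {
  tops <- run_cohort(params, "TOPS", horizon, perspective)
  ctrl <- run_cohort(params, "TLIF", horizon, perspective)
  incremental(tops, ctrl)
}

#' One-way (tornado) sensitivity analysis
#'
#' Perturbs each registry parameter to `(1 - fraction)` and `(1 + fraction)`
#' of its base value with all others held at base, re-evaluating the ICER
#' and NMB each time. Entries are ordered by ICER range (descending); when
#' either ICER endpoint is a dominance label rather than a number, the NMB
#' range at `wtp` is used for ordering instead.
#'
#' @param params Base-case [model_params()].
#' @param fraction Perturbation fraction (default 0.2).
#' @param registry Parameter registry; default [default_owsa_parameters()].
#' @param horizon,perspective Evaluation point for the outcome.
#' @param wtp Threshold for the NMB fallback ordering (default 100000).
#' @return Data frame: `parameter`, `base_value`, `icer_low`, `icer_high`
#'   (NA where dominance), `label_low`, `label_high`, `nmb_low`, `nmb_high`,
#'   `range`, sorted descending by `range`.
#' @export
owsa <- function(params, fraction = 0.2, registry = default_owsa_parameters(params),
                 horizon = 24, perspective = "health_system", wtp = 100000) {
  rows <- lapply(registry, function(e) {
    base <- e$get(params)
    res <- lapply(c(1 - fraction, 1 + fraction), function(f) {
      inc <- eval_incremental(e$set(params, base * f), horizon, perspective)
      ic <- icer(inc$delta_cost, inc$delta_qaly)
      list(icer = ic$icer, label = ic$label,
           nmb = nmb(inc$delta_cost, inc$delta_qaly, wtp))
    })
    rng <- if (!is.na(res[[1]]$icer) && !is.na(res[[2]]$icer)) {
      abs(res[[2]]$icer - res[[1]]$icer)
    } else {
      abs(res[[2]]$nmb - res[[1]]$nmb)
    }
    data.frame(parameter = e$id, base_value = base,
               icer_low = res[[1]]$icer, icer_high = res[[2]]$icer,
               label_low = res[[1]]$label, label_high = res[[2]]$label,
               nmb_low = res[[1]]$nmb, nmb_high = res[[2]]$nmb,
               range = rng, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(-out$range), ]
}

#' Probabilistic sensitivity analysis
#'
#' Draws all registry parameters simultaneously each iteration — costs from
#' gamma distributions with the conventional CV, utilities via a beta (or,
#' optionally, a gamma truncated to \[0, 1\]) on the utility decrement
#' `1 - u` with matched mean and SD — runs both arms, and records the
#' incremental cost and QALYs. Parameters with a zero base value stay fixed.
#' Reproducible under `seed`; all draws are made up front so results do not
#' depend on evaluation order.
#'
#' @param params Base-case [model_params()].
#' @param n_iterations Monte Carlo iterations (default 5000).
#' @param seed RNG seed.
#' @param registry Parameter registry; default [default_owsa_parameters()].
#' @param cv Coefficient of variation for costs and utility decrements
#'   (default 0.153 = 30%/1.96).
#' @param horizon,perspective Evaluation point for the outcome.
#' @param utility_dist `"beta"` (default) or `"truncated_gamma"` for the
#'   utility-decrement distribution.
#' @return Data frame of class `psa_result`: `iteration`, `delta_cost`,
#'   `delta_qaly`.
#' @export
run_psa <- function(params, n_iterations = 5000, seed = 1,
                    registry = default_owsa_parameters(params),
                    cv = 0.153, horizon = 24, perspective = "health_system",
                    utility_dist = c("beta", "truncated_gamma")) {
  utility_dist <- match.arg(utility_dist)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  ids <- names(registry)
  draws <- matrix(NA_real_, n_iterations, length(ids), dimnames = list(NULL, ids))
  for (id in ids) {
    e <- registry[[id]]
    base <- e$get(params)
    if (e$kind == "cost") {
      if (base <= 0) { draws[, id] <- base; next }
      g <- gamma_from_mean_cv(base, cv)
      draws[, id] <- stats::rgamma(n_iterations, shape = g["shape"], scale = g["scale"])
    } else {
      dec <- 1 - base
      if (dec <= 0) { draws[, id] <- base; next }
      sd <- cv * dec
      if (utility_dist == "beta") {
        v <- sd^2
        ab <- dec * (1 - dec) / v - 1
        if (ab <= 0) { draws[, id] <- base; next }
        ddraw <- stats::rbeta(n_iterations, dec * ab, (1 - dec) * ab)
      } else {
        g <- gamma_from_mean_cv(dec, cv)
        ddraw <- stats::rgamma(n_iterations, shape = g["shape"], scale = g["scale"])
        ddraw <- pmin(ddraw, 1)
      }
      draws[, id] <- 1 - ddraw
    }
  }

  dc <- dq <- numeric(n_iterations)
  for (it in seq_len(n_iterations)) {
    p <- params
    for (id in ids) p <- registry[[id]]$set(p, draws[it, id])
    inc <- eval_incremental(p, horizon, perspective)
    dc[it] <- inc$delta_cost
    dq[it] <- inc$delta_qaly
  }
  out <- data.frame(iteration = seq_len(n_iterations), delta_cost = dc, delta_qaly = dq)
  attr(out, "draws") <- draws
  class(out) <- c("psa_result", class(out))
  out
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay threshold, the fraction of PSA iterations in
#' which the intervention is cost-effective, i.e. `delta_qaly * wtp -
#' delta_cost > 0`.
#'
#' @param iterations Data frame with `delta_cost`, `delta_qaly` (one row per
#'   PSA iteration).
#' @param wtp_grid Thresholds in USD per QALY.
#' @return Data frame: `wtp`, `probability_cost_effective`.
#' @export
ceac <- function(iterations, wtp_grid = seq(0, 200000, by = 5000)) {
  if (nrow(iterations) < 1L) stop("ceac: need at least one PSA iteration")
  prob <- vapply(wtp_grid, function(w) {
    mean(iterations$delta_qaly * w - iterations$delta_cost > 0)
  }, numeric(1))
  data.frame(wtp = wtp_grid, probability_cost_effective = prob)
}

#' Default scenario grid
#'
#' The 3 payer mixes (Medicare-only, private-only, 50/50) crossed with the 3
#' surgical settings (inpatient, outpatient, 50/50 mixed), minus the
#' base case (50/50 payers, inpatient): eight scenarios.
#'
#' @return Named list of scenario override lists (`mix`, `setting`).
#' @export
default_scenarios <- function() {
  mixes <- list(medicare_only = payer_mix(1), private_only = payer_mix(0),
                mix_50_50 = payer_mix(0.5))
  settings <- c("inpatient", "outpatient", "mixed")
  out <- list()
  for (m in names(mixes)) {
    for (s in settings) {
      if (m == "mix_50_50" && s == "inpatient") next  # base case
      out[[paste(m, s, sep = "__")]] <- list(mix = mixes[[m]], setting = s)
    }
  }
  out
}

#' Scenario sensitivity analysis
#'
#' Re-runs the incremental analysis under named overrides of payer mix,
#' surgical setting, and/or device upcharge. Unknown override keys are a
#' configuration error.
#'
#' @param params Base-case [model_params()].
#' @param scenarios Named list of override lists; default [default_scenarios()].
#' @param horizons Horizons in months.
#' @param perspective Costing perspective.
#' @param wtp NMB thresholds.
#' @return Data frame: one row per scenario x horizon with incremental
#'   outcomes, ICER-or-label, and NMB at each threshold.
#' @export
run_scenarios <- function(params, scenarios = default_scenarios(),
                          horizons = c(12, 24), perspective = "health_system",
                          wtp = c(50000, 100000, 150000)) {
  allowed <- c("mix", "setting", "upcharge")
  rows <- list()
  for (nm in names(scenarios)) {
    ov <- scenarios[[nm]]
    bad <- setdiff(names(ov), allowed)
    if (length(bad)) stop("run_scenarios: unknown override key(s) in '", nm,
                          "': ", paste(bad, collapse = ", "))
    p <- params
    for (k in names(ov)) p[[k]] <- ov[[k]]
    for (h in horizons) {
      inc <- eval_incremental(p, h, perspective)
      ic <- icer(inc$delta_cost, inc$delta_qaly)
      row <- data.frame(scenario = nm, horizon_months = h,
                        delta_cost = inc$delta_cost, delta_qaly = inc$delta_qaly,
                        icer = ic$icer, icer_label = ic$display,
                        stringsAsFactors = FALSE)
      for (w in wtp) row[[paste0("nmb_", format(w, scientific = FALSE))]] <- nmb(inc$delta_cost, inc$delta_qaly, w)
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
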