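#' Build the variable-length cycle schedule
#'
#' Cycles start short to resolve early postoperative recovery and lengthen as
#' the trajectory stabilises: two 1.5-month cycles, three 3-month cycles,
#' then 12-month cycles. The pattern is truncated (or extended with
#' 12-month cycles, plus a remainder cycle if needed) so the cycle lengths
#' sum exactly to the analysis horizon.
#'
#' @param horizon_months Analysis horizon in months (>= 3).
#' @return Numeric vector of cycle lengths in months.
#' @export
build_cycle_schedule <- function(horizon_months) {
  if (horizon_months < 3) stop("build_cycle_schedule: horizon must be >= 3 months")
  base <- c(1.5, 1.5, 3, 3, 3)
  out <- numeric(0)
  remaining <- horizon_months
  for (len in base) {
    if (remaining < len - 1e-9) break
    out <- c(out, len)
    remaining <- remaining - len
  }
  while (remaining >= 12 - 1e-9) {
    out <- c(out, 12)
    remaining <- remaining - 12
  }
  if (remaining > 1e-9) out <- c(out, remaining)
  out
}

#' Discount factor
#'
#' Present-value factor `(1 + rate)^(-t)` for a quantity accrued `t` years
#' from baseline.
#'
#' @param t_years Time in years (>= 0), vectorised.
#' @param rate Annual discount rate (>= 0), default 0.03.
#' @return Factor in (0, 1\].
#' @export
discount_factor <- function(t_years, rate = 0.03) {
  if (any(t_years < 0)) stop("discount_factor: t must be >= 0")
  if (rate < 0) stop("discount_factor: rate must be >= 0")
  (1 + rate)^(-t_years)
}

#' Assemble the full Markov model parameter set
#'
#' Bundles everything the cohort engine needs: the initial state
#' distribution, per-arm transition matrices over the base 24-month cycle
#' schedule (the final 12-month matrix is reused stationarily when the
#' horizon is extrapolated beyond the matrices provided), per-state utilities
#' and annual direct costs, adverse-event tables and unit costs, indirect
#' (productivity) parameters, payer mix, surgical setting, device upcharge
#' and discount rate.
#'
#' @param initial Length-5 initial state distribution (sums to 1).
#' @param transitions Named list with elements `TLIF` and `TOPS`, each a list
#'   of 5x5 row-stochastic matrices, one per cycle of the base schedule.
#' @param utilities Length-5 per-state utility weights in \[0, 1\].
#' @param state_costs Length-5 per-state direct cost, USD per year of state
#'   membership (scaled by cycle length).
#' @param medication_costs Length-5 per-state medication cost, USD per year
#'   (default zero).
#' @param ae [load_ae_params()] tables.
#' @param indirect [indirect_params()].
#' @param cost_table [load_cost_table()].
#' @param mix [payer_mix()].
#' @param setting Surgical setting for the index operation.
#' @param upcharge TOPS device upcharge, USD.
#' @param discount_rate Annual discount rate (default 0.03).
#' @param supplemental_scale Multiplier on the supplemental-procedure bundle.
#' @param half_cycle Apply a half-cycle correction (average of start- and
#'   end-of-cycle occupancy); default FALSE.
#' @return Object of class `model_params`.
#' @export
model_params <- function(initial,
                         transitions,
                         utilities,
                         state_costs,
                         medication_costs = rep(0, 5),
                         ae = load_ae_params(),
                         indirect = indirect_params(),
                         cost_table = load_cost_table(),
                         mix = payer_mix(),
                         setting = "inpatient",
                         upcharge = 4000,
                         discount_rate = 0.03,
                         supplemental_scale = 1,
                         half_cycle = FALSE) {
  initial <- state_distribution(initial)
  if (!all(c("TLIF", "TOPS") %in% names(transitions))) {
    stop("model_params: transitions must have elements 'TLIF' and 'TOPS'")
  }
  for (arm in c("TLIF", "TOPS")) {
    if (length(transitions[[arm]]) < 1L) {
      stop("model_params: transitions[['", arm, "']] needs at least one matrix")
    }
    for (i in seq_along(transitions[[arm]])) {
      m <- transitions[[arm]][[i]]
      if (any(abs(rowSums(m) - 1) > 1e-9) || any(m < -1e-12)) {
        stop("model_params: transitions[['", arm, "']][[", i, "]] is not row-stochastic")
      }
    }
  }
  if (length(utilities) != 5L || any(utilities < 0 | utilities > 1)) {
    stop("model_params: utilities must be 5 values in [0, 1]")
  }
  if (length(state_costs) != 5L || any(state_costs < 0)) {
    stop("model_params: state_costs must be 5 nonnegative values")
  }
  if (discount_rate < 0) stop("model_params: discount_rate must be >= 0")
  structure(list(initial = initial, transitions = transitions,
                 utilities = as.numeric(utilities),
                 state_costs = as.numeric(state_costs),
                 medication_costs = as.numeric(medication_costs),
                 ae = ae, indirect = indirect, cost_table = cost_table,
                 mix = mix, setting = setting, upcharge = upcharge,
                 discount_rate = discount_rate,
                 supplemental_scale = supplemental_scale,
                 half_cycle = half_cycle),
            class = "model_params")
}

# Rescale per-window AE probabilities to a cycle length via the standard
# rate conversion p_cycle = 1 - (1 - p_window)^(dt / window), which keeps
# probabilities in [0, 1] for any cycle length.
scale_ae_window <- function(ae, dt_months) {
  frac <- dt_months / ae$window_months
  out <- ae
  out$p_serious <- 1 - (1 - ae$p_serious)^frac
  out$p_nonserious <- 1 - (1 - ae$p_nonserious)^frac
  out$window_months <- dt_months
  out
}

# Per-state cost of one cycle of length dt months for one arm: direct state
# membership + medications (annual rates scaled by dt) + expected AE cost at
# the cycle-rescaled incidence. Returns a length-5 vector.
cycle_state_costs <- function(params, arm, dt_months) {
  c_supp <- supplemental_cost(params$mix, params$cost_table,
                              scale = params$supplemental_scale)
  c_surg <- reoperation_cost(params$mix, params$cost_table)
  aec <- scale_ae_window(params$ae, dt_months)
  ae_cost <- vapply(1:5, function(s) {
    expected_ae_cost(s, arm, aec, c_supp, c_surg, window_scale = 1)
  }, numeric(1))
  (params$state_costs + params$medication_costs) * dt_months / 12 + ae_cost
}

# Per-state productivity loss for one cycle (USD); zero vector under the
# health-system perspective.
cycle_state_prod <- function(params, arm, dt_months) {
  a <- match(arm, colnames(params$indirect$p_unable))
  (dt_months / 12) * params$indirect$annual_wage *
    (1 - params$indirect$retiree_fraction) * params$indirect$p_unable[, a]
}

# Transition matrix governing cycle k for an arm: the supplied sequence,
# reusing the final matrix stationarily past its end (extrapolation rule).
arm_matrix <- function(params, arm, k) {
  mats <- params$transitions[[arm]]
  mats[[min(k, length(mats))]]
}

#' Run the cohort Markov model
#'
#' Propagates the initial state distribution through the cycle schedule for
#' one arm, accumulating discounted costs and QALYs. State membership costs
#' and utilities are evaluated at the occupancy after each cycle's
#' transition and discounted at cycle end; the index surgery cost enters
#' undiscounted at t = 0. Under the societal perspective, productivity loss
#' is added to each cycle's cost.
#'
#' @param params A [model_params()] object.
#' @param arm `"TOPS"` or `"TLIF"`.
#' @param horizon_months Analysis horizon (months).
#' @param perspective `"health_system"` or `"societal"`.
#' @return Object of class `cohort_trace`: list with `trace` (per-cycle data
#'   frame: cycle, month, occupancy, discounted cost and QALY increments),
#'   `total_cost`, `total_qaly`, `index_cost`, and run metadata.
#' @export
run_cohort <- function(params, arm = c("TOPS", "TLIF"), horizon_months = 24,
                       perspective = c("health_system", "societal")) {
  arm <- match.arg(arm)
  perspective <- match.arg(perspective)
  schedule <- build_cycle_schedule(horizon_months)
  K <- length(schedule)
  t_end <- cumsum(schedule) / 12

  index_cost <- index_surgery_cost(arm, params$setting, params$mix,
                                   params$cost_table, params$upcharge)

  # per-state cycle costs depend only on cycle length; cache by length
  lens <- unique(schedule)
  cost_by_len <- lapply(lens, function(dt) cycle_state_costs(params, arm, dt))
  prod_by_len <- lapply(lens, function(dt) cycle_state_prod(params, arm, dt))
  names(cost_by_len) <- names(prod_by_len) <- as.character(lens)

  occ <- matrix(NA_real_, K, 5L, dimnames = list(NULL, health_states()))
  cost_inc <- qaly_inc <- numeric(K)
  pi_prev <- as.numeric(params$initial)
  for (k in seq_len(K)) {
    P <- arm_matrix(params, arm, k)
    pi_k <- as.numeric(pi_prev %*% P)
    occ[k, ] <- pi_k
    pi_eval <- if (isTRUE(params$half_cycle)) (pi_prev + pi_k) / 2 else pi_k
    d <- discount_factor(t_end[k], params$discount_rate)
    dt <- schedule[k]
    cvec <- cost_by_len[[as.character(dt)]]
    cost_k <- sum(pi_eval * cvec)
    if (perspective == "societal") {
      cost_k <- cost_k + sum(pi_eval * prod_by_len[[as.character(dt)]])
    }
    cost_inc[k] <- cost_k * d
    qaly_inc[k] <- sum(pi_eval * params$utilities) * (dt / 12) * d
    pi_prev <- pi_k
  }
  trace <- data.frame(cycle = seq_len(K), month = cumsum(schedule),
                      occ, cost_inc = cost_inc, qaly_inc = qaly_inc,
                      check.names = FALSE)
  structure(list(trace = trace,
                 index_cost = index_cost,
                 total_cost = index_cost + sum(cost_inc),
                 total_qaly = sum(qaly_inc),
                 arm = arm, perspective = perspective,
                 horizon_months = horizon_months),
            class = "cohort_trace")
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat(sprintf("Cohort trace: %s, %s perspective, %g-month horizon\n",
              x$arm, x$perspective, x$horizon_months))
  cat(sprintf("  total cost: $%.2f (index $%.2f)  total QALYs: %.4f\n",
              x$total_cost, x$index_cost, x$total_qaly))
  invisible(x)
}

#' Arm totals at several horizons from one cohort run
#'
#' The cycle schedule for a shorter horizon is a prefix of a longer one, so
#' totals at intermediate horizons are cumulative sums of one trace.
#'
#' @inheritParams run_cohort
#' @param horizons Vector of horizons in months (each a cycle boundary of the
#'   longest horizon's schedule).
#' @return Data frame with columns `horizon_months`, `total_cost`,
#'   `total_qaly`.
#' @export
run_cohort_horizons <- function(params, arm, horizons = c(3, 12, 24, 72, 120),
                                perspective = "health_system") {
  ct <- run_cohort(params, arm, max(horizons), perspective)
  months <- ct$trace$month
  idx <- vapply(horizons, function(h) {
    i <- which(abs(months - h) < 1e-9)
    if (!length(i)) stop("horizon ", h, " is not a cycle boundary")
    i
  }, integer(1))
  data.frame(horizon_months = horizons,
             total_cost = ct$index_cost + cumsum(ct$trace$cost_inc)[idx],
             total_qaly = cumsum(ct$trace$qaly_inc)[idx])
}

#' Individual-level microsimulation oracle
#'
#' Simulates `n_patients` independent state paths from the same transition
#' matrices and accumulates each patient's discounted cost and QALYs with the
#' same per-state cycle increments as [run_cohort()]. Sample means converge
#' to the cohort-trace totals; the function is the verification oracle for
#' the deterministic engine.
#'
#' @inheritParams run_cohort
#' @param n_patients Number of simulated patients.
#' @param seed RNG seed.
#' @return List with `mean_cost`, `mean_qaly`, `se_cost`, `se_qaly`, `n`.
#' @export
microsimulate <- function(params, arm = c("TOPS", "TLIF"), horizon_months = 24,
                          n_patients = 1000, seed = 1,
                          perspective = c("health_system", "societal")) {
  arm <- match.arg(arm)
  perspective <- match.arg(perspective)
  if (n_patients < 1) stop("microsimulate: n_patients must be >= 1")
  schedule <- build_cycle_schedule(horizon_months)
  K <- length(schedule)
  t_end <- cumsum(schedule) / 12
  index_cost <- index_surgery_cost(arm, params$setting, params$mix,
                                   params$cost_table, params$upcharge)
  lens <- unique(schedule)
  cost_by_len <- lapply(lens, function(dt) {
    v <- cycle_state_costs(params, arm, dt)
    if (perspective == "societal") v <- v + cycle_state_prod(params, arm, dt)
    v
  })
  names(cost_by_len) <- as.character(lens)

  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  states <- sample.int(5L, n_patients, replace = TRUE, prob = params$initial)
  cost <- rep(index_cost, n_patients)
  qaly <- numeric(n_patients)
  for (k in seq_len(K)) {
    P <- arm_matrix(params, arm, k)
    # vectorised transition: patients in state s draw from row s
    nxt <- integer(n_patients)
    for (s in 1:5) {
      i <- which(states == s)
      if (length(i)) nxt[i] <- sample.int(5L, length(i), replace = TRUE, prob = P[s, ])
    }
    states <- nxt
    d <- discount_factor(t_end[k], params$discount_rate)
    dt <- schedule[k]
    cvec <- cost_by_len[[as.character(dt)]]
    cost <- cost + cvec[states] * d
    qaly <- qaly + params$utilities[states] * (dt / 12) * d
  }
  list(mean_cost = mean(cost), mean_qaly = mean(qaly),
       se_cost = stats::sd(cost) / sqrt(n_patients),
       se_qaly = stats::sd(qaly) / sqrt(n_patients),
       n = n_patients)
}
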