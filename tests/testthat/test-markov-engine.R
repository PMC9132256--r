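test_that("the cycle schedule follows the short-to-long pattern and sums to the horizon", {
  expect_equal(build_cycle_schedule(24), c(1.5, 1.5, 3, 3, 3, 12))
  expect_equal(build_cycle_schedule(3), c(1.5, 1.5))
  expect_equal(build_cycle_schedule(12), c(1.5, 1.5, 3, 3, 3))
  s120 <- build_cycle_schedule(120)
  expect_equal(sum(s120), 120)
  expect_equal(s120, c(1.5, 1.5, 3, 3, 3, rep(12, 9)))
  expect_equal(sum(build_cycle_schedule(10)), 10)  # remainder cycle
  expect_error(build_cycle_schedule(2), ">= 3")
})

test_that("discounting matches the closed form", {
  expect_equal(discount_factor(0, 0.03), 1)
  expect_equal(discount_factor(c(1, 5, 20), 0), rep(1, 3))
  expect_equal(discount_factor(2, 0.03), 1.03^-2)
  expect_equal(discount_factor(2, 0.03), 0.94260, tolerance = 1e-5)
  expect_error(discount_factor(-1, 0.03), ">= 0")
})

test_that("undiscounted unit-utility QALYs equal the horizon exactly (conservation)", {
  p <- toy_params()
  expect_equal(run_cohort(p, "TOPS", 24)$total_qaly, 2.0)
  expect_equal(run_cohort(p, "TLIF", 120)$total_qaly, 10.0)
})

test_that("zero utilities zero out QALYs without touching costs", {
  p1 <- toy_params(utilities = rep(1, 5), state_costs = rep(1000, 5))
  p0 <- toy_params(utilities = rep(0, 5), state_costs = rep(1000, 5))
  r1 <- run_cohort(p1, "TOPS", 24)
  r0 <- run_cohort(p0, "TOPS", 24)
  expect_equal(r0$total_qaly, 0)
  expect_equal(r0$total_cost, r1$total_cost)
})

test_that("occupancy stays on the simplex at every cycle", {
  set.seed(21)
  for (rep in 1:5) {
    tm <- lapply(1:6, function(i) transition_matrix(random_stochastic_matrix(), 1))
    p <- toy_params(initial = random_simplex(),
                    transitions = list(TLIF = tm, TOPS = tm))
    tr <- run_cohort(p, "TOPS", 120)$trace
    occ <- as.matrix(tr[, health_states()])
    expect_equal(unname(rowSums(occ)), rep(1, nrow(occ)), tolerance = 1e-9)
    expect_true(all(occ >= -1e-12))
  }
})

test_that("totals are monotone nonincreasing in the discount rate", {
  fx <- fixture_model_params()
  rates <- c(0, 0.03, 0.08)
  runs <- lapply(rates, function(r) {
    fx$discount_rate <- r
    run_cohort(fx, "TOPS", 120, "societal")
  })
  costs <- vapply(runs, `[[`, numeric(1), "total_cost")
  qalys <- vapply(runs, `[[`, numeric(1), "total_qaly")
  expect_true(all(diff(costs) < 0))
  expect_true(all(diff(qalys) < 0))
})

test_that("societal minus health-system totals equal discounted productivity losses", {
  fx <- fixture_model_params()
  for (arm in c("TOPS", "TLIF")) {
    hs <- run_cohort(fx, arm, 72, "health_system")
    so <- run_cohort(fx, arm, 72, "societal")
    expect_equal(so$total_qaly, hs$total_qaly)
    # recompute the productivity stream from the trace occupancy
    sched <- build_cycle_schedule(72)
    occ <- as.matrix(hs$trace[, health_states()])
    d <- discount_factor(cumsum(sched) / 12, fx$discount_rate)
    a <- match(arm, colnames(fx$indirect$p_unable))
    prod <- sum((occ %*% fx$indirect$p_unable[, a]) * (sched / 12) * d) *
      fx$indirect$annual_wage * (1 - fx$indirect$retiree_fraction)
    expect_equal(so$total_cost - hs$total_cost, prod, tolerance = 1e-8)
  }
})

test_that("the extrapolation rule reuses the final matrix stationarily", {
  drift <- matrix(0.2, 5, 5)
  tm1 <- transition_matrix(diag(5), 1.5)
  tmf <- transition_matrix(drift, 12)
  p <- toy_params(initial = c(1, 0, 0, 0, 0),
                  transitions = list(TLIF = list(tm1), TOPS = list(tm1, tm1, tm1, tm1, tm1, tmf)))
  tr <- run_cohort(p, "TOPS", 120)$trace
  occ <- as.matrix(tr[, health_states()])
  # once the uniform matrix applies (cycle 6 on), occupancy is uniform forever
  for (k in 6:nrow(occ)) expect_equal(unname(occ[k, ]), rep(0.2, 5), tolerance = 1e-12)
})

test_that("the index surgery cost enters undiscounted at baseline", {
  p <- toy_params(discount_rate = 0.2, state_costs = rep(0, 5))
  ct <- run_cohort(p, "TOPS", 24)
  expect_equal(ct$index_cost,
               index_surgery_cost("TOPS", p$setting, p$mix, p$cost_table, p$upcharge))
  expect_equal(ct$total_cost, ct$index_cost + sum(ct$trace$cost_inc))
})

test_that("microsimulation is deterministic under seed and exact for degenerate paths", {
  fx <- fixture_model_params()
  a <- microsimulate(fx, "TOPS", 24, n_patients = 200, seed = 5)
  b <- microsimulate(fx, "TOPS", 24, n_patients = 200, seed = 5)
  expect_identical(a, b)
  # single patient, deterministic start and identity transitions: equals cohort
  p <- toy_params(utilities = c(1, 0.8, 0.6, 0.4, 0.2),
                  state_costs = c(100, 200, 300, 400, 500),
                  discount_rate = 0.03)
  ms <- microsimulate(p, "TLIF", 24, n_patients = 1, seed = 1)
  ct <- run_cohort(p, "TLIF", 24)
  expect_equal(ms$mean_cost, ct$total_cost, tolerance = 1e-10)
  expect_equal(ms$mean_qaly, ct$total_qaly, tolerance = 1e-10)
})

test_that("microsimulation means agree with the cohort trace on the fixture model", {
  fx <- fixture_model_params()
  ms <- microsimulate(fx, "TLIF", 24, n_patients = 10000, seed = 31)
  ct <- run_cohort(fx, "TLIF", 24)
  expect_lt(abs(ms$mean_cost - ct$total_cost), 3.5 * ms$se_cost)
  expect_lt(abs(ms$mean_qaly - ct$total_qaly), 3.5 * ms$se_qaly)
})

test_that("the half-cycle correction averages start and end occupancy", {
  # identity dynamics: start equals end, so the correction changes nothing
  p <- toy_params(utilities = c(1, 0.5, 0.5, 0.5, 0.5), discount_rate = 0.03)
  p_half <- p
  p_half$half_cycle <- TRUE
  expect_equal(run_cohort(p_half, "TOPS", 24)$total_qaly,
               run_cohort(p, "TOPS", 24)$total_qaly)
  # a one-step drift: first cycle evaluates halfway between the states
  drift <- matrix(0, 5, 5); drift[, 2] <- 1
  pd <- toy_params(utilities = c(1, 0, 0, 0, 0),
                   transitions = list(TLIF = list(transition_matrix(drift, 12)),
                                      TOPS = list(transition_matrix(drift, 12))))
  pd_half <- pd; pd_half$half_cycle <- TRUE
  expect_equal(run_cohort(pd, "TOPS", 24)$total_qaly, 0)       # all utility lost at once
  expect_equal(run_cohort(pd_half, "TOPS", 24)$total_qaly, 0.0625)  # half of cycle 1 (1.5 mo)
})

test_that("invalid parameter sets are rejected with informative errors", {
  tm <- transition_matrix(diag(5), 12)
  expect_error(model_params(initial = c(0.5, 0.5, 0, 0, 0.1),
                            transitions = list(TLIF = list(tm), TOPS = list(tm)),
                            utilities = rep(1, 5), state_costs = rep(0, 5)),
               "sum to 1")
  expect_error(model_params(initial = c(1, 0, 0, 0, 0),
                            transitions = list(TLIF = list(tm), TOPS = list()),
                            utilities = rep(1, 5), state_costs = rep(0, 5)),
               "at least one matrix")
  expect_error(model_params(initial = c(1, 0, 0, 0, 0),
                            transitions = list(TLIF = list(tm), TOPS = list(tm)),
                            utilities = rep(2, 5), state_costs = rep(0, 5)),
               "utilities")
  expect_error(transition_matrix(matrix(0.3, 5, 5), 12), "sum to 1")
})
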