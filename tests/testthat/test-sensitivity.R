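test_that("beta fits match the method-of-moments closed form", {
  ab <- beta_from_point_ci(0.5, 0.4, 0.6)
  sd <- 0.2 / 3.92
  absum <- 0.5 * 0.5 / sd^2 - 1
  expect_equal(unname(ab), c(0.5 * absum, 0.5 * absum))
  expect_equal(unname(ab["alpha"]), 47.52, tolerance = 1e-2)
  # fitted mean reproduces the point estimate for assorted valid inputs
  for (case in list(c(0.2, 0.1, 0.35), c(0.9, 0.8, 0.95), c(0.05, 0.02, 0.1))) {
    ab <- beta_from_point_ci(case[1], case[2], case[3])
    expect_equal(unname(ab["alpha"] / sum(ab)), case[1], tolerance = 1e-12)
  }
  expect_error(beta_from_point_ci(0.5, 0.6, 0.4), "inverted")
  expect_error(beta_from_point_ci(0, 0, 0.1), "needs n")
  # boundary estimate with known n applies the half-event correction
  ab0 <- beta_from_point_ci(0, 0, 0.1, n = 45)
  p_corr <- 0.5 / 46
  expect_equal(unname(ab0["alpha"] / sum(ab0)), p_corr, tolerance = 1e-12)
})

test_that("gamma fits reproduce mean and CV exactly", {
  g <- gamma_from_mean_cv(1, 0.153)
  expect_equal(unname(g["shape"]), 1 / 0.153^2)
  expect_equal(unname(g["shape"]), 42.72, tolerance = 1e-2)
  g2 <- gamma_from_mean_cv(24459, 0.153)
  expect_equal(unname(g2["scale"]), 24459 / (1 / 0.153^2))
  expect_equal(unname(g2["shape"] * g2["scale"]), 24459)          # mean
  expect_equal(unname(1 / sqrt(g2["shape"])), 0.153)              # CV
  expect_error(gamma_from_mean_cv(0, 0.153), "> 0")
  expect_error(gamma_from_mean_cv(100, 0), "> 0")
})

test_that("the default registry exposes the 34 costs and 5 utilities", {
  fx <- fixture_model_params()
  reg <- default_owsa_parameters(fx)
  expect_length(reg, 39)
  kinds <- vapply(reg, `[[`, character(1), "kind")
  expect_equal(sum(kinds == "cost"), 34)
  expect_equal(sum(kinds == "utility"), 5)
  # accessors round-trip
  e <- reg[["device_upcharge"]]
  expect_equal(e$get(fx), 4000)
  expect_equal(e$get(e$set(fx, 5000)), 5000)
  # utility writes are clipped to [0, 1]
  u <- reg[["utility_Minimal"]]
  expect_equal(u$get(u$set(fx, 1.4)), 1)
})

test_that("one-way sensitivity behaves directionally and ignores unread parameters", {
  fx <- fixture_model_params()
  reg <- default_owsa_parameters(fx)
  sub <- reg[c("device_upcharge", "medication_cost_Severe", "utility_Minimal")]
  tor <- owsa(fx, fraction = 0.2, registry = sub)
  expect_equal(nrow(tor), 3)
  # medication costs default to zero: no influence, zero tornado range
  med <- tor[tor$parameter == "medication_cost_Severe", ]
  expect_equal(med$range, 0)
  # a dearer device strictly raises the incremental cost
  up <- reg[["device_upcharge"]]
  inc_lo <- incremental(run_cohort(up$set(fx, 3200), "TOPS", 24),
                        run_cohort(up$set(fx, 3200), "TLIF", 24))
  inc_hi <- incremental(run_cohort(up$set(fx, 4800), "TOPS", 24),
                        run_cohort(up$set(fx, 4800), "TLIF", 24))
  expect_gt(inc_hi$delta_cost, inc_lo$delta_cost)
})

test_that("PSA is reproducible, collapses when variances vanish, and draws match moments", {
  fx <- fixture_model_params()
  reg <- default_owsa_parameters(fx)
  a <- run_psa(fx, n_iterations = 40, seed = 7, registry = reg)
  b <- run_psa(fx, n_iterations = 40, seed = 7, registry = reg)
  expect_equal(a, b)
  expect_equal(nrow(a), 40)
  # near-zero CV: every iteration reproduces the base case
  tiny <- run_psa(fx, n_iterations = 5, seed = 1, registry = reg, cv = 1e-5)
  base <- incremental(run_cohort(fx, "TOPS", 24), run_cohort(fx, "TLIF", 24))
  expect_equal(tiny$delta_cost, rep(base$delta_cost, 5), tolerance = 1e-2)
  expect_equal(tiny$delta_qaly, rep(base$delta_qaly, 5), tolerance = 1e-4)
  # drawn cost parameters have the configured means (within 3 SE)
  big <- run_psa(fx, n_iterations = 400, seed = 3, registry = reg)
  draws <- attr(big, "draws")
  for (id in c("cost_index_DRG460", "annual_wage")) {
    m <- reg[[id]]$get(fx)
    se <- 0.153 * m / sqrt(400)
    expect_lt(abs(mean(draws[, id]) - m), 3 * se)
  }
})

test_that("CEAC fractions follow the net-benefit rule and its limits", {
  it <- data.frame(delta_cost = c(-1, 1, 1), delta_qaly = c(0.1, 0.1, -0.1))
  cc <- ceac(it, wtp_grid = c(0, 20, 1e9))
  expect_equal(cc$probability_cost_effective[1], 1 / 3)   # P(delta cost < 0)
  expect_equal(cc$probability_cost_effective[2], 2 / 3)   # brute-force over outcomes
  expect_equal(cc$probability_cost_effective[3], 2 / 3)   # P(delta qaly > 0)
  expect_error(ceac(it[0, ]), "at least one")
  # monotone in wtp for iterations with positive QALY gain
  it2 <- data.frame(delta_cost = rnorm(50, 0, 100), delta_qaly = runif(50, 0.01, 0.1))
  prob <- ceac(it2, wtp_grid = seq(0, 5e4, 1e4))$probability_cost_effective
  expect_true(all(diff(prob) >= 0))
})

test_that("scenario analysis honors overrides and rejects unknown keys", {
  fx <- fixture_model_params()
  base_tab <- cea_table(fx, horizons = 24, perspectives = "health_system")
  sc <- run_scenarios(fx, list(base_again = list(mix = payer_mix(0.5),
                                                 setting = "inpatient")),
                      horizons = 24)
  expect_equal(sc$delta_cost, base_tab$delta_cost, tolerance = 1e-10)
  expect_equal(sc$delta_qaly, base_tab$delta_qaly, tolerance = 1e-12)
  expect_error(run_scenarios(fx, list(bad = list(payer = payer_mix(1)))),
               "unknown override key")
  # the default grid is the 3x3 payer/setting cross minus the base case
  expect_length(default_scenarios(), 8)
  full <- run_scenarios(fx, horizons = c(12, 24))
  expect_equal(nrow(full), 16)
})
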