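test_that("kendall tau handles the perfect-agreement limits and bad input", {
  expect_equal(kendall_tau(c(1, 2, 3), c(10, 20, 30)), 1.0)
  expect_equal(kendall_tau(c(1, 2, 3), c(3, 2, 1)), -1.0)
  expect_error(kendall_tau(1:3, 1:4), "equal length")
  expect_error(kendall_tau(1, 1), "at least 2")
})

test_that("kendall tau matches the brute-force pair-enumeration oracle", {
  # the spec-style 4-point case first
  x <- c(1, 2, 3, 4); y <- c(2, 1, 4, 3)
  expect_equal(kendall_tau(x, y), brute_force_tau_b(x, y))
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(3:50, 1)
    x <- sample(0:10, n, replace = TRUE)     # heavy ties, like VAS
    y <- sample(0:100, n, replace = TRUE)
    expect_equal(kendall_tau(x, y), brute_force_tau_b(x, y), tolerance = 1e-12)
    expect_equal(kendall_tau(x, y), kendall_tau(y, x))
  }
})

test_that("kendall tau is invariant to strictly monotone transforms", {
  set.seed(12)
  x <- sample(0:10, 40, replace = TRUE)
  y <- sample(0:100, 40, replace = TRUE)
  expect_equal(kendall_tau(exp(x), y), kendall_tau(x, y))
  expect_equal(kendall_tau(x, -1 / (y + 1)), kendall_tau(x, y))
})

test_that("the large-sample contingency-table path agrees with stats::cor", {
  set.seed(13)
  n <- 3000  # above the fast-path threshold
  x <- sample(seq(0, 10, 0.5), n, replace = TRUE)
  y <- round(pmin(pmax(8 * x + rnorm(n, 0, 15), 0), 100))
  expect_equal(kendall_tau(x, y), cor(x, y, method = "kendall"), tolerance = 1e-12)
})

test_that("state partition fitting recovers exact linear data and rejects degenerate input", {
  part <- fit_state_partition(c(0, 5, 10, 2, 7), c(0, 50, 100, 20, 70))
  expect_equal(part$slope, 10)
  expect_equal(part$intercept, 0, tolerance = 1e-12)
  expect_equal(part$thresholds, c(20, 40, 60, 80))
  expect_error(fit_state_partition(rep(5, 6), c(1, 2, 3, 4, 5, 6)), "zero variance")
  expect_error(fit_state_partition(1:3, c(1, 2, 3)), ">= 5")
  expect_error(state_partition(10, 0, thresholds = c(40, 20, 60, 80)), "ascending")
})

test_that("state classification covers the plane with half-open severity bands", {
  part <- state_partition(slope = 10, intercept = 0)
  expect_equal(classify_state(0, 0, part), "Minimal")
  expect_equal(classify_state(10, 100, part), "Bedbound")
  # composite exactly on a threshold goes to the more severe band's base
  expect_equal(classify_state(4, 40, part), "Severe")   # composite 40
  expect_equal(classify_state(2, 20, part), "Moderate") # composite 20
  expect_error(classify_state(11, 50, part), "VAS out of range")
  expect_error(classify_state(5, 101, part), "ODI out of range")
  # exhaustive grid scan against the bin definition
  grid <- expand.grid(vas = seq(0, 10, 0.5), odi = seq(0, 100, 5))
  comp <- composite_score(grid$vas, grid$odi, part)
  oracle <- cut(comp, c(-Inf, 20, 40, 60, 80, Inf), right = FALSE,
                labels = health_states())
  expect_equal(classify_state(grid$vas, grid$odi, part), as.character(oracle))
})

test_that("classification is monotone in the composite score", {
  part <- state_partition(slope = 8, intercept = 5)
  set.seed(14)
  vas <- runif(200, 0, 10); odi <- runif(200, 0, 100)
  comp <- composite_score(vas, odi, part)
  idx <- classify_state(vas, odi, part, as_index = TRUE)
  ord <- order(comp)
  expect_true(all(diff(idx[ord]) >= 0))
})

test_that("transition estimation counts frequencies and defaults empty rows to identity", {
  tm <- estimate_transition_matrix(
    from = c("Severe", "Severe", "Severe", "Severe"),
    to   = c("Minimal", "Minimal", "Severe", "Severe"),
    interval_months = 3)
  expect_equal(unname(tm["Severe", ]), c(0.5, 0, 0.5, 0, 0))
  expect_equal(unname(tm["Minimal", ]), c(1, 0, 0, 0, 0))  # unobserved row
  expect_equal(attr(tm, "interval_months"), 3)
  empty <- estimate_transition_matrix(character(0), character(0), 3)
  expect_equal(unclass(empty)[1:5, 1:5], diag(5), ignore_attr = TRUE)
  expect_error(estimate_transition_matrix("Severe", "Minimal", 0), "positive")
})

test_that("transition estimation recovers a known matrix as the sample grows", {
  set.seed(15)
  truth <- matrix(c(
    0.80, 0.15, 0.05, 0.00, 0.00,
    0.20, 0.60, 0.15, 0.05, 0.00,
    0.05, 0.25, 0.50, 0.15, 0.05,
    0.00, 0.10, 0.30, 0.50, 0.10,
    0.00, 0.05, 0.15, 0.30, 0.50), 5, 5, byrow = TRUE)
  l1_err <- function(n_per_row) {
    from <- rep(1:5, each = n_per_row)
    to <- vapply(from, function(s) sample.int(5, 1, prob = truth[s, ]), integer(1))
    est <- estimate_transition_matrix(from, to, 3)
    max(rowSums(abs(unclass(est)[1:5, 1:5] - truth)))
  }
  e500 <- l1_err(500)
  e5000 <- l1_err(5000)
  expect_lt(e5000, 0.05)
  expect_lt(e5000, e500 + 0.02)  # error shrinks with sample size
  # estimates are always row-stochastic
  set.seed(16)
  for (rep in 1:10) {
    n <- sample(5:60, 1)
    est <- estimate_transition_matrix(sample.int(5, n, TRUE), sample.int(5, n, TRUE), 1.5)
    expect_equal(unname(rowSums(est)), rep(1, 5), tolerance = 1e-12)
    expect_true(all(est >= 0 & est <= 1))
  }
})

test_that("interval-wise estimation from longitudinal records groups by spacing and arm", {
  visits <- data.frame(
    patient_id = rep(1:2, each = 3),
    arm = rep(c("TOPS", "TLIF"), each = 3),
    visit_month = rep(c(0, 3, 6), 2),
    state = c("Severe", "Moderate", "Minimal", "Crippled", "Crippled", "Severe"))
  est <- estimate_transitions_by_interval(visits)
  expect_named(est, c("TLIF", "TOPS"))
  expect_equal(unname(est$TOPS[["3"]]["Severe", "Moderate"]), 1)
  expect_equal(unname(est$TLIF[["3"]]["Crippled", "Crippled"]), 0.5)
  expect_equal(attr(est$TOPS[["3"]], "interval_months"), 3)
})

test_that("partition and matrices survive a JSON round trip", {
  part <- state_partition(9.5, 2.1)
  tm <- estimate_transition_matrix(c("Severe", "Severe"), c("Minimal", "Severe"), 3)
  path <- tempfile(fileext = ".json")
  write_states_json(list(partition = part, tm = tm), path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$partition$slope, 9.5)
  expect_equal(back$partition$thresholds, c(20, 40, 60, 80))
  expect_equal(back$tm$interval_months, 3)
})
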