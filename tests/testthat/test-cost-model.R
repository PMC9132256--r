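test_that("payer blending averages rates and reproduces pure rates at the corners", {
  item <- list(medicare = 100, private = 200)
  expect_equal(blended_rate(item, payer_mix(0.5)), 150)
  expect_equal(blended_rate(item, payer_mix(1)), 100)
  expect_equal(blended_rate(item, payer_mix(0)), 200)
  expect_equal(blended_rate(list(medicare = 24459, private = 1.5 * 24459), payer_mix(0.5)),
               30573.75)
  expect_error(blended_rate(list(medicare = 100, private = NA), payer_mix(0.5)),
               "private rate required")
  expect_error(payer_mix(0.7, 0.5), "sum to 1")
})

test_that("index surgery cost assembles the fee schedule correctly", {
  tab <- load_cost_table()
  # Medicare-only inpatient fusion: facility DRG 460 plus the component fees
  expect_equal(index_surgery_cost("TLIF", "inpatient", payer_mix(1), tab), 26900)
  # arthroplasty carries the flat device upcharge: Medicare facility 28459
  expect_equal(index_surgery_cost("TOPS", "inpatient", payer_mix(1), tab), 30900)
  expect_equal(index_surgery_cost("TOPS", "inpatient", payer_mix(1), tab, upcharge = 0),
               index_surgery_cost("TLIF", "inpatient", payer_mix(1), tab))
  # default private = 1.5x Medicare, so a 50/50 blend is 1.25x Medicare + upcharge
  expect_equal(index_surgery_cost("TLIF", "inpatient", payer_mix(0.5), tab), 1.25 * 26900)
  expect_equal(index_surgery_cost("TOPS", "inpatient", payer_mix(0.5), tab),
               1.25 * 26900 + 4000)
  # outpatient facility is cheaper; mixed averages the two settings
  ip <- index_surgery_cost("TLIF", "inpatient", payer_mix(1), tab)
  op <- index_surgery_cost("TLIF", "outpatient", payer_mix(1), tab)
  mx <- index_surgery_cost("TLIF", "mixed", payer_mix(1), tab)
  expect_lt(op, ip)
  expect_equal(mx, (ip + op) / 2)
  expect_error(index_surgery_cost("TLIF", "inpatient", payer_mix(1),
                                  tab[tab$code != "63047", ]),
               "missing required item")
})

test_that("reoperation cost sums the revision fee schedule and is linear in rates", {
  tab <- load_cost_table()
  expect_equal(reoperation_cost(payer_mix(1), tab), 42869)
  expect_equal(reoperation_cost(payer_mix(1), tab), reoperation_cost(payer_mix(1), tab))
  tab2 <- tab
  tab2$private <- 2 * tab2$medicare
  expect_equal(reoperation_cost(payer_mix(0.5), tab2), 1.5 * 42869)
})

test_that("the supplemental bundle is one visit, one MRI, one injection, six PT sessions", {
  tab <- load_cost_table()
  expect_equal(supplemental_cost(payer_mix(1), tab),
               51.90 + 224.52 + 88.66 + 6 * 31.35)
  expect_equal(supplemental_cost(payer_mix(1), tab, scale = 2),
               2 * supplemental_cost(payer_mix(1), tab))
})

test_that("expected AE cost reproduces the hand-computed severe-state fusion example", {
  ae <- load_ae_params()
  # serious 13.04% split 66.67/33.33 supplemental/surgery; nonserious 4.35% all supplemental
  got <- expected_ae_cost("Severe", "TLIF", ae, c_supplemental = 500, c_surgery = 42869)
  expect_equal(got, 0.1304 * (0.6667 * 500 + 0.3333 * 42869) + 0.0435 * 500,
               tolerance = 1e-6)
  expect_equal(expected_ae_cost("Severe", "TLIF", ae, 500, 42869, window_scale = 0), 0)
  # a state/arm with zero incidence costs nothing
  ae0 <- ae; ae0$p_serious[] <- 0; ae0$p_nonserious[] <- 0
  expect_equal(expected_ae_cost("Crippled", "TOPS", ae0, 500, 42869), 0)
})

test_that("AE tables load with valid probabilities and normalized action splits", {
  ae <- load_ae_params()
  expect_true(all(ae$p_serious >= 0 & ae$p_serious <= 1))
  expect_true(all(ae$p_nonserious >= 0 & ae$p_nonserious <= 1))
  expect_true(all(ae$serious_surgery >= 0 & ae$serious_surgery <= 1))
  # the moderate/TOPS serious split is printed as 0.50%/0.50%: renormalized 50/50
  expect_equal(unname(ae$serious_surgery["Moderate", "TOPS"]), 0.5)
  # all-zero action cells default to supplemental-only
  expect_equal(unname(ae$serious_surgery["Bedbound", "TOPS"]), 0)
})

test_that("productivity loss respects retirement, concentration, and linearity", {
  ind <- indirect_params(annual_wage = 50000, p_unable = c(0, 0, 1, 0, 0),
                         retiree_fraction = 0)
  occ <- c(0, 0, 1, 0, 0)
  expect_equal(productivity_loss(occ, "TLIF", ind, cycle_years = 1), 50000)
  expect_equal(productivity_loss(occ, "TLIF", ind, cycle_years = 0.5), 25000)
  all_retired <- indirect_params(annual_wage = 50000, retiree_fraction = 1)
  expect_equal(productivity_loss(occ, "TOPS", all_retired, 1), 0)
})

test_that("cost table loading fills private rates and applies inflation at load", {
  tab <- load_cost_table(private_multiplier = 2)
  expect_equal(tab$private, 2 * tab$medicare)
  infl <- load_cost_table(inflation = 1.1)
  base <- load_cost_table()
  expect_equal(infl$medicare, 1.1 * base$medicare)
})
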