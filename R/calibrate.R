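#' Published base-case totals used for engine calibration
#'
#' Per-arm discounted cost and QALY totals of the published base-case
#' analysis (both perspectives, five horizons). These are the calibration
#' targets the packaged fixture parameter set was back-solved against; they
#' also anchor the reproduction checks in the test suite.
#'
#' @return Data frame: `perspective`, `horizon_months`, `arm`, `cost`, `qaly`.
#' @export
load_reference_results <- function() {
  path <- system.file("extdata", "reference_results.csv", package = "facetCEA")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# --- internal fast evaluator -------------------------------------------------
#
# Replicates run_cohort()'s accumulation arithmetic for the calibration
# trajectory family: cycles 1-2 at a constant occupancy piA, cycles 3-5 at
# piB, and cycles 6+ evolving under a single 12-month matrix P12 (the
# engine's extrapolation rule). Exactness against run_cohort is asserted by
# verify_calibration().

calib_context <- function(ae = load_ae_params(), cost_table = load_cost_table(),
                          mix = payer_mix(), indirect = indirect_params(),
                          discount_rate = 0.03, upcharge = 4000,
                          setting = "inpatient") {
  schedule <- build_cycle_schedule(120)
  t_end <- cumsum(schedule) / 12
  d <- discount_factor(t_end, discount_rate)
  c_supp <- supplemental_cost(mix, cost_table)
  c_surg <- reoperation_cost(mix, cost_table)
  ae_row <- function(arm, dt) {
    sc <- scale_ae_window(ae, dt)
    vapply(1:5, function(s) expected_ae_cost(s, arm, sc, c_supp, c_surg), numeric(1))
  }
  ae_mat <- lapply(c(TLIF = "TLIF", TOPS = "TOPS"), function(a) {
    t(vapply(schedule, function(dt) ae_row(a, dt), numeric(5)))
  })
  list(schedule = schedule, t_end = t_end, d = d, ae_mat = ae_mat,
       index = c(TLIF = index_surgery_cost("TLIF", setting, mix, cost_table, upcharge),
                 TOPS = index_surgery_cost("TOPS", setting, mix, cost_table, upcharge)),
       wage_factor = indirect$annual_wage * (1 - indirect$retiree_fraction),
       horizons = c(3, 12, 24, 72, 120),
       hz_idx = c(2L, 5L, 6L, 10L, 14L),
       ae = ae, cost_table = cost_table, mix = mix, indirect = indirect,
       discount_rate = discount_rate, upcharge = upcharge, setting = setting)
}

softmax5 <- function(z4) {
  e <- exp(c(0, z4))
  e / sum(e)
}

# Occupancy path over the 14 cycles of the 120-month schedule.
calib_path <- function(piA, piB, P12) {
  occ <- matrix(NA_real_, 14L, 5L)
  occ[1L, ] <- piA; occ[2L, ] <- piA
  occ[3L, ] <- piB; occ[4L, ] <- piB; occ[5L, ] <- piB
  prev <- piB
  for (k in 6:14) {
    prev <- as.numeric(prev %*% P12)
    occ[k, ] <- prev
  }
  occ
}

# Cumulative discounted totals at the five horizons for one arm.
calib_totals <- function(ctx, arm, occ, u, cc) {
  dt12 <- ctx$schedule / 12
  qinc <- as.numeric(occ %*% u) * dt12 * ctx$d
  cinc <- (as.numeric(occ %*% cc) * dt12 + rowSums(occ * ctx$ae_mat[[arm]])) * ctx$d
  prodw <- occ * (dt12 * ctx$wage_factor * ctx$d)
  i <- ctx$hz_idx
  list(qaly = cumsum(qinc)[i],
       cost_hs = ctx$index[[arm]] + cumsum(cinc)[i],
       prod_weights = prodw)
}

# Profile out the per-arm unable-to-work probabilities: given the occupancy
# path they enter the societal targets linearly, so solve the 5x5 group
# system by ridge-regularised least squares (the trajectory can make the
# system ill-conditioned) and clip to [0, 1].
solve_p_unable <- function(ctx, cost_hs, prod_weights, target_soc) {
  i <- ctx$hz_idx
  cumw <- apply(prod_weights, 2L, cumsum)[i, , drop = FALSE]
  G <- rbind(cumw[1L, ], diff(cumw))
  s <- c(target_soc[1L] - cost_hs[1L], diff(target_soc - cost_hs))
  gtg <- crossprod(G)
  lam <- 1e-6 * mean(diag(gtg))
  p <- as.numeric(solve(gtg + diag(lam, 5L), crossprod(G, s)))
  pmin(pmax(p, 0), 1)
}

# Residual vector (relative errors over the 15 target cells) for one arm.
arm_residuals <- function(ctx, arm, block, u, cc, targets) {
  occ <- calib_path(block$piA, block$piB, block$P12)
  tot <- calib_totals(ctx, arm, occ, u, cc)
  tg <- targets[[arm]]
  p_un <- solve_p_unable(ctx, tot$cost_hs, tot$prod_weights, tg$cost_soc)
  soc <- tot$cost_hs + cumsum(as.numeric(tot$prod_weights %*% p_un))[ctx$hz_idx]
  c((tot$qaly - tg$qaly) / tg$qaly,
    (tot$cost_hs - tg$cost_hs) / tg$cost_hs,
    (soc - tg$cost_soc) / tg$cost_soc)
}

unpack_block <- function(z28) {
  list(piA = softmax5(z28[1:4]),
       piB = softmax5(z28[5:8]),
       P12 = t(vapply(0:4, function(r) softmax5(z28[8 + r * 4 + 1:4]), numeric(5))))
}

# Shared parameters, constrained to the clinically sensible ordering:
# utilities strictly decreasing with severity (top utility + 4 positive
# gaps), annual costs nondecreasing (log10 base cost + 4 nonnegative log
# increments).
unpack_shared <- function(z10) {
  u <- z10[1] - cumsum(c(0, z10[2:5]))
  cc <- 10^(z10[6] + cumsum(c(0, z10[7:10])))
  list(u = u, cc = cc)
}

# Inverse of softmax5 for a probability vector (logits relative to state 1).
prob_logits <- function(p) {
  p <- pmax(p, 1e-6)
  log(p[2:5] / p[1])
}

calib_targets_list <- function(reference = load_reference_results()) {
  out <- list()
  for (arm in c("TOPS", "TLIF")) {
    hs <- reference[reference$arm == arm & reference$perspective == "health_system", ]
    so <- reference[reference$arm == arm & reference$perspective == "societal", ]
    hs <- hs[order(hs$horizon_months), ]
    so <- so[order(so$horizon_months), ]
    out[[arm]] <- list(qaly = hs$qaly, cost_hs = hs$cost, cost_soc = so$cost)
  }
  out
}

#' Back-solve a fixture parameter set from published base-case totals
#'
#' Calibrates per-state utilities, per-state annual direct costs, per-arm
#' occupancy trajectories (two free early distributions realised as
#' rank-one transition matrices, plus a single 12-month matrix reused
#' stationarily from the second year on), and per-arm unable-to-work
#' probabilities, so that [run_cohort()] reproduces the published per-arm
#' discounted cost and QALY totals at every horizon and perspective. The
#' adverse-event tables, fee schedule, payer mix, device upcharge and
#' discount rate enter mechanically and are not varied.
#'
#' The fit minimises squared relative errors over all 30 target cells with
#' nlminb: per-arm trajectory blocks alternate with the shared
#' utility/cost parameters for a few rounds, followed by a joint polish;
#' the unable-to-work probabilities are profiled out linearly throughout.
#'
#' @param reference Target totals, default [load_reference_results()].
#' @param rounds Alternating block/shared rounds before the joint polish.
#' @param maxit Iteration cap per nlminb call.
#' @param quiet Suppress progress messages.
#' @return List with the calibrated pieces (`utilities`, `state_costs`,
#'   per-arm `transitions` as 6 cycle matrices, `p_unable` matrix), the
#'   achieved `objective` (sum of squared relative errors), and the
#'   assembled `params` ([model_params()]).
#' @export
calibrate_fixture <- function(reference = load_reference_results(),
                              rounds = 10, maxit = 3000, quiet = TRUE) {
  ctx <- calib_context()
  targets <- calib_targets_list(reference)
  say <- function(...) if (!quiet) message(...)

  shared <- c(0.93, 0.12, 0.10, 0.12, 0.16,      # top utility + gaps
              log10(500), 0.30, 0.20, 0.30, 1.50) # log10 base cost + log gaps
  shared_lo <- c(0.60, rep(0.02, 4), 1.5, rep(0, 4))
  shared_hi <- c(0.98, rep(0.25, 4), 4.0, rep(1.6, 4))
  drift_start <- function(r) {
    as.numeric(t(vapply(1:5, function(i) {
      prob_logits(0.7 * (1:5 == i) + 0.3 * r)
    }, numeric(4))))
  }
  blocks <- list(
    TOPS = c(prob_logits(c(0.35, 0.25, 0.20, 0.10, 0.10)),
             prob_logits(c(0.40, 0.30, 0.20, 0.07, 0.03)),
             drift_start(c(0.50, 0.25, 0.20, 0.04, 0.01))),
    TLIF = c(prob_logits(c(0.30, 0.15, 0.15, 0.10, 0.30)),
             prob_logits(c(0.35, 0.30, 0.20, 0.10, 0.05)),
             drift_start(c(0.20, 0.25, 0.30, 0.20, 0.05))))
  blk_lo <- rep(-25, 28); blk_hi <- rep(25, 28)

  arm_obj <- function(z, arm, sh) {
    sum(arm_residuals(ctx, arm, unpack_block(z), sh$u, sh$cc, targets)^2) +
      1e-9 * sum(z^2)
  }
  # keep the bottom utility positive and the top state cost within reason
  shared_penalty <- function(sh) {
    1e4 * max(0, 0.02 - sh$u[5])^2 + 10 * max(0, (sh$cc[5] - 3e5) / 1e5)^2
  }
  shared_obj <- function(z10) {
    sh <- unpack_shared(z10)
    shared_penalty(sh) + sum(vapply(c("TOPS", "TLIF"), function(a) {
      sum(arm_residuals(ctx, a, unpack_block(blocks[[a]]), sh$u, sh$cc, targets)^2)
    }, numeric(1)))
  }

  for (r in seq_len(rounds)) {
    sh <- unpack_shared(shared)
    for (arm in c("TOPS", "TLIF")) {
      fit <- stats::nlminb(blocks[[arm]], arm_obj, arm = arm, sh = sh,
                           lower = blk_lo, upper = blk_hi,
                           control = list(iter.max = maxit, eval.max = 3 * maxit))
      blocks[[arm]] <- fit$par
    }
    fit <- stats::nlminb(shared, shared_obj, lower = shared_lo, upper = shared_hi,
                         control = list(iter.max = maxit, eval.max = 3 * maxit))
    shared <- fit$par
    say("round ", r, ": objective ", signif(fit$objective, 4))
  }

  joint_obj <- function(z) {
    sh <- unpack_shared(z[1:10])
    shared_penalty(sh) + sum(vapply(c("TOPS", "TLIF"), function(a) {
      off <- if (a == "TOPS") 10L else 38L
      sum(arm_residuals(ctx, a, unpack_block(z[off + 1:28]), sh$u, sh$cc, targets)^2)
    }, numeric(1)))
  }
  z0 <- c(shared, blocks$TOPS, blocks$TLIF)
  jlo <- c(shared_lo, blk_lo, blk_lo)
  jhi <- c(shared_hi, blk_hi, blk_hi)
  polish <- function(z) {
    stats::nlminb(z, joint_obj, lower = jlo, upper = jhi,
                  control = list(iter.max = 4 * maxit, eval.max = 12 * maxit))
  }
  fit <- polish(z0)
  say("joint polish: objective ", signif(fit$objective, 4))
  # deterministic jittered restarts to escape shallow local minima
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(1)
  for (pass in 1:4) {
    jit <- fit$par + stats::rnorm(length(z0), 0, 0.15)
    jit[1:10] <- fit$par[1:10]  # keep the shared block anchored
    cand <- polish(pmin(pmax(jit, jlo), jhi))
    say("restart ", pass, ": objective ", signif(cand$objective, 4))
    if (cand$objective < fit$objective) fit <- cand
  }

  sh <- unpack_shared(fit$par[1:10])
  p_unable <- matrix(NA_real_, 5L, 2L,
                     dimnames = list(health_states(), c("TLIF", "TOPS")))
  transitions <- list()
  for (arm in c("TOPS", "TLIF")) {
    off <- if (arm == "TOPS") 10L else 38L
    b <- unpack_block(fit$par[off + 1:28])
    occ <- calib_path(b$piA, b$piB, b$P12)
    tot <- calib_totals(ctx, arm, occ, sh$u, sh$cc)
    p_unable[, arm] <- solve_p_unable(ctx, tot$cost_hs, tot$prod_weights,
                                      targets[[arm]]$cost_soc)
    rank1 <- function(p) matrix(rep(p, each = 5L), 5L, 5L)
    transitions[[arm]] <- list(
      transition_matrix(rank1(b$piA), 1.5), transition_matrix(rank1(b$piA), 1.5),
      transition_matrix(rank1(b$piB), 3), transition_matrix(rank1(b$piB), 3),
      transition_matrix(rank1(b$piB), 3), transition_matrix(b$P12, 12))
  }
  params <- model_params(initial = c(0, 0.04, 0.27, 0.39, 0.30),
                         transitions = transitions,
                         utilities = sh$u, state_costs = sh$cc,
                         ae = ctx$ae, cost_table = ctx$cost_table,
                         mix = ctx$mix,
                         indirect = indirect_params(
                           annual_wage = ctx$indirect$annual_wage,
                           p_unable = p_unable,
                           retiree_fraction = ctx$indirect$retiree_fraction),
                         setting = ctx$setting, upcharge = ctx$upcharge,
                         discount_rate = ctx$discount_rate)
  list(utilities = sh$u, state_costs = sh$cc, p_unable = p_unable,
       transitions = transitions, objective = fit$objective,
       theta = fit$par, params = params)
}

#' Compare a parameter set's engine output against the reference totals
#'
#' @param params A [model_params()] object.
#' @param reference Target totals, default [load_reference_results()].
#' @return Data frame with per-cell model values and relative errors.
#' @export
verify_calibration <- function(params, reference = load_reference_results()) {
  rows <- list()
  for (persp in unique(reference$perspective)) {
    for (arm in unique(reference$arm)) {
      sub <- reference[reference$perspective == persp & reference$arm == arm, ]
      got <- run_cohort_horizons(params, arm, sub$horizon_months, persp)
      rows[[paste(persp, arm)]] <- data.frame(
        perspective = persp, arm = arm, horizon_months = sub$horizon_months,
        cost = sub$cost, model_cost = got$total_cost,
        cost_rel_err = abs(got$total_cost - sub$cost) / sub$cost,
        qaly = sub$qaly, model_qaly = got$total_qaly,
        qaly_rel_err = abs(got$total_qaly - sub$qaly) / sub$qaly)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Load the packaged calibrated fixture parameter set
#'
#' Reads `inst/extdata/fixture_params.json` (the frozen output of
#' [calibrate_fixture()], a synthetic stand-in back-solved from the
#' published totals) and assembles a full [model_params()] with the packaged
#' fee schedule and adverse-event tables.
#'
#' @param ... Overrides forwarded to [model_params()] (e.g. `mix`,
#'   `setting`, `discount_rate`).
#' @return A [model_params()] object.
#' @export
fixture_model_params <- function(...) {
  path <- system.file("extdata", "fixture_params.json", package = "facetCEA")
  if (path == "") stop("fixture_params.json not found; run the calibration first")
  fx <- jsonlite::read_json(path, simplifyVector = FALSE)
  transitions <- lapply(fx$transitions, function(arm_list) {
    lapply(arm_list, function(m) {
      ent <- do.call(rbind, lapply(m$entries, unlist))
      transition_matrix(ent, m$interval_months)
    })
  })
  fx$initial <- unlist(fx$initial)
  fx$utilities <- unlist(fx$utilities)
  fx$state_costs <- unlist(fx$state_costs)
  p_unable <- do.call(rbind, lapply(fx$p_unable, unlist))
  dimnames(p_unable) <- list(health_states(), c("TLIF", "TOPS"))
  defaults <- list(initial = fx$initial,
                   transitions = transitions,
                   utilities = fx$utilities,
                   state_costs = fx$state_costs,
                   indirect = indirect_params(annual_wage = fx$annual_wage,
                                              p_unable = p_unable,
                                              retiree_fraction = fx$retiree_fraction))
  overrides <- list(...)
  do.call(model_params, utils::modifyList(defaults, overrides))
}

#' Freeze a calibration result to JSON
#'
#' @param fit Result of [calibrate_fixture()].
#' @param path Output path for the fixture JSON.
#' @return `path`, invisibly.
#' @export
write_fixture_json <- function(fit, path) {
  ser <- list(
    initial = c(0, 0.04, 0.27, 0.39, 0.30),
    utilities = fit$utilities,
    state_costs = fit$state_costs,
    p_unable = fit$p_unable,
    annual_wage = 56310,
    retiree_fraction = 0.5,
    objective = fit$objective,
    transitions = lapply(fit$transitions, function(mats) {
      lapply(mats, function(m) list(interval_months = attr(m, "interval_months"),
                                    entries = matrix(as.numeric(m), 5L, 5L)))
    }))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
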