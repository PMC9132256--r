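#' Gaussian-copula correlation from a Kendall tau target
#'
#' Greiner's relation for elliptical copulas: `rho = sin(pi * tau / 2)`. Used
#' to calibrate the VAS/ODI generator so the generated pairs reproduce the
#' target rank correlation.
#'
#' @param tau_target Kendall tau in (-1, 1).
#' @return Copula correlation in (-1, 1).
#' @export
calibrate_copula <- function(tau_target) {
  if (abs(tau_target) >= 1) stop("calibrate_copula: |tau| must be < 1")
  sin(pi * tau_target / 2)
}

# Truncated-normal quantile via the probability-integral transform.
qtruncnorm <- function(u, mean, sd, lo, hi) {
  pl <- stats::pnorm(lo, mean, sd)
  pu <- stats::pnorm(hi, mean, sd)
  q <- stats::qnorm(pl + u * (pu - pl), mean, sd)
  pmin(pmax(q, lo), hi)
}

#' Sample correlated VAS/ODI score pairs
#'
#' Draws from a bivariate Gaussian copula with truncated-normal marginals
#' (VAS on \[0, 10\], ODI on \[0, 100\]) and rounds to the configured score
#' precision. Note that coarse rounding inflates sample tau-b slightly (the
#' pairs removed as ties lean discordant); the default precision is fine
#' enough that the rank correlation of the rounded scores stays within a few
#' thousandths of the copula's tau.
#'
#' @param n Number of pairs (>= 1).
#' @param rho Copula correlation, e.g. from [calibrate_copula()].
#' @param seed RNG seed.
#' @param vas_mean,vas_sd,odi_mean,odi_sd Marginal location/scale before
#'   truncation.
#' @param vas_precision,odi_precision Rounding grid of each score.
#' @return Data frame with columns `vas`, `odi`.
#' @export
sample_vas_odi <- function(n, rho, seed = 1,
                           vas_mean = 7, vas_sd = 2,
                           odi_mean = 55, odi_sd = 18,
                           vas_precision = 0.01, odi_precision = 0.01) {
  if (n < 1) stop("sample_vas_odi: n must be >= 1")
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  vas <- qtruncnorm(stats::pnorm(z1), vas_mean, vas_sd, 0, 10)
  odi <- qtruncnorm(stats::pnorm(z2), odi_mean, odi_sd, 0, 100)
  data.frame(vas = round(vas / vas_precision) * vas_precision,
             odi = round(odi / odi_precision) * odi_precision)
}

#' Default generating transition matrices for the synthetic trial
#'
#' Per-arm 1.5-month recovery kernels (improvement-biased, the arthroplasty
#' arm recovering slightly faster), with longer-interval matrices derived by
#' matrix powers so the per-interval dynamics are mutually consistent.
#'
#' @return Named list (`TLIF`, `TOPS`) of lists of [transition_matrix()]
#'   keyed by interval months (`"1.5"`, `"3"`, `"6"`, `"12"`).
#' @export
default_generating_transitions <- function() {
  tops15 <- matrix(c(
    0.95, 0.05, 0.00, 0.00, 0.00,
    0.25, 0.70, 0.05, 0.00, 0.00,
    0.05, 0.30, 0.60, 0.05, 0.00,
    0.01, 0.09, 0.35, 0.53, 0.02,
    0.00, 0.03, 0.17, 0.35, 0.45), 5, 5, byrow = TRUE)
  tlif15 <- matrix(c(
    0.92, 0.08, 0.00, 0.00, 0.00,
    0.20, 0.72, 0.08, 0.00, 0.00,
    0.04, 0.24, 0.64, 0.08, 0.00,
    0.01, 0.07, 0.28, 0.60, 0.04,
    0.00, 0.02, 0.13, 0.35, 0.50), 5, 5, byrow = TRUE)
  powers <- function(m) {
    m3 <- m %*% m
    m6 <- m3 %*% m3
    m12 <- m6 %*% m6
    list(`1.5` = transition_matrix(m, 1.5), `3` = transition_matrix(m3, 3),
         `6` = transition_matrix(m6, 6), `12` = transition_matrix(m12, 12))
  }
  list(TLIF = powers(tlif15), TOPS = powers(tops15))
}

#' Synthetic-trial configuration
#'
#' The defaults encode the trial conditions the generator emulates: 121
#' patients randomized 2:1 to TOPS vs TLIF, baseline age N(64, 8.26^2), the
#' published baseline health-state distribution, a VAS/ODI rank correlation
#' of 0.655, the follow-up visit schedule, per-state/per-arm adverse-event
#' incidence, and per-state work-status probabilities.
#'
#' @param n_patients Trial size (default 121).
#' @param randomization_ratio TOPS:TLIF allocation ratio (default 2).
#' @param age_mean,age_sd Baseline age distribution (64, 8.26).
#' @param kendall_tau_target VAS/ODI rank-correlation target (0.655).
#' @param initial_distribution Baseline state probabilities.
#' @param visit_schedule Visit months, starting at 0.
#' @param generating_transitions Per-arm per-interval transition matrices.
#' @param ae [load_ae_params()] tables used to draw AEs.
#' @param utilities Per-state utility assigned at each visit.
#' @param p_unable Per-state probability a non-retired patient is unable to
#'   work.
#' @param retiree_fraction Fraction of patients retired (default 0.5).
#' @param seed Master RNG seed.
#' @return List of class `trial_config`.
#' @export
trial_config <- function(n_patients = 121,
                         randomization_ratio = 2,
                         age_mean = 64, age_sd = 8.26,
                         kendall_tau_target = 0.655,
                         initial_distribution = c(0, 0.04, 0.27, 0.39, 0.30),
                         visit_schedule = c(0, 1.5, 3, 6, 12, 24),
                         generating_transitions = default_generating_transitions(),
                         ae = load_ae_params(),
                         utilities = c(0.90, 0.78, 0.68, 0.58, 0.42),
                         p_unable = c(0.05, 0.15, 0.35, 0.60, 0.80),
                         retiree_fraction = 0.5,
                         seed = 20220325) {
  if (randomization_ratio <= 0) stop("trial_config: randomization ratio must be positive")
  if (visit_schedule[1] != 0 || any(diff(visit_schedule) <= 0)) {
    stop("trial_config: visit schedule must be strictly increasing from 0")
  }
  structure(list(n_patients = n_patients,
                 randomization_ratio = randomization_ratio,
                 age_mean = age_mean, age_sd = age_sd,
                 kendall_tau_target = kendall_tau_target,
                 initial_distribution = state_distribution(initial_distribution),
                 visit_schedule = visit_schedule,
                 generating_transitions = generating_transitions,
                 ae = ae, utilities = utilities, p_unable = p_unable,
                 retiree_fraction = retiree_fraction, seed = seed),
            class = "trial_config")
}

# Draw a (vas, odi) pair whose composite score lies inside a state's band
# under the canonical generator partition (slope 10, intercept 0): draw the
# composite from a truncated normal centred in the band, then split it into
# odi = c + delta and vas = (c - delta)/10 with delta truncated so both
# scores stay in range. The construction keeps classify_state() exactly
# consistent with the drawn state.
sample_scores_for_state <- function(state_idx, partition, n = length(state_idx),
                                    comp_sd = 8, delta_sd = 12) {
  cuts <- c(0, partition$thresholds, 100)
  lo <- cuts[state_idx]
  hi <- cuts[state_idx + 1L]
  # keep strictly inside the half-open band so score rounding cannot move the
  # composite across a threshold
  u <- stats::runif(n)
  comp <- qtruncnorm(u, (lo + hi) / 2, comp_sd, lo + 0.05, hi - 0.05)
  dlo <- pmax(-comp, comp - 100)
  dhi <- pmin(100 - comp, comp)
  delta <- qtruncnorm(stats::runif(n), 0, delta_sd, dlo, dhi)
  odi <- comp + delta
  vas <- (comp - delta) / 10
  data.frame(vas = vas, odi = odi, composite = comp)
}

#' Generate a synthetic randomized trial
#'
#' Produces patient-level longitudinal records with the structure the
#' downstream analysis assumes: 2:1 randomization (rounding toward the
#' experimental arm), baseline states drawn from the configured initial
#' distribution, VAS/ODI pairs consistent with each visit's state,
#' state trajectories evolving under the per-interval generating matrices,
#' adverse events drawn per state and arm (incidence rescaled to each visit
#' interval) with actions drawn from the configured splits, and work status
#' drawn per state with retirees never contributing productivity loss.
#'
#' @param config A [trial_config()].
#' @return Data frame, one row per patient-visit, with columns `patient_id`,
#'   `arm`, `age`, `retired`, `visit_month`, `vas`, `odi`, `state`,
#'   `utility`, `work_status`, `ae_serious` (NA when no AE), `ae_action`.
#' @export
generate_trial <- function(config = trial_config()) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)

  n <- config$n_patients
  r <- config$randomization_ratio
  n_tops <- as.integer(ceiling(n * r / (r + 1)))
  arms <- c(rep("TOPS", n_tops), rep("TLIF", n - n_tops))
  ages <- stats::rnorm(n, config$age_mean, config$age_sd)
  retired <- stats::runif(n) < config$retiree_fraction
  partition <- state_partition(slope = 10, intercept = 0)

  visits <- config$visit_schedule
  intervals <- diff(visits)
  arm_cols <- colnames(config$ae$p_serious)

  states <- matrix(NA_integer_, n, length(visits))
  states[, 1L] <- sample.int(5L, n, replace = TRUE,
                             prob = config$initial_distribution)
  for (j in seq_along(intervals)) {
    key <- as.character(intervals[j])
    for (arm in c("TLIF", "TOPS")) {
      mats <- config$generating_transitions[[arm]]
      P <- mats[[key]]
      if (is.null(P)) stop("generate_trial: no generating matrix for interval ", key,
                           " months (arm ", arm, ")")
      rows <- which(arms == arm)
      for (s in 1:5) {
        i <- rows[states[rows, j] == s]
        if (length(i)) states[i, j + 1L] <- sample.int(5L, length(i), replace = TRUE,
                                                       prob = P[s, ])
      }
    }
  }

  out <- vector("list", length(visits))
  for (j in seq_along(visits)) {
    st <- states[, j]
    sc <- sample_scores_for_state(st, partition)
    dt <- if (j == 1L) NA_real_ else intervals[j - 1L]
    ae_serious <- rep(NA, n)
    ae_action <- rep(NA_character_, n)
    if (j > 1L) {
      aec <- scale_ae_window(config$ae, dt)
      a_idx <- match(arms, arm_cols)
      p_ser <- aec$p_serious[cbind(st, a_idx)]
      p_non <- aec$p_nonserious[cbind(st, a_idx)]
      u1 <- stats::runif(n); u2 <- stats::runif(n)
      has_ser <- u1 < p_ser
      has_non <- !has_ser & u2 < p_non  # serious takes precedence within a window
      surg_p <- ifelse(has_ser, aec$serious_surgery[cbind(st, a_idx)],
                       aec$nonserious_surgery[cbind(st, a_idx)])
      has_ae <- has_ser | has_non
      ae_serious[has_ae] <- has_ser[has_ae]
      act <- ifelse(stats::runif(n) < surg_p, "surgery", "supplemental")
      ae_action[has_ae] <- act[has_ae]
    }
    p_un <- config$p_unable[st]
    unable <- !retired & stats::runif(n) < p_un
    work_status <- ifelse(retired, "not_working_unrelated",
                          ifelse(unable, "unable_to_work", "work_no_restriction"))
    out[[j]] <- data.frame(patient_id = seq_len(n), arm = arms, age = ages,
                           retired = retired, visit_month = visits[j],
                           vas = round(sc$vas, 2), odi = round(sc$odi, 2),
                           state = health_states()[st],
                           utility = config$utilities[st],
                           work_status = work_status,
                           ae_serious = ae_serious, ae_action = ae_action,
                           stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  df[order(df$patient_id, df$visit_month), ]
}

#' Write trial records to CSV
#'
#' @param trial Data frame from [generate_trial()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(trial, path) {
  utils::write.csv(trial, path, row.names = FALSE)
  invisible(path)
}
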