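#' Load the direct-cost table
#'
#' Reads the packaged Medicare fee schedule (DRG facility fees and CPT
#' component fees for the index operation, revision surgery, and ancillary
#' care). Private rates that are not supplied explicitly default to
#' `private_multiplier` times the Medicare rate; an inflation multiplier can
#' rescale every rate at load time.
#'
#' @param path CSV with columns `code`, `descriptor`, `category`, `medicare`,
#'   `private` (NA where unknown). Defaults to the packaged table.
#' @param private_multiplier Fallback private/Medicare ratio (default 1.5).
#' @param inflation Multiplier applied to all rates at load (default 1).
#' @return Data frame of cost items (class `cost_table`).
#' @export
load_cost_table <- function(path = NULL, private_multiplier = 1.5, inflation = 1.0) {
  if (is.null(path)) {
    path <- system.file("extdata", "cost_items.csv", package = "facetCEA")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("code", "descriptor", "category", "medicare")
  if (!all(needed %in% names(df))) {
    stop("cost table missing columns: ", paste(setdiff(needed, names(df)), collapse = ", "))
  }
  if (any(df$medicare < 0, na.rm = TRUE)) stop("cost table: negative Medicare rate")
  df$code <- as.character(df$code)
  if (!"private" %in% names(df)) df$private <- NA_real_
  df$private <- suppressWarnings(as.numeric(df$private))
  fill <- is.na(df$private)
  df$private[fill] <- df$medicare[fill] * private_multiplier
  df$medicare <- df$medicare * inflation
  df$private <- df$private * inflation
  class(df) <- c("cost_table", class(df))
  df
}

#' Payer mix
#'
#' @param medicare Weight on Medicare rates in \[0, 1\].
#' @param private Weight on private rates; must sum with `medicare` to 1.
#' @return Named list (class `payer_mix`).
#' @export
payer_mix <- function(medicare = 0.5, private = 1 - medicare) {
  if (medicare < 0 || private < 0 || abs(medicare + private - 1) > 1e-9) {
    stop("payer_mix: weights must be nonnegative and sum to 1")
  }
  structure(list(medicare = medicare, private = private), class = "payer_mix")
}

lookup_item <- function(table, code, category = NULL) {
  keep <- table$code == code
  if (!is.null(category)) keep <- keep & table$category == category
  rows <- table[keep, , drop = FALSE]
  if (nrow(rows) == 0L) stop("cost table: missing required item ", code,
                             if (!is.null(category)) paste0(" (", category, ")"))
  rows[1L, ]
}

#' Payer-blended rate for one cost item
#'
#' @param item One-row data frame (or list) with `medicare` and `private`.
#' @param mix A [payer_mix()].
#' @return Blended USD rate.
#' @export
blended_rate <- function(item, mix) {
  if (mix$private > 0 && (is.null(item$private) || is.na(item$private))) {
    stop("blended_rate: private rate required when private weight > 0")
  }
  priv <- if (is.null(item$private) || is.na(item$private)) 0 else item$private
  mix$medicare * item$medicare + mix$private * priv
}

blended_code <- function(table, code, mix, category = NULL) {
  blended_rate(lookup_item(table, code, category), mix)
}

#' Index surgery cost
#'
#' Facility fee (arm- and setting-specific) plus the component procedure fees
#' (laminectomy 63047, instrumentation 22840, interbody device 22853,
#' allograft 20931, fluoroscopy 77003), payer-blended. The arthroplasty
#' device carries a flat upcharge over the fusion facility fee; the upcharge
#' is a device cost and is applied after payer blending, so at Medicare-only
#' rates the TOPS facility fee equals the fusion DRG fee plus the upcharge.
#' The `mixed` setting averages inpatient and outpatient facility fees 50/50.
#'
#' @param arm `"TOPS"` or `"TLIF"`.
#' @param setting `"inpatient"`, `"outpatient"`, or `"mixed"`.
#' @param mix A [payer_mix()].
#' @param table A [load_cost_table()] result.
#' @param upcharge Device upcharge in USD (default 4000) added for TOPS.
#' @return Total index operation cost in USD.
#' @export
index_surgery_cost <- function(arm = c("TOPS", "TLIF"),
                               setting = c("inpatient", "outpatient", "mixed"),
                               mix = payer_mix(),
                               table = load_cost_table(),
                               upcharge = 4000) {
  arm <- match.arg(arm)
  setting <- match.arg(setting)
  fac_in <- blended_code(table, "DRG460", mix, "index")
  facility <- switch(setting,
    inpatient  = fac_in,
    outpatient = blended_code(table, "APC_INDEX", mix, "index"),
    mixed      = 0.5 * fac_in + 0.5 * blended_code(table, "APC_INDEX", mix, "index"))
  comps <- c("63047", "22840", "22853", "20931", "77003")
  total <- facility + sum(vapply(comps, blended_code, numeric(1),
                                 table = table, mix = mix, category = "index"))
  if (arm == "TOPS") total <- total + upcharge
  total
}

#' Revision / reoperation cost
#'
#' Revision facility fee (DRG 459) plus device removal (22850) and the
#' instrumentation/device/allograft/fluoroscopy components, payer-blended.
#'
#' @inheritParams index_surgery_cost
#' @return Total reoperation cost in USD.
#' @export
reoperation_cost <- function(mix = payer_mix(), table = load_cost_table()) {
  codes <- c("DRG459", "22850", "22840", "22853", "20931", "77003")
  sum(vapply(codes, blended_code, numeric(1),
             table = table, mix = mix, category = "revision"))
}

#' Supplemental-procedure bundle cost
#'
#' The nonoperative response to an adverse event: one office visit, one
#' lumbar MRI (without contrast), one epidural steroid injection, and six
#' physical-therapy sessions, payer-blended. The composition is fixed; the
#' bundle total can be scaled via `scale` (used by sensitivity analyses).
#'
#' @inheritParams index_surgery_cost
#' @param scale Multiplier on the bundle total (default 1).
#' @return Bundle cost in USD.
#' @export
supplemental_cost <- function(mix = payer_mix(), table = load_cost_table(), scale = 1) {
  total <- blended_code(table, "99213", mix, "ancillary") +
    blended_code(table, "72148", mix, "ancillary") +
    blended_code(table, "62322", mix, "ancillary") +
    6 * blended_code(table, "97110", mix, "ancillary")
  scale * total
}

#' Load per-state, per-arm adverse-event tables
#'
#' Reads the packaged AE incidence (serious / nonserious, per health state
#' and trial arm, probabilities over a 12-month observation window) and the
#' subsequent-action splits (supplemental procedures vs reoperation). Action
#' splits are renormalized to sum to 1 per cell; all-zero cells default to
#' 100% supplemental procedures.
#'
#' @param path CSV path; defaults to the packaged table.
#' @param window_months Observation window the incidence refers to (12).
#' @return List of class `ae_params` with array components indexed by
#'   \[state, arm\]: `p_serious`, `p_nonserious`, `serious_surgery`,
#'   `nonserious_surgery` (surgery shares; supplemental = 1 - surgery).
#' @export
load_ae_params <- function(path = NULL, window_months = 12) {
  if (is.null(path)) path <- system.file("extdata", "ae_tables.csv", package = "facetCEA")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  arms <- c("TLIF", "TOPS")
  mk <- function() matrix(0, 5L, 2L, dimnames = list(health_states(), arms))
  p_ser <- mk(); p_non <- mk(); surg_ser <- mk(); surg_non <- mk()
  for (r in seq_len(nrow(df))) {
    s <- as_state_index(df$state[r]); a <- match(df$arm[r], arms)
    if (is.na(a)) stop("ae table: unknown arm ", df$arm[r])
    p_ser[s, a] <- df$p_serious[r]
    p_non[s, a] <- df$p_nonserious[r]
    surg_ser[s, a] <- normalize_split(df$serious_supplemental[r], df$serious_surgery[r])
    surg_non[s, a] <- normalize_split(df$nonserious_supplemental[r], df$nonserious_surgery[r])
  }
  if (any(p_ser < 0 | p_ser > 1 | p_non < 0 | p_non > 1)) {
    stop("ae table: incidence probabilities outside [0, 1]")
  }
  structure(list(p_serious = p_ser, p_nonserious = p_non,
                 serious_surgery = surg_ser, nonserious_surgery = surg_non,
                 window_months = window_months),
            class = "ae_params")
}

# Returns the surgery share of an action split; all-zero cells resolve to
# supplemental-only, and non-unit sums are renormalized.
normalize_split <- function(supp, surg) {
  tot <- supp + surg
  if (tot <= 0) return(0)
  surg / tot
}

#' Expected adverse-event cost for one state and arm
#'
#' Expected per-window cost: incidence of each AE seriousness times the
#' action-split-weighted cost of the response (supplemental bundle or
#' reoperation), scaled linearly by `window_scale` for partial windows.
#'
#' @param state State label or index.
#' @param arm `"TOPS"` or `"TLIF"`.
#' @param ae An `ae_params` object.
#' @param c_supplemental Cost of the supplemental-procedure bundle (USD).
#' @param c_surgery Cost of reoperation (USD).
#' @param window_scale Fraction of the observation window covered in \[0, 1\].
#' @return Expected cost in USD.
#' @export
expected_ae_cost <- function(state, arm, ae, c_supplemental, c_surgery,
                             window_scale = 1) {
  if (c_supplemental < 0 || c_surgery < 0) stop("expected_ae_cost: negative costs")
  s <- as_state_index(state)
  a <- match(arm, colnames(ae$p_serious))
  if (is.na(a)) stop("expected_ae_cost: unknown arm ", arm)
  ser <- ae$p_serious[s, a] *
    ((1 - ae$serious_surgery[s, a]) * c_supplemental + ae$serious_surgery[s, a] * c_surgery)
  non <- ae$p_nonserious[s, a] *
    ((1 - ae$nonserious_surgery[s, a]) * c_supplemental + ae$nonserious_surgery[s, a] * c_surgery)
  window_scale * (ser + non)
}

#' Indirect-cost (productivity) parameters
#'
#' @param annual_wage 2020 US national average annual wage, USD/year.
#' @param p_unable 5x2 matrix (state x arm TLIF/TOPS) of probabilities of
#'   being unable to work, or a length-5 vector applied to both arms.
#' @param retiree_fraction Fraction of the cohort retired (no productivity
#'   loss), default 0.5.
#' @return List of class `indirect_params`.
#' @export
indirect_params <- function(annual_wage = 56310,
                            p_unable = c(0.05, 0.15, 0.35, 0.60, 0.80),
                            retiree_fraction = 0.5) {
  if (is.null(dim(p_unable))) {
    p_unable <- matrix(rep(as.numeric(p_unable), 2L), 5L, 2L,
                       dimnames = list(health_states(), c("TLIF", "TOPS")))
  }
  if (any(p_unable < 0 | p_unable > 1)) stop("indirect_params: probabilities outside [0, 1]")
  if (retiree_fraction < 0 || retiree_fraction > 1) stop("indirect_params: retiree fraction outside [0, 1]")
  structure(list(annual_wage = annual_wage, p_unable = p_unable,
                 retiree_fraction = retiree_fraction),
            class = "indirect_params")
}

#' Productivity loss over a cycle
#'
#' Lost-wage cost of a cycle given the cohort's state occupancy: cycle length
#' in years times the annual wage times the non-retired fraction times the
#' occupancy-weighted probability of being unable to work. Retired patients
#' accrue no productivity loss.
#'
#' @param occupancy Length-5 state-occupancy vector (sums to 1).
#' @param arm `"TOPS"` or `"TLIF"`.
#' @param ind An [indirect_params()] object.
#' @param cycle_years Cycle length in years (>= 0).
#' @return Expected productivity loss in USD.
#' @export
productivity_loss <- function(occupancy, arm, ind, cycle_years) {
  if (cycle_years < 0) stop("productivity_loss: cycle_years must be >= 0")
  a <- match(arm, colnames(ind$p_unable))
  if (is.na(a)) stop("productivity_loss: unknown arm ", arm)
  cycle_years * ind$annual_wage * (1 - ind$retiree_fraction) *
    sum(occupancy * ind$p_unable[, a])
}
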