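#' Health-state labels
#'
#' The model tracks five mutually exclusive pain/disability states built from
#' the visual analog scale (VAS, 0-10) and the Oswestry Disability Index
#' (ODI, 0-100), ordered by worsening disability. The labels follow the
#' conventional ODI severity taxonomy.
#'
#' @return Character vector of the five state labels, least to most severe.
#' @export
health_states <- function() {
  c("Minimal", "Moderate", "Severe", "Crippled", "Bedbound")
}

#' Number of health states
#' @return Integer, always 5.
#' @export
n_states <- function() 5L

#' Kendall rank correlation (tau-b)
#'
#' Tie-corrected Kendall correlation between two ordinal score vectors.
#' For large discretized samples a contingency-table algorithm based on
#' two-dimensional cumulative sums is used (O(levels^2) rather than O(n^2));
#' otherwise the computation is delegated to [stats::cor()].
#'
#' @param x,y Numeric vectors of equal length (n >= 2); ties allowed.
#' @return Tau-b in \[-1, 1\].
#' @export
kendall_tau <- function(x, y) {
  if (length(x) != length(y)) stop("kendall_tau: x and y must have equal length")
  if (length(x) < 2L) stop("kendall_tau: need at least 2 observations")
  if (anyNA(x) || anyNA(y)) stop("kendall_tau: missing values not allowed")
  n <- length(x)
  ux <- unique(x)
  uy <- unique(y)
  # Table-based path pays off when both margins are coarse relative to n.
  if (n > 2000L && length(ux) <= 512L && length(uy) <= 512L) {
    return(kendall_tau_table(x, y))
  }
  stats::cor(x, y, method = "kendall")
}

# Tau-b from the joint frequency table. Concordant pairs are counted via the
# cumulative table strictly below-left of each cell; discordant via below-right.
kendall_tau_table <- function(x, y) {
  tab <- table(factor(x, levels = sort(unique(x))),
               factor(y, levels = sort(unique(y))))
  tab <- unclass(tab)
  n <- sum(tab)
  R <- nrow(tab); C <- ncol(tab)
  # cumulative sums over rows then columns
  cum <- apply(apply(tab, 2L, cumsum), 1L, cumsum)
  cum <- t(cum)  # cum[i,j] = sum tab[1:i, 1:j]
  full_below <- function(i, j) if (i < 1L || j < 1L) 0 else cum[i, j]
  conc <- 0; disc <- 0
  for (i in seq_len(R)) {
    for (j in seq_len(C)) {
      nij <- tab[i, j]
      if (nij == 0) next
      lower_left  <- full_below(i - 1L, j - 1L)
      lower_all   <- full_below(i - 1L, C)
      lower_right <- lower_all - full_below(i - 1L, j)
      conc <- conc + nij * lower_left
      disc <- disc + nij * lower_right
    }
  }
  n0 <- n * (n - 1) / 2
  tx <- rowSums(tab); ty <- colSums(tab)
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  (conc - disc) / sqrt((n0 - n1) * (n0 - n2))
}

#' Fit the VAS/ODI health-state partition
#'
#' Regresses ODI on VAS by least squares and attaches the severity thresholds
#' that cut the composite disability axis into the five states. The default
#' thresholds are the conventional ODI severity bands (20/40/60/80).
#'
#' @param vas Numeric vector of VAS scores in \[0, 10\].
#' @param odi Numeric vector of ODI scores in \[0, 100\], same length.
#' @param thresholds Four strictly ascending cut points on the composite
#'   (ODI-scale) axis. Default `c(20, 40, 60, 80)`.
#' @return An object of class `state_partition` with elements `slope`,
#'   `intercept`, `thresholds`.
#' @export
fit_state_partition <- function(vas, odi, thresholds = c(20, 40, 60, 80)) {
  if (length(vas) != length(odi)) stop("fit_state_partition: length mismatch")
  if (length(vas) < 5L) stop("fit_state_partition: need >= 5 paired observations")
  if (stats::var(vas) <= 0) stop("fit_state_partition: degenerate fit, VAS has zero variance")
  check_thresholds(thresholds)
  fit <- stats::lm(odi ~ vas)
  partition <- list(slope = unname(stats::coef(fit)[2L]),
                    intercept = unname(stats::coef(fit)[1L]),
                    thresholds = as.numeric(thresholds))
  class(partition) <- "state_partition"
  partition
}

check_thresholds <- function(thresholds) {
  if (length(thresholds) != 4L || any(diff(thresholds) <= 0)) {
    stop("thresholds must be 4 strictly ascending cut points")
  }
  invisible(thresholds)
}

#' Manually construct a state partition
#'
#' @param slope ODI units per VAS unit.
#' @param intercept ODI units.
#' @param thresholds Four ascending cut points (composite ODI-scale axis).
#' @return A `state_partition`.
#' @export
state_partition <- function(slope, intercept, thresholds = c(20, 40, 60, 80)) {
  check_thresholds(thresholds)
  structure(list(slope = slope, intercept = intercept,
                 thresholds = as.numeric(thresholds)),
            class = "state_partition")
}

#' Composite disability score
#'
#' Projects a (VAS, ODI) pair onto the fitted composite axis: the mean of the
#' observed ODI and the VAS-predicted ODI.
#'
#' @param vas,odi Numeric vectors (recycled to common length).
#' @param partition A `state_partition`.
#' @return Numeric composite scores on the ODI scale.
#' @export
composite_score <- function(vas, odi, partition) {
  (odi + partition$intercept + partition$slope * vas) / 2
}

#' Classify a (VAS, ODI) pair into a health state
#'
#' Bins the composite disability score by the partition thresholds. Bins are
#' half-open `[lo, hi)`: a score exactly on a threshold is assigned to the
#' more severe side's lower bound, i.e. composite 40 with default thresholds
#' is Severe; boundary handling is deterministic.
#'
#' @param vas Numeric vector in \[0, 10\].
#' @param odi Numeric vector in \[0, 100\].
#' @param partition A `state_partition`.
#' @param as_index Return 1-based state indices instead of labels.
#' @return Character labels (or integer indices) of length `max(length(vas),
#'   length(odi))`.
#' @export
classify_state <- function(vas, odi, partition, as_index = FALSE) {
  if (any(vas < 0 | vas > 10)) stop("classify_state: VAS out of range [0, 10]")
  if (any(odi < 0 | odi > 100)) stop("classify_state: ODI out of range [0, 100]")
  comp <- composite_score(vas, odi, partition)
  idx <- findInterval(comp, partition$thresholds) + 1L
  idx[idx > 5L] <- 5L
  idx[idx < 1L] <- 1L
  if (as_index) idx else health_states()[idx]
}

#' Estimate a transition matrix from observed state changes
#'
#' Row-wise relative frequencies of `(from, to)` transitions observed over a
#' common interval. From-states with no observations default to the identity
#' row (the cohort stays put), keeping the result row-stochastic.
#'
#' @param from,to Vectors of state labels or 1-based indices, equal length.
#' @param interval_months Positive duration the transitions span.
#' @return A `transition_matrix`: a 5x5 row-stochastic matrix with attribute
#'   `interval_months`.
#' @export
estimate_transition_matrix <- function(from, to, interval_months) {
  if (interval_months <= 0) stop("estimate_transition_matrix: interval must be positive")
  if (length(from) != length(to)) stop("estimate_transition_matrix: length mismatch")
  fi <- as_state_index(from)
  ti <- as_state_index(to)
  counts <- matrix(0, 5L, 5L, dimnames = list(health_states(), health_states()))
  for (k in seq_along(fi)) counts[fi[k], ti[k]] <- counts[fi[k], ti[k]] + 1
  mat <- counts
  for (i in 1:5) {
    rs <- sum(counts[i, ])
    if (rs > 0) mat[i, ] <- counts[i, ] / rs else {
      mat[i, ] <- 0; mat[i, i] <- 1
    }
  }
  transition_matrix(mat, interval_months)
}

as_state_index <- function(s) {
  if (is.numeric(s)) {
    idx <- as.integer(s)
    if (any(idx < 1L | idx > 5L)) stop("state index out of range 1..5")
    return(idx)
  }
  idx <- match(as.character(s), health_states())
  if (anyNA(idx)) stop("unknown state label: ", paste(unique(s[is.na(idx)]), collapse = ", "))
  idx
}

#' Construct and validate a transition matrix
#'
#' @param mat 5x5 matrix of probabilities, each row summing to 1.
#' @param interval_months Duration in months the matrix spans.
#' @return `transition_matrix` object.
#' @export
transition_matrix <- function(mat, interval_months) {
  mat <- as.matrix(mat)
  if (!all(dim(mat) == c(5L, 5L))) stop("transition matrix must be 5x5")
  if (any(mat < -1e-12 | mat > 1 + 1e-12)) stop("transition probabilities outside [0, 1]")
  if (any(abs(rowSums(mat) - 1) > 1e-9)) stop("transition matrix rows must sum to 1")
  dimnames(mat) <- list(health_states(), health_states())
  attr(mat, "interval_months") <- interval_months
  class(mat) <- c("transition_matrix", class(mat))
  mat
}

#' Validate a state distribution
#'
#' @param p Length-5 probability vector summing to 1.
#' @return Named numeric vector.
#' @export
state_distribution <- function(p) {
  p <- as.numeric(p)
  if (length(p) != 5L) stop("state distribution must have 5 entries")
  if (any(p < -1e-12)) stop("state distribution has negative entries")
  if (abs(sum(p) - 1) > 1e-9) stop("state distribution must sum to 1")
  stats::setNames(pmax(p, 0), health_states())
}

#' Estimate per-interval transition matrices from longitudinal records
#'
#' Pairs consecutive visits of each patient and estimates one matrix per
#' distinct between-visit interval (months), optionally per arm.
#'
#' @param visits Data frame with columns `patient_id`, `arm`, `visit_month`,
#'   `state` (label or index).
#' @param by_arm Estimate separately per arm (default TRUE).
#' @return Named list (per arm if `by_arm`) of lists of `transition_matrix`,
#'   keyed by interval length in months (as character).
#' @export
estimate_transitions_by_interval <- function(visits, by_arm = TRUE) {
  stopifnot(all(c("patient_id", "visit_month", "state") %in% names(visits)))
  split_arm <- if (by_arm) split(visits, visits$arm) else list(all = visits)
  lapply(split_arm, function(df) {
    df <- df[order(df$patient_id, df$visit_month), ]
    trans <- do.call(rbind, lapply(split(df, df$patient_id), function(p) {
      if (nrow(p) < 2L) return(NULL)
      data.frame(from = p$state[-nrow(p)], to = p$state[-1L],
                 interval = diff(p$visit_month))
    }))
    out <- lapply(split(trans, trans$interval), function(tr) {
      estimate_transition_matrix(tr$from, tr$to, tr$interval[1L])
    })
    out
  })
}

#' Read longitudinal patient-visit records from CSV
#'
#' Expected columns: `patient_id`, `arm`, `visit_month`, `vas`, `odi`,
#' `work_status` (and optionally `state`, `utility`, AE fields).
#'
#' @param path CSV file path.
#' @return Data frame of visits.
#' @export
read_trial_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("patient_id", "arm", "visit_month", "vas", "odi")
  missing <- setdiff(required, names(df))
  if (length(missing)) stop("trial CSV missing columns: ", paste(missing, collapse = ", "))
  df
}

#' Write a state partition or transition matrices to JSON
#'
#' @param x A `state_partition`, a `transition_matrix`, or a (nested) list of
#'   them as produced by [estimate_transitions_by_interval()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_states_json <- function(x, path) {
  ser <- function(obj) {
    if (inherits(obj, "state_partition")) {
      list(slope = obj$slope, intercept = obj$intercept, thresholds = obj$thresholds)
    } else if (inherits(obj, "transition_matrix")) {
      list(interval_months = attr(obj, "interval_months"),
           entries = unclass(matrix(obj, 5L, 5L)))
    } else if (is.list(obj)) {
      lapply(obj, ser)
    } else obj
  }
  jsonlite::write_json(ser(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
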