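# Shared fixtures built in code.

# A deliberately simple model: identity transitions, flat costs, no AEs or
# medications, used where engine arithmetic must be checkable by hand.
zero_ae_params <- function() {
  ae <- load_ae_params()
  ae$p_serious[] <- 0
  ae$p_nonserious[] <- 0
  ae
}

toy_params <- function(utilities = rep(1, 5), state_costs = rep(0, 5),
                       discount_rate = 0, initial = c(1, 0, 0, 0, 0),
                       transitions = NULL, ...) {
  tm <- transition_matrix(diag(5), 12)
  if (is.null(transitions)) transitions <- list(TLIF = list(tm), TOPS = list(tm))
  model_params(initial = initial, transitions = transitions,
               utilities = utilities, state_costs = state_costs,
               ae = zero_ae_params(), discount_rate = discount_rate,
               indirect = indirect_params(p_unable = rep(0, 5)), ...)
}

random_stochastic_matrix <- function() {
  m <- matrix(stats::runif(25, 0.01, 1), 5, 5)
  m / rowSums(m)
}

random_simplex <- function() {
  p <- stats::runif(5)
  p / sum(p)
}

# O(n^2) pair-enumeration tau-b oracle, independent of the implementation.
brute_force_tau_b <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
      if (dx == 0 && dy == 0) { tx <- tx + 1; ty <- ty + 1 }
      else if (dx == 0) tx <- tx + 1
      else if (dy == 0) ty <- ty + 1
      else if (dx == dy) conc <- conc + 1
      else disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}
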