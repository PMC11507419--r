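# shared fixtures and independent oracles

# published annual transition intensities for the three-state ADL model
# (order 1-2, 1-3, 2-1, 2-3, 3-1, 3-2)
printed_rates <- c(`12` = 0.2764, `13` = 0.0003, `21` = 0.4731,
                   `23` = 0.2226, `31` = 0.0068, `32` = 0.1204)

printed_Q <- function() intensity_matrix(printed_rates)

# the one-year probability block as published alongside those intensities
printed_P <- matrix(c(0.8022, 0.1758, 0.0220,
                      0.3014, 0.5452, 0.1534,
                      0.0258, 0.0836, 0.8905), 3, 3, byrow = TRUE)

# independent matrix-exponential oracle: truncated power series
# sum_{k<=nterm} A^k / k!  (adequate to 1e-12 for the small generators here)
expm_series <- function(A, nterm = 50) {
  S <- diag(nrow(A))
  Tk <- diag(nrow(A))
  for (k in seq_len(nterm)) {
    Tk <- Tk %*% A / k
    S <- S + Tk
  }
  dimnames(S) <- NULL
  S
}

# brute-force panel log-likelihood: naive per-pair evaluation, every
# interval probability re-derived through the power-series oracle
loglik_brute <- function(ds, Q) {
  ll <- 0
  for (id in unique(ds$subject)) {
    sub <- ds[ds$subject == id, ]
    if (nrow(sub) < 2) next
    for (j in seq_len(nrow(sub) - 1)) {
      P <- expm_series(unclass(Q) * (sub$time[j + 1] - sub$time[j]))
      ll <- ll + log(P[sub$state[j], sub$state[j + 1]])
    }
  }
  ll
}

# random valid generator for property checks
random_Q <- function() {
  intensity_matrix(stats::setNames(stats::runif(6, 0, 0.8),
                                   c("12", "13", "21", "23", "31", "32")))
}

tiny_panel <- function() {
  panel_data(data.frame(subject = c(1, 1, 1, 2, 2),
                        time = c(0, 1, 2, 0, 1),
                        state = c(1, 1, 2, 3, 3)))
}
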