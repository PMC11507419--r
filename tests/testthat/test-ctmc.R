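test_that("intensity matrix fills the diagonal as negative row sums", {
  Q <- printed_Q()
  expect_equal(unname(diag(Q)), c(-0.2767, -0.6957, -0.1272))
  expect_equal(unname(rowSums(Q)), rep(0, 3))

  Q0 <- intensity_matrix(stats::setNames(rep(0, 6), names(printed_rates)))
  expect_true(all(Q0 == 0))

  expect_error(intensity_matrix(c(`12` = -0.1)), ">= 0")
  expect_error(intensity_matrix(c(`14` = 0.1)), "unknown transition")
})

test_that("covariates scale intensities proportionally", {
  theta <- log(printed_rates)
  m0 <- covariate_model(theta)
  expect_equal(unclass(covariate_intensity(m0)), unclass(printed_Q()),
               tolerance = 1e-12)

  # null coefficients: any covariate value gives the baseline exactly
  bz <- matrix(0, 6, 1, dimnames = list(names(theta), "x"))
  mz <- covariate_model(theta, bz)
  expect_equal(unclass(covariate_intensity(mz, c(x = 3.7))),
               unclass(printed_Q()), tolerance = 1e-12)

  # log(2) on every transition doubles every intensity
  b2 <- matrix(log(2), 6, 1, dimnames = list(names(theta), "x"))
  m2 <- covariate_model(theta, b2)
  Q2 <- covariate_intensity(m2, c(x = 1))
  off <- row(Q2) != col(Q2)
  expect_equal(unclass(Q2)[off], 2 * unclass(printed_Q())[off],
               tolerance = 1e-12)

  # a single-transition effect multiplies only that intensity
  b13 <- matrix(0, 6, 1, dimnames = list(names(theta), "needs_allowances"))
  b13["13", 1] <- log(4.65)
  m13 <- covariate_model(theta, b13)
  Q13 <- covariate_intensity(m13, c(needs_allowances = 1))
  expect_equal(Q13[1, 3], 4.65 * printed_rates[["13"]], tolerance = 1e-12)
  expect_equal(Q13[1, 2], printed_rates[["12"]], tolerance = 1e-12)

  expect_error(covariate_intensity(m13, c(other = 1)), "missing covariate")
})

test_that("transition probabilities are stochastic and handle edge cases", {
  P <- transition_probability(printed_Q(), 1)
  expect_equal(unname(rowSums(P)), rep(1, 3), tolerance = 1e-9)
  expect_true(all(P >= 0 & P <= 1))

  expect_equal(unclass(transition_probability(printed_Q(), 0)), diag(3),
               ignore_attr = TRUE)
  Q0 <- intensity_matrix(matrix(0, 3, 3))
  expect_equal(unclass(transition_probability(Q0, 7)), diag(3),
               ignore_attr = TRUE)
  expect_error(transition_probability(printed_Q(), -1), ">= 0")
})

test_that("matrix exponential matches the power-series oracle to 1e-10", {
  set.seed(202)
  for (rep in 1:10) {
    Q <- random_Q()
    t <- stats::runif(1, 0.1, 3)
    expect_equal(unclass(transition_probability(Q, t)),
                 expm_series(unclass(Q) * t),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("Chapman-Kolmogorov holds on random generators", {
  set.seed(203)
  for (rep in 1:10) {
    Q <- random_Q()
    a <- stats::runif(1, 0.1, 2)
    b <- stats::runif(1, 0.1, 2)
    Pab <- unclass(transition_probability(Q, a + b))
    prod <- unclass(transition_probability(Q, a)) %*%
      unclass(transition_probability(Q, b))
    expect_lt(max(abs(Pab - prod)), 1e-8)
  }
})

test_that("small-interval linearization P(dt) ~ I + Q dt", {
  Q <- printed_Q()
  dt <- 1e-4
  P <- unclass(transition_probability(Q, dt))
  expect_lt(max(abs(P - (diag(3) + unclass(Q) * dt))), 1e-6)  # O(dt^2)
})

test_that("simulated sojourns and jump choices match the generator", {
  Q0 <- intensity_matrix(matrix(0, 3, 3))
  path <- simulate_path(Q0, 2, t_max = 100)
  expect_equal(nrow(path), 1L)
  expect_equal(path$state, 2L)

  set.seed(204)
  Q <- printed_Q()
  # sojourn in state 2 is exponential with rate -q22 = 0.6957
  soj <- replicate(4000, {
    p <- simulate_path(Q, 2, t_max = 200)
    if (nrow(p) > 1) p$time[2] else NA_real_
  })
  soj <- soj[!is.na(soj)]
  expect_equal(mean(soj), 1 / 0.6957, tolerance = 0.05)

  # embedded chain out of state 3: P(next = 2) = q32 / (q31 + q32)
  nxt <- replicate(4000, {
    p <- simulate_path(Q, 3, t_max = 500)
    if (nrow(p) > 1) p$state[2] else NA_integer_
  })
  nxt <- nxt[!is.na(nxt)]
  expect_equal(mean(nxt == 2), 0.1204 / 0.1272, tolerance = 0.02)
})

test_that("paths are read right-continuously at assessment times", {
  path <- structure(data.frame(time = c(0, 0.5), state = c(1L, 2L)),
                    t_max = 2)
  expect_equal(observe_at(path, c(0, 1)), c(1L, 2L))
  expect_equal(observe_at(path, 0.5), 2L)   # state entered at the jump time
  expect_equal(observe_at(path, 0.499), 1L)
  expect_error(observe_at(path, 3), "within")
})

test_that("piecewise-constant time-varying intensities are honoured", {
  # rates switch off after t = 1: a function-valued generator frozen at
  # each state entry
  Qhot <- intensity_matrix(c(`12` = 50))
  Qcold <- intensity_matrix(matrix(0, 3, 3))
  set.seed(205)
  path <- simulate_path(function(t) if (t < 1) Qhot else Qcold,
                        1, t_max = 10)
  expect_equal(path$state[nrow(path)], 2L)   # jumped 1 -> 2 early, then froze
  expect_true(all(path$time[-1] < 1.5))
})

test_that("panel frequencies from simulated paths converge to expm rows", {
  set.seed(206)
  Q <- printed_Q()
  P <- unclass(transition_probability(Q, 1))
  n <- 4000
  to <- vapply(seq_len(n), function(i) {
    observe_at(simulate_path(Q, 2, t_max = 1), 1)
  }, integer(1))
  emp <- tabulate(to, 3) / n
  # chi-square consistency of one-step frequencies against P row 2
  chisq <- n * sum((emp - P[2, ])^2 / P[2, ])
  expect_lt(chisq, qchisq(0.999, df = 2))
})
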