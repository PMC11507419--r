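test_that("panel log-likelihood matches single-pair and trivial cases", {
  pd <- panel_data(data.frame(subject = 1, time = c(0, 1), state = c(1, 1)))
  ll <- panel_loglik(pd, printed_Q())
  # single 1 -> 1 pair over one year: log P11(1), P from the series oracle
  P <- expm_series(unclass(printed_Q()))
  expect_equal(ll, log(P[1, 1]), tolerance = 1e-10)
  expect_equal(ll, log(0.8022), tolerance = 1e-3)  # the published entry

  empty <- panel_data(data.frame(subject = numeric(0), time = numeric(0),
                                 state = integer(0)))
  expect_identical(panel_loglik(empty, printed_Q()), 0)

  # independence: two identical subjects double the log-likelihood
  pd2 <- panel_data(data.frame(subject = c(1, 1, 2, 2), time = c(0, 1, 0, 1),
                               state = c(1, 1, 1, 1)))
  expect_equal(panel_loglik(pd2, printed_Q()), 2 * ll, tolerance = 1e-12)
})

test_that("grouped likelihood equals the brute-force per-pair oracle", {
  set.seed(501)
  for (rep in 1:5) {
    n <- sample(2:5, 1)
    df <- do.call(rbind, lapply(seq_len(n), function(i) {
      nobs <- sample(2:4, 1)
      data.frame(subject = i,
                 time = cumsum(c(0, stats::runif(nobs - 1, 0.5, 2))),
                 state = sample(1:3, nobs, replace = TRUE))
    }))
    pd <- panel_data(df)
    Q <- random_Q()
    expect_equal(panel_loglik(pd, Q), loglik_brute(pd, Q), tolerance = 1e-10)
  }
})

test_that("covariate-model likelihood equals a per-pair oracle", {
  set.seed(502)
  df <- data.frame(subject = rep(1:4, each = 3), time = rep(0:2, 4),
                   state = sample(1:3, 12, replace = TRUE),
                   x = rep(c(0, 1, 0, 1), each = 3))
  pd <- panel_data(df, covariates = "x")
  theta <- log(printed_rates)
  beta <- matrix(stats::runif(6, -0.5, 0.5), 6, 1,
                 dimnames = list(names(theta), "x"))
  model <- covariate_model(theta, beta)
  ll <- panel_loglik(pd, model)
  # oracle: per-pair, covariate at interval start, series expm
  brute <- 0
  for (i in 1:4) {
    sub <- df[df$subject == i, ]
    for (j in 1:2) {
      Qz <- unclass(covariate_intensity(model, c(x = sub$x[j])))
      P <- expm_series(Qz * (sub$time[j + 1] - sub$time[j]))
      brute <- brute + log(P[sub$state[j], sub$state[j + 1]])
    }
  }
  expect_equal(ll, brute, tolerance = 1e-10)
})

test_that("crude initial estimates follow the moment formula and floor", {
  freq <- matrix(c(6647, 1556, 176,
                   1484, 2538, 810,
                   118, 366, 3487), 3, 3, byrow = TRUE)
  q0 <- crude_initial_estimates(freq, mean_interval = 1)
  expect_equal(q0[1, 2], 1556 / 8379, tolerance = 1e-12)
  expect_equal(q0[2, 1], 1484 / 4832, tolerance = 1e-12)

  # doubling all counts leaves the initialisation unchanged
  expect_equal(unclass(crude_initial_estimates(2 * freq, 1)), unclass(q0),
               tolerance = 1e-12)

  # zero off-diagonal counts hit the floor
  fz <- diag(c(10, 10, 10))
  qz <- crude_initial_estimates(fz, 1)
  expect_equal(qz[1, 2], 1e-4)

  expect_warning(crude_initial_estimates(matrix(0, 3, 3), 1), "all-zero")
})

test_that("fitting improves the likelihood and ignores subject order", {
  set.seed(503)
  co <- generate_cohort(cohort_config(n_subjects = 400, seed = 31))
  fit <- msm_fit(co$data)
  expect_true(fit$converged)
  expect_gte(fit$loglik, fit$loglik_init)  # monotone improvement

  perm <- as.data.frame(co$data)
  perm <- perm[order(rev(seq_len(nrow(perm)))), ]
  fit2 <- msm_fit(panel_data(perm, covariates = panel_covariates(co$data)))
  expect_equal(fit2$par, fit$par, tolerance = 1e-8)
})

test_that("a transition never observed is driven to the boundary", {
  # truth has q13 = 0 and no 1 -> 3 pairs can occur in one wave step
  rates <- c(`12` = 0.3, `21` = 0.4, `23` = 0.2, `31` = 0.01, `32` = 0.1)
  set.seed(504)
  cfg <- cohort_config(n_subjects = 300, Q = intensity_matrix(rates),
                       seed = 32)
  co <- generate_cohort(cfg)
  fit <- msm_fit(co$data)
  expect_lt(exp(fit$theta[["13"]]), 0.02)  # pushed toward zero
})

test_that("hazard-ratio tables implement the Wald construction", {
  # synthetic fitted object with known estimates and covariance
  par <- c(stats::setNames(log(printed_rates), paste0("theta.", names(printed_rates))),
           beta.x.12 = 0, beta.x.13 = log(2))
  cov <- diag(c(rep(1e-4, 6), 0.1^2, 1e-12))
  dimnames(cov) <- list(names(par), names(par))
  fake <- structure(list(par = par, covariance = cov,
                         covariates = "x",
                         covariate_transitions = list(x = c("12", "13"))),
                    class = "msm_fit")
  hrt <- hazard_ratios(fake)
  r12 <- hrt[hrt$transition == "12", ]
  expect_equal(r12$hr, 1)
  expect_equal(r12$lower, exp(-1.96 * 0.1), tolerance = 1e-9)
  expect_equal(r12$upper, exp(1.96 * 0.1), tolerance = 1e-9)
  expect_false(r12$significant)
  r13 <- hrt[hrt$transition == "13", ]
  expect_equal(r13$hr, 2, tolerance = 1e-6)  # degenerate SE: HR exactly exp(beta)
  expect_true(all(hrt$lower <= hrt$hr & hrt$hr <= hrt$upper))

  fake$covariance <- NULL
  expect_error(hazard_ratios(fake), "covariance")

  wide <- hr_wide_table(hrt)
  expect_equal(wide$covariate, "x")
  expect_match(wide$`1-3`, "^2\\.00")
})

test_that("an injected covariate effect is recovered with correct scaling", {
  # log-linearity: doubling the generating log-HR on 2 -> 1 roughly doubles
  # the recovered log-HR (checked at effect sizes 2 and 4)
  est <- vapply(c(2, 4), function(hr_true) {
    beta <- matrix(log(hr_true), 1, 1, dimnames = list("21", "female"))
    cfg <- cohort_config(n_subjects = 1500, beta = beta, seed = 33)
    co <- generate_cohort(cfg)
    fit <- msm_fit(co$data, covariates = "female")
    log(hazard_ratios(fit)$hr[hazard_ratios(fit)$transition == "21"])
  }, numeric(1))
  expect_equal(est[1], log(2), tolerance = 0.25)
  expect_equal(est[2], log(4), tolerance = 0.25)
  expect_equal(est[2] / est[1], 2, tolerance = 0.3)
})

test_that("univariate screening fits each covariate separately", {
  expect_identical(univariate_screen(tiny_panel(), character()),
                   stats::setNames(list(), character()))

  set.seed(505)
  beta <- matrix(log(3), 1, 1, dimnames = list("12", "institution"))
  cfg <- cohort_config(n_subjects = 800, beta = beta, seed = 34)
  co <- generate_cohort(cfg)
  scr <- univariate_screen(co$data, c("institution", "comorbidity"))
  expect_named(scr, c("institution", "comorbidity"))
  expect_s3_class(scr$institution, "hazard_ratio_table")
  hr_inst <- scr$institution
  expect_gt(hr_inst$hr[hr_inst$transition == "12"], 1.5)  # true effect seen
  # comorbidity is truly null here: its 1-2 CI should cover 1
  hr_com <- scr$comorbidity
  r <- hr_com[hr_com$transition == "12", ]
  expect_true(r$lower < 1 && r$upper > 1)
})

test_that("fit JSON round-trips through serialization", {
  set.seed(506)
  co <- generate_cohort(cohort_config(n_subjects = 200, seed = 35))
  fit <- msm_fit(co$data)
  f <- withr::local_tempfile(fileext = ".json")
  write_fit_json(fit, f)
  back <- read_fit_json(f)
  expect_equal(back$par, fit$par, tolerance = 1e-12)
  expect_equal(back$covariance, fit$covariance, tolerance = 1e-12)
  expect_equal(back$loglik, fit$loglik, tolerance = 1e-12)
  expect_equal(unclass(baseline_intensities(back)),
               unclass(baseline_intensities(fit)), tolerance = 1e-12)
})
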