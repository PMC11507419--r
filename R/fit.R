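#' Maximum likelihood fitting of the panel multi-state model
#'
#' Because the chain is observed only at assessment times, the likelihood is
#' a product of interval transition probabilities: each consecutive pair of
#' observations on a subject, state r at time t and state s at time t + dt,
#' contributes P_rs(dt; z) where P = expm(Q(z) dt) and z holds the covariate
#' values at the start of the interval (covariates are held constant across
#' each interval). Baseline intensities are parameterised on the log scale,
#' which enforces positivity and makes Wald intervals for hazard ratios
#' natural.
#'
#' @name msm_fitting
NULL

# ---- interval pairs and likelihood grouping -------------------------------

interval_pairs <- function(ds, covariates = character()) {
  n <- nrow(ds)
  out <- data.frame(from = integer(0), to = integer(0), dt = numeric(0))
  for (cv in covariates) out[[cv]] <- numeric(0)
  if (n < 2L) return(out)
  same <- ds$subject[-n] == ds$subject[-1L]
  i <- which(same)
  if (length(i) == 0L) return(out)
  out <- data.frame(from = ds$state[i], to = ds$state[i + 1L],
                    dt = ds$time[i + 1L] - ds$time[i])
  for (cv in covariates) out[[cv]] <- ds[[cv]][i]  # value at interval start
  out
}

# pairs sharing (dt, covariate pattern) share one expm call; the grouped
# log-likelihood is identical to the naive per-pair sum
group_pairs <- function(pairs, covariates = character()) {
  if (nrow(pairs) == 0L) return(list())
  keycols <- c("dt", covariates)
  key <- do.call(paste, c(lapply(keycols, function(cc) signif(pairs[[cc]], 12)),
                          sep = "|"))
  lapply(split(seq_len(nrow(pairs)), key), function(idx) {
    z <- vapply(covariates, function(cv) pairs[[cv]][idx[1L]], numeric(1))
    names(z) <- covariates
    list(dt = pairs$dt[idx[1L]], z = z,
         counts = unclass(table(factor(pairs$from[idx], 1:3),
                                factor(pairs$to[idx], 1:3))))
  })
}

loglik_groups <- function(model, groups, clamp = TRUE) {
  ll <- 0
  flagged <- FALSE
  for (g in groups) {
    P <- transition_probability(covariate_intensity(model, g$z), g$dt)
    if (any(P[g$counts > 0] == 0)) flagged <- TRUE
    if (clamp) P[P < 1e-300] <- 1e-300
    ll <- ll + sum(g$counts * log(P))
  }
  if (flagged) {
    ll <- -Inf
    attr(ll, "flagged") <- "zero interval probability with observed count"
  }
  ll
}

#' Panel-data log-likelihood
#'
#' Sum over all consecutive within-subject observation pairs of
#' log P_(r -> s)(dt; z at interval start). An empty dataset gives 0. A pair
#' whose interval probability is numerically zero makes the result -Inf
#' (with an attribute naming the problem) rather than raising an error.
#'
#' @param ds a `panel_data` object.
#' @param model a [covariate_model()], or an `intensity_matrix` for a
#'   covariate-free evaluation.
#' @param covariates covariate columns entering the model (defaults to the
#'   covariate names in `model$beta`).
#' @return The log-likelihood (a scalar).
#' @export
panel_loglik <- function(ds, model, covariates = NULL) {
  stopifnot(inherits(ds, "panel_data"))
  if (inherits(model, "intensity_matrix") ||
      (is.matrix(model) && !inherits(model, "covariate_model"))) {
    Q <- validate_intensity(model)
    q <- Q[row(Q) != col(Q)]
    groups <- group_pairs(interval_pairs(ds), character())
    ll <- 0; flagged <- FALSE
    for (g in groups) {
      P <- transition_probability(Q, g$dt)
      if (any(P[g$counts > 0] == 0)) flagged <- TRUE
      P[P < 1e-300] <- 1e-300
      ll <- ll + sum(g$counts * log(P))
    }
    if (flagged) { ll <- -Inf; attr(ll, "flagged") <- "zero interval probability" }
    return(ll)
  }
  stopifnot(inherits(model, "covariate_model"))
  if (is.null(covariates)) {
    covariates <- if (is.null(model$beta)) character() else colnames(model$beta)
  }
  loglik_groups(model, group_pairs(interval_pairs(ds, covariates), covariates))
}

# ---- initial values -------------------------------------------------------

#' Crude initial intensity estimates from a transition-frequency table
#'
#' A quick moment-style initialisation for the optimizer:
#' q_rs = count(r -> s) / (row total(r) * mean interval length), floored at
#' a small positive value so log-intensities stay finite. Not a consistent
#' estimator (observed one-step frequencies mix multiple latent jumps); only
#' a starting point.
#'
#' @param freq 3x3 count matrix from [count_transitions()].
#' @param mean_interval mean interval length in years.
#' @param floor minimum rate (default 1e-4).
#' @return An `intensity_matrix`.
#' @export
crude_initial_estimates <- function(freq, mean_interval = 1, floor = 1e-4) {
  freq <- as.matrix(freq)
  if (all(freq == 0)) {
    warning("all-zero frequency matrix; using uniform small initialisation")
    return(intensity_matrix(matrix(floor, nrow(freq), ncol(freq))))
  }
  rt <- rowSums(freq)
  q <- freq / ifelse(rt > 0, rt, 1) / mean_interval
  q[q < floor] <- floor
  intensity_matrix(q)
}

# ---- parameter packing ----------------------------------------------------

par_names <- function(covariates, covariate_transitions) {
  nm <- paste0("theta.", TRANSITIONS)
  for (cv in covariates) {
    nm <- c(nm, paste0("beta.", cv, ".", covariate_transitions[[cv]]))
  }
  nm
}

par_to_model <- function(par, covariates, covariate_transitions) {
  theta <- par[1:6]
  names(theta) <- TRANSITIONS
  beta <- NULL
  if (length(covariates) > 0L) {
    beta <- matrix(0, 6L, length(covariates),
                   dimnames = list(TRANSITIONS, covariates))
    k <- 6L
    for (cv in covariates) {
      trs <- covariate_transitions[[cv]]
      beta[trs, cv] <- par[k + seq_along(trs)]
      k <- k + length(trs)
    }
  }
  covariate_model(theta, beta)
}

# ---- fitting --------------------------------------------------------------

#' Fit the three-state panel Markov model by maximum likelihood
#'
#' Maximises the interval-censored panel log-likelihood over the six baseline
#' log-intensities and, optionally, transition-specific covariate
#' coefficients, using BFGS quasi-Newton iteration started from
#' [crude_initial_estimates()]. The covariance matrix is the inverse of the
#' numerically differenced observed information at the optimum.
#'
#' By default every covariate receives its own coefficient on each of the
#' six transitions (36 coefficients for the full six-covariate model);
#' `covariate_transitions` restricts a covariate to a subset of transitions.
#'
#' @param ds a `panel_data` object (subjects with a single observation
#'   contribute nothing; run [apply_inclusion()] first).
#' @param covariates character vector of covariate columns to model.
#' @param covariate_transitions optional named list mapping a covariate to
#'   the transitions (`"12" ... "32"`) it enters; default all six.
#' @param q_init optional `intensity_matrix` of starting intensities.
#' @param control passed to [stats::optim()] (BFGS); defaults: `maxit` 500,
#'   `reltol` 1e-10.
#' @return An `msm_fit` object: estimates, covariance, log-likelihood and
#'   convergence diagnostics. See [fitted_intensities()], [hazard_ratios()].
#' @export
msm_fit <- function(ds, covariates = character(), covariate_transitions = NULL,
                    q_init = NULL, control = list()) {
  stopifnot(inherits(ds, "panel_data"))
  miss <- setdiff(covariates, names(ds))
  if (length(miss) > 0L) {
    stop("covariate(s) not in dataset: ", paste(miss, collapse = ", "))
  }
  if (is.null(covariate_transitions)) {
    covariate_transitions <- stats::setNames(
      rep(list(TRANSITIONS), length(covariates)), covariates)
  }
  pairs <- interval_pairs(ds, covariates)
  if (nrow(pairs) == 0L) stop("no observation pairs: need >= 2 observations ",
                              "for at least one subject")
  groups <- group_pairs(pairs, covariates)

  if (is.null(q_init)) {
    freq <- count_transitions(ds)
    q_init <- crude_initial_estimates(freq, mean_interval = mean(pairs$dt))
  }
  Qm <- unclass(q_init)
  theta0 <- vapply(TRANSITIONS, function(tr)
    log(max(Qm[trans_from(tr), trans_to(tr)], 1e-4)), numeric(1))
  nbeta <- sum(lengths(covariate_transitions[covariates]))
  par0 <- c(theta0, rep(0, nbeta))
  pnames <- par_names(covariates, covariate_transitions)
  names(par0) <- pnames

  negll <- function(par) {
    if (any(!is.finite(par)) || any(par[1:6] > 50)) return(1e10)
    model <- par_to_model(par, covariates, covariate_transitions)
    ll <- tryCatch(loglik_groups(model, groups), error = function(e) -Inf)
    if (!is.finite(ll)) return(1e10)
    -as.numeric(ll)
  }

  ctrl <- utils::modifyList(list(maxit = 500L, reltol = 1e-10), control)
  opt <- stats::optim(par0, negll, method = "BFGS", control = ctrl)

  # gradient max-norm at the optimum (central differences)
  grad <- vapply(seq_along(opt$par), function(j) {
    h <- 1e-6 * max(1, abs(opt$par[j]))
    pp <- pm <- opt$par
    pp[j] <- pp[j] + h; pm[j] <- pm[j] - h
    (negll(pp) - negll(pm)) / (2 * h)
  }, numeric(1))
  grad_norm <- max(abs(grad))

  covariance <- NULL
  hess <- tryCatch(stats::optimHess(opt$par, negll), error = function(e) NULL)
  if (!is.null(hess)) {
    covariance <- tryCatch(solve(hess), error = function(e) NULL)
    if (!is.null(covariance)) {
      covariance <- (covariance + t(covariance)) / 2
      if (any(diag(covariance) < 0)) {
        warning("observed information is not positive definite; ",
                "standard errors unreliable")
      }
      dimnames(covariance) <- list(pnames, pnames)
    } else {
      warning("singular observed information; covariance omitted")
    }
  }

  model <- par_to_model(opt$par, covariates, covariate_transitions)
  structure(list(
    par = stats::setNames(opt$par, pnames),
    theta = model$theta,
    beta = model$beta,
    covariance = covariance,
    loglik = -opt$value,
    loglik_init = -negll(par0),
    converged = (opt$convergence == 0L),
    iterations = opt$counts[["function"]],
    gradient_norm = grad_norm,
    covariates = covariates,
    covariate_transitions = covariate_transitions,
    n_subjects = length(unique(ds$subject)),
    n_pairs = nrow(pairs),
    frequency = count_transitions(ds)
  ), class = "msm_fit")
}

#' @export
print.msm_fit <- function(x, ...) {
  cat("Three-state panel Markov model fit\n")
  cat(sprintf("  %d subjects, %d observation pairs; log-likelihood %.3f\n",
              x$n_subjects, x$n_pairs, x$loglik))
  cat(sprintf("  converged: %s (%d function evaluations, |grad| %.2e)\n",
              x$converged, x$iterations, x$gradient_norm))
  cat("\nBaseline transition intensities (per year):\n")
  print(round(unclass(baseline_intensities(x)), 4))
  if (length(x$covariates) > 0L) {
    cat("\nHazard ratios:\n")
    print(hazard_ratios(x))
  }
  invisible(x)
}

#' Baseline intensity matrix of a fitted model
#'
#' Intensities with every covariate at its reference value (0).
#'
#' @param fit an `msm_fit` object.
#' @return An `intensity_matrix`.
#' @export
baseline_intensities <- function(fit) {
  stopifnot(inherits(fit, "msm_fit"))
  intensity_matrix(exp(fit$theta))
}

#' Fitted transition intensities with standard errors
#'
#' Standard errors on the intensity scale by the delta method
#' (SE(q) = q * SE(theta)); 95% intervals are computed on the log scale.
#'
#' @param fit an `msm_fit` object.
#' @return data frame with columns `transition`, `estimate`, `se`, `lower`,
#'   `upper` (`NA` standard errors when the covariance is unavailable).
#' @export
fitted_intensities <- function(fit) {
  stopifnot(inherits(fit, "msm_fit"))
  q <- exp(fit$theta)
  se_theta <- rep(NA_real_, 6L)
  if (!is.null(fit$covariance)) {
    se_theta <- sqrt(pmax(diag(fit$covariance)[1:6], 0))
  }
  data.frame(
    transition = TRANSITIONS,
    estimate = unname(q),
    se = unname(q * se_theta),
    lower = unname(exp(fit$theta - 1.96 * se_theta)),
    upper = unname(exp(fit$theta + 1.96 * se_theta))
  )
}

# ---- hazard ratios --------------------------------------------------------

#' Wald hazard-ratio table for a fitted model
#'
#' For each modelled (covariate, transition): HR = exp(beta), 95% CI
#' exp(beta +/- 1.96 SE) on the log scale, and a two-sided Wald p-value.
#' The significance flag marks p < 0.05 (equivalently, the CI excluding 1).
#' No multiplicity adjustment is applied across the table cells.
#'
#' @param fit an `msm_fit` object with an available covariance matrix.
#' @return A `hazard_ratio_table` data frame: `covariate`, `transition`,
#'   `hr`, `lower`, `upper`, `p`, `significant`.
#' @export
hazard_ratios <- function(fit) {
  stopifnot(inherits(fit, "msm_fit"))
  if (length(fit$covariates) == 0L) {
    return(structure(data.frame(covariate = character(0),
                                transition = character(0), hr = numeric(0),
                                lower = numeric(0), upper = numeric(0),
                                p = numeric(0), significant = logical(0)),
                     class = c("hazard_ratio_table", "data.frame")))
  }
  if (is.null(fit$covariance)) {
    stop("no covariance available (singular information); see the fit's ",
         "convergence diagnostics before interpreting hazard ratios")
  }
  rows <- list()
  for (cv in fit$covariates) {
    for (tr in fit$covariate_transitions[[cv]]) {
      pn <- paste0("beta.", cv, ".", tr)
      b <- fit$par[[pn]]
      se <- sqrt(max(fit$covariance[pn, pn], 0))
      z <- if (se > 0) b / se else Inf * sign(b)
      rows[[pn]] <- data.frame(
        covariate = cv, transition = tr, hr = exp(b),
        lower = exp(b - 1.96 * se), upper = exp(b + 1.96 * se),
        p = if (se > 0) 2 * stats::pnorm(-abs(z)) else as.numeric(b != 0) * 0,
        significant = NA
      )
    }
  }
  out <- do.call(rbind, rows)
  out$significant <- out$p < 0.05
  rownames(out) <- NULL
  structure(out, class = c("hazard_ratio_table", "data.frame"))
}

#' @export
print.hazard_ratio_table <- function(x, digits = 2, ...) {
  if (nrow(x) == 0L) { cat("(no covariates modelled)\n"); return(invisible(x)) }
  y <- x
  y$`HR (95% CI)` <- sprintf(paste0("%.", digits, "f (%.", digits, "f-%.",
                                    digits, "f)%s"),
                             x$hr, x$lower, x$upper,
                             ifelse(x$significant, " *", ""))
  print(as.data.frame(y[, c("covariate", "transition", "HR (95% CI)", "p")]),
        row.names = FALSE, ...)
  invisible(x)
}

#' Wide-format hazard-ratio table
#'
#' Reshapes a [hazard_ratios()] table into the customary layout: one row per
#' covariate, one column per transition (`1-2` ... `3-2`), cells formatted
#' as `"HR (lower-upper)"` with a `*` marking p < 0.05.
#'
#' @param hrt a `hazard_ratio_table`.
#' @param digits decimal places (default 2).
#' @return A data frame ready for CSV export.
#' @export
hr_wide_table <- function(hrt, digits = 2) {
  covs <- unique(hrt$covariate)
  trs <- TRANSITIONS[TRANSITIONS %in% unique(hrt$transition)]
  out <- data.frame(covariate = covs)
  for (tr in trs) {
    col <- paste0(substr(tr, 1, 1), "-", substr(tr, 2, 2))
    out[[col]] <- vapply(covs, function(cv) {
      r <- hrt[hrt$covariate == cv & hrt$transition == tr, ]
      if (nrow(r) == 0L) return("")
      sprintf(paste0("%.", digits, "f (%.", digits, "f-%.", digits, "f)%s"),
              r$hr, r$lower, r$upper, if (isTRUE(r$significant)) " *" else "")
    }, character(1))
  }
  out
}

#' Univariate covariate screen
#'
#' Fits one single-covariate model per listed covariate (each entering all
#' six transitions) and collects the hazard-ratio tables — the usual first
#' pass before a multivariate model.
#'
#' @param ds a `panel_data` object.
#' @param covariates character vector of covariates to screen.
#' @param ... passed to [msm_fit()].
#' @return Named list of `hazard_ratio_table`s (a failed fit yields a
#'   `try-error` element; the rest are still produced).
#' @export
univariate_screen <- function(ds, covariates, ...) {
  out <- lapply(covariates, function(cv) {
    tryCatch(hazard_ratios(msm_fit(ds, covariates = cv, ...)),
             error = function(e) structure(conditionMessage(e),
                                           class = "try-error"))
  })
  stats::setNames(out, covariates)
}

# ---- serialization --------------------------------------------------------

#' Serialize a fitted model to JSON
#'
#' Writes estimates, covariance, log-likelihood and convergence diagnostics;
#' [read_fit_json()] restores an `msm_fit` usable by
#' [transition_probability()] workflows, [expected_prevalence()] and
#' [hazard_ratios()].
#'
#' @param fit an `msm_fit` object.
#' @param path output file.
#' @param extra optional named list merged into the JSON (e.g. provenance).
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path, extra = NULL) {
  stopifnot(inherits(fit, "msm_fit"))
  obj <- list(
    par = as.list(fit$par),
    covariance = fit$covariance,
    loglik = fit$loglik,
    converged = fit$converged,
    iterations = fit$iterations,
    gradient_norm = fit$gradient_norm,
    covariates = fit$covariates,
    covariate_transitions = fit$covariate_transitions,
    n_subjects = fit$n_subjects,
    n_pairs = fit$n_pairs,
    frequency = fit$frequency
  )
  if (!is.null(extra)) obj <- c(obj, extra)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", pretty = TRUE)
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  par <- unlist(obj$par)
  covs <- as.character(obj$covariates %||% character())
  ctr <- lapply(obj$covariate_transitions, as.character)
  model <- par_to_model(par, covs, ctr)
  covariance <- obj$covariance
  if (!is.null(covariance)) {
    covariance <- as.matrix(covariance)
    dimnames(covariance) <- list(names(par), names(par))
  }
  structure(list(
    par = par, theta = model$theta, beta = model$beta,
    covariance = covariance, loglik = obj$loglik,
    converged = obj$converged, iterations = obj$iterations,
    gradient_norm = obj$gradient_norm, covariates = covs,
    covariate_transitions = ctr, n_subjects = obj$n_subjects,
    n_pairs = obj$n_pairs,
    frequency = if (!is.null(obj$frequency)) as.matrix(obj$frequency) else NULL
  ), class = "msm_fit")
}
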