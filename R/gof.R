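#' Prevalence-based goodness of fit
#'
#' The model is assessed by comparing, at each assessment time, the observed
#' percentage of subjects in each state against the percentage expected when
#' every subject's baseline state is propagated through the fitted
#' transition probability matrix — the familiar observed-vs-expected
#' prevalence plot for panel multi-state models.
#'
#' @name gof
NULL

#' Model-expected state prevalence over time
#'
#' The expected count in state s at time t sums, over the subjects under
#' observation at t (last observation time >= t; there is no absorbing
#' state), the probability P_(s0 -> s)(t; z) of reaching s from the
#' subject's baseline state s0. Covariates are taken at baseline; with
#' `marginal = TRUE` a single pooled (baseline-covariate-free) intensity
#' matrix is used for everyone.
#'
#' @param fit an `msm_fit` object.
#' @param ds the `panel_data` the expectations refer to.
#' @param times numeric vector of times in years (>= 0).
#' @param marginal if `TRUE`, ignore covariates and use the baseline
#'   intensity matrix for every subject.
#' @return data frame with columns `time`, `n` (subjects under observation)
#'   and `pct1`, `pct2`, `pct3`; times beyond the last observation are
#'   computed over the whole cohort and carry an `extrapolated` flag.
#' @export
expected_prevalence <- function(fit, ds, times, marginal = FALSE) {
  stopifnot(inherits(fit, "msm_fit"), inherits(ds, "panel_data"))
  if (any(times < 0)) stop("times must be >= 0")
  covs <- if (marginal) character() else fit$covariates
  first <- !duplicated(ds$subject)
  base <- ds[first, , drop = FALSE]
  last_time <- tapply(ds$time, ds$subject, max)[as.character(base$subject)]
  t_end <- max(ds$time)

  # subjects sharing a covariate pattern share one expm per time
  if (length(covs) > 0L) {
    key <- do.call(paste, c(lapply(covs, function(cv) signif(base[[cv]], 12)),
                            sep = "|"))
  } else {
    key <- rep("all", nrow(base))
  }
  groups <- split(seq_len(nrow(base)), key)
  model <- covariate_model(fit$theta, fit$beta)

  out <- data.frame(time = times, n = 0L, pct1 = NA_real_, pct2 = NA_real_,
                    pct3 = NA_real_, extrapolated = times > t_end)
  for (k in seq_along(times)) {
    t0 <- times[k]
    tot <- c(0, 0, 0)
    n <- 0L
    for (idx in groups) {
      z <- if (length(covs) > 0L) {
        stats::setNames(vapply(covs, function(cv) base[[cv]][idx[1L]],
                               numeric(1)), covs)
      } else numeric()
      # beyond the last observation nobody is formally under observation;
      # extrapolated times propagate the whole cohort and carry the flag
      at_risk <- if (t0 > t_end) idx else idx[last_time[idx] >= t0]
      if (length(at_risk) == 0L) next
      P <- transition_probability(covariate_intensity(model, z), t0)
      s0 <- tabulate(base$state[at_risk], nbins = 3L)
      tot <- tot + drop(s0 %*% P)
      n <- n + length(at_risk)
    }
    out$n[k] <- n
    if (n > 0L) out[k, c("pct1", "pct2", "pct3")] <- 100 * tot / n
  }
  out
}

#' Combine observed and expected prevalence into a goodness-of-fit report
#'
#' @param observed output of [observed_prevalence()].
#' @param expected output of [expected_prevalence()] on the same time grid.
#' @return A `gof_report`: the merged per-time table plus, as attribute
#'   `"max_discrepancy"`, the maximum absolute observed-minus-expected
#'   percentage-point gap per state across times. Plot with [plot()].
#' @export
gof_report <- function(observed, expected) {
  if (nrow(observed) != nrow(expected) ||
      any(abs(observed$time - expected$time) > 1e-9)) {
    stop("observed and expected prevalence must share the same time grid")
  }
  tab <- data.frame(
    time = observed$time,
    n_observed = observed$n, n_expected = expected$n,
    obs1 = observed$pct1, obs2 = observed$pct2, obs3 = observed$pct3,
    exp1 = expected$pct1, exp2 = expected$pct2, exp3 = expected$pct3
  )
  disc <- vapply(1:3, function(s)
    max(abs(tab[[paste0("obs", s)]] - tab[[paste0("exp", s)]]), na.rm = TRUE),
    numeric(1))
  names(disc) <- paste0("state", 1:3)
  structure(tab, max_discrepancy = disc,
            class = c("gof_report", "data.frame"))
}

#' @rdname gof_report
#' @param report a `gof_report`.
#' @export
max_discrepancy <- function(report) attr(report, "max_discrepancy")

#' @export
print.gof_report <- function(x, ...) {
  cat("Observed vs expected state prevalence (%):\n")
  print(round(as.data.frame(x), 2), row.names = FALSE)
  cat("\nMax |observed - expected| (percentage points):\n")
  print(round(attr(x, "max_discrepancy"), 2))
  invisible(x)
}

#' @export
plot.gof_report <- function(x, ...) {
  labels <- adl_state_labels()
  op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 3, 1))
  on.exit(graphics::par(op))
  for (s in 1:3) {
    obs <- x[[paste0("obs", s)]]
    expd <- x[[paste0("exp", s)]]
    graphics::plot(x$time, obs, type = "b", pch = 16, ylim = c(0, 100),
                   xlab = "years since baseline", ylab = "prevalence (%)",
                   main = labels[s], ...)
    graphics::lines(x$time, expd, lty = 2, col = "red")
    graphics::points(x$time, expd, col = "red")
    graphics::legend("topright", legend = c("observed", "expected"),
                     lty = c(1, 2), col = c("black", "red"), bty = "n",
                     cex = 0.8)
  }
  invisible(x)
}
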