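#' Continuous-time Markov chain machinery
#'
#' The disability process is modelled as a time-homogeneous continuous-time
#' Markov chain on states 1 (none) < 2 (mild) < 3 (severe). Its generator Q
#' holds the transition intensities q_rs — instantaneous per-year rates of
#' moving from state r to state s — with diagonal entries equal to the
#' negative off-diagonal row sum, so rows sum to zero. The matrix of interval
#' transition probabilities over an elapsed time t is P(t) = expm(Q t).
#'
#' @name ctmc
NULL

# canonical ordering of the six modelled transitions, as printed in
# hazard-ratio tables: 1-2, 1-3, 2-1, 2-3, 3-1, 3-2
TRANSITIONS <- c("12", "13", "21", "23", "31", "32")

trans_from <- function(tr) as.integer(substr(tr, 1L, 1L))
trans_to <- function(tr) as.integer(substr(tr, 2L, 2L))

#' Build a transition intensity (generator) matrix
#'
#' @param rates either a named numeric vector of off-diagonal intensities
#'   with names among `"12", "13", "21", "23", "31", "32"` (unnamed vectors
#'   of length 6 are taken in that order; omitted transitions are 0), or a
#'   square matrix whose off-diagonal entries are the intensities (its
#'   diagonal is ignored and rebuilt).
#' @return An `intensity_matrix`: a k x k matrix with non-negative
#'   off-diagonals and diagonal = negative off-diagonal row sum.
#' @examples
#' Q <- intensity_matrix(c(`12` = 0.2764, `13` = 0.0003, `21` = 0.4731,
#'                         `23` = 0.2226, `31` = 0.0068, `32` = 0.1204))
#' diag(Q)  # -0.2767 -0.6957 -0.1272
#' @export
intensity_matrix <- function(rates) {
  if (is.matrix(rates)) {
    k <- nrow(rates)
    if (ncol(rates) != k) stop("intensity matrix must be square")
    q <- rates
    diag(q) <- 0
  } else {
    rates <- unlist(rates)
    if (is.null(names(rates))) {
      if (length(rates) != 6L) {
        stop("unnamed rate vectors must have length 6 (order ",
             paste(TRANSITIONS, collapse = ", "), ")")
      }
      names(rates) <- TRANSITIONS
    }
    bad <- setdiff(names(rates), TRANSITIONS)
    if (length(bad) > 0L) {
      stop("unknown transition name(s): ", paste(bad, collapse = ", "))
    }
    q <- matrix(0, 3L, 3L)
    for (tr in names(rates)) {
      q[trans_from(tr), trans_to(tr)] <- rates[[tr]]
    }
  }
  if (any(!is.finite(q)) || any(q[row(q) != col(q)] < 0)) {
    stop("transition intensities must be finite and >= 0")
  }
  diag(q) <- -rowSums(q)
  dimnames(q) <- list(seq_len(nrow(q)), seq_len(ncol(q)))
  structure(q, class = c("intensity_matrix", "matrix"))
}

#' @export
print.intensity_matrix <- function(x, digits = 4, ...) {
  cat("Transition intensity matrix (per year):\n")
  print(round(unclass(x), digits), ...)
  invisible(x)
}

validate_intensity <- function(Q) {
  Q <- unclass(as.matrix(Q))
  if (nrow(Q) != ncol(Q)) stop("Q must be square")
  off <- Q[row(Q) != col(Q)]
  if (any(off < -1e-12)) stop("off-diagonal intensities must be >= 0")
  if (any(abs(rowSums(Q)) > 1e-8)) stop("intensity matrix rows must sum to 0")
  Q
}

#' Proportional-intensity covariate model
#'
#' Covariates act multiplicatively on each transition intensity, in the
#' manner of a proportional hazards model:
#' q_rs(z) = q_rs(0) * exp(beta_rs' z), where q_rs(0) = exp(theta_rs) is the
#' baseline intensity (all covariates at their reference value 0) and
#' beta_rs is a transition-specific coefficient vector. exp(beta) is the
#' hazard ratio reported for that covariate and transition.
#'
#' @param theta named numeric vector of baseline log-intensities over the
#'   transitions `"12" ... "32"` (missing transitions are disallowed, i.e.
#'   intensity fixed at 0).
#' @param beta numeric matrix of coefficients, rows named by transition,
#'   columns named by covariate; `NULL` for a covariate-free model.
#' @return A `covariate_model` object.
#' @export
covariate_model <- function(theta, beta = NULL) {
  if (is.null(names(theta)) && length(theta) == 6L) names(theta) <- TRANSITIONS
  if (!all(names(theta) %in% TRANSITIONS)) {
    stop("theta names must be among: ", paste(TRANSITIONS, collapse = ", "))
  }
  if (any(!is.finite(theta))) stop("theta must be finite")
  if (!is.null(beta)) {
    beta <- as.matrix(beta)
    if (is.null(rownames(beta))) rownames(beta) <- names(theta)
    if (!all(rownames(beta) %in% names(theta))) {
      stop("beta rows must match modelled transitions")
    }
    if (is.null(colnames(beta))) {
      stop("beta columns must be named by covariate")
    }
    if (any(!is.finite(beta))) stop("beta must be finite")
  }
  structure(list(theta = theta, beta = beta), class = "covariate_model")
}

#' Intensity matrix at a covariate value
#'
#' Evaluates q_rs(z) = exp(theta_rs + beta_rs' z) for every modelled
#' transition and rebuilds the generator diagonal.
#'
#' @param model a [covariate_model()].
#' @param z named numeric vector of covariate values (names must cover the
#'   model's covariates); may be empty for a covariate-free model.
#' @return An `intensity_matrix`.
#' @export
covariate_intensity <- function(model, z = numeric()) {
  stopifnot(inherits(model, "covariate_model"))
  lin <- model$theta
  if (!is.null(model$beta)) {
    covs <- colnames(model$beta)
    missing_cov <- setdiff(covs, names(z))
    if (length(missing_cov) > 0L) {
      stop("missing covariate value(s): ", paste(missing_cov, collapse = ", "))
    }
    lin <- lin + drop(model$beta[names(model$theta), , drop = FALSE] %*%
                        z[covs])
  }
  intensity_matrix(exp(lin))
}

#' Interval transition probability matrix
#'
#' P(t) = expm(Q t), computed by scaling-and-squaring with Pade
#' approximation ([Matrix::expm()]). Entry (r, s) is the probability of
#' occupying state s after `delta` years given state r now; rows sum to 1.
#'
#' @param Q an `intensity_matrix` (or any valid generator matrix).
#' @param delta elapsed time in years, >= 0.
#' @return A `probability_matrix` (stochastic matrix).
#' @examples
#' Q <- intensity_matrix(c(`12` = 0.2764, `13` = 0.0003, `21` = 0.4731,
#'                         `23` = 0.2226, `31` = 0.0068, `32` = 0.1204))
#' round(transition_probability(Q, 1), 4)
#' @export
transition_probability <- function(Q, delta) {
  Q <- validate_intensity(Q)
  if (!is.finite(delta) || delta < 0) stop("delta must be finite and >= 0")
  P <- as.matrix(Matrix::expm(Q * delta))
  P[P < 0] <- 0  # zap tiny negative round-off
  dimnames(P) <- dimnames(Q)
  structure(P, class = c("probability_matrix", "matrix"))
}

#' @export
print.probability_matrix <- function(x, digits = 4, ...) {
  cat("Transition probability matrix:\n")
  print(round(unclass(x), digits), ...)
  invisible(x)
}

#' Simulate a continuous sample path of the chain
#'
#' Standard event-driven (Gillespie) simulation: the sojourn in state r is
#' exponential with rate -q_rr and the next state is s with probability
#' q_rs / (-q_rr). Paths are right-continuous: the state entered at a jump
#' time is the state occupied at that time.
#'
#' @param Q an `intensity_matrix`, or a function of time returning one; a
#'   function is re-evaluated at each state entry and held constant until
#'   the next jump (piecewise-constant intensities, appropriate when
#'   covariates change only at assessment times).
#' @param start_state initial state.
#' @param t_max simulation horizon in years.
#' @param t0 path start time (default 0).
#' @return A data frame with columns `time` (entry time) and `state`,
#'   carrying attribute `t_max`.
#' @export
simulate_path <- function(Q, start_state, t_max, t0 = 0) {
  if (t_max < t0) stop("t_max must be >= t0")
  q_at <- if (is.function(Q)) {
    function(t) validate_intensity(Q(t))
  } else {
    Qv <- validate_intensity(Q)
    function(t) Qv
  }
  k <- nrow(q_at(t0))
  if (!(start_state %in% seq_len(k))) stop("invalid start_state")
  times <- t0
  states <- as.integer(start_state)
  t <- t0
  s <- as.integer(start_state)
  repeat {
    Qt <- q_at(t)
    rate <- -Qt[s, s]
    if (rate <= 0) break  # no exits from this state
    t <- t + stats::rexp(1L, rate)
    if (t >= t_max) break
    probs <- Qt[s, ]
    probs[s] <- 0
    s <- sample.int(k, 1L, prob = probs)
    times <- c(times, t)
    states <- c(states, s)
  }
  structure(data.frame(time = times, state = states), t_max = t_max)
}

#' Read a sample path at assessment times
#'
#' Panel observation of a latent continuous path: returns the state occupied
#' at each requested time under the right-continuous convention (an
#' observation exactly at a jump time sees the new state). Jumps between
#' requested times are not visible — this is the interval censoring the
#' panel likelihood accounts for.
#'
#' @param path a path from [simulate_path()].
#' @param times sorted numeric vector within `[path start, t_max]`.
#' @return integer vector of states, one per requested time.
#' @export
observe_at <- function(path, times) {
  t_max <- attr(path, "t_max")
  if (any(times < path$time[1L]) || any(times > t_max)) {
    stop("requested times must lie within [", path$time[1L], ", ", t_max, "]")
  }
  idx <- findInterval(times, path$time)
  path$state[idx]
}
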