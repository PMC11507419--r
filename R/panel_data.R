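#' Long-format panel data for multi-state modelling
#'
#' A `panel_data` object is a long-format data frame of interval-censored
#' observations: one row per subject per assessment, with the occupied
#' disability state recorded at each assessment time. Transitions between
#' assessments are unobserved; the likelihood machinery in [msm_fit()] uses
#' interval transition probabilities.
#'
#' Required columns: `subject` (identifier), `time` (years since baseline,
#' non-negative), `state` (integer 1/2/3). Covariate columns are declared at
#' construction and must be numeric: continuous covariates as-is (e.g. age in
#' years), ordered categorical as consecutive integer scores (e.g. education
#' 1-5), binary as 0/1 with the reference level coded 0 (conventions used
#' here: male, home-based, with-pensions and non-co-morbidity are 0).
#'
#' @param df data frame with columns `subject`, `time`, `state` and any
#'   covariates.
#' @param covariates character vector naming the covariate columns.
#' @return A `panel_data` object (a validated, sorted data frame).
#' @examples
#' df <- data.frame(subject = c(1, 1, 2, 2), time = c(0, 1, 0, 1),
#'                  state = c(1, 2, 3, 3))
#' pd <- panel_data(df)
#' count_transitions(pd)
#' @export
panel_data <- function(df, covariates = character()) {
  df <- as.data.frame(df)
  req <- c("subject", "time", "state")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0L) {
    stop("panel data is missing column(s): ", paste(miss, collapse = ", "))
  }
  miss_cov <- setdiff(covariates, names(df))
  if (length(miss_cov) > 0L) {
    stop("declared covariate(s) not in data: ", paste(miss_cov, collapse = ", "))
  }
  df$time <- as.numeric(df$time)
  df$state <- as.integer(df$state)
  if (any(!is.finite(df$time)) || any(df$time < 0)) {
    stop("observation times must be finite and >= 0")
  }
  if (any(is.na(df$state)) || !all(df$state %in% 1:3)) {
    bad <- which(is.na(df$state) | !(df$state %in% 1:3))
    stop("state must be 1, 2 or 3; offending row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  for (cv in covariates) {
    if (!is.numeric(df[[cv]])) {
      stop("covariate '", cv, "' must be numeric (code categories as integers)")
    }
  }
  df <- df[order(df$subject, df$time), , drop = FALSE]
  dup <- duplicated(df[, c("subject", "time")])
  if (any(dup)) {
    stop("duplicate (subject, time) pair(s); offending row(s): ",
         paste(utils::head(which(dup), 5L), collapse = ", "))
  }
  rownames(df) <- NULL
  structure(df, covariates = covariates,
            class = c("panel_data", "data.frame"))
}

#' @export
print.panel_data <- function(x, ...) {
  ns <- length(unique(x$subject))
  cat("Panel dataset: ", nrow(x), " observations on ", ns, " subjects\n",
      sep = "")
  cv <- attr(x, "covariates")
  if (length(cv) > 0L) cat("Covariates: ", paste(cv, collapse = ", "), "\n",
                           sep = "")
  NextMethod()
  invisible(x)
}

#' Covariate names declared on a panel dataset
#' @param ds a `panel_data` object.
#' @return character vector of covariate column names.
#' @export
panel_covariates <- function(ds) attr(ds, "covariates") %||% character()

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a long-format panel file
#'
#' Reads a delimited text file (CSV, or TSV when the filename ends in `.tsv`)
#' and maps its columns onto the panel-data schema. The column map may be a
#' list or the path to a YAML/JSON file with entries:
#' \describe{
#'   \item{subject}{subject identifier column (required)}
#'   \item{time / wave}{observation time in years, or an integer wave index
#'     converted as 1 wave = 1 year (one of the two required)}
#'   \item{state / adl_total}{a 3-level state column, or a 0-20 ADL total
#'     classified through [adl_state()] (one of the two required)}
#'   \item{covariates}{character vector of covariate columns (optional)}
#'   \item{death_flag}{optional 0/1 column; subjects with any 1 are dropped
#'     (deceased participants are excluded, no death state is modelled)}
#' }
#'
#' @param file path to the delimited file.
#' @param column_map list, or path to a YAML/JSON file describing the mapping.
#' @return A `panel_data` object.
#' @export
read_panel <- function(file, column_map) {
  if (is.character(column_map) && length(column_map) == 1L) {
    column_map <- if (grepl("\\.json$", column_map, ignore.case = TRUE)) {
      jsonlite::read_json(column_map, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(column_map)
    }
  }
  sep <- if (grepl("\\.tsv$", file, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(file, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- function(key) {
    col <- column_map[[key]]
    if (!is.null(col) && !all(col %in% names(raw))) {
      stop("mapped column '", col, "' (", key, ") not present in ", file)
    }
    col
  }
  subj_col <- need("subject")
  if (is.null(subj_col)) stop("column map must name a 'subject' column")
  time_col <- need("time"); wave_col <- need("wave")
  if (is.null(time_col) && is.null(wave_col)) {
    stop("column map must name a 'time' or 'wave' column")
  }
  state_col <- need("state"); adl_col <- need("adl_total")
  if (is.null(state_col) && is.null(adl_col)) {
    stop("column map must name a 'state' or 'adl_total' column")
  }
  covs <- need("covariates") %||% character()
  death_col <- need("death_flag")

  out <- data.frame(subject = raw[[subj_col]])
  out$time <- if (!is.null(time_col)) as.numeric(raw[[time_col]]) else
    as.numeric(raw[[wave_col]]) * 1.0
  out$state <- if (!is.null(state_col)) {
    st <- suppressWarnings(as.integer(raw[[state_col]]))
    if (any(is.na(st))) stop("unparseable state value(s) in column '",
                             state_col, "'")
    st
  } else {
    adl_state(raw[[adl_col]])
  }
  for (cv in covs) out[[cv]] <- as.numeric(raw[[cv]])
  if (!is.null(death_col)) {
    dead <- unique(out$subject[raw[[death_col]] %in% 1])
    out <- out[!(out$subject %in% dead), , drop = FALSE]
  }
  panel_data(out, covariates = covs)
}

#' Apply cohort inclusion criteria
#'
#' Removes subjects whose baseline age is below `min_age` and subjects
#' observed fewer than two times (a single assessment contributes nothing to
#' an interval-censored likelihood). The exclusion counts are attached as the
#' `"exclusions"` attribute and available through [exclusion_report()].
#'
#' @param ds a `panel_data` object.
#' @param min_age minimum baseline age in years (default 60); `NULL` skips
#'   the age rule.
#' @param age_col name of the age covariate column (default `"age"`).
#' @return The filtered `panel_data` with an exclusion report attached.
#' @export
apply_inclusion <- function(ds, min_age = 60, age_col = "age") {
  stopifnot(inherits(ds, "panel_data"))
  n0 <- length(unique(ds$subject))
  removed_age <- 0L
  if (!is.null(min_age)) {
    if (!age_col %in% names(ds)) {
      stop("age filtering requested but column '", age_col, "' is absent")
    }
    base_idx <- !duplicated(ds$subject)  # sorted by time: first row = baseline
    young <- unique(ds$subject[base_idx][ds[[age_col]][base_idx] < min_age])
    removed_age <- length(young)
    ds <- ds[!(ds$subject %in% young), , drop = FALSE]
  }
  nobs <- table(ds$subject)
  single <- names(nobs)[nobs < 2]
  removed_single <- length(single)
  ds <- ds[!(as.character(ds$subject) %in% single), , drop = FALSE]
  rownames(ds) <- NULL
  report <- data.frame(
    rule = c(paste0("baseline age < ", min_age %||% NA),
             "fewer than two assessments"),
    subjects_removed = c(removed_age, removed_single)
  )
  attr(ds, "exclusions") <- report
  attr(ds, "n_before") <- n0
  ds
}

#' @rdname apply_inclusion
#' @export
exclusion_report <- function(ds) attr(ds, "exclusions")

#' Count observed state-to-state transitions
#'
#' Tabulates all consecutive within-subject observation pairs, regardless of
#' the elapsed interval; same-state pairs land on the diagonal. This is the
#' raw transition-frequency table usually reported alongside the fitted
#' intensities.
#'
#' @param ds a `panel_data` object.
#' @return A 3x3 integer matrix of counts, rows = state at the earlier
#'   assessment, columns = state at the later assessment.
#' @export
count_transitions <- function(ds) {
  stopifnot(inherits(ds, "panel_data"))
  counts <- matrix(0L, 3L, 3L,
                   dimnames = list(from = 1:3, to = 1:3))
  if (nrow(ds) > 0L) {
    same <- ds$subject[-nrow(ds)] == ds$subject[-1L]
    from <- ds$state[-nrow(ds)][same]
    to <- ds$state[-1L][same]
    if (length(from) > 0L) {
      tab <- table(factor(from, 1:3), factor(to, 1:3))
      counts <- counts + unclass(tab)
      dimnames(counts) <- list(from = 1:3, to = 1:3)
    }
  }
  storage.mode(counts) <- "integer"
  counts
}

#' Observed state prevalence over time
#'
#' For each requested time, every subject's nearest observation within
#' `tolerance` years is matched and the percentage of matched subjects in
#' each state is computed (the "actual frequency percentage" curve of a
#' prevalence-based goodness-of-fit display).
#'
#' @param ds a `panel_data` object.
#' @param times numeric vector of non-negative times in years.
#' @param tolerance matching half-window in years (default 0.5).
#' @return data frame with columns `time`, `n` (matched subjects) and
#'   `pct1`, `pct2`, `pct3`. Times with no matched subject have `n = 0` and
#'   `NA` percentages.
#' @export
observed_prevalence <- function(ds, times, tolerance = 0.5) {
  stopifnot(inherits(ds, "panel_data"))
  if (any(times < 0)) stop("requested times must be >= 0")
  if (tolerance < 0) stop("tolerance must be >= 0")
  subj <- split(seq_len(nrow(ds)), ds$subject)
  out <- data.frame(time = times, n = 0L,
                    pct1 = NA_real_, pct2 = NA_real_, pct3 = NA_real_)
  for (k in seq_along(times)) {
    t0 <- times[k]
    states <- vapply(subj, function(idx) {
      dt <- abs(ds$time[idx] - t0)
      j <- which.min(dt)
      if (dt[j] <= tolerance) ds$state[idx[j]] else NA_integer_
    }, integer(1))
    states <- states[!is.na(states)]
    out$n[k] <- length(states)
    if (length(states) > 0L) {
      p <- 100 * tabulate(states, nbins = 3L) / length(states)
      out[k, c("pct1", "pct2", "pct3")] <- p
    }
  }
  out
}
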