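#' ADL scale: total score and three-level disability state
#'
#' The disability outcome is measured on a 20-item activities-of-daily-living
#' (ADL) scale. Each item is scored in \[0, 1\] and the 20 item scores are
#' summed to a total in \[0, 20\]. Totals are classified into three ordered
#' disability states:
#' \itemize{
#'   \item state 1, no ADL disability: total exactly 20;
#'   \item state 2, mild ADL disability: total in \[8, 20);
#'   \item state 3, severe ADL disability: total in \[0, 8).
#' }
#' Higher state codes mean more severe disability.
#'
#' @name adl_scale
NULL

#' Sum 20 ADL item scores to a total
#'
#' @param items numeric vector of exactly 20 item scores, each in \[0, 1\].
#' @return The arithmetic total, a number in \[0, 20\].
#' @examples
#' adl_total(rep(1, 20))                    # 20: fully independent
#' adl_total(c(rep(1, 10), rep(0.5, 10)))   # 15
#' @export
adl_total <- function(items) {
  items <- as.numeric(items)
  if (length(items) != 20L) {
    stop("ADL assessment must have exactly 20 items, got ", length(items))
  }
  bad <- which(!is.finite(items) | items < 0 | items > 1)
  if (length(bad) > 0L) {
    stop("ADL item score out of [0, 1] at index ", bad[1L],
         " (value ", items[bad[1L]], ")")
  }
  sum(items)
}

#' Classify an ADL total score into a disability state
#'
#' Vectorised. Cutpoints: 20 -> state 1 (none); \[8, 20) -> state 2 (mild);
#' \[0, 8) -> state 3 (severe). The boundaries are exact: a total of exactly
#' 8 is mild, and only a perfect 20 is state 1.
#'
#' @param total numeric vector of ADL totals, each in \[0, 20\].
#' @return integer vector of state codes in \{1, 2, 3\}.
#' @examples
#' adl_state(c(20, 8, 7.999))  # 1 2 3
#' @export
adl_state <- function(total) {
  total <- as.numeric(total)
  bad <- which(!is.finite(total) | total < 0 | total > 20)
  if (length(bad) > 0L) {
    stop("ADL total out of [0, 20] at position ", bad[1L],
         " (value ", total[bad[1L]], ")")
  }
  ifelse(total == 20, 1L, ifelse(total >= 8, 2L, 3L))
}

#' State labels used throughout the package
#' @return character vector of length 3, named by state code.
#' @export
adl_state_labels <- function() {
  c(`1` = "no ADL disability", `2` = "mild ADL disability",
    `3` = "severe ADL disability")
}
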