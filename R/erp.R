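#' Instantaneous-change traces over readout activity (P600 analog)
#'
#' A neural "processing cost" signal derived from the readout trajectory:
#' for each time step t >= 2 and readout difference
#' d_i(t) = y_i(t) - y_i(t-1),
#' \describe{
#'   \item{`sum_diff`}{signed sum over units of d_i(t),}
#'   \item{`abs_sum_diff`}{sum of |d_i(t)| - the headline measure, analogous
#'     to the P600 amplitude: words that force a reanalysis of the predicted
#'     coded meaning produce large values,}
#'   \item{`abs_max_diff`}{max over units of |d_i(t)|.}
#' }
#' By construction `abs_sum_diff >= |sum_diff|` and
#' `abs_sum_diff >= abs_max_diff >= 0`; the first time step has no defined
#' difference, so the trace starts at step 2.
#'
#' @param y Output trajectory (time steps x readout_dim), e.g. from
#'   [readout_trajectory()].
#' @param AT Activation time used to produce `y`; annotates each step with
#'   its word index.
#' @return Data frame of class `esn_erp_trace` with columns `step`, `word`,
#'   `sum_diff`, `abs_sum_diff`, `abs_max_diff`.
#' @export
derivative_traces <- function(y, AT = 1) {
  if (is.list(y) && !is.null(y$y)) y <- y$y
  y <- as.matrix(y)
  if (nrow(y) < 2) stop("need at least 2 time steps to form differences")
  d <- diff(y)
  out <- data.frame(
    step = seq(2L, nrow(y)),
    word = ceiling(seq(2L, nrow(y)) / AT),
    sum_diff = rowSums(d),
    abs_sum_diff = rowSums(abs(d)),
    abs_max_diff = apply(abs(d), 1, max)
  )
  class(out) <- c("esn_erp_trace", class(out))
  out
}

#' Word-aligned summary of a change trace
#'
#' Collapses the per-step trace to one value per word: the maximum of
#' `abs_sum_diff` (and of the other traces) within each word's
#' AT-step window.
#'
#' @param trace An [derivative_traces()] result.
#' @return Data frame with one row per word.
#' @export
word_change_summary <- function(trace) {
  agg <- function(col) tapply(trace[[col]], trace$word, max)
  words <- sort(unique(trace$word))
  data.frame(word = words,
             sum_diff = as.numeric(agg("sum_diff")),
             abs_sum_diff = as.numeric(agg("abs_sum_diff")),
             abs_max_diff = as.numeric(agg("abs_max_diff")))
}
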