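#' Encode a surface form as a time-indexed input matrix
#'
#' Words are presented one at a time as square waves: each token activates
#' its input channel (value 1, all other channels 0) for `AT` consecutive
#' time steps, so a sentence of `k` tokens yields a `k * AT` row matrix.
#' Inflections, commas and the period occupy one AT-expanded step like any
#' other word. All semantic words share a single marker channel in the
#' extended schemes (`SW`), while nouns and verbs have separate channels in
#' `basic45`; the model therefore never sees lexical identity, only word
#' category and closed-class structure.
#'
#' @param tokens Character vector of tokens (or an `esn_construction`).
#' @param scheme An [coding_scheme()].
#' @param AT Activation time: simulation steps per word (`>= 1`). The
#'   integration step of the reservoir is `dt = 1/AT`.
#' @return A `length(tokens) * AT` by `scheme$input_dim` binary matrix.
#' @export
encode_inputs <- function(tokens, scheme, AT = 1) {
  if (inherits(tokens, "esn_construction")) tokens <- tokens$tokens
  stopifnot(AT >= 1, AT == round(AT))
  idx <- match(tokens, scheme$vocab)
  if (anyNA(idx)) {
    stop("token(s) not in scheme ", scheme$scheme_id, " vocabulary: ",
         paste(unique(tokens[is.na(idx)]), collapse = ", "))
  }
  n <- length(tokens) * AT
  u <- matrix(0, n, scheme$input_dim)
  rows <- rep(seq_along(tokens), each = AT)
  u[cbind(seq_len(n), idx[rows])] <- 1
  u
}

#' Encode a coded meaning as a teacher target
#'
#' The teacher vector has value +1 at each readout unit whose
#' (semantic word, clause, role) triple is assigned in the meaning and -1
#' everywhere else. In `continuous` mode the same vector is imposed at
#' every input time step from sentence onset; in `sentence_final` mode it
#' is imposed only once, at the last step.
#'
#' @param meaning Data frame with columns `sw`, `clause`, `role` (or an
#'   `esn_construction`).
#' @param scheme An [coding_scheme()].
#' @param mode `"continuous"` or `"sentence_final"`.
#' @param input_length Number of input time steps (required for
#'   `continuous`).
#' @return Matrix of teacher rows: `input_length` rows for continuous, one
#'   row for sentence-final.
#' @export
encode_targets <- function(meaning, scheme,
                           mode = c("sentence_final", "continuous"),
                           input_length = NULL) {
  mode <- match.arg(mode)
  y <- target_vector(meaning, scheme)
  if (mode == "sentence_final") {
    matrix(y, nrow = 1)
  } else {
    if (is.null(input_length)) stop("continuous mode needs input_length")
    matrix(y, nrow = input_length, ncol = length(y), byrow = TRUE)
  }
}

# The +/-1 teacher vector for one coded meaning.
target_vector <- function(meaning, scheme) {
  if (inherits(meaning, "esn_construction")) meaning <- meaning$meaning
  y <- rep(-1, scheme$readout_dim)
  for (i in seq_len(nrow(meaning))) {
    y[readout_index(meaning$sw[i], meaning$clause[i], meaning$role[i],
                    scheme)] <- 1
  }
  y
}
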