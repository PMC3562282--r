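# ---- internal: batched reservoir runs over a corpus ------------------------

# Encode every construction of a corpus under its scheme at the params' AT.
corpus_inputs <- function(corp, scheme, AT) {
  lapply(corp, function(cc) encode_inputs(cc$tokens, scheme, AT))
}

# Run all sequences through the reservoir in a vectorized batch: at step t
# every still-active sequence is advanced with one sparse matrix product.
# Each sequence starts from the zero state (reset before each sentence /
# discourse segment). Returns final states (n x N) and, if keep_all, the
# full per-step state matrix (sum(lens) x N) with row offsets.
batch_states <- function(inputs, W, keep_all = FALSE) {
  n <- length(inputs)
  N <- W$params$N
  lens <- vapply(inputs, nrow, integer(1))
  offs <- cumsum(c(0L, lens))[seq_len(n)]
  U <- do.call(rbind, inputs)
  WinT <- t(W$W_in)
  WresT <- Matrix::t(W$W_res)
  h <- W$params$leak
  X <- matrix(0, n, N)
  S <- if (keep_all) matrix(0, sum(lens), N) else NULL
  for (t in seq_len(max(lens, 0L))) {
    act <- which(lens >= t)
    u_rows <- offs[act] + t
    Z <- U[u_rows, , drop = FALSE] %*% WinT +
      as.matrix(X[act, , drop = FALSE] %*% WresT)
    X[act, ] <- (1 - h) * X[act, , drop = FALSE] + h * tanh(Z)
    if (keep_all) S[u_rows, ] <- X[act, , drop = FALSE]
  }
  list(final = X, all = S, lens = lens, offsets = offs)
}

#' Harvest reservoir states and teacher targets over a corpus
#'
#' Presents every construction to the reservoir (state reset before each
#' sequence) and stacks the recorded states and aligned teacher rows into
#' ridge-regression design matrices. In `sentence_final` mode each sentence
#' contributes exactly one row (its final state); in `continuous` mode every
#' time step from sentence onset contributes a row. A constant-1 bias
#' column is appended to the states.
#'
#' @param corp An `esn_corpus`.
#' @param W Reservoir weights from [init_reservoir()].
#' @param scheme An [coding_scheme()]; defaults to the corpus' scheme.
#' @param mode `"sentence_final"` or `"continuous"`.
#' @return List with `X` (rows x N+1), `Y` (rows x readout_dim), and
#'   `sentence` (the construction index of each row).
#' @export
harvest_states <- function(corp, W,
                           scheme = scheme_for_corpus(corp),
                           mode = c("sentence_final", "continuous")) {
  mode <- match.arg(mode)
  inputs <- corpus_inputs(corp, scheme, W$params$AT)
  bs <- batch_states(inputs, W, keep_all = (mode == "continuous"))
  targets <- t(vapply(corp, target_vector, numeric(scheme$readout_dim),
                      scheme = scheme))
  if (mode == "sentence_final") {
    list(X = cbind(bs$final, 1), Y = targets, sentence = seq_along(corp))
  } else {
    sent <- rep(seq_along(corp), bs$lens)
    list(X = cbind(bs$all, 1), Y = targets[sent, , drop = FALSE],
         sentence = sent)
  }
}

#' Fit readout weights by ridge regression
#'
#' Solves the regularized normal equations
#' `(X^T X + lambda P) W = X^T Y` with `P` the identity except for a zero
#' in the bias position (the bias column is not penalized). Deterministic
#' given the design matrices.
#'
#' @param X Design matrix including the trailing bias column.
#' @param Y Teacher matrix with the same number of rows.
#' @param lambda Ridge parameter (> 0; default 1e-9).
#' @return Readout weight matrix (`ncol(X) x ncol(Y)`), class
#'   `esn_readout`.
#' @export
fit_ridge <- function(X, Y, lambda = 1e-9) {
  if (is.list(X) && !is.null(X$X)) { # accept harvest_states() output
    Y <- X$Y
    X <- X$X
  }
  stopifnot(nrow(X) == nrow(Y), nrow(X) >= 1, lambda > 0)
  if (!all(is.finite(X)) || !all(is.finite(Y))) {
    stop("non-finite entries in design matrices")
  }
  ridge_solve(crossprod(X), crossprod(X, Y), lambda)
}

# Core solver, shared with the cross-validation engine (which updates the
# Gram matrices incrementally instead of recomputing them per fold).
ridge_solve <- function(XtX, XtY, lambda) {
  p <- nrow(XtX)
  pen <- c(rep(lambda, p - 1L), 0) # last column is the unpenalized bias
  A <- XtX + diag(pen, p)
  W_out <- solve(A, XtY)
  class(W_out) <- c("esn_readout", class(W_out))
  W_out
}

#' Train a full sentence-comprehension model
#'
#' Convenience wrapper: initialize the reservoir, harvest states over the
#' training corpus and fit the readout.
#'
#' @param corp Training `esn_corpus`.
#' @param params [reservoir_params()].
#' @param scheme [coding_scheme()]; defaults to the corpus' scheme.
#' @param mode Learning mode, `"sentence_final"` or `"continuous"`.
#' @param lambda Ridge parameter.
#' @return An object of class `esn_model` holding the reservoir weights,
#'   readout weights, scheme and configuration.
#' @export
train_readout <- function(corp, params = reservoir_params(),
                          scheme = scheme_for_corpus(corp),
                          mode = c("sentence_final", "continuous"),
                          lambda = 1e-9) {
  mode <- match.arg(mode)
  W <- init_reservoir(params, scheme$input_dim)
  D <- harvest_states(corp, W, scheme, mode)
  W_out <- fit_ridge(D$X, D$Y, lambda)
  structure(list(W = W, W_out = W_out, scheme = scheme, mode = mode,
                 lambda = lambda, params = params),
            class = "esn_model")
}

#' @export
print.esn_model <- function(x, ...) {
  cat("<esn_model> scheme ", x$scheme$scheme_id, ", mode ", x$mode,
      ", N=", x$params$N, ", SR=", x$params$SR, ", tau=", x$params$tau,
      "\n", sep = "")
  invisible(x)
}

#' Readout activity over time for one sentence
#'
#' Runs a sentence (or explicit token vector) through a trained model and
#' returns the real-valued readout trajectory, the real-time "striatal"
#' role predictions.
#'
#' @param model An [train_readout()] model.
#' @param tokens An `esn_construction` or a character token vector.
#' @param reset Reset the reservoir state first (default).
#' @param x0 Initial state when `reset = FALSE`.
#' @return List with `y` (time steps x readout_dim), `x` (state
#'   trajectory) and `word` (the word index of each time step).
#' @export
readout_trajectory <- function(model, tokens, reset = TRUE, x0 = NULL) {
  if (inherits(tokens, "esn_construction")) tokens <- tokens$tokens
  u <- encode_inputs(tokens, model$scheme, model$params$AT)
  x <- run_reservoir(u, model$W, reset = reset, x0 = x0)
  list(y = readout(x, model$W_out), x = x,
       word = rep(seq_along(tokens), each = model$params$AT))
}

# Scheme lookup for a corpus, enabling the modifier channel when the corpus
# contains ADJ tokens.
scheme_for_corpus <- function(corp) {
  id <- attr(corp, "scheme_id")
  mods <- id == "ext462" &&
    any(vapply(corp, function(cc) "ADJ" %in% cc$tokens, logical(1)))
  coding_scheme(id, modifiers = mods)
}
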