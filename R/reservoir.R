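#' Reservoir parameters
#'
#' Parameters of the fixed random recurrent network of leaky-integrator
#' tanh neurons. The state update is
#' \deqn{x(t+1) = (1 - h)\,x(t) + h \tanh(W_{in} u(t+1) + W_{res} x(t)),}
#' with leak \eqn{h = \Delta t / \tau} and \eqn{\Delta t = 1/AT}, so at
#' `AT = 1` and `tau = 6` the leak rate is 1/6 (about 0.167) per step.
#'
#' @param N Number of reservoir units.
#' @param SR Spectral radius: the recurrent matrix is rescaled so that its
#'   largest-modulus eigenvalue equals `SR` exactly.
#' @param tau Time constant, in units of word presentations.
#' @param AT Activation time: simulation steps per word; `dt = 1/AT`.
#' @param input_scale Magnitude of the nonzero input weights (+/-0.75).
#' @param density Expected nonzero fraction of both weight matrices
#'   (i.i.d. Bernoulli mask per entry).
#' @param seed Integer seed; the whole weight draw is a pure function of
#'   (params, seed).
#' @return An object of class `esn_params`.
#' @export
reservoir_params <- function(N = 1000, SR = 1, tau = 6, AT = 1,
                             input_scale = 0.75, density = 0.1, seed = 1) {
  stopifnot(N >= 1, SR > 0, tau > 0, AT >= 1)
  h <- (1 / AT) / tau
  if (h <= 0 || h > 1) {
    stop("effective leak h = dt/tau must lie in (0, 1]; got ", h)
  }
  structure(list(N = as.integer(N), SR = SR, tau = tau, AT = as.integer(AT),
                 dt = 1 / AT, leak = h, input_scale = input_scale,
                 density = density, seed = as.integer(seed)),
            class = "esn_params")
}

#' @export
print.esn_params <- function(x, ...) {
  cat(sprintf(
    "<esn_params> N=%d SR=%g tau=%g AT=%d (dt=%g, leak=%.4g) seed=%d\n",
    x$N, x$SR, x$tau, x$AT, x$dt, x$leak, x$seed))
  invisible(x)
}

#' Initialize reservoir weights
#'
#' Draws the recurrent matrix `W_res` (normal(0, 1) values on an i.i.d.
#' Bernoulli(density) mask) and the input matrix `W_in` (+/-`input_scale`
#' with equal probability on an independent Bernoulli(density) mask), then
#' rescales `W_res` so that its largest-modulus eigenvalue equals `SR`
#' exactly (computed with a full eigendecomposition, tolerance 1e-10).
#' Identical (params, input_dim) give identical weights. The draw order is
#' fixed: recurrent mask, recurrent values, input mask, input signs.
#'
#' @param params An [reservoir_params()] object.
#' @param input_dim Number of input channels (see [coding_scheme()]).
#' @return An object of class `esn_weights` with fields `W_res` (sparse
#'   `N x N`), `W_in` (`N x input_dim`), `params`, and `sr_unscaled` (the
#'   spectral radius of the raw draw, kept so the matrix can be rescaled to
#'   a different SR without re-computing eigenvalues, see [rescale_sr()]).
#' @export
init_reservoir <- function(params, input_dim) {
  N <- params$N
  w <- with_seed(params$seed, {
    mask_res <- stats::runif(N * N) < params$density
    vals <- stats::rnorm(sum(mask_res))
    W_res <- Matrix::sparseMatrix(
      i = ((which(mask_res) - 1L) %% N) + 1L,
      j = ((which(mask_res) - 1L) %/% N) + 1L,
      x = vals, dims = c(N, N))
    mask_in <- matrix(stats::runif(N * input_dim) < params$density,
                      N, input_dim)
    signs <- matrix(sample(c(-1, 1), N * input_dim, replace = TRUE),
                    N, input_dim)
    W_in <- mask_in * signs * params$input_scale
    list(W_res = W_res, W_in = W_in)
  })
  sr0 <- spectral_radius(w$W_res)
  if (sr0 == 0) {
    # empty draw (possible at tiny N): leave the zero matrix as is
    W_res <- w$W_res
  } else {
    W_res <- w$W_res * (params$SR / sr0)
  }
  structure(list(W_res = W_res, W_in = w$W_in, params = params,
                 input_dim = input_dim, sr_unscaled = sr0),
            class = "esn_weights")
}

#' Rescale an existing reservoir to a different spectral radius
#'
#' Rescaling is linear, so a reservoir drawn for one SR can be reused at
#' another without re-drawing or re-computing eigenvalues.
#'
#' @param W An `esn_weights` object.
#' @param SR New spectral radius.
#' @return An `esn_weights` object with updated `W_res` and params.
#' @export
rescale_sr <- function(W, SR) {
  stopifnot(inherits(W, "esn_weights"), SR > 0)
  old <- W$params$SR
  W$W_res <- W$W_res * (SR / old)
  W$params$SR <- SR
  W
}

# Largest-modulus eigenvalue of a (sparse) square matrix.
spectral_radius <- function(M) {
  if (nrow(M) == 1L) return(abs(as.numeric(M[1, 1])))
  ev <- eigen(as.matrix(M), only.values = TRUE)$values
  max(Mod(ev))
}

#' One leaky-integrator update step
#'
#' `x' = (1 - h) x + h * tanh(W_in u + W_res x)` with `h = dt/tau`. With
#' `x(0) = 0` and `h` in (0, 1] every state component stays in (-1, 1) for
#' any input (each update is a convex combination of the previous state and
#' a tanh image).
#'
#' @param x State vector (length N).
#' @param u Input vector (length input_dim).
#' @param W An [init_reservoir()] object.
#' @return The next state vector.
#' @export
reservoir_step <- function(x, u, W) {
  if (length(x) != W$params$N) stop("state has wrong dimension")
  if (length(u) != W$input_dim) stop("input has wrong dimension")
  h <- W$params$leak
  as.numeric((1 - h) * x +
               h * tanh(W$W_in %*% u + W$W_res %*% x))
}

#' Run the reservoir over an input sequence
#'
#' Iterates [reservoir_step()] over the rows of `u`. With `reset = TRUE`
#' the state starts from zero (the convention before every sentence, or
#' before every discourse segment for multi-sentence sequences); otherwise
#' it continues from `x0`.
#'
#' @param u Input matrix (time steps x input_dim), e.g. from
#'   [encode_inputs()].
#' @param W An [init_reservoir()] object.
#' @param reset Start from the zero state (default) or from `x0`.
#' @param x0 Initial state when `reset = FALSE`.
#' @return Matrix `x(t)` of size `nrow(u) x N` (0 rows for empty input).
#' @export
run_reservoir <- function(u, W, reset = TRUE, x0 = NULL) {
  N <- W$params$N
  if (!is.matrix(u)) u <- matrix(u, ncol = W$input_dim)
  if (ncol(u) != W$input_dim) stop("input has wrong dimension")
  x <- if (reset || is.null(x0)) rep(0, N) else x0
  out <- matrix(0, nrow(u), N)
  for (t in seq_len(nrow(u))) {
    x <- reservoir_step(x, u[t, ], W)
    out[t, ] <- x
  }
  out
}

#' Apply a trained linear readout to a state trajectory
#'
#' The readout is affine: `y(t) = W_out^T [x(t); 1]` row-wise, with no
#' output nonlinearity.
#'
#' @param traj State trajectory (time steps x N).
#' @param W_out Readout weight matrix (`(N + 1) x readout_dim`; the last
#'   row is the bias), as returned by [fit_ridge()].
#' @return Output trajectory (time steps x readout_dim).
#' @export
readout <- function(traj, W_out) {
  if (is.null(W_out)) stop("readout weights have not been trained")
  if (ncol(traj) + 1L != nrow(W_out)) {
    stop("trajectory/readout dimension mismatch")
  }
  cbind(traj, 1) %*% W_out
}
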