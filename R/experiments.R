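# ---- internal cross-validation engine --------------------------------------
#
# One reservoir instance per seed; the full-corpus state harvest is computed
# once per instance and reused across folds (the ridge Gram matrices for a
# training fold are obtained by subtracting the test block from the
# full-corpus Gram matrices). Decoding always happens at the final time step
# of each test sentence.

# Partition 1:n into k folds. With groups, whole groups are assigned to
# folds (largest-first greedy balancing after a seeded shuffle).
cv_folds <- function(n, k, seed, groups = NULL) {
  stopifnot(k >= 2, k <= n)
  if (is.null(groups)) {
    idx <- with_seed(seed, sample.int(n))
    return(split(idx, rep_len(seq_len(k), n)))
  }
  stopifnot(length(groups) == n)
  gs <- split(seq_len(n), groups)
  if (max(lengths(gs)) > ceiling(n / k)) {
    stop("a redundancy group is larger than a fold; cannot partition")
  }
  gs <- with_seed(seed, sample(gs))
  gs <- gs[order(-lengths(gs))]
  folds <- vector("list", k)
  sizes <- numeric(k)
  for (g in gs) {
    j <- which.min(sizes)
    folds[[j]] <- c(folds[[j]], g)
    sizes[j] <- sizes[j] + length(g)
  }
  folds
}

# Run one CV protocol. folds: list of test-index vectors (train = rest).
# measure: "wta" scores word-level coded meanings (the standard measures);
# "neurons" scores thresholded unit signs against the teacher targets (the
# small-corpus experiments' measure, see evaluate_neurons()).
cv_engine <- function(corp, scheme, params, mode, lambda, folds,
                      n_instances, seed, measure = "wta") {
  n <- length(corp)
  inputs <- corpus_inputs(corp, scheme, params$AT)
  targets <- t(vapply(corp, target_vector, numeric(scheme$readout_dim),
                      scheme = scheme))
  seeds <- spawn_seeds(seed, n_instances)
  inst <- vector("list", n_instances)
  for (i in seq_len(n_instances)) {
    p <- params
    p$seed <- seeds[i]
    W <- init_reservoir(p, scheme$input_dim)
    bs <- batch_states(inputs, W, keep_all = (mode == "continuous"))
    if (mode == "sentence_final") {
      X <- cbind(bs$final, 1)
      Y <- targets
      sent <- seq_len(n)
    } else {
      X <- cbind(bs$all, 1)
      sent <- rep(seq_len(n), bs$lens)
      Y <- targets[sent, , drop = FALSE]
    }
    XtX <- crossprod(X)
    XtY <- crossprod(X, Y)
    finals <- cbind(bs$final, 1)
    fold_detail <- vector("list", length(folds))
    for (f in seq_along(folds)) {
      test <- folds[[f]]
      rows <- which(sent %in% test)
      Xt <- X[rows, , drop = FALSE]
      W_out <- ridge_solve(XtX - crossprod(Xt),
                           XtY - crossprod(Xt, Y[rows, , drop = FALSE]),
                           lambda)
      Yhat <- finals[test, , drop = FALSE] %*% W_out
      if (measure == "neurons") {
        wr <- rowSums((Yhat > 0) != (targets[test, , drop = FALSE] > 0))
        fold_detail[[f]] <- data.frame(
          fold = f, n_test = length(test), wrong = sum(wr),
          mappings = length(test) * scheme$readout_dim,
          bad_sentences = sum(wr > 0))
      } else {
        rep_f <- score_outputs(Yhat, corp[test], scheme)
        fold_detail[[f]] <- data.frame(
          fold = f, n_test = length(test),
          wrong = sum(rep_f$per_sentence$wrong),
          mappings = rep_f$n_mappings,
          bad_sentences = sum(rep_f$per_sentence$wrong > 0))
      }
    }
    fd <- do.call(rbind, fold_detail)
    inst[[i]] <- list(
      meaning_error = sum(fd$wrong) / sum(fd$mappings),
      sentence_error = sum(fd$bad_sentences) / sum(fd$n_test),
      folds = fd, seed = seeds[i])
  }
  me <- vapply(inst, `[[`, numeric(1), "meaning_error") * 100
  se <- vapply(inst, `[[`, numeric(1), "sentence_error") * 100
  structure(list(
    meaning_error_mean = mean(me), meaning_error_sd = stats::sd(me),
    sentence_error_mean = mean(se), sentence_error_sd = stats::sd(se),
    per_instance = data.frame(instance = seq_along(inst),
                              seed = vapply(inst, `[[`, numeric(1), "seed"),
                              meaning_error = me, sentence_error = se),
    instances = inst,
    config = list(N = params$N, SR = params$SR, tau = params$tau,
                  AT = params$AT, mode = mode, lambda = lambda,
                  k = length(folds), n_instances = n_instances,
                  seed = seed, n = n)
  ), class = "esn_cv_result")
}

#' @export
print.esn_cv_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<esn_cv_result> %d folds x %d instances (N=%d, SR=%g, tau=%g, %s)\n",
    cfg$k, cfg$n_instances, cfg$N, cfg$SR, cfg$tau, cfg$mode))
  cat(sprintf("  meaning error  %.4f%% (sd %.4f)\n",
              x$meaning_error_mean, x$meaning_error_sd))
  cat(sprintf("  sentence error %.4f%% (sd %.4f)\n",
              x$sentence_error_mean, x$sentence_error_sd))
  invisible(x)
}

#' k-fold cross-validation over a corpus
#'
#' Partitions the corpus into `k` folds (a seeded shuffle; when
#' `group_aware = TRUE`, whole redundancy groups - e.g. a construction and
#' its modifier-inserted variants - are kept within one fold so that
#' train and test never share a group). For each fold and each of
#' `n_instances` freshly seeded reservoir instances, the readout is trained
#' on the other folds and tested on the held-out fold; each instance's
#' errors are pooled over its folds and the result reports the mean and
#' standard deviation across instances, in percent.
#'
#' @param corp An `esn_corpus`.
#' @param k Number of folds (`k = length(corp)` gives leave-one-out).
#' @param params [reservoir_params()] (the `seed` field is overridden by
#'   per-instance seeds spawned from `seed`).
#' @param mode `"sentence_final"` or `"continuous"` learning.
#' @param n_instances Number of reservoir instances to average over.
#' @param lambda Ridge parameter.
#' @param seed Master seed for fold assignment and instance seeds.
#' @param group_aware Keep redundancy groups within folds.
#' @param scheme Coding scheme; defaults to the corpus' scheme.
#' @return An `esn_cv_result`.
#' @export
kfold_cv <- function(corp, k = 10, params = reservoir_params(),
                     mode = c("sentence_final", "continuous"),
                     n_instances = 10, lambda = 1e-9, seed = 1,
                     group_aware = FALSE,
                     scheme = scheme_for_corpus(corp)) {
  mode <- match.arg(mode)
  n <- length(corp)
  if (n < 2) stop("need at least 2 constructions for cross-validation")
  groups <- NULL
  if (group_aware) {
    groups <- vapply(corp, function(cc) {
      g <- cc$meta$group
      if (is.null(g) || is.na(g)) NA_integer_ else as.integer(g)
    }, integer(1))
    if (anyNA(groups)) stop("group-aware CV needs a group id on every construction")
  }
  folds <- cv_folds(n, k, seed, groups)
  cv_engine(corp, scheme, params, mode, lambda, folds, n_instances, seed)
}

#' Leave-one-out cross-validation
#'
#' For each construction, train on all the others and test on it; repeat
#' per reservoir instance and aggregate as in [kfold_cv()].
#'
#' @inheritParams kfold_cv
#' @param measure `"wta"` for the standard word-level coded-meaning
#'   measures, `"neurons"` for the small-corpus experiments' per-unit sign
#'   measure (see [evaluate_neurons()]).
#' @return An `esn_cv_result`.
#' @export
leave_one_out <- function(corp, params = reservoir_params(N = 100),
                          mode = c("sentence_final", "continuous"),
                          n_instances = 100, lambda = 1e-9, seed = 1,
                          measure = c("wta", "neurons"),
                          scheme = scheme_for_corpus(corp)) {
  mode <- match.arg(mode)
  measure <- match.arg(measure)
  if (length(corp) < 2) stop("need at least 2 constructions")
  folds <- as.list(seq_along(corp))
  cv_engine(corp, scheme, params, mode, lambda, folds,
            n_instances, seed, measure)
}

#' Training-set performance (no cross-validation)
#'
#' Trains on the full corpus and scores the same corpus, averaged over
#' reservoir instances - the "train" rows of the experiment tables.
#'
#' @inheritParams kfold_cv
#' @return An `esn_cv_result` (single "fold" containing every sentence).
#' @export
train_error <- function(corp, params = reservoir_params(),
                        mode = c("sentence_final", "continuous"),
                        n_instances = 10, lambda = 1e-9, seed = 1,
                        scheme = scheme_for_corpus(corp)) {
  mode <- match.arg(mode)
  inputs <- corpus_inputs(corp, scheme, params$AT)
  targets <- t(vapply(corp, target_vector, numeric(scheme$readout_dim),
                      scheme = scheme))
  seeds <- spawn_seeds(seed, n_instances)
  res <- lapply(seq_len(n_instances), function(i) {
    p <- params
    p$seed <- seeds[i]
    W <- init_reservoir(p, scheme$input_dim)
    bs <- batch_states(inputs, W, keep_all = (mode == "continuous"))
    if (mode == "sentence_final") {
      X <- cbind(bs$final, 1)
      Y <- targets
    } else {
      sent <- rep(seq_along(corp), bs$lens)
      X <- cbind(bs$all, 1)
      Y <- targets[sent, , drop = FALSE]
    }
    W_out <- ridge_solve(crossprod(X), crossprod(X, Y), lambda)
    score_outputs(cbind(bs$final, 1) %*% W_out, corp, scheme)
  })
  me <- vapply(res, `[[`, numeric(1), "meaning_error") * 100
  se <- vapply(res, `[[`, numeric(1), "sentence_error") * 100
  structure(list(
    meaning_error_mean = mean(me), meaning_error_sd = stats::sd(me),
    sentence_error_mean = mean(se), sentence_error_sd = stats::sd(se),
    per_instance = data.frame(instance = seq_along(res), seed = seeds,
                              meaning_error = me, sentence_error = se),
    instances = res,
    config = list(N = params$N, SR = params$SR, tau = params$tau,
                  AT = params$AT, mode = mode, lambda = lambda,
                  k = 1L, n_instances = n_instances, seed = seed,
                  n = length(corp))
  ), class = "esn_cv_result")
}

#' Two-fold cross-validation on random sub-corpora
#'
#' Progressive-exposure protocol: per reservoir instance, a random
#' sub-corpus of `subset_fraction * length(corp)` constructions is drawn,
#' split in half, the model is trained on one half and tested on the other,
#' and then the halves are swapped; errors are pooled over the two folds.
#'
#' @inheritParams kfold_cv
#' @param subset_fraction Fraction of the corpus in the sub-corpus (the
#'   training set is half of that), in (0, 1].
#' @return An `esn_cv_result`.
#' @export
subset_twofold <- function(corp, subset_fraction, params = reservoir_params(),
                           mode = c("sentence_final", "continuous"),
                           n_instances = 5, lambda = 1e-9, seed = 1,
                           scheme = scheme_for_corpus(corp)) {
  mode <- match.arg(mode)
  n <- length(corp)
  n_sub <- round(subset_fraction * n)
  if (subset_fraction <= 0 || subset_fraction > 1 || n_sub < 2) {
    stop("subset_fraction must leave at least one construction per half")
  }
  seeds <- spawn_seeds(seed, n_instances)
  runs <- lapply(seq_len(n_instances), function(i) {
    sub <- with_seed(seeds[i], sort(sample.int(n, n_sub)))
    half <- seq_len(floor(n_sub / 2))
    folds <- list(half, setdiff(seq_len(n_sub), half))
    cv_engine(corp[sub], scheme, params, mode, lambda, folds,
              n_instances = 1, seed = seeds[i])
  })
  me <- vapply(runs, `[[`, numeric(1), "meaning_error_mean")
  se <- vapply(runs, `[[`, numeric(1), "sentence_error_mean")
  structure(list(
    meaning_error_mean = mean(me), meaning_error_sd = stats::sd(me),
    sentence_error_mean = mean(se), sentence_error_sd = stats::sd(se),
    per_instance = data.frame(instance = seq_along(runs), seed = seeds,
                              meaning_error = me, sentence_error = se),
    instances = runs,
    config = list(N = params$N, SR = params$SR, tau = params$tau,
                  AT = params$AT, mode = mode, lambda = lambda,
                  k = 2L, n_instances = n_instances, seed = seed,
                  n = n, subset_fraction = subset_fraction)
  ), class = "esn_cv_result")
}

#' Hyperparameter sweep over spectral radius, time constant or size
#'
#' Runs the given cross-validation protocol at every grid point and returns
#' the full grid of results.
#'
#' @param corp An `esn_corpus`.
#' @param SR_list,tau_list,N_list Grid values; the grid is the Cartesian
#'   product of the three.
#' @param k,mode,n_instances,lambda,seed Protocol settings passed to
#'   [kfold_cv()].
#' @param AT Activation time.
#' @return Data frame of class `esn_grid_result` with one row per grid
#'   point (columns `N`, `SR`, `tau`, error means and sds) and the full
#'   `esn_cv_result`s in `attr(, "results")`.
#' @export
parameter_sweep <- function(corp, SR_list = 1, tau_list = 6, N_list = 1000,
                            k = 10, mode = c("sentence_final", "continuous"),
                            n_instances = 10, lambda = 1e-9, seed = 1,
                            AT = 1) {
  mode <- match.arg(mode)
  if (!length(SR_list) || !length(tau_list) || !length(N_list)) {
    stop("empty parameter grid")
  }
  grid <- expand.grid(N = N_list, SR = SR_list, tau = tau_list)
  results <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    params <- reservoir_params(N = grid$N[i], SR = grid$SR[i],
                               tau = grid$tau[i], AT = AT)
    results[[i]] <- kfold_cv(corp, k = k, params = params, mode = mode,
                             n_instances = n_instances, lambda = lambda,
                             seed = seed)
    grid$meaning_error_mean[i] <- results[[i]]$meaning_error_mean
    grid$meaning_error_sd[i] <- results[[i]]$meaning_error_sd
    grid$sentence_error_mean[i] <- results[[i]]$sentence_error_mean
    grid$sentence_error_sd[i] <- results[[i]]$sentence_error_sd
  }
  attr(grid, "results") <- results
  class(grid) <- c("esn_grid_result", class(grid))
  grid
}

#' Two-sentence discourse experiment
#'
#' Trains a model on the full 45-construction fixture corpus (each
#' discourse segment presented as one continuous sequence, with the state
#' reset only at segment start) and evaluates the ten two-sentence
#' discourse segments, in which the pronouns of the second sentence must be
#' resolved against the proper-noun ("he"/"him") and common-noun ("it")
#' referents of the first sentence.
#'
#' @param params [reservoir_params()]; the experiment's setting is 300
#'   units.
#' @param mode Learning mode.
#' @param lambda Ridge parameter.
#' @return List with the trained `model`, the error `report` over the ten
#'   segments, and the per-segment `decoded` meanings.
#' @export
run_discourse <- function(params = reservoir_params(N = 300),
                          mode = c("sentence_final", "continuous"),
                          lambda = 1e-9) {
  mode <- match.arg(mode)
  fx <- build_fixture_corpus_45()
  model <- train_readout(fx, params = params, mode = mode, lambda = lambda)
  seg <- fixture_subset("discourse")
  list(model = model,
       report = evaluate_corpus(model, seg),
       decoded = decoded_meanings(model, seg))
}
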