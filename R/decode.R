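#' Decode the word-level coded meaning for one semantic word
#'
#' Two-step decoding of a readout snapshot: activities of the role units
#' belonging to this (semantic word, clause) pair are thresholded at 0, and
#' a winner-takes-all over the remaining roles is performed. If no unit is
#' above threshold the decoded meaning is "none" (`NA`). Exact ties on the
#' positive maximum are broken toward the earliest role in the scheme's
#' role order (P, A, O, R) so decoding is deterministic.
#'
#' @param y_row Readout snapshot (numeric vector of length
#'   `scheme$readout_dim`).
#' @param scheme An [coding_scheme()].
#' @param sw Semantic-word ordinal.
#' @param clause Clause label.
#' @return Role code (`"P"`, `"A"`, `"O"`, `"R"`) or `NA_character_`.
#' @export
decode_word_meaning <- function(y_row, scheme, sw, clause) {
  roles <- scheme$clause_roles[[clause]]
  units <- vapply(roles, function(r) readout_index(sw, clause, r, scheme),
                  integer(1))
  vals <- y_row[units]
  if (!any(vals > 0)) return(NA_character_)
  roles[which.max(vals)] # first maximum wins: role-order tie-break
}

#' Relevant word-level mappings of a construction
#'
#' The mappings evaluated by the error measures: the Cartesian product of
#' the semantic words present in the construction and the clauses present.
#' A word participating in both clauses therefore has two word-level coded
#' meanings; the gold answer for a pair with no role assignment is "none".
#'
#' @param cc An `esn_construction` (its `meta` must carry `n_sw` and
#'   `clauses`, as all generators in this package ensure).
#' @return Data frame with columns `sw`, `clause` and `gold` (role code or
#'   `NA` for none).
#' @export
relevant_mappings <- function(cc) {
  grid <- expand.grid(sw = seq_len(cc$meta$n_sw), clause = cc$meta$clauses,
                      stringsAsFactors = FALSE)
  key <- paste(cc$meaning$sw, cc$meaning$clause)
  hit <- match(paste(grid$sw, grid$clause), key)
  grid$gold <- ifelse(is.na(hit), NA_character_, cc$meaning$role[hit])
  grid
}

# Count decoding errors of one readout snapshot against a construction's
# gold meaning. Returns c(wrong, total).
score_snapshot <- function(y_row, cc, scheme) {
  maps <- relevant_mappings(cc)
  wrong <- 0L
  for (i in seq_len(nrow(maps))) {
    dec <- decode_word_meaning(y_row, scheme, maps$sw[i], maps$clause[i])
    ok <- (is.na(dec) && is.na(maps$gold[i])) ||
      (!is.na(dec) && !is.na(maps$gold[i]) && dec == maps$gold[i])
    if (!ok) wrong <- wrong + 1L
  }
  c(wrong = wrong, total = nrow(maps))
}

#' Evaluate a model over a corpus
#'
#' Decodes every relevant word-level mapping of every construction at the
#' evaluation time step (the final step of the sentence, where the whole
#' sentence has been seen) and aggregates the two error measures:
#' *meaning error*, the fraction of word-level coded meanings decoded
#' incorrectly, and *sentence error*, the fraction of sentences with at
#' least one incorrect word-level coded meaning. Both are exact rational
#' counts in \[0, 1\].
#'
#' @param model An [train_readout()] model.
#' @param corp An `esn_corpus` encodable under the model's scheme.
#' @return An object of class `esn_error_report`: `meaning_error`,
#'   `sentence_error`, counts, and a per-sentence data frame.
#' @export
evaluate_corpus <- function(model, corp) {
  scheme <- model$scheme
  inputs <- corpus_inputs(corp, scheme, model$params$AT)
  finals <- batch_states(inputs, model$W)$final
  Yhat <- readout(finals, model$W_out)
  score_outputs(Yhat, corp, scheme)
}

# Shared scorer: one decoded snapshot per corpus row.
score_outputs <- function(Yhat, corp, scheme) {
  per <- t(vapply(seq_along(corp), function(i) {
    score_snapshot(Yhat[i, ], corp[[i]], scheme)
  }, c(wrong = 0L, total = 0L)))
  detail <- data.frame(sentence = seq_along(corp),
                       wrong = per[, "wrong"], mappings = per[, "total"])
  structure(list(
    meaning_error = sum(detail$wrong) / sum(detail$mappings),
    sentence_error = mean(detail$wrong > 0),
    n_sentences = length(corp),
    n_mappings = sum(detail$mappings),
    per_sentence = detail
  ), class = "esn_error_report")
}

#' @export
print.esn_error_report <- function(x, ...) {
  cat(sprintf("meaning error %.4f%%  sentence error %.4f%%  (%d sentences, %d mappings)\n",
              100 * x$meaning_error, 100 * x$sentence_error,
              x$n_sentences, x$n_mappings))
  invisible(x)
}

#' Neuron-level error measures
#'
#' Alternative, more lenient error measures used by the small-corpus
#' (basic45) experiments: every readout unit's activity is thresholded at 0
#' and compared with the sign of its +/-1 teacher target. The neuron-level
#' meaning error is the fraction of readout units with the wrong sign
#' (pooled over sentences); the neuron-level sentence error is the fraction
#' of sentences with at least one wrong-sign unit. Unlike the word-level
#' WTA measures of [evaluate_corpus()], these score every unit, not only
#' the winner among a word's role units.
#'
#' @param model An [train_readout()] model.
#' @param corp An `esn_corpus`.
#' @return List with `meaning_error`, `sentence_error` (fractions) and a
#'   per-sentence data frame.
#' @export
evaluate_neurons <- function(model, corp) {
  scheme <- model$scheme
  inputs <- corpus_inputs(corp, scheme, model$params$AT)
  finals <- batch_states(inputs, model$W)$final
  Yhat <- readout(finals, model$W_out)
  targets <- t(vapply(corp, target_vector, numeric(scheme$readout_dim),
                      scheme = scheme))
  wrong <- rowSums((Yhat > 0) != (targets > 0))
  detail <- data.frame(sentence = seq_along(corp), wrong = wrong,
                       units = scheme$readout_dim)
  list(meaning_error = sum(wrong) / (length(corp) * scheme$readout_dim),
       sentence_error = mean(wrong > 0),
       per_sentence = detail)
}

#' Decoded coded meanings for every construction of a corpus
#'
#' @param model An [train_readout()] model.
#' @param corp An `esn_corpus`.
#' @return Data frame with one row per relevant mapping: `sentence`, `sw`,
#'   `clause`, `gold`, `decoded`.
#' @export
decoded_meanings <- function(model, corp) {
  scheme <- model$scheme
  inputs <- corpus_inputs(corp, scheme, model$params$AT)
  finals <- batch_states(inputs, model$W)$final
  Yhat <- readout(finals, model$W_out)
  out <- lapply(seq_along(corp), function(i) {
    maps <- relevant_mappings(corp[[i]])
    maps$decoded <- vapply(seq_len(nrow(maps)), function(j) {
      d <- decode_word_meaning(Yhat[i, ], scheme, maps$sw[j], maps$clause[j])
      if (is.na(d)) NA_character_ else d
    }, character(1))
    cbind(sentence = i, maps)
  })
  do.call(rbind, out)
}
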