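#' Coding schemes: vocabularies and readout layouts
#'
#' A coding scheme fixes (i) the input vocabulary, i.e. which closed-class
#' words, inflections, punctuation and semantic-word markers map onto which
#' input channel, and (ii) the readout layout, i.e. which readout unit codes
#' each (semantic word, clause, thematic role) triple.
#'
#' Three schemes are provided:
#' \describe{
#'   \item{`basic45`}{The scheme of the 45-construction fixture corpus.
#'     Nouns (`N`) and verbs (`V`) have separate input channels; 11 slots
#'     for closed-class words plus the period give input dimension 14.
#'     The readout codes 4 nouns x 3 roles (A, O, R) x 2 verbs = 24 units;
#'     verbs themselves receive no role units and meaning is evaluated for
#'     nouns only.}
#'   \item{`ext462`}{The scheme of the 462-construction grammar. All
#'     semantic words share a single `SW` channel; 10 closed-class words
#'     plus `SW`, comma and period give input dimension 13 (14 when the
#'     modifier channel `ADJ` is enabled with `modifiers = TRUE`). The
#'     readout codes 6 semantic words x 4 roles (P, A, O, R) for the main
#'     clause and x 3 roles (P, A, O; relative clauses never take a
#'     recipient) for the relative clause: 6 * (4 + 3) = 42 units.}
#'   \item{`ext90k`}{The scheme of the extended redundant grammar: input
#'     dimension 12 (including `who` and the `-m` inflection of `whom`),
#'     readout 7 semantic words x 4 roles x 2 clauses = 56 units.}
#' }
#'
#' The readout layout is semantic-word-major, then clause (main before
#' relative), then role in the order P, A, O, R.
#'
#' @param scheme_id One of `"basic45"`, `"ext462"`, `"ext90k"`.
#' @param modifiers Logical; add the adjective/adverb channel `ADJ`
#'   (only meaningful for `ext462`).
#' @return An object of class `esn_scheme`.
#' @export
#' @examples
#' sc <- coding_scheme("ext462")
#' sc$input_dim   # 13
#' sc$readout_dim # 42
coding_scheme <- function(scheme_id = c("ext462", "basic45", "ext90k"),
                          modifiers = FALSE) {
  scheme_id <- match.arg(scheme_id)
  sc <- switch(scheme_id,
    ext462 = list(
      scheme_id = "ext462",
      vocab = c("-ed", "-ing", "-s", "by", "is", "it", "that", "the", "to",
                "was", "SW", ",", "."),
      semantic_tokens = "SW",
      indexed_tokens = "SW",
      clauses = c("main", "relative"),
      clause_roles = list(main = c("P", "A", "O", "R"),
                          relative = c("P", "A", "O")),
      max_sw = 6L
    ),
    basic45 = list(
      scheme_id = "basic45",
      vocab = c("the", "that", "was", "by", "to", "and", "it", "then",
                "he", "him", "who", "N", "V", "."),
      semantic_tokens = c("N", "V"),
      indexed_tokens = "N",
      clauses = c("v1", "v2"),
      clause_roles = list(v1 = c("A", "O", "R"), v2 = c("A", "O", "R")),
      max_sw = 4L
    ),
    ext90k = list(
      scheme_id = "ext90k",
      vocab = c("by", "is", "to", "that", "the", "who", "-ed", "-s", "-m",
                "SW", ",", "."),
      semantic_tokens = "SW",
      indexed_tokens = "SW",
      clauses = c("main", "relative"),
      clause_roles = list(main = c("P", "A", "O", "R"),
                          relative = c("P", "A", "O", "R")),
      max_sw = 7L
    )
  )
  if (modifiers) {
    if (scheme_id != "ext462") {
      stop("the modifier channel is only defined for scheme 'ext462'")
    }
    sc$vocab <- c(sc$vocab, "ADJ")
    sc$has_modifier <- TRUE
  } else {
    sc$has_modifier <- FALSE
  }
  sc$input_dim <- length(sc$vocab)
  layout <- scheme_layout(sc)
  sc$layout <- layout
  sc$readout_dim <- nrow(layout)
  class(sc) <- "esn_scheme"
  sc
}

# Readout layout table: one row per readout unit, sw-major, clause order as
# declared, roles in the clause's declared order.
scheme_layout <- function(sc) {
  rows <- list()
  for (sw in seq_len(sc$max_sw)) {
    for (cl in sc$clauses) {
      for (role in sc$clause_roles[[cl]]) {
        rows[[length(rows) + 1L]] <- data.frame(
          sw = sw, clause = cl, role = role, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$unit <- seq_len(nrow(out))
  out
}

#' Readout unit index for a (semantic word, clause, role) triple
#'
#' Stable bijection between valid triples and readout units (1-based).
#'
#' @param sw 1-based ordinal of the semantic word in the surface form.
#' @param clause Clause label (`"main"`/`"relative"` for the extended
#'   schemes, `"v1"`/`"v2"` for `basic45`).
#' @param role Thematic role code (`"P"`, `"A"`, `"O"`, `"R"`).
#' @param scheme An [coding_scheme()] object.
#' @return Integer unit index in `1:scheme$readout_dim`.
#' @export
readout_index <- function(sw, clause, role, scheme) {
  if (!is.numeric(sw) || sw < 1 || sw > scheme$max_sw) {
    stop("sw index out of range 1..", scheme$max_sw, " for scheme ",
         scheme$scheme_id)
  }
  lay <- scheme$layout
  hit <- which(lay$sw == sw & lay$clause == clause & lay$role == role)
  if (length(hit) != 1L) {
    stop("no readout unit for (sw=", sw, ", clause=", clause, ", role=",
         role, ") in scheme ", scheme$scheme_id)
  }
  lay$unit[hit]
}

#' Inverse of [readout_index()]
#'
#' @param unit Readout unit index.
#' @param scheme An [coding_scheme()] object.
#' @return List with fields `sw`, `clause`, `role`.
#' @export
readout_triple <- function(unit, scheme) {
  lay <- scheme$layout
  if (unit < 1 || unit > nrow(lay)) stop("unit out of range")
  as.list(lay[unit, c("sw", "clause", "role")])
}

#' @export
print.esn_scheme <- function(x, ...) {
  cat("<esn_scheme ", x$scheme_id, ">: input dim ", x$input_dim,
      ", readout dim ", x$readout_dim, "\n", sep = "")
  cat("  vocabulary: ", paste(x$vocab, collapse = " "), "\n", sep = "")
  invisible(x)
}
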