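#' Grammatical constructions and corpora
#'
#' A construction pairs a surface form (an ordered token sequence over
#' closed-class words and semantic-word markers, terminated by a period)
#' with a coded meaning: a partial assignment of thematic roles to
#' (semantic word, clause) pairs. A corpus is an ordered list of
#' constructions targeting one coding scheme.
#'
#' @param tokens Character vector of tokens; must end with `"."`.
#' @param meaning Data frame with columns `sw` (1-based ordinal of the
#'   semantic word), `clause` and `role`; at most one role per
#'   (`sw`, `clause`) pair.
#' @param meta Named list of metadata (arities, order labels, attachment,
#'   redundancy group, flags).
#' @return An object of class `esn_construction`.
#' @export
construction <- function(tokens, meaning, meta = list()) {
  stopifnot(is.character(tokens), length(tokens) >= 1)
  if (tokens[length(tokens)] != ".") {
    stop("a surface form must end with the period token")
  }
  meaning <- as.data.frame(meaning, stringsAsFactors = FALSE)
  stopifnot(all(c("sw", "clause", "role") %in% names(meaning)))
  key <- paste(meaning$sw, meaning$clause)
  if (anyDuplicated(key)) {
    stop("at most one role per (sw, clause) pair")
  }
  structure(list(tokens = tokens, meaning = meaning, meta = meta),
            class = "esn_construction")
}

#' @export
print.esn_construction <- function(x, ...) {
  cat(paste(x$tokens, collapse = " "), "\n")
  if (nrow(x$meaning)) {
    cat("  ", paste(sprintf("SW%d:%s(%s)", x$meaning$sw, x$meaning$role,
                            x$meaning$clause), collapse = " "), "\n", sep = "")
  }
  invisible(x)
}

#' Bundle constructions into a corpus
#'
#' @param constructions List of [construction()] objects.
#' @param scheme_id Identifier of the target [coding_scheme()].
#' @param provenance One of `"generated"`, `"loaded"`, `"scrambled"`,
#'   `"augmented"`.
#' @return An object of class `esn_corpus` (a list of constructions with
#'   `scheme_id` and `provenance` attributes).
#' @export
corpus <- function(constructions, scheme_id, provenance = "generated") {
  stopifnot(is.list(constructions))
  structure(constructions, class = "esn_corpus",
            scheme_id = scheme_id, provenance = provenance)
}

#' @export
print.esn_corpus <- function(x, ...) {
  cat("<esn_corpus> ", length(x), " constructions, scheme ",
      attr(x, "scheme_id"), ", provenance ", attr(x, "provenance"),
      "\n", sep = "")
  invisible(x)
}

#' @export
`[.esn_corpus` <- function(x, i) {
  corpus(unclass(x)[i], scheme_id = attr(x, "scheme_id"),
         provenance = attr(x, "provenance"))
}

#' Surface forms of a corpus as strings
#'
#' @param x An `esn_corpus`.
#' @return Character vector, one space-joined surface form per construction.
#' @export
surface_forms <- function(x) {
  vapply(x, function(cc) paste(cc$tokens, collapse = " "), character(1))
}

# Canonical string form of a coded meaning, for identity comparisons.
meaning_key <- function(cc) {
  m <- cc$meaning
  if (!nrow(m)) return("")
  o <- order(m$sw, m$clause, m$role)
  paste(m$sw[o], m$clause[o], m$role[o], sep = ":", collapse = "|")
}
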