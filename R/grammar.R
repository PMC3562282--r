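#' Construction grammar for the 462-corpus
#'
#' The grammar enumerates clause-level word orders for verbs taking 1 to 3
#' arguments, optionally inserts a relative clause after any noun of the
#' main clause, and renders each abstract order as a token sequence over the
#' `ext462` vocabulary via a fixed compositional template table. Coded
#' meanings are derived positionally: the i-th semantic-word marker of the
#' final surface form is semantic word i, and receives the role its clause
#' element carries; the head noun of a relative clause receives two
#' assignments, one per clause.
#'
#' With all options enabled the grammar yields
#' 2 + 6 + 24 main-clause orders (arity 1, 2, 3), each alone or combined
#' with one of 5 relative-clause patterns (arity-1 head = Agent; arity-2
#' head in {Agent, Object} x 2 internal orders) attached after any of the
#' main clause's nouns: 2*1*5 + 6*2*5 + 24*3*5 + 32 = 462 constructions.
#'
#' @param main_arities Integer subset of `1:3`: verb arities allowed in the
#'   main clause.
#' @param relative_arities Integer subset of `c(0, 1, 2)`; `0` stands for
#'   "no relative clause".
#' @param orders `"all"` or a character vector of order labels (e.g.
#'   `"APO"`) to restrict to.
#' @return An object of class `esn_grammar_spec`.
#' @export
grammar_spec <- function(main_arities = 1:3, relative_arities = c(0, 1, 2),
                         orders = "all") {
  stopifnot(all(main_arities %in% 1:3), all(relative_arities %in% 0:2))
  structure(list(main_arities = sort(unique(as.integer(main_arities))),
                 relative_arities = sort(unique(as.integer(relative_arities))),
                 orders = orders),
            class = "esn_grammar_spec")
}

# All permutations of a character vector, in lexicographic order.
role_permutations <- function(elts) {
  n <- length(elts)
  if (n == 1L) return(list(elts))
  out <- list()
  for (e in sort(elts)) {
    rest <- elts[-match(e, elts)]
    for (p in role_permutations(rest)) out[[length(out) + 1L]] <- c(e, p)
  }
  out
}

# Clause roles by verb arity: the verb (P) plus its arguments.
clause_roles_for_arity <- function(arity) {
  switch(arity, c("A", "P"), c("A", "O", "P"), c("A", "O", "P", "R"))
}

# Order labels (e.g. "APO") for a given arity, lexicographic.
order_labels <- function(arity) {
  vapply(role_permutations(clause_roles_for_arity(arity)),
         paste, character(1), collapse = "")
}

# Relative-clause patterns "head:internal order", by relative arity.
relative_patterns <- function(rel_arities) {
  pats <- character(0)
  if (1 %in% rel_arities) pats <- c(pats, "A:P")
  if (2 %in% rel_arities) pats <- c(pats, "A:OP", "A:PO", "O:AP", "O:PA")
  sort(pats)
}

# --- Rendering templates -----------------------------------------------------
#
# Each clause element renders as a small token unit whose closed-class frame
# depends on the element's role and its position relative to the verb:
#   P  clause-initial        SW -ing was      (fronted participial)
#   P  right after A         SW -s            (active)
#   P  right after O         was SW -ed       (passive)
#   P  right after R         SW -ed
#   A  before P              the SW
#   A  after P               by the SW        (bare "the SW" in arity-1 "PA")
#   O  right before P        the SW
#   O  before P, not adjacent  the SW is
#   O  after P               the SW
#   R  anywhere              to the SW
# The frames are chosen so that every permutation of clause elements maps to
# a distinct token sequence (verified by the corpus uniqueness invariant),
# while the canonical English-like orders come out as the familiar active
# ("the SW SW -s the SW"), passive ("the SW was SW -ed by the SW") and
# dative ("the SW SW -s the SW to the SW") frames.
render_main_unit <- function(role, i, roles, arity) {
  p_pos <- match("P", roles)
  if (role == "P") {
    if (i == 1L) return(c("SW", "-ing", "was"))
    return(switch(roles[i - 1L],
                  A = c("SW", "-s"),
                  O = c("was", "SW", "-ed"),
                  R = c("SW", "-ed")))
  }
  if (role == "A") {
    if (i < p_pos) return(c("the", "SW"))
    if (p_pos == 1L && arity == 1L) return(c("the", "SW"))
    return(c("by", "the", "SW"))
  }
  if (role == "O") {
    if (i == p_pos - 1L) return(c("the", "SW"))
    if (i < p_pos) return(c("the", "SW", "is"))
    return(c("the", "SW"))
  }
  c("to", "the", "SW") # R
}

# Relative clause templates. Returns tokens plus the ordered roles of the
# semantic words they contain (the head noun is not part of these tokens).
relative_template <- function(pattern) {
  switch(pattern,
    "A:P"  = list(tokens = c("that", "SW", "-s"), sw_roles = "P"),
    "A:PO" = list(tokens = c("that", "SW", "-s", "the", "SW"),
                  sw_roles = c("P", "O")),
    "A:OP" = list(tokens = c("that", "the", "SW", "was", "SW", "-ed"),
                  sw_roles = c("O", "P")),
    "O:PA" = list(tokens = c("that", "was", "SW", "-ed", "by", "the", "SW"),
                  sw_roles = c("P", "A")),
    "O:AP" = list(tokens = c("that", "the", "SW", "SW", "-s"),
                  sw_roles = c("A", "P")),
    stop("no rendering template for relative pattern label '", pattern, "'")
  )
}

# Build one construction from (main order label, attachment noun ordinal,
# relative pattern). attach = 0 means no relative clause.
build_construction_462 <- function(order, attach = 0L, rel_pattern = NULL) {
  roles <- strsplit(order, "")[[1]]
  arity <- length(roles) - 1L
  tokens <- character(0)
  # role annotations of each SW token, in order of appearance; each entry is
  # a list of (clause, role) rows
  sw_notes <- list()
  noun_ord <- 0L
  for (i in seq_along(roles)) {
    unit <- render_main_unit(roles[i], i, roles, arity)
    tokens <- c(tokens, unit)
    notes <- list(c("main", roles[i]))
    is_noun <- roles[i] != "P"
    if (is_noun) noun_ord <- noun_ord + 1L
    if (is_noun && attach > 0L && noun_ord == attach) {
      # head noun: add its relative-clause role, then splice in the clause
      head_role <- substr(rel_pattern, 1, 1)
      notes[[2]] <- c("relative", head_role)
      tpl <- relative_template(rel_pattern)
      sw_notes[[length(sw_notes) + 1L]] <- notes
      tokens <- c(tokens, tpl$tokens)
      for (r in tpl$sw_roles) {
        sw_notes[[length(sw_notes) + 1L]] <- list(c("relative", r))
      }
      next
    }
    sw_notes[[length(sw_notes) + 1L]] <- notes
  }
  tokens <- c(tokens, ".")
  rows <- list()
  for (sw in seq_along(sw_notes)) {
    for (nt in sw_notes[[sw]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        sw = sw, clause = nt[1], role = nt[2], stringsAsFactors = FALSE)
    }
  }
  meaning <- do.call(rbind, rows)
  has_rel <- attach > 0L
  construction(tokens, meaning, meta = list(
    main_arity = arity,
    order = order,
    attach = attach,
    rel_pattern = if (has_rel) rel_pattern else "",
    n_sw = length(sw_notes),
    clauses = if (has_rel) c("main", "relative") else "main",
    group = NA_integer_
  ))
}

#' Enumerate all constructions reachable under a grammar spec
#'
#' Deterministic output order: lexicographic in (main arity, order label,
#' attachment ordinal, relative pattern label), with the no-relative variant
#' (attachment 0) first within each order.
#'
#' @param spec A [grammar_spec()].
#' @return An `esn_corpus` targeting scheme `ext462`.
#' @export
#' @examples
#' length(enumerate_constructions(grammar_spec()))             # 462
#' length(enumerate_constructions(grammar_spec(relative_arities = 0))) # 32
enumerate_constructions <- function(spec = grammar_spec()) {
  stopifnot(inherits(spec, "esn_grammar_spec"))
  rel_pats <- relative_patterns(spec$relative_arities)
  out <- list()
  for (arity in spec$main_arities) {
    labels <- order_labels(arity)
    if (!identical(spec$orders, "all")) {
      labels <- intersect(labels, spec$orders)
    }
    for (order in labels) {
      if (0 %in% spec$relative_arities) {
        out[[length(out) + 1L]] <- build_construction_462(order)
      }
      if (length(rel_pats)) {
        for (attach in seq_len(arity)) {      # one noun per argument
          for (pat in rel_pats) {
            out[[length(out) + 1L]] <-
              build_construction_462(order, attach, pat)
          }
        }
      }
    }
  }
  corpus(out, scheme_id = "ext462", provenance = "generated")
}
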