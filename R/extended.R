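#' Best-effort extended redundant grammar
#'
#' Generator in the style of the large (>90k) redundant corpus: a
#' restricted set of intelligible word orders rendered over the `ext90k`
#' vocabulary (which uses "is", "who"/"whom" and no fronted participials),
#' expanded with individually toggleable redundancy options. Unlike the
#' 462 grammar, multiple surface forms may share one coded meaning
#' (redundancy, tracked by group ids) and distinct meanings may share one
#' surface form (ambiguity, flagged by [corpus_stats()]).
#'
#' The published corpus filtered "clearly non-intelligible" orders by hand,
#' so an exact cardinality match is out of reach by design; this generator
#' reproduces the corpus' qualitative properties (redundancy, ambiguity,
#' incomplete meanings), not its exact counts.
#'
#' @param proper_nouns Also render every construction with bare (proper)
#'   nouns instead of "the"-marked common nouns.
#' @param who_that Render relativizers both as "that" and as
#'   "who" ("who -m" for object heads).
#' @param by_position For passive relatives with "whom", add the
#'   by-fronted variant ("by who -m ... is SW -ed") next to the stranded
#'   one ("who -m ... is SW -ed by").
#' @param reduced_relatives Add reduced variants of passive relatives
#'   ("that is SW -ed by ..." -> "SW -ed by ...").
#' @param incomplete_meanings Include agentless passives ("the SW is
#'   SW -ed [to the SW]"), whose meanings have no Agent assignment.
#' @return An `esn_corpus` targeting scheme `ext90k`, with redundancy-group
#'   ids (variants of one base construction share a group).
#' @export
enumerate_extended <- function(proper_nouns = TRUE, who_that = TRUE,
                               by_position = TRUE, reduced_relatives = TRUE,
                               incomplete_meanings = TRUE) {
  main_orders <- list(`1` = "AP", `2` = c("APO", "OPA"),
                      `3` = c("APOR", "APRO", "OPAR", "OPRA"))
  if (incomplete_meanings) {
    main_orders[["2"]] <- c(main_orders[["2"]], "OP")
    main_orders[["3"]] <- c(main_orders[["3"]], "OPR")
  }
  rel_pats <- c("A:P", "A:PO", "O:AP", "O:PA")
  base <- list()
  for (orders in main_orders) {
    for (order in orders) {
      roles <- strsplit(order, "")[[1]]
      n_nouns <- sum(roles != "P")
      base[[length(base) + 1L]] <- list(order = order, attach = 0L,
                                        pat = NULL)
      for (attach in seq_len(n_nouns)) {
        for (pat in rel_pats) {
          base[[length(base) + 1L]] <- list(order = order, attach = attach,
                                            pat = pat)
        }
      }
    }
  }
  out <- list()
  for (g in seq_along(base)) {
    b <- base[[g]]
    rel_variants <- if (is.null(b$pat)) list(NULL) else {
      v <- list(ext_relative_tokens(b$pat, "that"))
      if (who_that) {
        v <- c(v, list(ext_relative_tokens(b$pat, "who")))
        if (by_position && b$pat == "O:PA") {
          v <- c(v, list(ext_relative_tokens(b$pat, "who",
                                             by_fronted = TRUE)))
        }
      }
      if (reduced_relatives && b$pat == "O:PA") {
        v <- c(v, list(ext_relative_tokens(b$pat, "that", reduced = TRUE)))
      }
      v
    }
    styles <- if (proper_nouns) c("common", "proper") else "common"
    for (rv in rel_variants) {
      for (style in styles) {
        cc <- ext_build(b$order, b$attach, b$pat, rv, style)
        cc$meta$group <- g
        out[[length(out) + 1L]] <- cc
      }
    }
  }
  corpus(out, scheme_id = "ext90k", provenance = "generated")
}

# Token unit for one main-clause element under the ext90k vocabulary.
# Orders are restricted so the verb is never clause-initial and a
# pre-verbal object is always adjacent to the verb.
ext_main_unit <- function(role, i, roles, noun) {
  p_pos <- match("P", roles)
  if (role == "P") {
    return(switch(roles[i - 1L],
                  A = c("SW", "-s"),
                  O = c("is", "SW", "-ed"),
                  R = c("SW", "-ed")))
  }
  if (role == "A" && i > p_pos) return(c("by", noun))
  if (role == "R") return(c("to", noun))
  noun
}

# Relative-clause variants under the ext90k vocabulary.
ext_relative_tokens <- function(pattern, rel = "that", reduced = FALSE,
                                by_fronted = FALSE) {
  head_obj <- substr(pattern, 1, 1) == "O"
  rel_toks <- if (rel == "who" && head_obj) c("who", "-m") else rel
  tpl <- switch(pattern,
    "A:P"  = list(tokens = c(rel_toks, "SW", "-s"), sw_roles = "P"),
    "A:PO" = list(tokens = c(rel_toks, "SW", "-s", "NOUN"),
                  sw_roles = c("P", "O")),
    "O:AP" = list(tokens = c(rel_toks, "NOUN", "SW", "-s"),
                  sw_roles = c("A", "P")),
    "O:PA" = list(tokens = c(rel_toks, "is", "SW", "-ed", "by", "NOUN"),
                  sw_roles = c("P", "A")),
    stop("no rendering template for relative pattern label '", pattern, "'"))
  if (pattern == "O:PA") {
    if (reduced) { # "SW -ed by NOUN"
      tpl$tokens <- c("SW", "-ed", "by", "NOUN")
    } else if (by_fronted) { # "by who -m NOUN is SW -ed"
      tpl$tokens <- c("by", rel_toks, "NOUN", "is", "SW", "-ed")
    }
  }
  tpl
}

ext_build <- function(order, attach, pat, rel_tpl, style) {
  roles <- strsplit(order, "")[[1]]
  noun <- if (style == "common") c("the", "SW") else "SW"
  tokens <- character(0)
  sw_notes <- list()
  noun_ord <- 0L
  for (i in seq_along(roles)) {
    unit <- ext_main_unit(roles[i], i, roles, noun)
    unit <- unlist(lapply(unit, function(tk) if (tk == "NOUN") noun else tk))
    tokens <- c(tokens, unit)
    notes <- list(c("main", roles[i]))
    if (roles[i] != "P") {
      noun_ord <- noun_ord + 1L
      if (attach > 0L && noun_ord == attach) {
        notes[[2]] <- c("relative", substr(pat, 1, 1))
        sw_notes[[length(sw_notes) + 1L]] <- notes
        rel_toks <- unlist(lapply(rel_tpl$tokens,
                                  function(tk) if (tk == "NOUN") noun else tk))
        tokens <- c(tokens, rel_toks)
        for (r in rel_tpl$sw_roles) {
          sw_notes[[length(sw_notes) + 1L]] <- list(c("relative", r))
        }
        next
      }
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
  has_rel <- attach > 0L
  construction(tokens, do.call(rbind, rows), meta = list(
    main_arity = length(roles) - sum(roles == "P"),
    order = order, attach = attach,
    rel_pattern = if (has_rel) pat else "",
    n_sw = length(sw_notes),
    clauses = if (has_rel) c("main", "relative") else "main",
    style = style, group = NA_integer_))
}
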