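#' Scramble the word order of every construction
#'
#' Structure-removal control: per construction, all tokens except the final
#' period are randomly permuted (the period is kept as the sequence
#' terminator so evaluation timing is preserved); coded meanings are left
#' unchanged. One independent permutation is drawn per construction, in
#' corpus order, from a generator seeded once with `seed`, so the same seed
#' reproduces the same scrambled corpus.
#'
#' @param x An `esn_corpus`.
#' @param seed Integer seed.
#' @return An `esn_corpus` with provenance `"scrambled"`.
#' @export
scramble_corpus <- function(x, seed) {
  stopifnot(inherits(x, "esn_corpus"), length(x) >= 1)
  out <- with_seed(seed, lapply(unclass(x), function(cc) {
    n <- length(cc$tokens)
    body <- cc$tokens[-n]
    cc$tokens <- c(body[sample.int(length(body))], ".")
    cc
  }))
  corpus(out, scheme_id = attr(x, "scheme_id"), provenance = "scrambled")
}

#' Augment a corpus with modifier-inserted variants
#'
#' Robustness-to-time-distortion control: each source construction yields
#' itself plus `n_variants` copies in which adjective/adverb tokens (`ADJ`)
#' are inserted immediately before randomly chosen semantic-word markers.
#' For each variant the number of insertions is drawn uniformly between 1
#' and the number of semantic words, and the insertion sites are a random
#' subset of the marker positions. Meanings are unchanged; all copies of a
#' source construction share a redundancy-group id so that group-aware
#' cross-validation never splits them across train and test.
#'
#' @param x An `esn_corpus` whose target scheme has a modifier channel
#'   (scheme `ext462`).
#' @param n_variants Number of modified copies per source construction.
#' @param seed Integer seed.
#' @return An `esn_corpus` of size `length(x) * (1 + n_variants)` with
#'   provenance `"augmented"`; source and variants are contiguous.
#' @export
augment_with_modifiers <- function(x, n_variants = 5, seed = 1) {
  stopifnot(inherits(x, "esn_corpus"))
  if (n_variants < 0) stop("n_variants must be >= 0")
  if (attr(x, "scheme_id") != "ext462") {
    stop("modifier augmentation requires a scheme with a modifier channel ",
         "(ext462)")
  }
  out <- with_seed(seed, {
    res <- list()
    for (i in seq_along(x)) {
      cc <- x[[i]]
      cc$meta$group <- i
      res[[length(res) + 1L]] <- cc
      sw_pos <- which(cc$tokens == "SW")
      for (v in seq_len(n_variants)) {
        k <- sample.int(length(sw_pos), 1L)
        sites <- sort(sample(sw_pos, k))
        toks <- cc$tokens
        # insert back-to-front so earlier positions stay valid
        for (p in rev(sites)) toks <- append(toks, "ADJ", after = p - 1L)
        var <- cc
        var$tokens <- toks
        var$meta$group <- i
        res[[length(res) + 1L]] <- var
      }
    }
    res
  })
  corpus(out, scheme_id = attr(x, "scheme_id"), provenance = "augmented")
}

#' Corpus summary statistics
#'
#' @param x An `esn_corpus`.
#' @return A list of class `esn_corpus_stats`: construction counts by main
#'   arity and relative pattern, ambiguity (identical surface form, distinct
#'   coded meaning) counts and fraction, redundancy-group count (distinct
#'   coded meanings shared by several surface forms, or explicit group ids),
#'   and the distribution of relevant-mapping counts per sentence.
#' @export
corpus_stats <- function(x) {
  stopifnot(inherits(x, "esn_corpus"))
  sf <- surface_forms(x)
  mk <- vapply(x, meaning_key, character(1))
  # ambiguous: same surface, >1 distinct meaning among its bearers
  amb <- logical(length(x))
  for (s in unique(sf[duplicated(sf)])) {
    idx <- which(sf == s)
    if (length(unique(mk[idx])) > 1L) amb[idx] <- TRUE
  }
  groups <- vapply(x, function(cc) {
    g <- cc$meta$group
    if (is.null(g) || is.na(g)) NA_integer_ else as.integer(g)
  }, integer(1))
  n_groups <- if (all(is.na(groups))) {
    sum(table(mk) > 1L)
  } else {
    length(unique(groups[!is.na(groups)]))
  }
  arity <- vapply(x, function(cc) {
    a <- cc$meta$main_arity
    if (is.null(a)) NA_integer_ else as.integer(a)
  }, integer(1))
  relpat <- vapply(x, function(cc) {
    p <- cc$meta$rel_pattern
    if (is.null(p)) "" else p
  }, character(1))
  relmap <- vapply(x, function(cc) {
    cc$meta$n_sw * length(cc$meta$clauses)
  }, numeric(1))
  structure(list(
    n = length(x),
    by_arity = table(arity, useNA = "ifany"),
    by_relative = table(relpat, useNA = "ifany"),
    ambiguous_count = sum(amb),
    ambiguous_fraction = sum(amb) / length(x),
    ambiguous = amb,
    redundancy_groups = n_groups,
    relevant_mapping_dist = table(relmap)
  ), class = "esn_corpus_stats")
}

#' @export
print.esn_corpus_stats <- function(x, ...) {
  cat("corpus of", x$n, "constructions\n")
  cat("ambiguous:", x$ambiguous_count,
      sprintf("(%.2f%%)", 100 * x$ambiguous_fraction), "\n")
  cat("redundancy groups:", x$redundancy_groups, "\n")
  cat("relevant mappings per sentence:\n")
  print(x$relevant_mapping_dist)
  invisible(x)
}
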