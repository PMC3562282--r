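#' The 45-construction fixture corpus
#'
#' Reconstruction of the 45-construction corpus used by the small-scale
#' comprehension, P600-analog, generalization and discourse experiments.
#' The original supplementary listing is not shipped with this package, so
#' the corpus is rebuilt here from its printed anchors: the four example
#' surface forms of the basic-comprehension figures ("The N V the N to the
#' N", "The N V the N that V the N", "The N V the N that was V by the N",
#' "The N was V by the N"), the subject- and object-relative forms of the
#' P600 figures, the Caplan-protocol construction types (active, passive,
#' cleft-subject, cleft-object, dative, dative-passive, conjoined,
#' relatives), and the discourse design (ten two-sentence segments whose
#' first sentence contains one proper and one common noun and whose second
#' sentence uses "he"/"him" for the proper and "it" for the common noun).
#' This is a synthetic stand-in: indices, but not necessarily the exact
#' surface forms, match the original numbering convention.
#'
#' Layout: constructions 0-4 and 10-14 are two-sentence discourse segments
#' (presented as one input sequence, reset only at segment start); 5-9 are
#' simple fillers; 15-40 are the 26 core constructions used for basic
#' comprehension and leave-one-out generalization; 41-44 are
#' object-relatives. Constructions removed for the frequency-manipulated
#' (subject-relative-biased) corpus - object-relatives and
#' relative-passives - carry the flag `star = TRUE`.
#'
#' Coded meanings assign roles (A, O, R) to nouns only, per verb in surface
#' order (`v1` = first verb, `v2` = second); proper nouns are rendered as
#' bare `N` (no "the").
#'
#' @return An `esn_corpus` of 45 constructions targeting scheme `basic45`.
#' @export
#' @examples
#' fx <- build_fixture_corpus_45()
#' fx[[25]] # a relative-passive, flagged removable
build_fixture_corpus_45 <- function() {
  spec <- list(
    # index, surface, meaning ("<noun>:<role><verb>" terms), flags
    list(0L, "N V the N . then he V it .", "1:A1 1:A2 2:O1 2:O2", "d"),
    list(1L, "the N was V by N . then he V it .", "1:O1 1:O2 2:A1 2:A2", "d"),
    list(2L, "N V the N . then it V him .", "1:A1 1:O2 2:O1 2:A2", "d"),
    list(3L, "the N was V by N . then it V him .", "1:O1 1:A2 2:A1 2:O2", "d"),
    list(4L, "N V the N . then it was V by him .", "1:A1 1:A2 2:O1 2:O2", "d"),
    list(5L, "N V the N .", "1:A1 2:O1", ""),
    list(6L, "the N V N .", "1:A1 2:O1", ""),
    list(7L, "N was V by the N .", "1:O1 2:A1", ""),
    list(8L, "the N V to the N .", "1:A1 2:R1", ""),
    list(9L, "N V the N to the N .", "1:A1 2:O1 3:R1", ""),
    list(10L, "the N was V by N . then it was V by him .",
         "1:O1 1:O2 2:A1 2:A2", "d"),
    list(11L, "N V the N . then he V it to the N .",
         "1:A1 1:A2 2:O1 2:O2 3:R2", "d"),
    list(12L, "the N was V by N . then he V it to the N .",
         "1:O1 1:O2 2:A1 2:A2 3:R2", "d"),
    list(13L, "N V the N . then he was V by it .", "1:A1 1:O2 2:O1 2:A2", "d"),
    list(14L, "the N was V by N . then he was V by it .",
         "1:O1 1:A2 2:A1 2:O2", "d"),
    list(15L, "the N V the N .", "1:A1 2:O1", ""),
    list(16L, "the N was V by the N .", "1:O1 2:A1", ""),
    list(17L, "the N V the N to the N .", "1:A1 2:O1 3:R1", ""),
    list(18L, "the N was V to the N by the N .", "1:O1 2:R1 3:A1", ""),
    list(19L, "it was the N that V the N .", "1:A1 2:O1", ""),
    list(20L, "the N that V the N V the N .", "1:A1 1:A2 2:O1 3:O2", ""),
    list(21L, "it was the N that the N V .", "1:O1 2:A1", "*"),
    list(22L, "the N that V the N was V by the N .",
         "1:A1 1:O2 2:O1 3:A2", ""),
    list(23L, "the N V the N that V the N .", "1:A1 2:O1 2:A2 3:O2", ""),
    list(24L, "the N V the N that was V by the N .",
         "1:A1 2:O1 2:O2 3:A2", "*"),
    list(25L, "the N that was V by the N V the N .",
         "1:O1 1:A2 2:A1 3:O2", "*"),
    list(26L, "the N V the N and V the N .", "1:A1 1:A2 2:O1 3:O2", ""),
    list(27L, "the N and the N V the N .", "1:A1 2:A1 3:O1", ""),
    list(28L, "the N V the N and the N .", "1:A1 2:O1 3:O1", ""),
    list(29L, "the N was V by the N and the N .", "1:O1 2:A1 3:A1", ""),
    list(30L, "it was the N that V the N to the N .", "1:A1 2:O1 3:R1", ""),
    list(31L, "it was the N that the N V to the N .", "1:O1 2:A1 3:R1", "*"),
    list(32L, "the N V the N to the N and V the N .",
         "1:A1 1:A2 2:O1 3:R1 4:O2", ""),
    list(33L, "the N that V V the N .", "1:A1 1:A2 2:O2", ""),
    list(34L, "the N that V the N V the N to the N .",
         "1:A1 1:A2 2:O1 3:O2 4:R2", ""),
    list(35L, "the N V the N that V the N to the N .",
         "1:A1 2:O1 2:A2 3:O2 4:R2", ""),
    list(36L, "the N V the N to the N that V the N .",
         "1:A1 2:O1 3:R1 3:A2 4:O2", ""),
    list(37L, "the N was V by the N that V the N .",
         "1:O1 2:A1 2:A2 3:O2", ""),
    list(38L, "the N that V the N was V to the N by the N .",
         "1:A1 1:O2 2:O1 3:R2 4:A2", ""),
    list(39L, "the N that V was V by the N .", "1:A1 1:O2 2:A2", ""),
    list(40L, "the N was V by the N and was V by the N .",
         "1:O1 1:O2 2:A1 3:A2", ""),
    list(41L, "the N that the N V V the N .", "1:O1 1:A2 2:A1 3:O2", ""),
    list(42L, "the N that the N V was V by the N .",
         "1:O1 1:O2 2:A1 3:A2", "*"),
    list(43L, "the N V the N that the N V .", "1:A1 2:O1 2:O2 3:A2", "*"),
    list(44L, "the N that the N V V the N to the N .",
         "1:O1 1:A2 2:A1 3:O2 4:R2", "*")
  )
  cons <- lapply(spec, function(e) {
    toks <- strsplit(e[[2]], " ", fixed = TRUE)[[1]]
    terms <- strsplit(e[[3]], " ", fixed = TRUE)[[1]]
    mm <- do.call(rbind, lapply(terms, function(tm) {
      parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
      data.frame(sw = as.integer(parts[1]),
                 clause = paste0("v", substr(parts[2], 2, 2)),
                 role = substr(parts[2], 1, 1),
                 stringsAsFactors = FALSE)
    }))
    construction(toks, mm, meta = list(
      index = e[[1]],
      n_sw = sum(toks == "N"),
      clauses = paste0("v", seq_len(sum(toks == "V"))),
      discourse = e[[4]] == "d",
      star = e[[4]] == "*",
      group = NA_integer_
    ))
  })
  corpus(cons, scheme_id = "basic45", provenance = "generated")
}

#' Sub-corpora of the 45-construction fixture
#'
#' Convenience selectors for the experiment protocols: `"core26"` is
#' constructions 15-40 (basic comprehension and leave-one-out), `"p600_full"`
#' is 15-44 (core plus the four object-relatives), `"p600_biased"` is 15-41
#' minus the flagged constructions (subject-relatives more frequent than
#' object-relatives, one object-relative kept), `"discourse"` is the ten
#' two-sentence segments, and `"all"` the full fixture.
#'
#' @param which One of `"all"`, `"core26"`, `"p600_full"`, `"p600_biased"`,
#'   `"discourse"`.
#' @return An `esn_corpus`.
#' @export
fixture_subset <- function(which = c("all", "core26", "p600_full",
                                     "p600_biased", "discourse")) {
  which <- match.arg(which)
  fx <- build_fixture_corpus_45()
  idx <- vapply(fx, function(cc) cc$meta$index, integer(1))
  star <- vapply(fx, function(cc) cc$meta$star, logical(1))
  keep <- switch(which,
    all = rep(TRUE, length(fx)),
    core26 = idx >= 15 & idx <= 40,
    p600_full = idx >= 15 & idx <= 44,
    p600_biased = idx >= 15 & idx <= 41 & !star,
    discourse = vapply(fx, function(cc) cc$meta$discourse, logical(1))
  )
  fx[keep]
}
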