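test_that("grammar enumeration matches the independent permutation oracle", {
  co <- corpus_462()
  expect_length(co, 462)
  expect_equal(length(co), oracle_grammar_count())
  # relative clauses disabled: 2 + 6 + 24 = 32
  no_rel <- enumerate_constructions(grammar_spec(relative_arities = 0))
  expect_length(no_rel, 32)
  expect_equal(length(no_rel), oracle_grammar_count(with_relative = FALSE))
  # single-argument main clause only: orders AP and PA
  tiny <- enumerate_constructions(
    grammar_spec(main_arities = 1, relative_arities = 0))
  expect_length(tiny, 2)
  expect_setequal(vapply(tiny, function(cc) cc$meta$order, character(1)),
                  c("AP", "PA"))
  # deterministic output order
  expect_identical(surface_forms(co),
                   surface_forms(enumerate_constructions(grammar_spec())))
})

test_that("462 corpus surfaces and meanings are pairwise unique", {
  co <- corpus_462()
  expect_false(anyDuplicated(surface_forms(co)) > 0)
  keys <- vapply(co, esnparse:::meaning_key, character(1))
  expect_false(anyDuplicated(keys) > 0)
  # max sentence length bounds the continuous design-matrix size
  expect_lte(max(vapply(co, function(cc) length(cc$tokens), integer(1))), 19)
})

test_that("coded meanings are derived positionally", {
  co <- corpus_462()
  orders <- vapply(co, function(cc) cc$meta$order, character(1))
  rels <- vapply(co, function(cc) cc$meta$rel_pattern, character(1))
  # passive main clause, surface order O-P-A
  opa <- co[[which(orders == "OPA" & rels == "")[1]]]
  expect_equal(opa$meaning[order(opa$meaning$sw), "role"], c("O", "P", "A"))
  expect_true(all(opa$meaning$clause == "main"))
  # fronted-participial arity-1 with a 1-argument subject relative:
  # 3 semantic words, 2 clauses, 6 relevant mappings, head noun Agent twice
  pa_rel <- co[[which(orders == "PA" & rels == "A:P")[1]]]
  expect_equal(pa_rel$meta$n_sw * length(pa_rel$meta$clauses), 6)
  head_rows <- pa_rel$meaning[pa_rel$meaning$sw == 2, ]
  expect_setequal(head_rows$clause, c("main", "relative"))
  expect_true(all(head_rows$role == "A"))
  # arity-1 order AP, no relative
  ap <- co[[which(orders == "AP" & rels == "")[1]]]
  expect_equal(ap$meaning$role[order(ap$meaning$sw)], c("A", "P"))
  # a relative head noun always carries exactly two assignments
  with_rel <- co[vapply(co, function(cc) cc$meta$attach > 0, logical(1))]
  for (cc in with_rel[seq(1, length(with_rel), by = 37)]) {
    expect_equal(sum(table(cc$meaning$sw) == 2), 1)
  }
})

test_that("missing rendering template raises a configuration error naming the label", {
  expect_error(esnparse:::relative_template("O:XY"), "O:XY")
})

test_that("scrambling permutes tokens, keeps meanings, and is seed-deterministic", {
  co <- corpus_462()
  sc1 <- scramble_corpus(co, seed = 7)
  sc2 <- scramble_corpus(co, seed = 7)
  sc3 <- scramble_corpus(co, seed = 8)
  expect_identical(surface_forms(sc1), surface_forms(sc2))
  expect_false(identical(surface_forms(sc1), surface_forms(sc3)))
  expect_identical(attr(sc1, "provenance"), "scrambled")
  for (i in c(1, 100, 462)) {
    expect_identical(sort(sc1[[i]]$tokens), sort(co[[i]]$tokens))
    expect_identical(sc1[[i]]$tokens[length(sc1[[i]]$tokens)], ".")
    expect_identical(sc1[[i]]$meaning, co[[i]]$meaning)
  }
  expect_length(sc1, length(co))
})

test_that("modifier augmentation multiplies size and preserves meanings", {
  co <- corpus_462()
  aug <- augment_with_modifiers(co, n_variants = 5, seed = 3)
  expect_length(aug, 2772) # 462 * 6
  groups <- vapply(aug, function(cc) cc$meta$group, integer(1))
  expect_equal(length(unique(groups)), 462)
  expect_true(all(table(groups) == 6))
  # variants decode to the same gold meaning as their source and only
  # insert ADJ immediately before SW markers
  for (g in c(1, 200)) {
    members <- which(groups == g)
    src <- aug[[members[1]]]
    for (j in members[-1]) {
      v <- aug[[j]]
      expect_identical(v$meaning, src$meaning)
      expect_identical(v$tokens[v$tokens != "ADJ"], src$tokens)
      adj_pos <- which(v$tokens == "ADJ")
      expect_true(all(v$tokens[adj_pos + 1L] %in% c("SW", "ADJ")))
    }
  }
  # identity case
  aug0 <- augment_with_modifiers(co, n_variants = 0, seed = 3)
  expect_length(aug0, 462)
  expect_identical(surface_forms(aug0), surface_forms(co))
  expect_error(augment_with_modifiers(co, n_variants = -1), "n_variants")
  expect_error(augment_with_modifiers(build_fixture_corpus_45(), 2, 1),
               "modifier")
})

test_that("corpus statistics report mappings, ambiguity and redundancy", {
  st <- corpus_stats(corpus_462())
  expect_equal(st$n, 462)
  expect_equal(st$ambiguous_count, 0)
  # 88% of sentences have 10 or 12 relevant mappings
  frac <- sum(st$relevant_mapping_dist[c("10", "12")]) / st$n
  expect_equal(frac, 0.88, tolerance = 0.01)
})

test_that("corpus io round-trips and validates", {
  co <- corpus_462()[c(1:5, 200:205, 460:462)]
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus(co, path)
  back <- read_corpus(path)
  expect_identical(attr(back, "provenance"), "loaded")
  expect_identical(surface_forms(back), surface_forms(co))
  for (i in seq_along(co)) {
    expect_identical(back[[i]]$meaning, co[[i]]$meaning)
    expect_identical(back[[i]]$meta$order, co[[i]]$meta$order)
  }
  # unknown token symbol named in the error, with its line number
  lines <- readLines(path)
  bad <- sub("\"SW\"", "\"XYZZY\"", lines[4], fixed = TRUE)
  writeLines(c(lines[1:3], bad, lines[5:length(lines)]), path)
  expect_error(read_corpus(path), "XYZZY")
  expect_error(read_corpus(path), "line 4")
  # malformed record -> parse error with line number
  writeLines(c(lines[1:2], "{not json", lines[4:length(lines)]), path)
  expect_error(read_corpus(path), "line 3")
})

test_that("the 45-construction fixture has the documented structure", {
  fx <- build_fixture_corpus_45()
  expect_length(fx, 45)
  expect_false(anyDuplicated(surface_forms(fx)) > 0)
  sf <- surface_forms(fx)
  # printed anchor surface forms
  expect_true("the N V the N that was V by the N ." %in% sf)
  expect_true("the N V the N to the N ." %in% sf)
  pv <- fx[[which(sf == "the N was V by the N .")]]
  expect_equal(pv$meaning$role[pv$meaning$sw == 1], "O")
  expect_equal(pv$meaning$role[pv$meaning$sw == 2], "A")
  # removable constructions (object-relatives, relative-passives) flagged
  stars <- which(vapply(fx, function(cc) cc$meta$star, logical(1)))
  expect_gt(length(stars), 3)
  expect_true(all(grepl("that the N V|that was V", sf[stars])))
  # ten two-sentence discourse segments with the pronoun design
  seg <- fixture_subset("discourse")
  expect_length(seg, 10)
  for (cc in seg) {
    expect_equal(sum(cc$tokens == "."), 2)
    expect_true(any(cc$tokens %in% c("he", "him")))
    expect_true("it" %in% cc$tokens)
  }
  expect_length(fixture_subset("core26"), 26)
  # biased corpus: subject-relatives outnumber object-relatives (one kept)
  biased <- fixture_subset("p600_biased")
  bs <- surface_forms(biased)
  expect_equal(sum(grepl("that the N V", bs)), 1)
  expect_gt(sum(grepl("that V", bs)), 3)
})

test_that("extended grammar exposes redundancy, ambiguity and incomplete meanings", {
  ex <- enumerate_extended()
  # agentless passives exist and their meanings have no Agent
  inc <- ex[vapply(ex, function(cc) cc$meta$order == "OP", logical(1))]
  expect_gt(length(inc), 0)
  for (cc in inc) {
    expect_false("A" %in% cc$meaning$role[cc$meaning$clause == "main"])
  }
  # redundancy: groups with several members share one coded meaning
  groups <- vapply(ex, function(cc) cc$meta$group, integer(1))
  g <- as.integer(names(which(table(groups) > 2))[1])
  members <- which(groups == g)
  keys <- vapply(ex[members], esnparse:::meaning_key, character(1))
  expect_equal(length(unique(keys)), 1)
  expect_gt(length(unique(surface_forms(ex[members]))), 1)
  # constructions with identical surface but different meanings are flagged
  amb_pair <- corpus(list(
    construction(c("the", "SW", "SW", "-s", "."),
                 data.frame(sw = 1:2, clause = "main", role = c("A", "P")),
                 meta = list(n_sw = 2, clauses = "main")),
    construction(c("the", "SW", "SW", "-s", "."),
                 data.frame(sw = 1:2, clause = "main", role = c("O", "P")),
                 meta = list(n_sw = 2, clauses = "main"))), "ext90k")
  expect_equal(corpus_stats(amb_pair)$ambiguous_count, 2)
  # degenerate configuration: no redundancy options, complete meanings only
  plain <- enumerate_extended(proper_nouns = FALSE, who_that = FALSE,
                              by_position = FALSE, reduced_relatives = FALSE,
                              incomplete_meanings = FALSE)
  keys <- vapply(plain, esnparse:::meaning_key, character(1))
  expect_false(anyDuplicated(keys) > 0)
  expect_equal(corpus_stats(plain)$ambiguous_count, 0)
})
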