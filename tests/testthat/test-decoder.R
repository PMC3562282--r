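test_that("word-level decoding thresholds at 0 then takes the winner", {
  sc <- coding_scheme("ext462")
  roles <- sc$clause_roles$main
  y <- rep(-1, 42)
  set_roles <- function(y, sw, clause, vals) {
    for (i in seq_along(vals)) {
      y[readout_index(sw, clause, sc$clause_roles[[clause]][i], sc)] <- vals[i]
    }
    y
  }
  y1 <- set_roles(y, 2, "main", c(0.8, 0.3, -0.2, -0.9))
  expect_equal(decode_word_meaning(y1, sc, 2, "main"), "P")
  # all activities negative -> none
  y2 <- set_roles(y, 2, "main", c(-0.1, -0.5, -0.2, -0.9))
  expect_true(is.na(decode_word_meaning(y2, sc, 2, "main")))
  # exact tie on the positive maximum: earliest role (P < A < O < R) wins
  y3 <- set_roles(y, 2, "main", c(0.4, 0.4, 0.1, -0.9))
  expect_equal(decode_word_meaning(y3, sc, 2, "main"), "P")
  # brute-force oracle agreement on random snapshots
  set.seed(99)
  for (rep in 1:50) {
    vals <- round(runif(4, -1, 1), 2)
    yr <- set_roles(y, 3, "main", vals)
    expect_identical(decode_word_meaning(yr, sc, 3, "main"),
                     oracle_wta(vals, roles))
  }
  # relative-clause pool has only 3 roles (no Recipient)
  y4 <- set_roles(y, 1, "relative", c(-0.2, -0.1, 0.05))
  expect_equal(decode_word_meaning(y4, sc, 1, "relative"), "O")
})

test_that("relevant mappings are semantic words x clauses present", {
  co <- corpus_462()
  orders <- vapply(co, function(cc) cc$meta$order, character(1))
  rels <- vapply(co, function(cc) cc$meta$rel_pattern, character(1))
  # 3 semantic words, main + relative -> 6 mappings
  cc6 <- co[[which(orders == "PA" & rels == "A:P")[1]]]
  expect_equal(nrow(relevant_mappings(cc6)), 6)
  # 2 semantic words, main only -> 2 mappings
  cc2 <- co[[which(orders == "AP" & rels == "")[1]]]
  m2 <- relevant_mappings(cc2)
  expect_equal(nrow(m2), 2)
  expect_false(anyNA(m2$gold))
  # unassigned pairs have gold = none
  m6 <- relevant_mappings(cc6)
  expect_true(anyNA(m6$gold))
  # corpus-wide distribution: 88% of sentences have 10 or 12 mappings
  counts <- vapply(co, function(cc) nrow(relevant_mappings(cc)), integer(1))
  expect_equal(mean(counts %in% c(10, 12)), 0.88, tolerance = 0.01)
})

test_that("error measures follow the worked example and aggregation rules", {
  sc <- coding_scheme("ext462")
  co <- corpus_462()
  ap <- co[[which(vapply(co, function(cc) cc$meta$order, character(1)) == "AP"
                  & vapply(co, function(cc) cc$meta$rel_pattern,
                           character(1)) == "")[1]]]
  # one 2-SW sentence with one wrong mapping: meaning 0.5, sentence 1.0
  y <- target_row <- esnparse:::target_vector(ap$meaning, sc)
  y[readout_index(1, "main", "A", sc)] <- -1 # flip SW1's decoded role to none
  rep1 <- esnparse:::score_outputs(matrix(y, 1), corpus(list(ap), "ext462"), sc)
  expect_equal(rep1$meaning_error, 0.5)
  expect_equal(rep1$sentence_error, 1)
  # all mappings correct -> (0, 0)
  rep0 <- esnparse:::score_outputs(matrix(target_row, 1),
                                   corpus(list(ap), "ext462"), sc)
  expect_equal(rep0$meaning_error, 0)
  expect_equal(rep0$sentence_error, 0)
  # concentration: equal meaning error, 10x different sentence error
  ten <- corpus(rep(list(ap), 10), "ext462")
  Y_conc <- matrix(rep(target_row, each = 10), 10, 42)
  bad_row <- target_row
  bad_row[readout_index(1, "main", "A", sc)] <- -1
  bad_row[readout_index(2, "main", "P", sc)] <- -1
  Y_spread <- Y_conc
  Y_spread[, readout_index(1, "main", "A", sc)] <- -1 # one wrong per sentence
  Y_conc2 <- Y_conc
  Y_conc2[1, ] <- bad_row # two wrong mappings concentrated in one sentence
  Y_spread2 <- Y_conc
  Y_spread2[1:2, readout_index(1, "main", "A", sc)] <- -1
  rep_conc <- esnparse:::score_outputs(Y_conc2, ten, sc)
  rep_spread <- esnparse:::score_outputs(Y_spread2, ten, sc)
  expect_equal(rep_conc$meaning_error, rep_spread$meaning_error)
  expect_equal(rep_spread$sentence_error, 2 * rep_conc$sentence_error)
})

test_that("decoding a teacher vector returns the gold meaning exactly", {
  # encoder/decoder consistency across schemes and constructions
  sc <- coding_scheme("ext462")
  co <- corpus_462()
  for (i in seq(1, 462, by = 23)) {
    cc <- co[[i]]
    y <- esnparse:::target_vector(cc$meaning, sc)
    chk <- esnparse:::score_snapshot(y, cc, sc)
    expect_equal(unname(chk["wrong"]), 0)
  }
  fx <- build_fixture_corpus_45()
  sb <- coding_scheme("basic45")
  for (i in seq(1, 45, by = 7)) {
    y <- esnparse:::target_vector(fx[[i]]$meaning, sb)
    expect_equal(unname(esnparse:::score_snapshot(y, fx[[i]], sb)["wrong"]), 0)
  }
})

test_that("evaluation is invariant to corpus ordering", {
  core <- fixture_subset("core26")
  m <- train_readout(core[1:20], reservoir_params(N = 80, seed = 2))
  test_set <- core[21:26]
  r1 <- evaluate_corpus(m, test_set)
  r2 <- evaluate_corpus(m, test_set[6:1])
  expect_equal(r1$meaning_error, r2$meaning_error)
  expect_equal(r1$sentence_error, r2$sentence_error)
})

test_that("neuron-level measures count thresholded sign mismatches", {
  core <- fixture_subset("core26")
  m <- train_readout(core[1:20], reservoir_params(N = 80, seed = 2))
  rep <- evaluate_neurons(m, core[21:26])
  expect_true(rep$meaning_error >= 0 && rep$meaning_error <= 1)
  expect_gte(rep$sentence_error, rep$meaning_error)
  # perfect on the training set at this size
  rep_tr <- evaluate_neurons(m, core[1:20])
  expect_equal(rep_tr$meaning_error, 0)
})
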