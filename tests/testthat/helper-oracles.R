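# Independent oracles and small shared fixtures for the test suite.
# These deliberately avoid the package's own code paths.

# Exhaustive permutation oracle, independent of the package's recursive
# generator: enumerate every index tuple in {1..n}^n and keep the ones that
# visit each index exactly once.
oracle_permutations <- function(x) {
  n <- length(x)
  tuples <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  perms <- tuples[apply(tuples, 1, function(r) length(unique(r)) == n), ,
                  drop = FALSE]
  lapply(seq_len(nrow(perms)), function(i) x[perms[i, ]])
}

# Independent count of the construction grammar: for each main arity the
# number of clause-element permutations, each combined with "no relative"
# plus (number of nouns) x (number of relative patterns) insertions.
oracle_grammar_count <- function(arities = 1:3, n_rel_patterns = 5,
                                 with_relative = TRUE) {
  total <- 0
  for (a in arities) {
    n_orders <- length(unique(vapply(
      oracle_permutations(c("P", c("A", "O", "R")[seq_len(a)])),
      paste, character(1), collapse = "")))
    total <- total + n_orders *
      (1 + if (with_relative) a * n_rel_patterns else 0)
  }
  total
}

# Stable argmax with threshold: brute-force reference for WTA decoding.
oracle_wta <- function(vals, roles) {
  keep <- which(vals > 0)
  if (!length(keep)) return(NA_character_)
  best <- keep[1]
  for (i in keep) if (vals[i] > vals[best]) best <- i
  roles[best]
}

# Small standard objects used across tests.
small_params <- function(N = 60, seed = 1, ...) {
  reservoir_params(N = N, seed = seed, ...)
}

corpus_462 <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- enumerate_constructions(grammar_spec())
    val
  }
})
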