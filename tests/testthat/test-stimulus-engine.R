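test_that("backward reverses word order and is an involution", {
  s <- mini_sentence(c("the", "cat", "slept"))
  expect_equal(backward(s)$tokens, c("slept", "cat", "the"))
  expect_equal(backward(mini_sentence("apple"))$tokens, "apple")
  # involution on random sentences
  ss <- gen_base_sentences(5, 12, seed = 11)
  for (x in ss) {
    expect_identical(backward(backward(x))$tokens, surfaces(x))
  }
})

test_that("scramble_local applies exactly k adjacent transpositions", {
  lex <- mini_lexicon()
  s3 <- annotate("messages and gifts", lex)
  # k = 1: output is one adjacent transposition of the input
  outs <- vapply(1:30, function(seed)
    paste(scramble_local(s3, 1L, seed)$tokens, collapse = " "), character(1))
  expect_true(all(outs %in% reachable_by_k_swaps(surfaces(s3), 1L)))
  expect_true("and messages gifts" %in% outs)  # the position-1 swap
  # brute-force reachability for lengths <= 6, k <= 3
  s6 <- annotate(c("the", "cat", "saw", "a", "big", "dog"), lex)
  for (k in 1:3) {
    reach <- reachable_by_k_swaps(surfaces(s6), k)
    outs <- vapply(1:25, function(seed)
      paste(scramble_local(s6, k, seed)$tokens, collapse = " "), character(1))
    expect_true(all(outs %in% reach))
  }
  # multiset conservation and determinism
  v1 <- scramble_local(s6, 3L, seed = 99)
  v2 <- scramble_local(s6, 3L, seed = 99)
  expect_identical(v1$tokens, v2$tokens)
  expect_equal(sort(v1$tokens), sort(surfaces(s6)))
  expect_length(v1$provenance$swaps, 3L)
})

test_that("scramble_local rejects invalid swap counts", {
  s <- mini_sentence(c("the", "cat"))
  expect_error(scramble_local(s, 2L, 1), "less than")
  expect_error(scramble_local(mini_sentence("cat"), 1L, 1), "at least 2")
})

test_that("scramble_low_pmi separates proximal content words", {
  lex <- mini_lexicon()
  # content words adjacent at positions 2,3: exhaustive search must reach 0
  s <- annotate(c("the", "cat", "dog", "a", "the", "in"), lex)
  v <- scramble_low_pmi(s, seed = 7)
  expect_equal(v$provenance$objective, 0L)
  pos <- match(c("cat", "dog"), v$tokens)
  expect_gt(abs(pos[1] - pos[2]), 3)
  expect_equal(sort(v$tokens), sort(surfaces(s)))
  # already-distant content words: identity is optimal, objective 0
  s2 <- annotate(c("cat", "the", "a", "the", "a", "dog"), lex)
  expect_equal(scramble_low_pmi(s2, seed = 1)$provenance$objective, 0L)
  # returned objective never exceeds the identity objective (any seed)
  ss <- gen_base_sentences(4, 12, seed = 21)
  for (i in seq_along(ss)) {
    v <- scramble_low_pmi(ss[[i]], seed = i, n_restarts = 3L)
    expect_lte(v$provenance$objective, v$provenance$identity_objective)
  }
  expect_error(scramble_low_pmi(mini_sentence(c("the", "cat")), 1),
               "at least 2 content")
})

test_that("make_nonsense replaces content words within their feature key", {
  ss <- gen_base_sentences(8, 12, seed = 31)
  dict <- build_replacement_dictionary(ss)
  s <- ss[[1]]
  v <- make_nonsense(s, dict, seed = 13)
  expect_length(v$tokens, length(s))
  fn <- !s$tokens$is_content
  expect_identical(v$tokens[fn], surfaces(s)[fn])
  # every replacement is drawn from the exact candidate multiset of its key
  for (sub in v$provenance$substitutions) {
    key <- token_keys_for_test(s, sub$position)
    expect_true(sub$replacement %in% dict$entries[[key]])
  }
  # determinism
  expect_identical(make_nonsense(s, dict, seed = 13)$tokens, v$tokens)
})

test_that("make_nonsense handles degenerate dictionaries", {
  lex <- mini_lexicon()
  # zero content words: output identical
  s <- annotate(c("the", "a", "and", "in"), lex)
  suppressWarnings(d0 <- build_replacement_dictionary(list(
    mini_sentence("the cat slept"))))
  expect_identical(make_nonsense(s, d0, seed = 1)$tokens, surfaces(s))
  # single-candidate key: replacement equals the original (self-replacement)
  s1 <- mini_sentence("the apple slept")
  d1 <- build_replacement_dictionary(list(s1))
  v <- make_nonsense(s1, d1, seed = 1)
  expect_identical(v$tokens, surfaces(s1))
})

test_that("make_jabberwocky preserves skeleton, suffix and avoids real words", {
  lex <- mini_lexicon()
  s <- annotate(c("the", "cats", "slept", "quietly"), lex)
  v <- make_jabberwocky(s, lex$surface, seed = 3)
  expect_identical(v$tokens[1], "the")
  nw <- v$tokens[2]  # replacement for "cats"
  expect_equal(nchar(nw), 4L)
  expect_true(endsWith(nw, "s"))
  vow <- function(w) strsplit(w, "")[[1]] %in% c("a", "e", "i", "o", "u")
  expect_equal(vow(nw), vow("cats"))  # CVCC skeleton
  expect_false(any(v$tokens[c(2, 3, 4)] %in% lex$surface))
  # function-word-only sentence unchanged
  sf <- annotate(c("the", "a", "in"), lex)
  expect_identical(make_jabberwocky(sf, lex$surface, seed = 1)$tokens,
                   surfaces(sf))
  # outputs over many seeds stay off the blocklist
  for (seed in 1:10) {
    vv <- make_jabberwocky(s, lex$surface, seed = seed)
    expect_false(any(vv$tokens[s$tokens$is_content] %in% lex$surface))
  }
})

test_that("recombine_lists conserves the pooled token multiset", {
  lex <- mini_lexicon()
  pool <- list(annotate(c("the", "cat"), lex), annotate(c("a", "dog"), lex))
  out <- recombine_lists(pool, 2L, 2L, seed = 5)
  expect_length(out, 2L)
  expect_true(all(lengths(lapply(out, surfaces)) == 2L))
  expect_equal(sort(unlist(lapply(out, surfaces))),
               sort(c("the", "cat", "a", "dog")))
  expect_error(recombine_lists(list(c("a", "b", "c", "d", "e")), 2L, 2L, 1),
               "expected 4")
})

test_that("stimulus TSV round-trips conditions, tokens and provenance", {
  ss <- gen_base_sentences(2, 12, seed = 41)
  stim <- list(intact(ss[[1]]), backward(ss[[1]]),
               scramble_local(ss[[2]], 3L, seed = 8))
  p <- tempfile(fileext = ".tsv")
  on.exit(unlink(p))
  write_stimuli_tsv(stim, p)
  back <- read_stimuli_tsv(p)
  expect_equal(vapply(back, `[[`, character(1), "condition"),
               c("Intact", "Backward", "Scrambled3"))
  for (i in seq_along(stim)) expect_identical(back[[i]]$tokens, stim[[i]]$tokens)
  expect_length(back[[3]]$provenance$swaps, 3L)
})
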