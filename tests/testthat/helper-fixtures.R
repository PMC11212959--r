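# Shared fixtures: small grammars with enumerable languages (the
# enumeration path is the independent oracle for the chart algorithms) and
# a hand-built mini lexicon for stimulus tests.

# Deterministic two-word grammar.
fixture_g_det <- function() {
  pcfg(tibble::tibble(
    lhs = "S", rhs = list(c("a", "b")), prob = 1
  ))
}

# Two-way branch after a shared first word.
fixture_g_branch <- function() {
  pcfg(tibble::tibble(
    lhs = c("S", "S"),
    rhs = list(c("a", "b"), c("a", "c")),
    prob = c(0.5, 0.5)
  ))
}

# Nonterminal children + shared left corner (stresses the closure).
fixture_g_lc <- function() {
  pcfg(tibble::tibble(
    lhs = c("S", "S", "A", "B", "C"),
    rhs = list(c("A", "B"), c("A", "C"), "a", "b", "c"),
    prob = c(0.5, 0.5, 1, 1, 1)
  ))
}

# Unit chains, ternary rules, and lexical ambiguity.
fixture_g_np <- function() {
  pcfg(tibble::tibble(
    lhs = c("S", "NP", "NP", "VP", "VP", "Det", "N", "N", "Adj", "V", "V"),
    rhs = list(c("NP", "VP"), c("Det", "N"), c("Det", "Adj", "N"),
               c("V", "NP"), "V", "the", "cat", "dog", "big", "saw", "slept"),
    prob = c(1, 0.5, 0.5, 0.6, 0.4, 1, 0.6, 0.4, 1, 0.7, 0.3)
  ))
}

fixture_grammars <- function() {
  list(det = fixture_g_det(), branch = fixture_g_branch(),
       lc = fixture_g_lc(), np = fixture_g_np())
}

# Independent oracle: prefix probability by summing enumerated sentence
# probabilities over sentences extending the prefix.
oracle_prefix <- function(lang, prefix) {
  pat <- paste0(paste(prefix, collapse = " "), " ")
  sum(lang$prob[startsWith(paste0(lang$sentence, " "), pat)])
}

# Mini lexicon for stimulus-engine tests.
mini_lexicon <- function() {
  lexicon(
    surface = c("the", "a", "and", "in", "cat", "cats", "dog", "gifts",
                "messages", "apple", "slept", "saw", "big", "quietly"),
    pos = c("DET", "DET", "CCONJ", "ADP", "NOUN", "NOUN", "NOUN", "NOUN",
            "NOUN", "NOUN", "VERB", "VERB", "ADJ", "ADV"),
    dep = c("det", "det", "cc", "case", "arg", "arg", "arg", "arg",
            "arg", "arg", "root", "root", "amod", "advmod"),
    morph = c("Definite=Def", "Definite=Ind", "_", "_", "Number=Sing",
              "Number=Plur", "Number=Sing", "Number=Plur", "Number=Plur",
              "Number=Sing", "Tense=Past", "Tense=Past", "Degree=Pos", "_"),
    valence = c(NA, NA, NA, NA, NA, NA, NA, NA, NA, NA,
                "intransitive", "transitive", NA, NA)
  )
}

mini_sentence <- function(words, id = "t1") annotate(words, mini_lexicon(), id)

# Full feature key of token i of a sentence (via the exported constructor).
token_keys_for_test <- function(s, i) {
  t <- s$tokens[i, ]
  feature_key(t$pos, t$dep, t$morph, t$valence, t$onset)
}

# All strings reachable from `tokens` by exactly k adjacent transpositions
# (BFS over swap sequences; cancellation allowed).
reachable_by_k_swaps <- function(tokens, k) {
  frontier <- list(tokens)
  key <- function(w) paste(w, collapse = " ")
  for (step in seq_len(k)) {
    nxt <- list()
    seen <- character(0)
    for (w in frontier) {
      for (i in seq_len(length(w) - 1L)) {
        v <- w
        v[c(i, i + 1L)] <- v[c(i + 1L, i)]
        kk <- key(v)
        if (!(kk %in% seen)) {
          seen <- c(seen, kk)
          nxt[[length(nxt) + 1L]] <- v
        }
      }
    }
    frontier <- nxt
  }
  unique(vapply(frontier, key, character(1)))
}
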