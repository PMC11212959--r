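# Condition generators: local scrambles, low-combinability scrambles,
# backward reversal, nonsense and jabberwocky substitution, list recombination.

STIMULUS_CONDITIONS <- c(
  "Intact", "Scrambled1", "Scrambled3", "Scrambled5", "Scrambled7",
  "Scrambled_LowPMI", "Backward", "Nonsense", "Jabberwocky",
  "WordList", "NonwordList"
)

new_variant <- function(item_id, condition, tokens, provenance = list(),
                        seed = NA_integer_) {
  structure(
    list(item_id = item_id, condition = condition,
         tokens = as.character(tokens), provenance = provenance, seed = seed),
    class = "stimulus_variant"
  )
}

#' @export
print.stimulus_variant <- function(x, ...) {
  cat("<stimulus_variant ", x$condition, "> ",
      paste(x$tokens, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @export
length.stimulus_variant <- function(x) length(x$tokens)

#' Intact condition (identity)
#'
#' @param s an `annotated_sentence`.
#' @return A `stimulus_variant` with condition `"Intact"`.
#' @export
intact <- function(s) {
  new_variant(s$item_id, "Intact", surfaces(s),
              provenance = list(map = seq_along(surfaces(s))))
}

#' Backward condition: full word-order reversal
#'
#' Reverses the word order of the sentence. Reversal preserves which words
#' co-occur within any local window, so window-based combinability scores
#' are untouched while the word-order cues a parser relies on are destroyed.
#'
#' @param s an `annotated_sentence` (or `stimulus_variant`).
#' @return A `stimulus_variant` with condition `"Backward"`.
#' @export
backward <- function(s) {
  w <- surfaces(s)
  n <- length(w)
  id <- if (inherits(s, "annotated_sentence")) s$item_id else s$item_id
  new_variant(id, "Backward", rev(w), provenance = list(map = rev(seq_len(n))))
}

#' Locally scrambled conditions (Scrambled k)
#'
#' Applies `k` adjacent transpositions: `k` word positions are sampled
#' without replacement, and each selected position is swapped, in sampled
#' order on the evolving string, with a uniformly chosen existing immediate
#' neighbor (edge positions have only one). Swaps may cancel; the result is
#' always reachable from the input by exactly `k` adjacent transpositions.
#'
#' @param s an `annotated_sentence`.
#' @param k number of swaps (the experiment uses 1, 3, 5, or 7); must be
#'   less than the sentence length.
#' @param seed integer seed; the draw is fully determined by it.
#' @return A `stimulus_variant` with condition `"Scrambled<k>"`; its
#'   provenance records each `(position, direction)` swap in order.
#' @export
scramble_local <- function(s, k, seed) {
  w <- surfaces(s)
  n <- length(w)
  if (n < 2L) stop("sentence must have at least 2 words to scramble")
  if (k >= n) stop("swap count k (", k, ") must be less than sentence length (",
                   n, ")")
  if (k == 0L) return(new_variant(s$item_id, "Scrambled0", w,
                                  provenance = list(swaps = list()), seed = seed))
  with_seed(seed, {
    pos <- sample.int(n, k)
    swaps <- vector("list", k)
    for (m in seq_len(k)) {
      i <- pos[m]
      dir <- if (i == 1L) 1L else if (i == n) -1L
             else sample(c(-1L, 1L), 1L)
      j <- i + dir
      tmp <- w[i]; w[i] <- w[j]; w[j] <- tmp
      swaps[[m]] <- list(position = i, direction = dir)
    }
    new_variant(s$item_id, paste0("Scrambled", k), w,
                provenance = list(swaps = swaps), seed = seed)
  })
}

# Objective of the low-combinability scramble: among content-word pairs that
# sit within the 4-word window (distance <= window) of the ORIGINAL order,
# how many are still within that window after permuting? Lower is better.
low_pmi_objective <- function(perm, content_pos, window = 3L) {
  if (length(content_pos) < 2L) return(0L)
  inv <- integer(length(perm))
  inv[perm] <- seq_along(perm)   # inv[orig position] = new position
  pr <- utils::combn(content_pos, 2L)
  orig_close <- (pr[2L, ] - pr[1L, ]) <= window
  if (!any(orig_close)) return(0L)
  new_d <- abs(inv[pr[1L, orig_close]] - inv[pr[2L, orig_close]])
  sum(new_d <= window)
}

#' Low-combinability scramble (Scrambled_LowPMI)
#'
#' Permutes the whole string so that content words that are proximal in the
#' original sentence end up far apart, destroying the local dependencies a
#' window-based combinability measure would pick up. The objective counts
#' content-word pairs within window distance (default 3, the sliding
#' four-word window) in *both* the original and permuted orders; it is
#' minimized exhaustively for sentences of up to 8 words, and by seeded
#' hill-climbing with random restarts otherwise. The identity permutation is
#' always a candidate, so the returned objective never exceeds the identity's.
#'
#' @param s an `annotated_sentence` with at least 2 content words.
#' @param seed integer seed.
#' @param n_restarts hill-climbing restarts (ignored on the exhaustive path).
#' @param window window distance defining "proximal" (default 3).
#' @return A `stimulus_variant`, condition `"Scrambled_LowPMI"`; provenance
#'   holds the permutation `map` and the achieved and identity `objective`s.
#' @export
scramble_low_pmi <- function(s, seed, n_restarts = 10L, window = 3L) {
  w <- surfaces(s)
  n <- length(w)
  content_pos <- which(s$tokens$is_content)
  if (length(content_pos) < 2L) {
    stop("need at least 2 content words for a low-combinability scramble")
  }
  obj <- function(p) low_pmi_objective(p, content_pos, window)
  identity_obj <- obj(seq_len(n))

  best <- with_seed(seed, {
    if (n <= 8L) {
      perms <- all_permutations(n)
      vals <- vapply(perms, obj, integer(1))
      perms[[which.min(vals)]]
    } else {
      best_p <- seq_len(n)
      best_v <- identity_obj
      for (r in seq_len(n_restarts)) {
        p <- sample.int(n)
        v <- obj(p)
        repeat {
          improved <- FALSE
          for (a in seq_len(n - 1L)) for (b in seq(a + 1L, n)) {
            q <- p; q[c(a, b)] <- q[c(b, a)]
            vq <- obj(q)
            if (vq < v) { p <- q; v <- vq; improved <- TRUE }
          }
          if (!improved || v == 0L) break
        }
        if (v < best_v) { best_p <- p; best_v <- v }
        if (best_v == 0L) break
      }
      best_p
    }
  })
  new_variant(
    s$item_id, "Scrambled_LowPMI", w[best],
    provenance = list(map = best, objective = obj(best),
                      identity_objective = identity_obj),
    seed = seed
  )
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) for (i in seq_len(n)) {
    k <- k + 1L
    out[[k]] <- append(p, n, after = i - 1L)
  }
  out
}

# Relaxation ladder for replacement-candidate lookup: progressively drop
# annotation slots until candidates are found, erroring only when matching
# at the bare-POS level fails.
RELAXATION_LADDER <- list(
  character(0),
  "dep",
  c("dep", "onset"),
  c("dep", "onset", "morph"),
  c("dep", "onset", "morph", "valence")
)

lookup_candidates <- function(tokens, i, dict_tokens) {
  for (drop in RELAXATION_LADDER) {
    key <- token_keys(tokens[i, , drop = FALSE], drop = drop)
    dk <- token_keys(dict_tokens, drop = drop)
    hit <- dict_tokens$surface[dk == key]
    if (length(hit) > 0L) return(list(candidates = hit, key = key))
  }
  NULL
}

#' Nonsense condition: feature-matched content-word substitution
#'
#' Replaces every content word with a word sampled from the replacement
#' dictionary under the same feature key (POS, dependency label, morphology,
#' verb valence, noun onset); function words stay in place, so the result is
#' grammatically parallel to the original but semantically implausible. When
#' a key has no candidate the match is relaxed in a fixed order (drop the
#' dependency label, then onset, then morphology, keeping POS and valence;
#' finally bare POS), erroring only if even POS-level matching fails.
#' Sampling the original word itself is permitted.
#'
#' @param s an `annotated_sentence`.
#' @param dict a `replacement_dictionary` built with
#'   [build_replacement_dictionary()].
#' @param seed integer seed.
#' @return A `stimulus_variant`, condition `"Nonsense"`; provenance records
#'   one `(position, original, replacement, key)` entry per substitution.
#' @export
make_nonsense <- function(s, dict, seed) {
  tokens <- s$tokens
  w <- tokens$surface
  # Reconstitute a token table view of the dictionary for relaxed matching.
  dict_tokens <- dictionary_token_table(dict)
  subs <- list()
  with_seed(seed, {
    for (i in which(tokens$is_content)) {
      found <- lookup_candidates(tokens, i, dict_tokens)
      if (is.null(found)) {
        stop("no replacement candidate for position ", i, " ('", w[i],
             "', key ", token_keys(tokens[i, , drop = FALSE]),
             ") even after relaxation")
      }
      repl <- found$candidates[sample.int(length(found$candidates), 1L)]
      subs[[length(subs) + 1L]] <- list(position = i, original = w[i],
                                        replacement = repl, key = found$key)
      w[i] <- repl
    }
  })
  new_variant(s$item_id, "Nonsense", w, provenance = list(substitutions = subs),
              seed = seed)
}

# The dictionary stores surfaces keyed by the full feature key; expand keys
# back into annotation columns so relaxed re-keying works.
dictionary_token_table <- function(dict) {
  if (!is.null(attr(dict, "token_table"))) return(attr(dict, "token_table"))
  keys <- rep(names(dict$entries), lengths(dict$entries))
  surf <- unlist(dict$entries, use.names = FALSE)
  f <- do.call(rbind, strsplit(keys, "\036", fixed = TRUE))
  unnorm <- function(x) ifelse(x == "-", NA_character_, x)
  tibble::tibble(
    surface = surf,
    pos = unnorm(f[, 1]), dep = unnorm(f[, 2]), morph = unnorm(f[, 3]),
    valence = unnorm(f[, 4]), onset = unnorm(f[, 5]),
    is_content = TRUE
  )
}

CONSONANTS <- setdiff(letters, VOWELS)
INFLECTIONAL_SUFFIXES <- c("ing", "est", "ed", "er", "s")

detect_suffix <- function(word) {
  for (suf in INFLECTIONAL_SUFFIXES) {
    if (nchar(word) > nchar(suf) + 1L && endsWith(word, suf)) return(suf)
  }
  ""
}

# One nonword attempt: resample each stem letter within its consonant/vowel
# class, keeping the detected inflectional suffix.
nonword_attempt <- function(word) {
  suf <- detect_suffix(word)
  stem <- substr(word, 1L, nchar(word) - nchar(suf))
  ch <- strsplit(stem, "", fixed = TRUE)[[1]]
  out <- vapply(ch, function(c) {
    if (c %in% VOWELS) sample(setdiff(VOWELS, c), 1L)
    else if (c %in% CONSONANTS) sample(setdiff(CONSONANTS, c), 1L)
    else c
  }, character(1))
  paste0(paste(out, collapse = ""), suf)
}

#' Jabberwocky condition: structure-preserving nonword substitution
#'
#' Replaces every content word with a pronounceable nonword that preserves
#' the word's length, consonant/vowel skeleton, and any detected
#' inflectional suffix (-s, -ed, -ing, -er, -est), so functional morphology
#' survives while lexical content is removed. Function words stay in place.
#' Candidates are rejected if they appear in the real-word blocklist (the
#' lexicon) or equal the original word. This is a deliberately simple
#' skeleton-preserving generator; syllable-transition frequencies are not
#' modeled.
#'
#' @param s an `annotated_sentence`.
#' @param blocklist character vector of real words (typically
#'   `lexicon$surface`) the generator must avoid.
#' @param seed integer seed.
#' @param max_attempts attempts per word before erroring.
#' @return A `stimulus_variant`, condition `"Jabberwocky"`.
#' @export
make_jabberwocky <- function(s, blocklist, seed, max_attempts = 100L) {
  tokens <- s$tokens
  w <- tokens$surface
  subs <- list()
  with_seed(seed, {
    for (i in which(tokens$is_content)) {
      orig <- w[i]
      ok <- FALSE
      for (a in seq_len(max_attempts)) {
        cand <- nonword_attempt(orig)
        if (!(cand %in% blocklist) && cand != orig) { ok <- TRUE; break }
      }
      if (!ok) stop("failed to generate a nonword for '", orig, "' after ",
                    max_attempts, " attempts")
      subs[[length(subs) + 1L]] <- list(position = i, original = orig,
                                        replacement = cand)
      w[i] <- cand
    }
  })
  new_variant(s$item_id, "Jabberwocky", w,
              provenance = list(substitutions = subs), seed = seed)
}

#' Recombine a stimulus pool into word/nonword lists
#'
#' Pools every token across the input stimuli and redistributes them, by
#' sampling without replacement, into `n_seqs` sequences of `seq_len` tokens
#' each. The pooled token multiset is conserved exactly; the pool size must
#' equal `n_seqs * seq_len`.
#'
#' @param pool list of `annotated_sentence` / `stimulus_variant` objects (or
#'   character vectors of tokens).
#' @param n_seqs number of output sequences.
#' @param seq_len tokens per output sequence.
#' @param seed integer seed.
#' @param condition condition label for the outputs (default `"WordList"`;
#'   use `"NonwordList"` when pooling jabberwocky stimuli).
#' @return List of `n_seqs` `stimulus_variant` objects.
#' @export
recombine_lists <- function(pool, n_seqs, seq_len, seed,
                            condition = "WordList") {
  tokens <- unlist(lapply(pool, surfaces), use.names = FALSE)
  if (length(tokens) != n_seqs * seq_len) {
    stop("pool size mismatch: expected ", n_seqs * seq_len, " tokens (",
         n_seqs, " x ", seq_len, "), got ", length(tokens))
  }
  with_seed(seed, {
    shuffled <- sample(tokens)
    lapply(seq_len(n_seqs), function(i) {
      new_variant(sprintf("%s_%03d", tolower(condition), i), condition,
                  shuffled[((i - 1L) * seq_len + 1L):(i * seq_len)],
                  seed = seed)
    })
  })
}

#' Write / read stimuli as TSV
#'
#' Columns: item_id, condition, seed, tokens (space-joined), provenance
#' (JSON).
#'
#' @param stimuli list of `stimulus_variant` objects.
#' @param path file path.
#' @export
write_stimuli_tsv <- function(stimuli, path) {
  d <- data.frame(
    item_id = vapply(stimuli, function(v) v$item_id, character(1)),
    condition = vapply(stimuli, function(v) v$condition, character(1)),
    seed = vapply(stimuli, function(v) as.numeric(v$seed %||% NA), numeric(1)),
    tokens = vapply(stimuli, function(v) paste(v$tokens, collapse = " "),
                    character(1)),
    provenance = vapply(stimuli, function(v)
      as.character(jsonlite::toJSON(v$provenance, auto_unbox = TRUE)),
      character(1))
  )
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stimuli_tsv
#' @export
read_stimuli_tsv <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, quote = "",
                  colClasses = c(item_id = "character"))
  lapply(seq_len(nrow(d)), function(i) {
    new_variant(d$item_id[i], d$condition[i],
                strsplit(d$tokens[i], " ", fixed = TRUE)[[1]],
                provenance = jsonlite::fromJSON(d$provenance[i],
                                                simplifyVector = FALSE),
                seed = d$seed[i])
  })
}
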