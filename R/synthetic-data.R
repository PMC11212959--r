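# Synthetic-data generators: a toy lexicon and grammar, grammar-sampled
# base sentences and n-gram counts, simulated participants with a
# parameterized repair-skill model, and simulated voxel maps. Together they
# give every analysis in the package a self-contained test surface with the
# statistical structure the analyses assume.

#' The packaged toy lexicon and grammar
#'
#' The lexicon annotates 36 word types (determiners, adjectives, nouns with
#' vowel/consonant onsets, transitive and intransitive past-tense verbs,
#' prepositions, adverbs); the grammar is a small non-recursive PCFG over
#' those words whose sentences range from 4 to 15 words, with 12-word
#' sentences reachable through many derivations. Both ship as versioned
#' fixture files.
#'
#' @return [toy_lexicon()] a `synreco_lexicon`; [toy_grammar()] a `pcfg`.
#' @export
toy_lexicon <- function() {
  read_lexicon(system.file("extdata", "toy_lexicon.tsv", package = "synreco",
                           mustWork = TRUE))
}

#' @rdname toy_lexicon
#' @export
toy_grammar <- function() {
  read_pcfg(system.file("extdata", "toy_grammar.txt", package = "synreco",
                        mustWork = TRUE))
}

#' Sample one sentence from a grammar
#'
#' Expands from the start symbol, drawing each rule by its probability.
#' Draws come from the current RNG stream (callers seed via their own
#' `seed` arguments).
#'
#' @param g a `pcfg`.
#' @return Character vector of terminals.
#' @export
sample_sentence <- function(g) {
  rules_by_lhs <- split(seq_len(nrow(g$rules)), g$rules$lhs)
  expand <- function(sym) {
    if (!(sym %in% g$nonterminals)) return(sym)
    ks <- rules_by_lhs[[sym]]
    k <- ks[sample.int(length(ks), 1L, prob = g$rules$prob[ks])]
    unlist(lapply(g$rules$rhs[[k]], expand), use.names = FALSE)
  }
  expand(g$start)
}

#' Generate annotated base sentences of fixed length
#'
#' Rejection-samples the grammar until `n` sentences of exactly `length`
#' tokens are collected, then annotates each against the lexicon. Every
#' returned sentence is grammar-generable by construction (its prefix
#' probability is positive).
#'
#' @param g a `pcfg` (default [toy_grammar()]).
#' @param lex a `synreco_lexicon` (default [toy_lexicon()]).
#' @param n number of sentences.
#' @param length tokens per sentence (default 12).
#' @param seed integer seed.
#' @param max_attempts rejection-sampling bound.
#' @return List of `n` `annotated_sentence` objects with item ids
#'   `item_001`, `item_002`, ...
#' @export
gen_base_sentences <- function(n, length = 12L, seed = 1L,
                               g = toy_grammar(), lex = toy_lexicon(),
                               max_attempts = 2000L * n) {
  with_seed(seed, {
    out <- vector("list", n)
    got <- 0L
    for (a in seq_len(max_attempts)) {
      w <- sample_sentence(g)
      if (base::length(w) == length) {
        got <- got + 1L
        out[[got]] <- annotate(w, lex, item_id = sprintf("item_%03d", got))
        if (got == n) return(out)
      }
    }
    stop("rejection-sampling bound exceeded: got ", got, " of ", n,
         " sentences of length ", length, " in ", max_attempts, " attempts")
  })
}

#' Tally an n-gram table from grammar samples
#'
#' Samples `sample_size` sentences (any length) from the grammar and counts
#' unigrams and within-window pairs, emulating corpus-derived co-occurrence
#' statistics that are consistent with the text-generating process.
#'
#' @param sample_size number of sentences to sample.
#' @param g a `pcfg`.
#' @param seed integer seed.
#' @param alpha Laplace smoothing constant.
#' @param window window distance.
#' @return An `ngram_table`.
#' @export
gen_ngram_table <- function(sample_size, seed = 1L, g = toy_grammar(),
                            alpha = 0.1, window = 3L) {
  stopifnot(sample_size >= 1L)
  sents <- with_seed(seed, {
    lapply(seq_len(sample_size), function(i) sample_sentence(g))
  })
  count_ngrams(sents, alpha = alpha, window = window)
}

#' Default per-condition repair-skill profile
#'
#' Repair skill is the per-displaced-word probability that a simulated
#' participant restores the original relative order at a reveal step. The
#' defaults decay with the severity of the word-order manipulation: local
#' swaps remain largely repairable while the low-combinability scramble and
#' full reversal are nearly unrepairable in real time.
#'
#' @return Named numeric vector of skills in `[0, 1]`.
#' @export
default_skill <- function() {
  c(Intact = 0.95, Scrambled1 = 0.9, Scrambled3 = 0.8, Scrambled5 = 0.7,
    Scrambled7 = 0.6, Scrambled_LowPMI = 0.1, Backward = 0.05)
}

# One simulated trial: at each reveal, compute the original relative order
# of the revealed words; with probability skill^(number of displaced words)
# the display is restored to that order, otherwise left untouched.
simulate_trial <- function(stimulus, original, skill) {
  t <- synreco_trial(stimulus$item_id, stimulus$condition, stimulus$tokens)
  orig <- as.character(original)
  while (!trial_complete(t)) {
    t <- reveal_next(t)
    target <- restrict_to_multiset(orig, t$current_order)
    displaced <- sum(t$current_order != target)
    if (displaced > 0L && runif(1) < skill^displaced) {
      t <- apply_reorder(t, target)
    }
  }
  t
}

# Original-order restriction to a revealed multiset: walk the original
# sequence, keeping each token while its revealed count lasts.
restrict_to_multiset <- function(original, revealed) {
  counts <- table(revealed)
  keep <- logical(length(original))
  for (i in seq_along(original)) {
    w <- original[i]
    if (!is.na(counts[w]) && counts[w] > 0L) {
      keep[i] <- TRUE
      counts[w] <- counts[w] - 1L
    }
  }
  original[keep]
}

#' Simulate participant logs for the reordering paradigm
#'
#' Runs the trial state machine for every (participant, stimulus) pair
#' under the per-condition repair-skill model: at each reveal, the
#' simulated participant restores the original relative order of the words
#' on display with probability `skill(condition)` per displaced word
#' (jointly, `skill^n_displaced`), and otherwise leaves the display
#' untouched. With skill 1 every trial ends verbatim-correct; with skill 0
#' final orders equal the stimulus orders exactly. Attention-check and
#' filler outcomes are drawn as independent passes.
#'
#' @param stimuli list of `stimulus_variant` objects.
#' @param originals named list mapping item_id -> original token vector.
#' @param n_participants number of simulated participants.
#' @param skill named per-condition skill vector (default
#'   [default_skill()]).
#' @param seed integer seed.
#' @param assignment optional list of stimulus-index vectors, one per
#'   participant (defaults to every participant completing every stimulus).
#' @param attention_pass_prob,filler_pass_prob per-item pass probabilities
#'   for the 7 attention checks and 12 fillers.
#' @return List of `participant_log` objects.
#' @export
simulate_synreco_logs <- function(stimuli, originals, n_participants,
                                  skill = default_skill(), seed = 1L,
                                  assignment = NULL,
                                  attention_pass_prob = 0.95,
                                  filler_pass_prob = 0.9) {
  if (any(skill < 0 | skill > 1)) stop("skill values must be in [0, 1]")
  if (is.null(assignment)) {
    assignment <- rep(list(seq_along(stimuli)), n_participants)
  }
  lapply(seq_len(n_participants), function(p) {
    with_seed(child_seed(seed, p), {
      trials <- lapply(assignment[[p]], function(i) {
        v <- stimuli[[i]]
        sk <- skill[[v$condition]]
        if (is.null(sk) || is.na(sk)) {
          stop("no skill value for condition ", v$condition)
        }
        simulate_trial(v, originals[[v$item_id]], sk)
      })
      participant_log(
        sprintf("sim_%03d", p), trials,
        runif(7) < attention_pass_prob,
        runif(12) < filler_pass_prob
      )
    })
  })
}

#' Simulate a voxel map with planted condition effects
#'
#' A fraction of voxels carry signal: their localizer statistic is drawn
#' around `localizer_effect` and their condition responses around the
#' planted effects; the remaining voxels are noise-only. Gaussian noise of
#' sd `noise_sd` is added to every response.
#'
#' @param n_voxels mask size.
#' @param effects named numeric vector of per-condition response means
#'   (percent signal change) for signal voxels. The default mirrors the
#'   qualitative ordering Sentence ~ Nonsense > Backward > WordList ~
#'   Jabberwocky > NonwordList.
#' @param noise_sd response noise sd.
#' @param signal_fraction fraction of voxels carrying signal, in (0, 1].
#' @param localizer_effect mean localizer statistic of signal voxels (null
#'   voxels are standard normal).
#' @param seed integer seed.
#' @param mask_label label for the map.
#' @return A `voxel_map`; the indices of the signal voxels are attached as
#'   `attr(, "signal_voxels")`.
#' @export
simulate_voxel_data <- function(n_voxels = 500L,
                                effects = c(Sentence = 1.5, Backward = 0.9,
                                            Nonsense = 1.45, WordList = 0.7,
                                            Jabberwocky = 0.7,
                                            NonwordList = 0.4),
                                noise_sd = 1, signal_fraction = 0.2,
                                localizer_effect = 4, seed = 1L,
                                mask_label = "synthetic_parcel") {
  if (signal_fraction <= 0 || signal_fraction > 1) {
    stop("signal_fraction must be in (0, 1]")
  }
  with_seed(seed, {
    n_signal <- max(1L, round(signal_fraction * n_voxels))
    signal <- sort(sample.int(n_voxels, n_signal))
    stat <- rnorm(n_voxels, 0, 1)
    stat[signal] <- rnorm(n_signal, localizer_effect, 1)
    resp <- sapply(names(effects), function(cn) {
      mu <- numeric(n_voxels)
      mu[signal] <- effects[[cn]]
      mu + rnorm(n_voxels, 0, noise_sd)
    })
    m <- voxel_map(seq_len(n_voxels), stat, as.data.frame(resp),
                   mask_label = mask_label)
    attr(m, "signal_voxels") <- signal
    m
  })
}

#' Generate the full set of behavioral stimulus conditions for an item
#'
#' Convenience wrapper producing the seven word-order conditions of the
#' behavioral experiment from one base sentence: Intact, Scrambled{1,3,5,7},
#' Scrambled_LowPMI, and Backward.
#'
#' @param s an `annotated_sentence`.
#' @param seed integer seed (per-condition child seeds are derived).
#' @return Named list of `stimulus_variant` objects.
#' @export
behavioral_conditions <- function(s, seed = 1L) {
  out <- list(
    Intact = intact(s),
    Scrambled1 = scramble_local(s, 1L, child_seed(seed, 1)),
    Scrambled3 = scramble_local(s, 3L, child_seed(seed, 3)),
    Scrambled5 = scramble_local(s, 5L, child_seed(seed, 5)),
    Scrambled7 = scramble_local(s, 7L, child_seed(seed, 7)),
    Scrambled_LowPMI = scramble_low_pmi(s, child_seed(seed, 11)),
    Backward = backward(s)
  )
  out
}
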