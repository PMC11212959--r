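# Shared text data model: tokens, annotated sentences, feature keys, and the
# feature-keyed replacement dictionary behind nonsense-sentence generation.

# Part-of-speech tags counted as content words (proper nouns treated as nouns).
CONTENT_POS <- c("NOUN", "PROPN", "VERB", "ADJ", "ADV")

VOWELS <- c("a", "e", "i", "o", "u")

#' Annotation lexicon
#'
#' A lexicon maps word surfaces to their linguistic annotations: universal
#' part-of-speech tag, dependency label, morphological features, and (for
#' verbs) an argument-valence class. It is the deterministic annotation
#' backend used by [annotate()]; an external tagger's output can be supplied
#' through the same TSV format.
#'
#' @param surface character vector of word forms (lowercase).
#' @param pos universal POS tags (e.g. `"NOUN"`, `"VERB"`, `"DET"`).
#' @param dep dependency labels.
#' @param morph morphological features as pipe-separated `Feature=Value`
#'   strings; `"_"` for none.
#' @param valence verb argument-valence class (`"intransitive"`,
#'   `"transitive"`, `"ditransitive"`, `"copular"`); `NA` for non-verbs.
#' @return A tibble of class `synreco_lexicon`.
#' @export
lexicon <- function(surface, pos, dep, morph = "_", valence = NA_character_) {
  lex <- tibble::tibble(
    surface = as.character(surface),
    pos = as.character(pos),
    dep = as.character(dep),
    morph = rep_len(as.character(morph), length(surface)),
    valence = rep_len(as.character(valence), length(surface))
  )
  if (anyDuplicated(lex$surface)) {
    stop("duplicate surfaces in lexicon: ",
         paste(unique(lex$surface[duplicated(lex$surface)]), collapse = ", "))
  }
  bad <- !is.na(lex$valence) & lex$pos != "VERB"
  if (any(bad)) stop("valence given for non-verb: ",
                     paste(lex$surface[bad], collapse = ", "))
  class(lex) <- c("synreco_lexicon", class(lex))
  lex
}

#' Read / write a lexicon TSV
#'
#' Columns: FORM, UPOS, DEPREL, FEATS (pipe-separated `Feature=Value` or
#' `_`), VALENCE (`_` for non-verbs).
#'
#' @param path file path.
#' @return [read_lexicon()] returns a `synreco_lexicon`;
#'   [write_lexicon()] returns `path` invisibly.
#' @export
read_lexicon <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  lexicon(
    surface = d$FORM, pos = d$UPOS, dep = d$DEPREL,
    morph = d$FEATS,
    valence = ifelse(d$VALENCE == "_", NA_character_, d$VALENCE)
  )
}

#' @rdname read_lexicon
#' @param lex a `synreco_lexicon`.
#' @export
write_lexicon <- function(lex, path) {
  out <- data.frame(
    FORM = lex$surface, UPOS = lex$pos, DEPREL = lex$dep,
    FEATS = lex$morph,
    VALENCE = ifelse(is.na(lex$valence), "_", lex$valence)
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Annotate a raw sentence
#'
#' Tokenizes on whitespace and looks each word up in the lexicon, producing
#' one annotated token per word. Content-word status is derived from the POS
#' tag (noun, verb, adjective, adverb); noun onset class (vowel vs consonant)
#' is derived from the word's first letter, an orthographic proxy for its
#' phonological onset.
#'
#' @param raw_sentence a sentence as a single string (words separated by
#'   whitespace), or a character vector of tokens.
#' @param lex a `synreco_lexicon`.
#' @param item_id identifier carried on the result.
#' @return An `annotated_sentence`: a list with `item_id` and a tibble
#'   `tokens` (columns `surface`, `pos`, `dep`, `morph`, `valence`, `onset`,
#'   `is_content`).
#' @export
annotate <- function(raw_sentence, lex, item_id = NA_character_) {
  words <- if (length(raw_sentence) == 1L) {
    strsplit(trimws(raw_sentence), "\\s+")[[1]]
  } else {
    as.character(raw_sentence)
  }
  words <- words[nzchar(words)]
  if (length(words) == 0L) stop("empty sentence after tokenization")
  idx <- match(words, lex$surface)
  if (anyNA(idx)) {
    stop("unresolvable token(s) not in lexicon: ",
         paste(unique(words[is.na(idx)]), collapse = ", "))
  }
  tok <- lex[idx, c("surface", "pos", "dep", "morph", "valence")]
  tok$onset <- ifelse(
    tok$pos %in% c("NOUN", "PROPN"),
    ifelse(substr(tok$surface, 1, 1) %in% VOWELS, "vowel", "consonant"),
    NA_character_
  )
  tok$is_content <- tok$pos %in% CONTENT_POS
  annotated_sentence(tok, item_id = item_id)
}

#' Construct an annotated sentence from a token table
#'
#' @param tokens a data frame with columns `surface`, `pos`, `dep`, `morph`,
#'   `valence`, `onset`, `is_content` (the last three may be omitted and are
#'   then derived).
#' @param item_id identifier.
#' @return An object of class `annotated_sentence`.
#' @export
annotated_sentence <- function(tokens, item_id = NA_character_) {
  tokens <- tibble::as_tibble(tokens)
  if (nrow(tokens) < 1L) stop("sentence must contain at least one token")
  if (!("valence" %in% names(tokens))) tokens$valence <- NA_character_
  if (!("onset" %in% names(tokens))) {
    tokens$onset <- ifelse(
      tokens$pos %in% c("NOUN", "PROPN"),
      ifelse(substr(tokens$surface, 1, 1) %in% VOWELS, "vowel", "consonant"),
      NA_character_
    )
  }
  if (!("is_content" %in% names(tokens))) {
    tokens$is_content <- tokens$pos %in% CONTENT_POS
  }
  structure(
    list(item_id = item_id, tokens = tokens),
    class = "annotated_sentence"
  )
}

#' @export
length.annotated_sentence <- function(x) nrow(x$tokens)

#' @export
print.annotated_sentence <- function(x, ...) {
  cat("<annotated_sentence", if (!is.na(x$item_id)) paste0(" ", x$item_id),
      "> ", paste(x$tokens$surface, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Surfaces of a sentence or stimulus
#'
#' @param x an `annotated_sentence` or `stimulus_variant`.
#' @return Character vector of word surfaces in order.
#' @export
surfaces <- function(x) {
  if (inherits(x, "annotated_sentence")) return(x$tokens$surface)
  if (inherits(x, "stimulus_variant")) return(x$tokens)
  if (is.character(x)) return(x)
  stop("cannot extract surfaces from class ", paste(class(x), collapse = "/"))
}

#' Canonical feature key of a token
#'
#' Builds the canonical annotation key used by the replacement dictionary:
#' a string over (pos, dep, morph, valence, onset) with absent slots
#' normalized and morphological features sorted, so tokens with identical
#' annotations map to equal keys regardless of feature ordering.
#'
#' @param pos,dep,morph,valence,onset annotation fields (vectors of equal
#'   length; `morph` as pipe-separated `Feature=Value` strings).
#' @param drop character vector of slots to exclude (used by the matching
#'   relaxation ladder): any of `"dep"`, `"onset"`, `"morph"`, `"valence"`.
#' @return Character vector of keys.
#' @export
feature_key <- function(pos, dep, morph, valence, onset, drop = character()) {
  norm_morph <- vapply(strsplit(ifelse(is.na(morph) | morph == "", "_", morph),
                                "|", fixed = TRUE),
                       function(f) paste(sort(f), collapse = "|"), character(1))
  slot <- function(name, val) {
    if (name %in% drop) rep("*", length(pos))
    else ifelse(is.na(val), "-", val)
  }
  paste(
    ifelse(is.na(pos), "-", pos),
    slot("dep", dep),
    slot("morph", norm_morph),
    slot("valence", valence),
    slot("onset", onset),
    sep = "\036"  # field separator; keys are opaque identifiers
  )
}

token_keys <- function(tokens, drop = character()) {
  feature_key(tokens$pos, tokens$dep, tokens$morph, tokens$valence,
              tokens$onset, drop = drop)
}

#' Build the feature-keyed replacement dictionary
#'
#' Maps each feature key to the multiset of content-word surfaces carrying
#' that key across a corpus. Duplicates are retained: a word occurring twice
#' under the same key contributes two entries, so sampling from the
#' dictionary reflects corpus token frequency.
#'
#' @param corpus a list of `annotated_sentence` objects.
#' @return A `replacement_dictionary`: list with `entries` (named list of
#'   character vectors, key -> surfaces with multiplicity) and
#'   `total_entries` (content-token count with multiplicity).
#' @export
build_replacement_dictionary <- function(corpus) {
  if (length(corpus) == 0L) stop("corpus must be non-empty")
  toks <- do.call(rbind, lapply(corpus, function(s) s$tokens))
  content <- toks[toks$is_content, , drop = FALSE]
  if (nrow(content) == 0L) {
    warning("corpus contains no content tokens; dictionary is empty")
    return(structure(list(entries = list(), total_entries = 0L),
                     class = "replacement_dictionary"))
  }
  keys <- token_keys(content)
  entries <- split(content$surface, keys)
  structure(
    list(entries = entries, total_entries = nrow(content)),
    class = "replacement_dictionary"
  )
}

#' @export
print.replacement_dictionary <- function(x, ...) {
  cat("<replacement_dictionary> ", length(x$entries), " keys, ",
      x$total_entries, " entries (with multiplicity)\n", sep = "")
  invisible(x)
}

#' Read / write sentences as CoNLL-like TSV
#'
#' One token per row with columns ID, FORM, UPOS, DEPREL, FEATS, VALENCE,
#' ONSET, plus a SENT column holding the sentence's item id; sentences are
#' consecutive row groups.
#'
#' @param path file path.
#' @param corpus a list of `annotated_sentence` objects.
#' @return [read_sentences_tsv()] returns a list of `annotated_sentence`.
#' @export
read_sentences_tsv <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE,
                  colClasses = c(SENT = "character", FORM = "character"))
  lapply(split(d, factor(d$SENT, levels = unique(d$SENT))), function(g) {
    g <- g[order(g$ID), ]
    annotated_sentence(
      tibble::tibble(
        surface = g$FORM, pos = g$UPOS, dep = g$DEPREL, morph = g$FEATS,
        valence = ifelse(g$VALENCE == "_", NA_character_, g$VALENCE),
        onset = ifelse(g$ONSET == "_", NA_character_, g$ONSET)
      ),
      item_id = g$SENT[1]
    )
  })
}

#' @rdname read_sentences_tsv
#' @export
write_sentences_tsv <- function(corpus, path) {
  rows <- lapply(corpus, function(s) {
    t <- s$tokens
    data.frame(
      SENT = s$item_id, ID = seq_len(nrow(t)), FORM = t$surface,
      UPOS = t$pos, DEPREL = t$dep, FEATS = t$morph,
      VALENCE = ifelse(is.na(t$valence), "_", t$valence),
      ONSET = ifelse(is.na(t$onset), "_", t$onset)
    )
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
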