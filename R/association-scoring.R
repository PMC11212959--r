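# Sliding-window positive pointwise mutual information with Laplace
# smoothing: the per-sentence local-combinability statistic.

pair_key <- function(w1, w2) {
  a <- pmin(w1, w2); b <- pmax(w1, w2)
  paste(a, b, sep = "\036")
}

#' N-gram count table
#'
#' Holds unigram counts and unordered within-window pair counts, with a
#' Laplace smoothing constant. Probabilities are estimated as
#' `P(w) = (c(w) + alpha) / (N_uni + alpha * V)` and
#' `P(w1, w2) = (c(w1, w2) + alpha) / (N_pair + alpha * V^2)`, so every
#' word and pair — seen or not — has positive probability.
#'
#' @param unigram named numeric vector of word counts.
#' @param pair named numeric vector of pair counts; names are
#'   `pair_key(w1, w2)` strings, or supply a 3-column data frame
#'   (`w1`, `w2`, `count`) instead.
#' @param alpha Laplace smoothing constant (default 0.1).
#' @param V vocabulary size (defaults to `length(unigram)`).
#' @return An object of class `ngram_table`.
#' @export
ngram_table <- function(unigram, pair, alpha = 0.1, V = length(unigram)) {
  if (alpha <= 0) stop("alpha must be positive")
  if (is.data.frame(pair)) {
    keys <- pair_key(as.character(pair[[1]]), as.character(pair[[2]]))
    pair <- tapply(as.numeric(pair[[3]]), keys, sum)
    pair <- setNames(as.numeric(pair), names(pair))
  }
  if (any(unigram < 0) || any(pair < 0)) stop("counts must be non-negative")
  structure(
    list(unigram = unigram, pair = pair,
         N_uni = sum(unigram), N_pair = sum(pair),
         V = V, alpha = alpha),
    class = "ngram_table"
  )
}

#' @export
print.ngram_table <- function(x, ...) {
  cat("<ngram_table> V=", x$V, " N_uni=", x$N_uni, " N_pair=", x$N_pair,
      " alpha=", x$alpha, "\n", sep = "")
  invisible(x)
}

#' Extract sliding-window word pairs
#'
#' Returns all index pairs `(i, j)` with `1 <= j - i <= window`, i.e. the
#' pairs a sliding `(window + 1)`-word window collects: for the default
#' window of 3, the bigrams, 1-skip-grams and 2-skip-grams. A sentence of
#' `n >= window + 1` tokens yields `window * n - window * (window + 1) / 2`
#' pairs (`3n - 6` for the four-word window).
#'
#' @param n number of tokens (or a character vector of tokens).
#' @param window maximum index distance (default 3).
#' @return Integer matrix with columns `i`, `j`, rows in lexicographic
#'   order; zero rows when `n < 2`.
#' @export
extract_window_pairs <- function(n, window = 3L) {
  if (is.character(n)) n <- length(n)
  n <- as.integer(n)
  if (n < 2L) return(matrix(integer(0), ncol = 2L,
                            dimnames = list(NULL, c("i", "j"))))
  i <- rep(seq_len(n - 1L), each = window)
  j <- i + seq_len(window)
  keep <- j <= n
  cbind(i = i[keep], j = j[keep])
}

smoothed_p_uni <- function(w, t) {
  c_w <- ifelse(is.na(t$unigram[w]), 0, t$unigram[w])
  unname((c_w + t$alpha) / (t$N_uni + t$alpha * t$V))
}

smoothed_p_pair <- function(w1, w2, t) {
  c_p <- t$pair[pair_key(w1, w2)]
  c_p <- ifelse(is.na(c_p), 0, c_p)
  unname((c_p + t$alpha) / (t$N_pair + t$alpha * t$V^2))
}

#' Pointwise mutual information of a word pair
#'
#' `log P(w1, w2) / (P(w1) P(w2))` under the table's Laplace-smoothed
#' estimates. Pairs are unordered, so the score is symmetric; smoothing
#' keeps it finite for unseen words and pairs. Set `ordered = TRUE` for the
#' directional variant, which looks the ordered pair up in an ordered count
#' table (same smoothing).
#'
#' @param w1,w2 words (vectorized).
#' @param t an `ngram_table`.
#' @param base logarithm base (default `exp(1)`).
#' @param ordered treat `(w1, w2)` as ordered (requires a table whose pair
#'   counts were tallied ordered).
#' @return Numeric PMI value(s), possibly negative.
#' @export
pmi <- function(w1, w2, t, base = exp(1), ordered = FALSE) {
  p12 <- if (ordered) {
    c_p <- t$pair[paste(w1, w2, sep = "\036")]
    c_p <- ifelse(is.na(c_p), 0, c_p)
    unname((c_p + t$alpha) / (t$N_pair + t$alpha * t$V^2))
  } else {
    smoothed_p_pair(w1, w2, t)
  }
  log(p12 / (smoothed_p_uni(w1, t) * smoothed_p_uni(w2, t)), base = base)
}

#' Per-sentence PPMI score
#'
#' Scores every sliding-window pair of the string with `max(0, PMI)` and
#' averages. Negative PMI values are clipped to zero before averaging, on
#' the view that a negative association signals no local semantic
#' dependency worth building. Because the window pair set depends only on
#' unordered index distance, the score is exactly invariant to reversing
#' the string.
#'
#' Two normalizations are available: `"pairs"` (default) divides by the
#' actual number of window pairs (`3n - 6` for `n >= 4`); `"printed"`
#' divides by the constant `3n - 2` that appears in the published formula.
#'
#' @param tokens character vector of word surfaces (length >= 2).
#' @param t an `ngram_table`.
#' @param normalization `"pairs"` or `"printed"`.
#' @param base logarithm base.
#' @param window window distance (default 3, the four-word window).
#' @return A `ppmi_result`: list with `pair_scores` (tibble `i`, `j`,
#'   `score`), `mean_score`, `n_pairs`, and `normalization`.
#' @export
ppmi_string <- function(tokens, t, normalization = c("pairs", "printed"),
                        base = exp(1), window = 3L) {
  normalization <- match.arg(normalization)
  tokens <- surfaces(tokens)
  n <- length(tokens)
  if (n < 2L) stop("PPMI score undefined for strings of fewer than 2 tokens")
  pr <- extract_window_pairs(n, window)
  score <- pmax(0, pmi(tokens[pr[, "i"]], tokens[pr[, "j"]], t, base = base))
  denom <- switch(normalization,
                  pairs = nrow(pr),
                  printed = 3 * n - 2)
  structure(
    list(
      pair_scores = tibble::tibble(i = pr[, "i"], j = pr[, "j"], score = score),
      mean_score = sum(score) / denom,
      n_pairs = nrow(pr),
      normalization = normalization
    ),
    class = "ppmi_result"
  )
}

#' @export
print.ppmi_result <- function(x, ...) {
  cat("<ppmi_result> mean=", format(x$mean_score), " over ", x$n_pairs,
      " pairs (", x$normalization, " normalization)\n", sep = "")
  invisible(x)
}

#' Read / write an n-gram count table as TSV
#'
#' Section-tagged rows: `#V <int>` and `#ALPHA <num>` headers, then
#' `UNI <word> <count>` and `PAIR <w1> <w2> <count>` rows.
#'
#' @param t an `ngram_table`; `path` a file path.
#' @export
write_ngram_tsv <- function(t, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("#V\t", t$V), paste0("#ALPHA\t", t$alpha)), con)
  if (length(t$unigram)) {
    writeLines(paste("UNI", names(t$unigram), t$unigram, sep = "\t"), con)
  }
  if (length(t$pair)) {
    pp <- do.call(rbind, strsplit(names(t$pair), "\036", fixed = TRUE))
    writeLines(paste("PAIR", pp[, 1], pp[, 2], t$pair, sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_ngram_tsv
#' @export
read_ngram_tsv <- function(path) {
  lines <- readLines(path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  tag <- vapply(fields, `[[`, character(1), 1L)
  V <- as.integer(fields[[which(tag == "#V")[1]]][2])
  alpha <- as.numeric(fields[[which(tag == "#ALPHA")[1]]][2])
  uni <- fields[tag == "UNI"]
  pairr <- fields[tag == "PAIR"]
  unigram <- setNames(vapply(uni, function(f) as.numeric(f[3]), numeric(1)),
                      vapply(uni, `[[`, character(1), 2L))
  pair <- setNames(vapply(pairr, function(f) as.numeric(f[4]), numeric(1)),
                   vapply(pairr, function(f) pair_key(f[2], f[3]), character(1)))
  ngram_table(unigram, pair, alpha = alpha, V = V)
}

#' Tally an n-gram table from a corpus of token sequences
#'
#' Counts unigrams over all tokens and unordered within-window pairs from
#' each sequence.
#'
#' @param sequences list of character vectors (or objects with surfaces).
#' @param alpha smoothing constant.
#' @param window window distance.
#' @return An `ngram_table`.
#' @export
count_ngrams <- function(sequences, alpha = 0.1, window = 3L) {
  toks <- lapply(sequences, surfaces)
  all_tokens <- unlist(toks, use.names = FALSE)
  unigram_tab <- table(all_tokens)
  unigram <- setNames(as.numeric(unigram_tab), names(unigram_tab))
  keys <- unlist(lapply(toks, function(w) {
    pr <- extract_window_pairs(length(w), window)
    if (nrow(pr) == 0L) return(character(0))
    pair_key(w[pr[, "i"]], w[pr[, "j"]])
  }), use.names = FALSE)
  pair_tab <- table(keys)
  pair <- setNames(as.numeric(pair_tab), names(pair_tab))
  ngram_table(unigram, pair, alpha = alpha)
}
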