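# Incremental surprisal from probabilistic context-free grammars.
#
# Prefix probabilities are computed with a chart algorithm over the grammar
# in Chomsky normal form: ordinary inside probabilities give the mass of
# derivations whose yield IS a span, and a left-corner closure matrix
# resolves the recursion for derivations whose yield merely BEGINS with the
# span (Jelinek & Lafferty-style prefix computation).

#' Toy probabilistic context-free grammar
#'
#' @param rules a data frame with columns `lhs` (character), `rhs` (list of
#'   character vectors), and `prob` (numeric); or use [read_pcfg()].
#' @param start start symbol (default `"S"`).
#' @return An object of class `pcfg`. Rule probabilities must sum to 1
#'   (within 1e-9) for every left-hand side; terminals are the symbols that
#'   never appear as a left-hand side.
#' @export
pcfg <- function(rules, start = "S") {
  rules <- tibble::as_tibble(rules)
  stopifnot(all(c("lhs", "rhs", "prob") %in% names(rules)))
  rules$rhs <- lapply(rules$rhs, as.character)
  if (any(lengths(rules$rhs) == 0L)) stop("empty right-hand sides not supported")
  sums <- tapply(rules$prob, rules$lhs, sum)
  off <- abs(sums - 1) > 1e-9
  if (any(off)) {
    stop("rule probabilities do not sum to 1 for: ",
         paste(names(sums)[off], collapse = ", "))
  }
  nonterminals <- unique(rules$lhs)
  symbols <- unique(unlist(rules$rhs))
  terminals <- setdiff(symbols, nonterminals)
  if (!(start %in% nonterminals)) stop("start symbol ", start, " has no rules")
  g <- structure(
    list(rules = rules, start = start, nonterminals = nonterminals,
         terminals = terminals),
    class = "pcfg"
  )
  g$cnf <- to_cnf(g)
  g
}

#' @export
print.pcfg <- function(x, ...) {
  cat("<pcfg> ", length(x$nonterminals), " nonterminals, ",
      length(x$terminals), " terminals, ", nrow(x$rules), " rules; start ",
      x$start, "\n", sep = "")
  invisible(x)
}

#' Read / write a grammar file
#'
#' One rule per line: `LHS -> RHS1 RHS2 ... : prob`. Blank lines and lines
#' starting with `#` are ignored.
#'
#' @param path file path; `start` the start symbol.
#' @return [read_pcfg()] returns a `pcfg`.
#' @export
read_pcfg <- function(path, start = "S") {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parsed <- lapply(lines, function(l) {
    m <- regmatches(l, regexec("^(\\S+)\\s*->\\s*(.+?)\\s*:\\s*([0-9.eE+-]+)$", l))[[1]]
    if (length(m) != 4L) stop("malformed grammar rule: ", l)
    list(lhs = m[2], rhs = strsplit(m[3], "\\s+")[[1]], prob = as.numeric(m[4]))
  })
  pcfg(tibble::tibble(
    lhs = vapply(parsed, `[[`, character(1), "lhs"),
    rhs = lapply(parsed, `[[`, "rhs"),
    prob = vapply(parsed, `[[`, numeric(1), "prob")
  ), start = start)
}

#' @rdname read_pcfg
#' @param g a `pcfg`.
#' @export
write_pcfg <- function(g, path) {
  writeLines(sprintf("%s -> %s : %.12g", g$rules$lhs,
                     vapply(g$rules$rhs, paste, character(1), collapse = " "),
                     g$rules$prob), path)
  invisible(path)
}

# Convert to CNF: terminal lifting, binarization, unit-rule elimination.
# Returns binary rules (lhs, b, c, prob), lexical rules (lhs, word, prob),
# the nonterminal index, and the left-corner closure matrix R = (I - Q)^-1
# with Q[A, B] = sum over rules A -> B C of prob.
to_cnf <- function(g) {
  lhs <- g$rules$lhs; rhs <- g$rules$rhs; prob <- g$rules$prob
  terminals <- g$terminals
  # Lift terminals occurring in rules of length > 1 into preterminals.
  lift <- function(sym) paste0(".T_", sym)
  new_lex <- list()
  for (k in seq_along(rhs)) {
    if (length(rhs[[k]]) > 1L) {
      t_in <- rhs[[k]] %in% terminals
      if (any(t_in)) {
        for (s in unique(rhs[[k]][t_in])) new_lex[[s]] <- TRUE
        rhs[[k]][t_in] <- lift(rhs[[k]][t_in])
      }
    }
  }
  for (s in names(new_lex)) {
    lhs <- c(lhs, lift(s)); rhs <- c(rhs, list(s)); prob <- c(prob, 1)
  }
  # Binarize.
  b_lhs <- character(0); b_b <- character(0); b_c <- character(0); b_p <- numeric(0)
  u_lhs <- character(0); u_rhs <- character(0); u_p <- numeric(0)  # unit/lexical
  fresh <- 0L
  for (k in seq_along(rhs)) {
    r <- rhs[[k]]
    if (length(r) == 1L) {
      u_lhs <- c(u_lhs, lhs[k]); u_rhs <- c(u_rhs, r); u_p <- c(u_p, prob[k])
    } else {
      cur <- lhs[k]; p <- prob[k]
      while (length(r) > 2L) {
        fresh <- fresh + 1L
        nt <- paste0(".X", fresh)
        b_lhs <- c(b_lhs, cur); b_b <- c(b_b, r[1]); b_c <- c(b_c, nt)
        b_p <- c(b_p, p)
        cur <- nt; p <- 1; r <- r[-1]
      }
      b_lhs <- c(b_lhs, cur); b_b <- c(b_b, r[1]); b_c <- c(b_c, r[2])
      b_p <- c(b_p, p)
    }
  }
  nts <- unique(c(g$nonterminals, b_lhs, b_b, b_c, u_lhs))
  nts <- setdiff(nts, terminals)
  nt_id <- setNames(seq_along(nts), nts)
  n_nt <- length(nts)
  # Unit-rule closure: U = (I - P_unit)^-1 over rules A -> B, B nonterminal.
  is_unit <- u_rhs %in% nts
  Pu <- matrix(0, n_nt, n_nt, dimnames = list(nts, nts))
  for (k in which(is_unit)) {
    Pu[u_lhs[k], u_rhs[k]] <- Pu[u_lhs[k], u_rhs[k]] + u_p[k]
  }
  U <- solve(diag(n_nt) - Pu)
  dimnames(U) <- list(nts, nts)
  # Fold closure into binary and lexical rules: A => gamma with prob
  # sum_B U[A,B] * p(B -> gamma).
  fold <- function(r_lhs, r_p) {
    hits <- U[, r_lhs, drop = FALSE]
    out <- which(hits != 0, arr.ind = TRUE)
    list(lhs = nts[out[, 1]], src = out[, 2],
         prob = hits[out] * r_p[out[, 2]])
  }
  lex_k <- which(!is_unit)
  binary <- NULL; lexical <- NULL
  if (length(b_lhs)) {
    f <- fold(b_lhs, b_p)
    binary <- data.frame(lhs = f$lhs, b = b_b[f$src], c = b_c[f$src],
                         prob = f$prob, stringsAsFactors = FALSE)
    binary <- aggregate(prob ~ lhs + b + c, binary, sum)
  }
  if (length(lex_k)) {
    f <- fold(u_lhs[lex_k], u_p[lex_k])
    lexical <- data.frame(lhs = f$lhs, word = u_rhs[lex_k][f$src],
                          prob = f$prob, stringsAsFactors = FALSE)
    lexical <- aggregate(prob ~ lhs + word, lexical, sum)
  }
  # Left-corner closure over the binary rules.
  Q <- matrix(0, n_nt, n_nt, dimnames = list(nts, nts))
  if (!is.null(binary)) {
    for (k in seq_len(nrow(binary))) {
      Q[binary$lhs[k], binary$b[k]] <- Q[binary$lhs[k], binary$b[k]] +
        binary$prob[k]
    }
  }
  R <- solve(diag(n_nt) - Q)
  dimnames(R) <- list(nts, nts)
  list(nts = nts, nt_id = nt_id, binary = binary, lexical = lexical, R = R)
}

# Inside chart: beta[[i]][[j]][A] = P(A =>* tokens[i..j]). Represented as
# a list-of-lists of named numeric vectors over nonterminal ids.
inside_chart <- function(g, tokens) {
  cnf <- g$cnf
  n <- length(tokens)
  n_nt <- length(cnf$nts)
  beta <- array(0, dim = c(n, n, n_nt), dimnames = list(NULL, NULL, cnf$nts))
  lex <- cnf$lexical
  for (i in seq_len(n)) {
    hit <- lex[lex$word == tokens[i], , drop = FALSE]
    if (nrow(hit)) beta[i, i, hit$lhs] <- hit$prob
  }
  bin <- cnf$binary
  if (!is.null(bin) && n > 1L) {
    for (span in 2:n) for (i in seq_len(n - span + 1L)) {
      j <- i + span - 1L
      acc <- numeric(n_nt)
      for (k in i:(j - 1L)) {
        pb <- beta[i, k, bin$b]
        pc <- beta[k + 1L, j, bin$c]
        w <- bin$prob * pb * pc
        nz <- which(w != 0)
        if (length(nz)) {
          for (m in nz) {
            id <- cnf$nt_id[[bin$lhs[m]]]
            acc[id] <- acc[id] + w[m]
          }
        }
      }
      beta[i, j, ] <- acc
    }
  }
  beta
}

#' Prefix probability under a grammar
#'
#' Total probability of all complete sentences of the grammar whose yield
#' begins with `prefix`: `sum over sentences s extending prefix of P(s)`.
#' Computed by a chart algorithm (inside probabilities plus a left-corner
#' closure), so left-recursive and unit chains are handled exactly. The
#' empty prefix has probability 1; a prefix no sentence extends has
#' probability 0.
#'
#' @param g a `pcfg`.
#' @param prefix character vector of terminals.
#' @return A single probability in `[0, 1]`.
#' @export
prefix_probability <- function(g, prefix) {
  prefix <- as.character(prefix)
  if (length(prefix) == 0L) return(1)
  unknown <- setdiff(prefix, g$terminals)
  if (length(unknown)) {
    stop("out-of-vocabulary terminal(s): ", paste(unique(unknown), collapse = ", "))
  }
  pi_chart <- prefix_chart(g, prefix)
  m <- length(prefix)
  unname(pi_chart[1L, m, g$start])
}

# pi[i, j, A] = P(A's yield begins with tokens[i..j]); resolves the
# left-corner recursion per span with the closure matrix R.
prefix_chart <- function(g, tokens) {
  cnf <- g$cnf
  n <- length(tokens)
  n_nt <- length(cnf$nts)
  beta <- inside_chart(g, tokens)
  pi_arr <- array(0, dim = c(n, n, n_nt), dimnames = list(NULL, NULL, cnf$nts))
  bin <- cnf$binary
  for (j in seq_len(n)) {
    for (i in seq(j, 1L)) {
      # f = lexical base (single-token span) + (left child covers an exact
      # sub-span, prefix continues in the right child). Exact full-span
      # derivations are already inside the split term via pi of the right
      # child, so the full inside mass must not be added again.
      f <- if (i == j) beta[i, i, ] else numeric(n_nt)
      if (!is.null(bin) && j > i) {
        for (k in i:(j - 1L)) {
          pb <- beta[i, k, bin$b]
          pc <- pi_arr[k + 1L, j, bin$c]
          w <- bin$prob * pb * pc
          nz <- which(w != 0)
          for (m in nz) {
            id <- cnf$nt_id[[bin$lhs[m]]]
            f[id] <- f[id] + w[m]
          }
        }
      }
      pi_arr[i, j, ] <- as.numeric(cnf$R %*% f)
    }
  }
  pi_arr
}

#' Probability of a complete sentence
#'
#' @param g a `pcfg`; `tokens` the sentence.
#' @return `P(tokens)`: the summed probability of all derivations yielding
#'   exactly `tokens`.
#' @export
sentence_probability <- function(g, tokens) {
  tokens <- as.character(tokens)
  unknown <- setdiff(tokens, g$terminals)
  if (length(unknown)) {
    stop("out-of-vocabulary terminal(s): ", paste(unique(unknown), collapse = ", "))
  }
  beta <- inside_chart(g, tokens)
  unname(beta[1L, length(tokens), g$start])
}

#' Per-word surprisal under a grammar
#'
#' Surprisal of the word at `position` given its preceding context:
#' `log P(prefix up to position - 1) - log P(prefix up to position)` in the
#' chosen base. With `lambda = 0` (pure grammar) this is exact and may be
#' `Inf` when the word has zero conditional probability; the preceding
#' prefix must itself have positive probability. With `lambda > 0` the
#' conditional is interpolated with a uniform distribution over the
#' grammar's terminals, `p = (1 - lambda) * p_grammar + lambda / V`, which
#' keeps every surprisal finite — the behavior of a broad-coverage scorer —
#' at the cost of exactness.
#'
#' @param g a `pcfg`.
#' @param tokens full token sequence.
#' @param position word index (1-based).
#' @param base logarithm base (default `exp(1)`; use 2 for bits).
#' @param lambda uniform-interpolation weight in `[0, 1)` (default 0).
#' @return Non-negative surprisal value (for `lambda = 0`; interpolated
#'   surprisals are bounded by `log(V / lambda)`).
#' @export
word_surprisal <- function(g, tokens, position, base = exp(1), lambda = 0) {
  tokens <- as.character(tokens)
  stopifnot(position >= 1L, position <= length(tokens))
  if (lambda < 0 || lambda >= 1) stop("lambda must be in [0, 1)")
  known <- tokens[seq_len(position)] %in% g$terminals
  if (lambda == 0 && !all(known)) {
    stop("out-of-vocabulary terminal(s): ",
         paste(unique(tokens[seq_len(position)][!known]), collapse = ", "))
  }
  prev <- if (all(known[seq_len(position - 1L)])) {
    prefix_probability(g, tokens[seq_len(position - 1L)])
  } else 0
  cur <- if (all(known)) prefix_probability(g, tokens[seq_len(position)]) else 0
  cond <- if (prev > 0) cur / prev else 0
  if (lambda == 0) {
    if (prev == 0) {
      stop("prefix up to position ", position - 1L,
           " has zero probability; conditional surprisal undefined",
           " (use lambda > 0)")
    }
    -log(cond, base = base)
  } else {
    -log((1 - lambda) * cond + lambda / length(g$terminals), base = base)
  }
}

#' Surprisal profile of a full token sequence
#'
#' Computes every per-word surprisal in one chart pass and their mean. For
#' `lambda = 0` the per-word surprisals telescope: their sum equals
#' `-log P(sentence-as-prefix)`.
#'
#' @inheritParams word_surprisal
#' @param sentence_id identifier carried on the result.
#' @return A `surprisal_result`: list with `sentence_id`, `per_word`,
#'   `mean`, and `backend = "toy_pcfg"`.
#' @export
sentence_surprisal <- function(g, tokens, base = exp(1), lambda = 0,
                               sentence_id = NA_character_) {
  tokens <- as.character(tokens)
  n <- length(tokens)
  if (lambda < 0 || lambda >= 1) stop("lambda must be in [0, 1)")
  known <- tokens %in% g$terminals
  if (lambda == 0 && !all(known)) {
    stop("out-of-vocabulary terminal(s): ",
         paste(unique(tokens[!known]), collapse = ", "))
  }
  V <- length(g$terminals)
  # Prefix probabilities; unknown words zero out the rest of the chain.
  pp <- numeric(n + 1L)
  pp[1L] <- 1
  if (all(known)) {
    chart <- prefix_chart(g, tokens)
    pp[2:(n + 1L)] <- chart[1L, seq_len(n), g$start]
  } else {
    last_ok <- which(!known)[1] - 1L
    if (last_ok > 0L) {
      chart <- prefix_chart(g, tokens[seq_len(last_ok)])
      pp[2:(last_ok + 1L)] <- chart[1L, seq_len(last_ok), g$start]
    }
    # positions beyond the first unknown stay 0
  }
  cond <- ifelse(pp[seq_len(n)] > 0, pp[-1L] / pp[seq_len(n)], 0)
  if (lambda == 0) {
    # A zero-probability prefix strictly before the last word makes some
    # conditional undefined; only the final word may carry +Inf surprisal.
    if (any(pp[seq_len(n)] == 0)) {
      stop("prefix of length ", which(pp == 0)[1] - 1L,
           " has zero probability; conditional surprisal undefined",
           " (use lambda > 0)")
    }
    per_word <- -log(cond, base = base)
  } else {
    per_word <- -log((1 - lambda) * cond + lambda / V, base = base)
  }
  structure(
    list(sentence_id = sentence_id, per_word = as.numeric(per_word),
         mean = mean(per_word), backend = "toy_pcfg"),
    class = "surprisal_result"
  )
}

#' @export
print.surprisal_result <- function(x, ...) {
  cat("<surprisal_result ", x$backend, "> mean=", format(x$mean), " over ",
      length(x$per_word), " words\n", sep = "")
  invisible(x)
}

#' Mean surprisal from externally computed per-word values
#'
#' File-based backend: consumes a TSV of per-word surprisals produced by
#' any external scorer (a trained parser or a neural language model) with
#' columns `sentence_id`, `position`, `word`, `surprisal`, and averages the
#' values for one sentence after validating the alignment with the token
#' sequence.
#'
#' @param path TSV path (or a data frame already read).
#' @param sentence_id which sentence to score.
#' @param tokens the sentence's tokens, used to validate alignment.
#' @return A `surprisal_result` with `backend = "external_file"`.
#' @export
external_surprisal <- function(path, sentence_id, tokens) {
  d <- if (is.data.frame(path)) path else
    read.delim(path, stringsAsFactors = FALSE,
               colClasses = c(sentence_id = "character", word = "character"))
  d <- d[d$sentence_id == sentence_id, , drop = FALSE]
  d <- d[order(d$position), , drop = FALSE]
  tokens <- as.character(tokens)
  if (nrow(d) != length(tokens)) {
    stop("alignment error for sentence ", sentence_id, ": file has ",
         nrow(d), " words, tokens have ", length(tokens))
  }
  if (!all(d$word == tokens)) {
    stop("alignment error for sentence ", sentence_id,
         ": word mismatch at position ",
         which(d$word != tokens)[1])
  }
  structure(
    list(sentence_id = sentence_id, per_word = as.numeric(d$surprisal),
         mean = mean(d$surprisal), backend = "external_file"),
    class = "surprisal_result"
  )
}

#' Enumerate the full language of a finite grammar
#'
#' Exhaustively expands derivations (depth-first, with a derivation bound)
#' and returns each distinct sentence with its total probability. Intended
#' for small grammars; used as the independent oracle that the chart
#' algorithms are tested against.
#'
#' @param g a `pcfg`.
#' @param max_sentences abort if more than this many distinct sentences are
#'   produced.
#' @param max_length abort expansion of any derivation longer than this.
#' @return A tibble with columns `sentence` (space-joined) and `prob`.
#' @export
enumerate_language <- function(g, max_sentences = 100000L, max_length = 30L) {
  out <- new.env(parent = emptyenv())
  rules_by_lhs <- split(seq_len(nrow(g$rules)), g$rules$lhs)
  expand <- function(symbols, p) {
    nt_pos <- which(symbols %in% g$nonterminals)
    if (length(symbols) > max_length) {
      stop("derivation exceeded max_length = ", max_length,
           "; grammar language may be infinite")
    }
    if (length(nt_pos) == 0L) {
      key <- paste(symbols, collapse = " ")
      out[[key]] <- (out[[key]] %||% 0) + p
      if (length(ls(out)) > max_sentences) {
        stop("language exceeds max_sentences = ", max_sentences)
      }
      return(invisible())
    }
    i <- nt_pos[1]
    for (k in rules_by_lhs[[symbols[i]]]) {
      expand(append(symbols[-i], g$rules$rhs[[k]], after = i - 1L),
             p * g$rules$prob[k])
    }
  }
  expand(g$start, 1)
  keys <- ls(out)
  tibble::tibble(
    sentence = keys,
    prob = vapply(keys, function(k) out[[k]], numeric(1), USE.NAMES = FALSE)
  )
}
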