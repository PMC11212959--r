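# The incremental word-reordering paradigm as a deterministic state machine,
# plus the behavioral analyses: permissible-order checking, inclusion
# filters, verbatim accuracy, reconstruction grammaticality, rater QC.

#' Start an incremental-reordering trial
#'
#' A trial presents a stimulus one word at a time. Each newly revealed word
#' is appended to the participant's last submitted order; at every step the
#' participant may reorder the words currently on display. The trial is a
#' pure state machine: [reveal_next()] and [apply_reorder()] return updated
#' copies and record an event history, so logs are replayable.
#'
#' @param item_id item identifier.
#' @param condition condition label.
#' @param full_sequence character vector: the stimulus token sequence.
#' @param allowed_orders optional named list, step (as character) -> set of
#'   permissible orders (each a character vector or space-joined string);
#'   supplied for practice/filler items where feedback is given.
#' @return An object of class `synreco_trial`.
#' @export
synreco_trial <- function(item_id, condition, full_sequence,
                          allowed_orders = NULL) {
  structure(
    list(item_id = item_id, condition = condition,
         full_sequence = as.character(full_sequence),
         n_revealed = 0L, current_order = character(0),
         submissions = list(), allowed_orders = allowed_orders),
    class = "synreco_trial"
  )
}

#' @export
print.synreco_trial <- function(x, ...) {
  cat("<synreco_trial ", x$item_id, "/", x$condition, "> ",
      x$n_revealed, "/", length(x$full_sequence), " revealed: ",
      paste(x$current_order, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Has every word of a trial been revealed?
#' @param t a `synreco_trial`.
#' @export
trial_complete <- function(t) t$n_revealed == length(t$full_sequence)

#' Reveal the next word of a trial
#'
#' Appends the next stimulus word to the end of the current (last
#' submitted) order.
#'
#' @param t a `synreco_trial`.
#' @return The updated trial.
#' @export
reveal_next <- function(t) {
  if (trial_complete(t)) {
    stop("trial ", t$item_id, " is already complete (all ",
         length(t$full_sequence), " words revealed)")
  }
  t$n_revealed <- t$n_revealed + 1L
  t$current_order <- c(t$current_order, t$full_sequence[t$n_revealed])
  t
}

#' Reorder the words currently on display
#'
#' Replaces the displayed order with `new_order` and records the submission
#' at the current step. `new_order` must be a permutation of the multiset of
#' revealed words; duplicates are legal because only multiset identity is
#' checked.
#'
#' @param t a `synreco_trial`.
#' @param new_order character vector.
#' @return The updated trial.
#' @export
apply_reorder <- function(t, new_order) {
  new_order <- as.character(new_order)
  if (!identical(sort(new_order), sort(t$current_order))) {
    stop("illegal order for trial ", t$item_id, ": not a permutation of the ",
         t$n_revealed, " revealed words")
  }
  t$current_order <- new_order
  t$submissions[[length(t$submissions) + 1L]] <-
    list(step = t$n_revealed, order = new_order)
  t
}

#' Check the current order against the permissible set
#'
#' Practice and filler items carry, for each step, the set of word orders
#' human raters judged grammatical; this check backs the feedback those
#' items give. Any permissible order passes.
#'
#' @param t a `synreco_trial` whose `allowed_orders` covers the current step.
#' @return `TRUE` (pass) or `FALSE` (fail).
#' @export
check_order <- function(t) {
  key <- as.character(t$n_revealed)
  if (is.null(t$allowed_orders) || is.null(t$allowed_orders[[key]])) {
    stop("trial ", t$item_id, " has no permissible-order set for step ",
         t$n_revealed, "; order not checkable")
  }
  allowed <- vapply(t$allowed_orders[[key]], function(o)
    paste(as.character(o), collapse = " "), character(1))
  paste(t$current_order, collapse = " ") %in% allowed
}

#' Final submitted order of a completed trial
#' @param t a complete `synreco_trial`.
#' @export
final_order <- function(t) {
  if (!trial_complete(t)) {
    stop("trial ", t$item_id, " is incomplete (", t$n_revealed, "/",
         length(t$full_sequence), " words revealed)")
  }
  t$current_order
}

#' Participant log
#'
#' @param participant_id identifier.
#' @param trials list of completed `synreco_trial` objects (critical items).
#' @param attention_results logical vector: pass/fail on the 7 attention
#'   check items.
#' @param filler_results logical vector: pass/fail on the 12 remaining
#'   filler items.
#' @return An object of class `participant_log`.
#' @export
participant_log <- function(participant_id, trials, attention_results,
                            filler_results) {
  structure(
    list(participant_id = participant_id, trials = trials,
         attention_results = as.logical(attention_results),
         filler_results = as.logical(filler_results)),
    class = "participant_log"
  )
}

#' Participant inclusion filter
#'
#' A participant is included when they passed at least `min_attention` of
#' the 7 attention-check items AND at least `min_filler` of the 12
#' remaining filler items.
#'
#' @param p a `participant_log` with 7 attention and 12 filler results.
#' @param min_attention,min_filler inclusion thresholds (defaults 4 and 6).
#' @return `TRUE` to include, `FALSE` to exclude.
#' @export
include_participant <- function(p, min_attention = 4L, min_filler = 6L) {
  if (length(p$attention_results) != 7L || length(p$filler_results) != 12L ||
      anyNA(p$attention_results) || anyNA(p$filler_results)) {
    stop("malformed log for participant ", p$participant_id,
         ": need 7 complete attention results and 12 complete filler results")
  }
  sum(p$attention_results) >= min_attention &&
    sum(p$filler_results) >= min_filler
}

#' Verbatim reconstruction accuracy by condition
#'
#' For each completed trial, scores 1 when the final submitted order equals
#' the original (unscrambled) word order and 0 otherwise, then averages
#' within condition.
#'
#' @param trials list of completed `synreco_trial` objects.
#' @param originals named list/character mapping item_id -> original token
#'   sequence (character vector or space-joined string).
#' @return Tibble with columns `condition`, `accuracy`, `n_trials`.
#' @export
verbatim_accuracy <- function(trials, originals) {
  rows <- lapply(trials, function(t) {
    fin <- final_order(t)
    orig <- originals[[t$item_id]]
    if (is.null(orig)) stop("no original sentence for item ", t$item_id)
    if (length(orig) == 1L) orig <- strsplit(orig, " ", fixed = TRUE)[[1]]
    tibble::tibble(condition = t$condition,
                   correct = identical(fin, as.character(orig)))
  })
  d <- do.call(rbind, rows)
  agg <- aggregate(correct ~ condition, d, function(x) mean(x))
  n <- aggregate(correct ~ condition, d, length)
  tibble::tibble(condition = agg$condition, accuracy = agg$correct,
                 n_trials = n$correct)
}

#' Reconstruction grammaticality by condition
#'
#' Scores the grammatical well-formedness of participants' final submitted
#' orders as mean word surprisal under the supplied scorer, averaged within
#' condition, alongside the same score for the unreconstructed stimulus
#' sequences (the baseline the reconstructions are compared against).
#' Identical token sequences are scored once and cached, since final orders
#' concentrate on a few strings per item.
#'
#' @param trials list of completed `synreco_trial` objects.
#' @param scorer function(character vector of tokens) -> mean surprisal;
#'   e.g. `function(w) sentence_surprisal(g, w, lambda = 0.01)$mean`.
#' @return Tibble with columns `condition`, `reconstruction_surprisal`,
#'   `stimulus_surprisal`, `n_trials`.
#' @export
reconstruction_grammaticality <- function(trials, scorer) {
  cache <- new.env(parent = emptyenv())
  score <- function(tokens) {
    key <- paste(tokens, collapse = " ")
    if (is.null(cache[[key]])) cache[[key]] <- scorer(tokens)
    cache[[key]]
  }
  d <- do.call(rbind, lapply(trials, function(t) {
    tibble::tibble(
      condition = t$condition,
      reconstruction = score(final_order(t)),
      stimulus = score(t$full_sequence)
    )
  }))
  rec <- aggregate(reconstruction ~ condition, d, mean)
  sti <- aggregate(stimulus ~ condition, d, mean)
  n <- aggregate(reconstruction ~ condition, d, length)
  tibble::tibble(
    condition = rec$condition,
    reconstruction_surprisal = rec$reconstruction,
    stimulus_surprisal = sti$stimulus,
    n_trials = n$reconstruction
  )
}

#' Rater inclusion filter for the stimulus rating study
#'
#' A rater is included when (i) they used every point of the 1-5 Likert
#' scale at least once across their ratings, (ii) their mean grammaticality
#' rating of `Sentence` stimuli is at least 3, and (iii) their mean
#' grammaticality rating of `WordList` stimuli is at most 3.
#'
#' @param r a data frame with columns `condition`, `grammaticality`,
#'   `semantic` (both ratings in 1..5).
#' @param sentence_condition,wordlist_condition condition labels checked by
#'   criteria (ii)/(iii).
#' @return `TRUE` to include, `FALSE` to exclude.
#' @export
include_rater <- function(r, sentence_condition = "Sentence",
                          wordlist_condition = "WordList") {
  need <- c("condition", "grammaticality", "semantic")
  if (!all(need %in% names(r))) {
    stop("malformed rating record: need columns ", paste(need, collapse = ", "))
  }
  vals <- c(r$grammaticality, r$semantic)
  if (!all(vals %in% 1:5)) stop("ratings must be integers in 1..5")
  for (cond in c(sentence_condition, wordlist_condition)) {
    if (!any(r$condition == cond)) {
      stop("malformed rating record: no ratings for condition ", cond)
    }
  }
  used_full_scale <- all(1:5 %in% vals)
  s_mean <- mean(r$grammaticality[r$condition == sentence_condition])
  w_mean <- mean(r$grammaticality[r$condition == wordlist_condition])
  used_full_scale && s_mean >= 3 && w_mean <= 3
}

# ---- trial log serialization (JSON lines, one event per line) ----------

#' Write / read replayable trial logs as JSON lines
#'
#' Each line is one event: `{"participant": ..., "item": ..., "condition":
#' ..., "step": ..., "action": "reveal"|"reorder", "order": [...]}`. Reading
#' replays the events through the state machine, so any malformed log fails
#' loudly.
#'
#' @param logs list of `participant_log` objects.
#' @param path file path.
#' @export
write_synreco_logs <- function(logs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in logs) {
    for (t in p$trials) {
      step <- 0L
      order <- character(0)
      for (sub in replay_events(t)) {
        writeLines(as.character(jsonlite::toJSON(
          list(participant = p$participant_id, item = t$item_id,
               condition = t$condition, step = sub$step, action = sub$action,
               order = as.list(sub$order)),
          auto_unbox = TRUE)), con)
      }
    }
    meta <- list(participant = p$participant_id, item = NA, condition = NA,
                 step = NA, action = "summary",
                 order = list(),
                 attention = as.list(p$attention_results),
                 filler = as.list(p$filler_results))
    writeLines(as.character(jsonlite::toJSON(meta, auto_unbox = TRUE)), con)
  }
  invisible(path)
}

# Reconstruct the event stream of a completed trial from its submission
# history: reveal events interleaved with the recorded reorders.
replay_events <- function(t) {
  events <- list()
  order <- character(0)
  subs <- t$submissions
  si <- 1L
  for (step in seq_len(t$n_revealed)) {
    order <- c(order, t$full_sequence[step])
    events[[length(events) + 1L]] <-
      list(step = step, action = "reveal", order = order)
    while (si <= length(subs) && subs[[si]]$step == step) {
      order <- subs[[si]]$order
      events[[length(events) + 1L]] <-
        list(step = step, action = "reorder", order = order)
      si <- si + 1L
    }
  }
  events
}

#' @rdname write_synreco_logs
#' @export
read_synreco_logs <- function(path) {
  lines <- readLines(path)
  events <- lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
  logs <- list()
  trials <- list()
  cur_key <- NULL
  cur_trial <- NULL
  flush_trial <- function() {
    if (!is.null(cur_trial)) trials[[length(trials) + 1L]] <<- cur_trial
    cur_trial <<- NULL
    cur_key <<- NULL
  }
  for (e in events) {
    if (identical(e$action, "summary")) {
      flush_trial()
      logs[[length(logs) + 1L]] <- participant_log(
        e$participant, trials,
        unlist(e$attention), unlist(e$filler)
      )
      trials <- list()
    } else if (identical(e$action, "reveal")) {
      key <- paste(e$participant, e$item)
      if (!identical(key, cur_key)) {
        flush_trial()
        cur_key <- key
        cur_trial <- synreco_trial(e$item, e$condition, character(0))
      }
      # reveal: extend the known full sequence by the appended word
      new_word <- e$order[length(e$order)]
      cur_trial$full_sequence <- c(cur_trial$full_sequence, new_word)
      cur_trial <- reveal_next(cur_trial)
    } else if (identical(e$action, "reorder")) {
      cur_trial <- apply_reorder(cur_trial, e$order)
    } else {
      stop("unknown log action: ", e$action)
    }
  }
  flush_trial()
  if (length(trials)) {
    stop("trailing trials without a participant summary line")
  }
  logs
}
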