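# Counterbalanced list construction, blocked run schedules, trial timelines,
# and memory-probe assignment.

#' Design specification
#'
#' Holds the timing and layout constants of the blocked reading design.
#' Defaults: 12 words per trial at 350 ms each, a 300 ms blank, a 1000 ms
#' memory probe, and a 500 ms trailing blank (a 6 s trial; 3-trial blocks
#' of 18 s); 2 blocks per condition per run and 5 fixation blocks of 12 s.
#'
#' @param words_per_trial,word_ms,isi_blank_ms,probe_ms,end_blank_ms trial
#'   event layout (counts / milliseconds).
#' @param trials_per_block trials per block (same condition within block).
#' @param blocks_per_condition_per_run,fixation_blocks_per_run run layout.
#' @param fixation_block_s fixation block duration in seconds.
#' @return A `design_spec` list.
#' @export
design_spec <- function(words_per_trial = 12L, word_ms = 350, isi_blank_ms = 300,
                        probe_ms = 1000, end_blank_ms = 500,
                        trials_per_block = 3L,
                        blocks_per_condition_per_run = 2L,
                        fixation_blocks_per_run = 5L,
                        fixation_block_s = 12) {
  spec <- list(
    words_per_trial = as.integer(words_per_trial), word_ms = word_ms,
    isi_blank_ms = isi_blank_ms, probe_ms = probe_ms,
    end_blank_ms = end_blank_ms, trials_per_block = as.integer(trials_per_block),
    blocks_per_condition_per_run = as.integer(blocks_per_condition_per_run),
    fixation_blocks_per_run = as.integer(fixation_blocks_per_run),
    fixation_block_s = fixation_block_s
  )
  dur <- unlist(spec[c("word_ms", "isi_blank_ms", "probe_ms", "end_blank_ms",
                       "fixation_block_s")])
  if (any(dur <= 0)) stop("all durations must be positive")
  structure(spec, class = "design_spec")
}

#' Latin-square experimental lists
#'
#' Distributes `n_items x n_conditions` stimulus versions across
#' `n_lists = n_conditions` lists so that each list contains every item
#' exactly once, each item appears in a different condition on every list,
#' and per-list condition counts are equal. Item count must be divisible by
#' the number of lists.
#'
#' @param items character vector of item ids.
#' @param conditions character vector of condition labels being rotated.
#' @param n_lists number of lists (defaults to `length(conditions)`).
#' @return Tibble with columns `list_id`, `item_id`, `condition`.
#' @export
build_latin_square_lists <- function(items, conditions,
                                     n_lists = length(conditions)) {
  n_items <- length(items)
  k <- length(conditions)
  if (n_lists != k) {
    stop("n_lists (", n_lists, ") must equal the number of condition versions (",
         k, ")")
  }
  if (n_items %% n_lists != 0L) {
    stop("item count (", n_items, ") not divisible by the number of lists (",
         n_lists, ")")
  }
  rows <- lapply(seq_len(n_lists), function(l) {
    cond_idx <- ((seq_len(n_items) + l - 2L) %% k) + 1L
    tibble::tibble(list_id = l, item_id = items,
                   condition = conditions[cond_idx])
  })
  do.call(rbind, rows)
}

#' Trial timeline
#'
#' Event-level schedule of one trial: the word stream, the inter-stimulus
#' blank, the memory probe, and the trailing blank. The trial duration is
#' recomputed from the event timeline.
#'
#' @param spec a `design_spec`.
#' @return Tibble with columns `event`, `onset_ms`, `duration_ms`; total
#'   duration is `sum(duration_ms)` (6000 ms under the defaults).
#' @export
schedule_trial <- function(spec = design_spec()) {
  ev <- tibble::tibble(
    event = c(paste0("word_", seq_len(spec$words_per_trial)),
              "isi_blank", "probe", "end_blank"),
    duration_ms = c(rep(spec$word_ms, spec$words_per_trial),
                    spec$isi_blank_ms, spec$probe_ms, spec$end_blank_ms)
  )
  ev$onset_ms <- cumsum(c(0, ev$duration_ms[-nrow(ev)]))
  ev[, c("event", "onset_ms", "duration_ms")]
}

#' Divide a list into blocked, fixation-interleaved runs
#'
#' Splits one experimental list into runs with equal per-condition counts,
#' groups each run's stimuli into blocks of `trials_per_block` same-condition
#' trials, orders the blocks with a seeded permutation under the constraint
#' that the two blocks of a condition are never adjacent, and interleaves
#' fixation blocks (one at run start, then one after every 4 experimental
#' blocks). Every stimulus is used exactly once.
#'
#' @param list_df tibble with columns `item_id`, `condition` (one
#'   experimental list).
#' @param n_runs number of scanning runs.
#' @param spec a `design_spec`.
#' @param seed integer seed for block ordering and run splitting.
#' @return List of run schedules; each is a list with `blocks` (tibble:
#'   `block`, `block_type`, `condition`, `onset_s`, `duration_s`), `trials`
#'   (tibble: `block`, `condition`, `item_id`, `onset_s`), and
#'   `total_duration_s`.
#' @export
build_runs <- function(list_df, n_runs, spec = design_spec(), seed = 1L) {
  conds <- unique(list_df$condition)
  per_cond <- table(list_df$condition)
  if (length(unique(per_cond)) != 1L) {
    stop("unequal per-condition counts in list")
  }
  per_cond_per_run <- unname(per_cond[1]) / n_runs
  if (per_cond_per_run %% 1 != 0) {
    stop("per-condition count (", per_cond[1],
         ") not divisible by n_runs (", n_runs, ")")
  }
  if (per_cond_per_run %% spec$trials_per_block != 0) {
    stop("per-condition per-run count (", per_cond_per_run,
         ") not divisible by trials_per_block (", spec$trials_per_block, ")")
  }
  blocks_per_cond <- per_cond_per_run / spec$trials_per_block
  with_seed(seed, {
    # Assign stimuli of each condition to runs, shuffled.
    assignments <- lapply(conds, function(cn) {
      ids <- sample(list_df$item_id[list_df$condition == cn])
      split(ids, rep(seq_len(n_runs), each = per_cond_per_run))
    })
    names(assignments) <- conds
    lapply(seq_len(n_runs), function(r) {
      # blocks: blocks_per_cond per condition, trials_per_block stimuli each
      block_defs <- list()
      for (cn in conds) {
        ids <- assignments[[cn]][[r]]
        for (b in seq_len(blocks_per_cond)) {
          sel <- ids[((b - 1L) * spec$trials_per_block + 1L):
                       (b * spec$trials_per_block)]
          block_defs[[length(block_defs) + 1L]] <-
            list(condition = cn, items = sel)
        }
      }
      ord <- nonadjacent_order(
        vapply(block_defs, `[[`, character(1), "condition"))
      block_defs <- block_defs[ord]
      assemble_run(block_defs, spec)
    })
  })
}

# Seeded permutation of block indices such that equal-condition blocks are
# never adjacent (rejection sampling; the layouts used have many valid
# orders).
nonadjacent_order <- function(conditions, max_tries = 1000L) {
  n <- length(conditions)
  for (try in seq_len(max_tries)) {
    ord <- sample.int(n)
    if (!any(conditions[ord][-1] == conditions[ord][-n])) return(ord)
  }
  stop("could not find a block order without adjacent same-condition blocks")
}

assemble_run <- function(block_defs, spec) {
  trial_s <- sum(schedule_trial(spec)$duration_ms) / 1000
  block_s <- trial_s * spec$trials_per_block
  n_exp <- length(block_defs)
  # fixation placement: run start, then after every 4 experimental blocks
  seq_types <- character(0)
  exp_i <- 0L
  fix_left <- spec$fixation_blocks_per_run
  seq_types <- c(seq_types, "fixation"); fix_left <- fix_left - 1L
  while (exp_i < n_exp) {
    take <- min(4L, n_exp - exp_i)
    seq_types <- c(seq_types, rep("experimental", take))
    exp_i <- exp_i + take
    if (fix_left > 0L) { seq_types <- c(seq_types, "fixation"); fix_left <- fix_left - 1L }
  }
  while (fix_left > 0L) { seq_types <- c(seq_types, "fixation"); fix_left <- fix_left - 1L }
  onset <- 0
  bi <- 0L
  blocks <- list(); trials <- list()
  for (ty in seq_types) {
    if (ty == "fixation") {
      blocks[[length(blocks) + 1L]] <- tibble::tibble(
        block = length(blocks) + 1L, block_type = "fixation",
        condition = NA_character_, onset_s = onset,
        duration_s = spec$fixation_block_s)
      onset <- onset + spec$fixation_block_s
    } else {
      bi <- bi + 1L
      bd <- block_defs[[bi]]
      blocks[[length(blocks) + 1L]] <- tibble::tibble(
        block = length(blocks) + 1L, block_type = "experimental",
        condition = bd$condition, onset_s = onset, duration_s = block_s)
      for (k in seq_along(bd$items)) {
        trials[[length(trials) + 1L]] <- tibble::tibble(
          block = length(blocks), condition = bd$condition,
          item_id = bd$items[k], onset_s = onset + (k - 1L) * trial_s)
      }
      onset <- onset + block_s
    }
  }
  list(blocks = do.call(rbind, blocks), trials = do.call(rbind, trials),
       total_duration_s = onset)
}

#' Assign memory probes to a run's trials
#'
#' For each condition, exactly half of the trials receive a matching probe
#' (the stimulus's final token); the other half receive the final token of
#' a same-condition stimulus from a different block of the same run.
#' Per-condition trial counts must be even and each condition must occupy
#' at least two blocks.
#'
#' @param run a run schedule from [build_runs()].
#' @param stimuli named list mapping item_id -> token character vector (used
#'   for final tokens).
#' @param seed integer seed.
#' @return The run's `trials` tibble with added columns `probe` and
#'   `probe_match`.
#' @export
assign_probes <- function(run, stimuli, seed = 1L) {
  trials <- run$trials
  trials$probe <- NA_character_
  trials$probe_match <- NA
  last_tok <- function(id) {
    w <- stimuli[[id]]
    if (is.null(w)) stop("no stimulus tokens for item ", id)
    w <- surfaces(w)
    w[length(w)]
  }
  with_seed(seed, {
    for (cn in unique(trials$condition)) {
      idx <- which(trials$condition == cn)
      if (length(idx) %% 2L != 0L) {
        stop("odd trial count (", length(idx), ") for condition ", cn)
      }
      if (length(unique(trials$block[idx])) < 2L) {
        stop("condition ", cn, " occupies a single block; cannot draw",
             " different-block probes")
      }
      match_idx <- sample(idx, length(idx) / 2L)
      for (i in match_idx) {
        trials$probe[i] <- last_tok(trials$item_id[i])
        trials$probe_match[i] <- TRUE
      }
      for (i in setdiff(idx, match_idx)) {
        donors <- idx[trials$block[idx] != trials$block[i]]
        don <- donors[sample.int(length(donors), 1L)]
        trials$probe[i] <- last_tok(trials$item_id[don])
        trials$probe_match[i] <- FALSE
      }
    }
  })
  trials
}

#' Write a run's trials as a BIDS-style events TSV
#'
#' Columns: onset, duration, trial_type, stimulus, probe, probe_match.
#'
#' @param trials a trials tibble (with probes assigned) from a run.
#' @param stimuli named list mapping item_id -> token vector.
#' @param spec a `design_spec`.
#' @param path file path.
#' @export
write_run_events <- function(trials, stimuli, path, spec = design_spec()) {
  trial_s <- sum(schedule_trial(spec)$duration_ms) / 1000
  d <- data.frame(
    onset = trials$onset_s,
    duration = trial_s,
    trial_type = trials$condition,
    stimulus = vapply(trials$item_id, function(id)
      paste(surfaces(stimuli[[id]]), collapse = " "), character(1)),
    probe = if (is.null(trials$probe)) NA_character_ else trials$probe,
    probe_match = if (is.null(trials$probe_match)) NA else trials$probe_match
  )
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
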