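test_that("trial state machine reveals, reorders, and guards legality", {
  t <- synreco_trial("i1", "Scrambled1", c("this", "a", "is", "nice"))
  t <- reveal_next(t)
  expect_equal(t$current_order, "this")
  t <- reveal_next(t)
  expect_equal(t$current_order, c("this", "a"))
  # "a this" is no better; reveal "is", then reorder to the grammatical order
  t <- reveal_next(t)
  expect_equal(t$current_order, c("this", "a", "is"))
  t <- apply_reorder(t, c("this", "is", "a"))
  expect_equal(t$current_order, c("this", "is", "a"))
  expect_equal(t$submissions[[1]]$step, 3L)
  # identity reorder is accepted and recorded
  t <- apply_reorder(t, t$current_order)
  expect_length(t$submissions, 2L)
  # non-permutations and unseen words are rejected
  expect_error(apply_reorder(t, c("this", "is")), "not a permutation")
  expect_error(apply_reorder(t, c("this", "is", "nice")), "not a permutation")
  t <- reveal_next(t)
  expect_equal(t$current_order, c("this", "is", "a", "nice"))
  expect_true(trial_complete(t))
  expect_error(reveal_next(t), "already complete")
})

test_that("check_order accepts any permissible order and only those", {
  allowed <- list(`3` = list(c("this", "is", "a")),
                  `2` = list(c("books", "and"), c("and", "books")))
  t <- synreco_trial("p1", "practice", c("this", "a", "is"),
                     allowed_orders = allowed)
  t <- reveal_next(reveal_next(reveal_next(t)))
  expect_false(check_order(t))                 # "this a is"
  t <- apply_reorder(t, c("this", "is", "a"))
  expect_true(check_order(t))
  # multiple permissible orders at one step
  t2 <- synreco_trial("p2", "practice", c("books", "and"),
                      allowed_orders = allowed)
  t2 <- reveal_next(reveal_next(t2))
  expect_true(check_order(t2))                 # "books and"
  t2 <- apply_reorder(t2, c("and", "books"))
  expect_true(check_order(t2))
  # missing permissible set is an error, not a silent pass
  t3 <- reveal_next(synreco_trial("c1", "Intact", c("a", "b")))
  expect_error(check_order(t3), "not checkable")
})

test_that("display multiset always equals the revealed multiset (fuzz)", {
  set.seed(77)
  for (rep in 1:20) {
    seqn <- sample(letters[1:6], 8, replace = TRUE)
    t <- synreco_trial("f", "fuzz", seqn)
    while (!trial_complete(t)) {
      t <- reveal_next(t)
      if (runif(1) < 0.5) t <- apply_reorder(t, sample(t$current_order))
      expect_equal(sort(t$current_order),
                   sort(seqn[seq_len(t$n_revealed)]))
    }
  }
})

test_that("participant inclusion applies both thresholds with boundaries", {
  mk <- function(att, fil) participant_log(
    "p", list(), c(rep(TRUE, att), rep(FALSE, 7 - att)),
    c(rep(TRUE, fil), rep(FALSE, 12 - fil)))
  expect_true(include_participant(mk(5, 8)))
  expect_true(include_participant(mk(4, 6)))    # boundary: "at least"
  expect_false(include_participant(mk(3, 12)))  # attention fails alone
  expect_false(include_participant(mk(7, 5)))   # fillers fail alone
  expect_error(include_participant(participant_log("p", list(), TRUE, TRUE)),
               "malformed")
  # monotonicity: flipping any fail to a pass never flips include -> exclude
  set.seed(3)
  for (rep in 1:20) {
    att <- runif(7) < 0.6; fil <- runif(12) < 0.6
    base <- include_participant(participant_log("p", list(), att, fil))
    i <- sample.int(7, 1); att2 <- att; att2[i] <- TRUE
    j <- sample.int(12, 1); fil2 <- fil; fil2[j] <- TRUE
    up <- include_participant(participant_log("p", list(), att2, fil2))
    expect_true(!base || up)
  }
})

test_that("verbatim accuracy is exact on degenerate participants", {
  ss <- gen_base_sentences(4, 12, seed = 51)
  orig <- setNames(lapply(ss, surfaces),
                   vapply(ss, function(x) x$item_id, character(1)))
  stim <- c(lapply(ss, intact), lapply(ss, backward))
  # skill 1: every final order is verbatim in every condition
  logs1 <- simulate_synreco_logs(stim, orig, 3, skill = c(Intact = 1, Backward = 1),
                                 seed = 61)
  tr1 <- unlist(lapply(logs1, `[[`, "trials"), recursive = FALSE)
  acc1 <- verbatim_accuracy(tr1, orig)
  expect_equal(acc1$accuracy, c(1, 1))
  # skill 0: never reorders, so Intact is verbatim, Backward never is
  logs0 <- simulate_synreco_logs(stim, orig, 3, skill = c(Intact = 0, Backward = 0),
                                 seed = 62)
  tr0 <- unlist(lapply(logs0, `[[`, "trials"), recursive = FALSE)
  acc0 <- verbatim_accuracy(tr0, orig)
  expect_equal(acc0$accuracy[acc0$condition == "Intact"], 1)
  expect_equal(acc0$accuracy[acc0$condition == "Backward"], 0)
  # final orders equal the stimulus orders exactly under skill 0
  for (t in tr0) expect_identical(final_order(t), t$full_sequence)
  # incomplete trials are rejected
  t_inc <- reveal_next(synreco_trial(ss[[1]]$item_id, "Intact", surfaces(ss[[1]])))
  expect_error(verbatim_accuracy(list(t_inc), orig), "incomplete")
})

test_that("reconstruction grammaticality reduces to the stimulus baseline for no-op participants", {
  g <- toy_grammar()
  scorer <- function(w) sentence_surprisal(g, w, lambda = 0.01)$mean
  ss <- gen_base_sentences(3, 12, seed = 71)
  orig <- setNames(lapply(ss, surfaces),
                   vapply(ss, function(x) x$item_id, character(1)))
  stim <- c(lapply(ss, intact),
            lapply(seq_along(ss), function(i) scramble_local(ss[[i]], 3L, i)))
  skill0 <- c(Intact = 0, Scrambled3 = 0)
  logs <- simulate_synreco_logs(stim, orig, 2, skill = skill0, seed = 81)
  tr <- unlist(lapply(logs, `[[`, "trials"), recursive = FALSE)
  rg <- reconstruction_grammaticality(tr, scorer)
  expect_equal(rg$reconstruction_surprisal, rg$stimulus_surprisal)
  # perfect reconstructions score like the intact stimuli
  skill1 <- c(Intact = 1, Scrambled3 = 1)
  logs1 <- simulate_synreco_logs(stim, orig, 2, skill = skill1, seed = 82)
  tr1 <- unlist(lapply(logs1, `[[`, "trials"), recursive = FALSE)
  rg1 <- reconstruction_grammaticality(tr1, scorer)
  expect_equal(rg1$reconstruction_surprisal[rg1$condition == "Scrambled3"],
               rg1$stimulus_surprisal[rg1$condition == "Intact"])
})

test_that("rater inclusion needs the full scale and sane anchor conditions", {
  mk <- function(gram_s, gram_w, extra_gram = integer(0)) {
    n_s <- length(gram_s); n_w <- length(gram_w); n_e <- length(extra_gram)
    data.frame(
      condition = c(rep("Sentence", n_s), rep("WordList", n_w),
                    rep("Nonsense", n_e)),
      grammaticality = c(gram_s, gram_w, extra_gram),
      semantic = rep(c(1, 2, 3, 4, 5), length.out = n_s + n_w + n_e)
    )
  }
  expect_true(include_rater(mk(c(4, 5, 4), c(2, 1, 2))))
  # never uses rating 5 anywhere
  r <- mk(c(4, 4, 4), c(2, 1, 2))
  r$semantic <- rep(c(1, 2, 3, 4), length.out = nrow(r))
  expect_false(include_rater(r))
  # Sentence grammaticality mean below 3
  expect_false(include_rater(mk(c(3, 3, 2), c(1, 1, 5))))   # mean 2.67
  # WordList grammaticality mean above 3 (a mean of exactly 3 is allowed)
  expect_false(include_rater(mk(c(5, 4, 5), c(4, 4, 3))))
  expect_true(include_rater(mk(c(5, 4, 5), c(4, 4, 1))))
  expect_error(include_rater(data.frame(condition = "Sentence",
                                        grammaticality = 4, semantic = 6)),
               "1..5")
  expect_error(include_rater(mk(c(4, 5), integer(0))), "WordList")
})

test_that("JSONL trial logs replay to identical analyses", {
  ss <- gen_base_sentences(3, 12, seed = 91)
  orig <- setNames(lapply(ss, surfaces),
                   vapply(ss, function(x) x$item_id, character(1)))
  stim <- c(lapply(ss, intact), lapply(ss, backward),
            lapply(seq_along(ss), function(i) scramble_local(ss[[i]], 5L, i)))
  logs <- simulate_synreco_logs(stim, orig, 3,
                                skill = c(Intact = 0.9, Backward = 0.1,
                                          Scrambled5 = 0.6), seed = 95)
  p <- tempfile(fileext = ".jsonl")
  on.exit(unlink(p))
  write_synreco_logs(logs, p)
  back <- read_synreco_logs(p)
  expect_length(back, 3L)
  expect_equal(back[[1]]$participant_id, logs[[1]]$participant_id)
  expect_equal(back[[2]]$attention_results, logs[[2]]$attention_results)
  tr_a <- unlist(lapply(logs, `[[`, "trials"), recursive = FALSE)
  tr_b <- unlist(lapply(back, `[[`, "trials"), recursive = FALSE)
  expect_equal(lapply(tr_b, final_order), lapply(tr_a, final_order))
  expect_equal(verbatim_accuracy(tr_b, orig), verbatim_accuracy(tr_a, orig))
})
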