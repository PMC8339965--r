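test_that("the generator is byte-identical for a fixed seed", {
  g1 <- generate_corpus(generator_config(seed = 7, n_children = 4))
  g2 <- generate_corpus(generator_config(seed = 7, n_children = 4))
  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  write_corpus(g1$clean, f1)
  write_corpus(g2$clean, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(as.data.frame(g1$verbatim), as.data.frame(g2$verbatim))
})

test_that("clean and verbatim variants share gold scores item by item", {
  g <- generate_corpus(generator_config(seed = 3, n_children = 5))
  key <- function(x) paste(x$child_id, x$subtest, x$item_index)
  expect_equal(key(g$clean), key(g$verbatim))
  expect_equal(g$clean$gold_score, g$verbatim$gold_score)
})

test_that("chatter_prob 1 makes every verbatim response longer in tokens", {
  g <- generate_corpus(generator_config(seed = 9, n_children = 3,
                                        chatter_prob = 1))
  n_clean <- vapply(g$clean$response_text,
                    function(t) length(normalize_tokens(t)), integer(1))
  n_verb <- vapply(g$verbatim$response_text,
                   function(t) length(normalize_tokens(t)), integer(1))
  expect_true(all(n_verb > n_clean))
})

test_that("stimulus banks carry labeled exemplars with the canonical items", {
  ev <- build_stimulus_bank("EV", 27, seed = 1)
  expect_length(ev$stimuli, 27)
  expect_equal(length(unique(vapply(ev$stimuli, `[[`, character(1),
                                    "stimulus_id"))), 27)
  lime <- ev$stimuli[[1]]
  expect_equal(lime$prompt, "lime")
  expect_true("lime" %in% lime$exemplars[["2"]])
  expect_true("fruit" %in% lime$exemplars[["1"]])
  ws <- build_stimulus_bank("WS", 10, seed = 1)
  fix <- ws$stimuli[[1]]
  expect_match(fix$prompt, "fixed$")
  expect_true("fixed" %in% fix$exemplars[["1"]])
  expect_true("fix" %in% fix$exemplars[["0"]])
  # every class has >= 1 exemplar and classes never share an exemplar string
  for (code in c("EV", "WS", "FS")) {
    bank <- build_stimulus_bank(code, 5, seed = 2)
    classes <- as.character(subtest_params(code)$score_classes)
    for (stim in bank$stimuli) {
      expect_setequal(names(stim$exemplars), classes)
      all_ex <- unlist(stim$exemplars)
      expect_gte(min(lengths(stim$exemplars)), 1)
      expect_equal(anyDuplicated(all_ex), 0)
    }
  }
})

test_that("error injection produces exactly the requested error count", {
  target <- normalize_tokens("the small boat drifted past a green island")
  expect_equal(inject_rs_errors(target, 0, c(1, 0, 0), 0, seed = 4), target)
  # a repetition alone is not an error
  resp <- inject_rs_errors(c("the", "quick", "fox"), 0, c(1, 0, 0), 1,
                           seed = 5)
  expect_gt(length(resp), 3)
  expect_equal(align_tokens(collapse_repetitions(resp),
                            c("the", "quick", "fox"))$total_errors, 0L)
  # all-substitution mix: alignment must report exactly 2 substitutions
  resp <- inject_rs_errors(target, 2, c(0, 0, 1), 0, seed = 6)
  ops <- align_tokens(collapse_repetitions(resp), target)
  expect_equal(ops$substitutions, 2L)
  expect_equal(ops$insertions, 0L)
  expect_equal(ops$deletions, 0L)
  # infeasible request errors out
  expect_error(inject_rs_errors(c("a", "b"), 5, c(0, 1, 0), 0, seed = 7),
               "insertions")
})

test_that("generated RS items reproduce their gold scores under the rule scorer", {
  g <- generate_corpus(generator_config(seed = 21, n_children = 8))
  rs <- g$clean[g$clean$subtest == "RS", ]
  got <- vapply(seq_len(nrow(rs)), function(i) {
    rs_item_score(rs$response_text[i], rs$prompt_text[i])
  }, integer(1))
  expect_equal(got, rs$gold_score)
})

test_that("empirical score distributions match the configured ones", {
  cfg <- generator_config(seed = 33, n_children = 60, zero_run_prob = 0)
  g <- generate_corpus(cfg)
  for (code in subtest_codes()) {
    rows <- g$clean[g$clean$subtest == code, ]
    expect_gte(nrow(rows), 1000)
    classes <- subtest_params(code)$score_classes
    obs <- tabulate(rows$gold_score + 1L, nbins = length(classes))
    p <- suppressWarnings(
      stats::chisq.test(obs, p = cfg$score_dist[[code]])$p.value)
    expect_gt(p, 0.01)
  }
})

test_that("default corpora exercise every discontinuation rule", {
  g <- generate_corpus(generator_config(seed = 2, n_children = 40))
  for (code in c("EV", "RS", "FS")) {
    run <- subtest_params(code)$discontinuation_run
    triggered <- FALSE
    for (cid in unique(g$clean$child_id)) {
      scores <- g$clean$gold_score[g$clean$child_id == cid &
                                     g$clean$subtest == code]
      if (!is.na(apply_discontinuation(scores, code)$discontinued_at)) {
        triggered <- TRUE
        break
      }
    }
    expect_true(triggered, label = paste("discontinuation triggered for", code))
  }
  # WS administrations are never truncated
  ws_lens <- table(g$clean$child_id[g$clean$subtest == "WS"])
  expect_true(all(ws_lens == subtest_params("WS")$max_items))
})
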