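test_that("classification metrics match hand-computed confusion matrices", {
  perfect <- classification_metrics(c(0, 1, 2), c(0, 1, 2))
  expect_equal(unname(perfect), c(1, 1, 1))
  m <- classification_metrics(c(0, 0, 1, 1), c(0, 1, 0, 1), "macro")
  expect_equal(unname(m), c(0.5, 0.5, 0.5))
  expect_error(classification_metrics(c(0, 1), c(0, 1, 2)), "length")
})

test_that("support-weighted recall equals accuracy on random confusions", {
  set.seed(55)
  for (trial in 1:20) {
    k <- sample(2:4, 1)
    n <- sample(10:60, 1)
    gold <- sample(seq_len(k) - 1L, n, replace = TRUE)
    pred <- sample(seq_len(k) - 1L, n, replace = TRUE)
    m <- classification_metrics(gold, pred, "weighted")
    expect_equal(m[["recall"]], m[["accuracy"]])
  }
})

test_that("macro metrics are invariant under class relabeling", {
  gold <- c(0, 0, 1, 2, 2, 1, 0)
  pred <- c(0, 1, 1, 2, 1, 1, 2)
  m1 <- classification_metrics(gold, pred, "macro")
  relabel <- c(`0` = 5, `1` = 9, `2` = 7)
  m2 <- classification_metrics(relabel[as.character(gold)],
                               relabel[as.character(pred)], "macro")
  expect_equal(m1, m2)
})

test_that("tier MAE aligns frames on their keys and pools items", {
  corpus <- tiny_corpus(c(2, 1, 0))
  corpus$item_score <- corpus$gold_score
  expect_equal(tier_mae(corpus, corpus, "item"), 0)
  fifty <- tiny_corpus(rep(1L, 50))
  fifty$item_score <- fifty$gold_score
  off <- fifty
  off$item_score[7] <- off$item_score[7] + 2L
  expect_equal(tier_mae(fifty, off, "item"), 0.04)
  g <- tibble::tibble(child_id = c("a", "b"), subtest = "EV",
                      raw = c(10L, 20L))
  p <- tibble::tibble(child_id = c("a", "b"), subtest = "EV",
                      raw = c(12L, 19L))
  expect_equal(tier_mae(g, p, "raw"), 1.5)
  expect_error(tier_mae(g, p[1, ], "raw"), "misaligned")
})

test_that("Spearman handles ties, reversal, and zero variance", {
  expect_equal(spearman_rho(1:10, 1:10), 1)
  expect_equal(spearman_rho(1:10, 10:1), -1)
  expect_equal(spearman_rho(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_true(is.na(spearman_rho(c(1, 1, 1), c(1, 2, 3))))
  expect_error(spearman_rho(1:2, 1:2), "at least 3")
})

test_that("cross-validation partitions children into disjoint exhaustive folds", {
  g <- generate_corpus(generator_config(seed = 23, n_children = 10,
                                        zero_run_prob = 0))
  cl <- g$clean[g$clean$subtest %in% c("EV", "WS"), ]
  rep <- cross_validate(cl, "ngram", train_config(seed = 1),
                        eval_config(n_folds = 5, n_repetitions = 2, seed = 4))
  # every item of every child predicted exactly once per repetition
  for (r in 1:2) {
    preds <- rep$predictions[rep$predictions$rep == r, ]
    expect_equal(nrow(preds), nrow(cl))
    expect_false(any(is.na(preds$predicted)))
  }
  # deterministic for a fixed seed
  rep2 <- cross_validate(cl, "ngram", train_config(seed = 1),
                         eval_config(n_folds = 5, n_repetitions = 2, seed = 4))
  expect_equal(as.data.frame(rep$summary), as.data.frame(rep2$summary))
  expect_error(
    cross_validate(cl, "ngram", train_config(),
                   eval_config(n_folds = 50, n_repetitions = 1)),
    "folds"
  )
})

test_that("gold scores fed through the harness give perfect metrics", {
  g <- generate_corpus(generator_config(seed = 25, n_children = 8))
  scored <- g$clean
  scored$item_score <- scored$gold_score
  tab <- small_built_norms()
  metrics <- elscore:::rep_metrics(scored, tab, "weighted", "scored", 1L)
  acc <- metrics$value[metrics$metric == "accuracy"]
  expect_true(all(acc == 1))
  mae <- metrics$value[metrics$metric == "mae"]
  expect_true(all(mae == 0))
  rho <- metrics$value[metrics$metric == "spearman"]
  expect_equal(rho[!is.na(rho)], rep(1, sum(!is.na(rho))))
})

test_that("subgroup reports stratify the same predictions without retraining", {
  g <- generate_corpus(generator_config(seed = 26, n_children = 10,
                                        zero_run_prob = 0, td_prob = 0.5))
  cl <- g$clean[g$clean$subtest == "WS", ]
  rep <- cross_validate(cl, "ngram", train_config(seed = 1),
                        eval_config(n_folds = 5, n_repetitions = 1, seed = 2))
  by_group <- subgroup_report(rep)
  expect_setequal(unique(by_group$group), c("TD", "nonTD"))
  # one group's items, pooled, must reproduce the overall count
  preds <- rep$predictions
  expect_equal(sum(preds$group == "TD") + sum(preds$group == "nonTD"),
               nrow(preds))
  # with a single group the stratified metrics equal the unstratified ones
  one <- cl
  one$group <- "ALL"
  rep1 <- cross_validate(one, "ngram", train_config(seed = 1),
                         eval_config(n_folds = 5, n_repetitions = 1, seed = 2))
  bg <- subgroup_report(rep1)
  overall <- rep1$summary
  acc_strat <- bg$mean[bg$metric == "accuracy" & bg$subtest == "WS"]
  acc_overall <- overall$mean[overall$metric == "accuracy" &
                                overall$subtest == "WS"]
  expect_equal(acc_strat, acc_overall)
})

test_that("label noise degrades accuracy and inflates MAE monotonically", {
  g <- generate_corpus(generator_config(seed = 27, n_children = 12,
                                        zero_run_prob = 0))
  rows <- g$clean[g$clean$subtest == "RS", ]
  gold <- rows$gold_score
  classes <- subtest_params("RS")$score_classes
  flip <- function(scores, rate, seed) {
    set.seed(seed)
    hit <- runif(length(scores)) < rate
    scores[hit] <- vapply(scores[hit], function(s) {
      sample(setdiff(classes, s), 1)
    }, integer(1))
    scores
  }
  accs <- maes <- matrix(0, nrow = 20, ncol = 2)
  for (i in 1:20) {
    lo <- flip(gold, 0.1, 1000 + i)
    hi <- flip(gold, 0.4, 2000 + i)
    accs[i, ] <- c(mean(lo == gold), mean(hi == gold))
    maes[i, ] <- c(mean(abs(lo - gold)), mean(abs(hi - gold)))
  }
  # one-sided sign test over replicates
  expect_gt(sum(accs[, 1] > accs[, 2]), 15)
  expect_gt(sum(maes[, 1] < maes[, 2]), 15)
})
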