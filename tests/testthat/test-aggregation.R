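test_that("discontinuation fires at the item completing the zero run", {
  res <- apply_discontinuation(c(1, 0, 0, 0, 0, 0, 0, 0, 2), "EV")
  expect_equal(res$retained, c(1, 0, 0, 0, 0, 0, 0, 0))
  expect_equal(res$discontinued_at, 7L)
  # WS has no rule: an all-zero administration passes through
  ws <- apply_discontinuation(rep(0L, 32), "WS")
  expect_equal(ws$retained, rep(0L, 32))
  expect_true(is.na(ws$discontinued_at))
  # a run shorter than the threshold does not discontinue
  fs <- apply_discontinuation(c(0, 0, 0, 0), "FS")
  expect_equal(fs$retained, c(0, 0, 0, 0))
  expect_true(is.na(fs$discontinued_at))
  # RS discontinues after five consecutive zeros
  rs <- apply_discontinuation(c(3, 0, 0, 0, 0, 0, 2, 1), "RS")
  expect_equal(rs$discontinued_at, 5L)
  expect_equal(rs$retained, c(3, 0, 0, 0, 0, 0))
})

test_that("raw scores are sums bounded by the subtest scale", {
  expect_equal(raw_score(c(2, 2, 1, 0, 2)), 7L)
  expect_equal(raw_score(rep(3L, 32)), 96L)  # RS full-scale upper bound
  expect_equal(raw_score(integer(0)), 0L)
})

test_that("scaled lookup respects age bands and half-open raw intervals", {
  tab <- norm_table(
    tibble::tibble(subtest = "EV", age_min_months = 60L,
                   age_max_months = 120L,
                   raw_min = c(0L, 11L, 21L), raw_max = c(10L, 20L, 54L),
                   scaled = c(1L, 10L, 19L)),
    tibble::tibble(sum_min = 3L, sum_max = 57L, eli = 100L)
  )
  expect_equal(scaled_score(15, 72, "EV", tab), 10L)
  expect_equal(scaled_score(10, 72, "EV", tab), 1L)
  expect_equal(scaled_score(11, 72, "EV", tab), 10L)
  expect_error(scaled_score(15, 59, "EV", tab), "age 59")
  # a child exactly on a band edge falls in the upper band
  tab2 <- toy_norm_table()
  expect_equal(scaled_score(0, 60, "EV", tab2), 1L)
  expect_error(scaled_score(0, 120, "EV", tab2), "age 120")
})

test_that("the ELI composite sums FS, RS, WS and rejects missing inputs", {
  tab <- toy_norm_table()
  expect_equal(eli_composite(10L, 10L, 10L, tab), 100L)
  expect_gte(eli_composite(1L, 1L, 1L, tab), 45L)
  expect_error(eli_composite(10L, 10L, NA, tab), "all three")
})

test_that("score reports aggregate per child and emit one ELI per child", {
  g <- generate_corpus(generator_config(seed = 19, n_children = 6))
  scored <- g$clean
  scored$item_score <- scored$gold_score
  tab <- small_built_norms()
  rep <- score_reports(scored, tab)
  n_children <- length(unique(scored$child_id))
  expect_equal(nrow(rep$subtest_reports), n_children * 4)
  expect_equal(nrow(rep$eli_reports), n_children)
  expect_true(all(rep$subtest_reports$scaled >= 1 &
                    rep$subtest_reports$scaled <= 19))
  expect_true(all(rep$eli_reports$eli >= 45 & rep$eli_reports$eli <= 155))
  # a child without RS loses the ELI but keeps subtest rows
  no_rs <- scored[!(scored$child_id == scored$child_id[1] &
                      scored$subtest == "RS"), ]
  rep2 <- score_reports(no_rs, tab)
  expect_equal(nrow(rep2$eli_reports), n_children - 1)
})

test_that("aggregation conserves sums and is idempotent on random data", {
  set.seed(77)
  for (trial in 1:40) {
    code <- sample(subtest_codes(), 1)
    classes <- subtest_params(code)$score_classes
    scores <- sample(classes, sample(5:30, 1), replace = TRUE)
    once <- apply_discontinuation(scores, code)
    expect_equal(raw_score(once$retained), sum(once$retained))
    twice <- apply_discontinuation(once$retained, code)
    expect_equal(twice$retained, once$retained)
  }
})

test_that("pointwise-increasing item scores never decrease any tier", {
  tab <- small_built_norms()
  set.seed(78)
  for (trial in 1:15) {
    base <- sample(0:2, 20, replace = TRUE)
    bumped <- pmin(base + sample(0:1, 20, replace = TRUE), 2L)
    r1 <- raw_score(apply_discontinuation(base, "FS")$retained)
    r2 <- raw_score(apply_discontinuation(bumped, "FS")$retained)
    expect_gte(r2, r1)
    expect_gte(scaled_score(r2, 72, "FS", tab), scaled_score(r1, 72, "FS", tab))
  }
})

test_that("moving a zero run earlier never increases the raw score", {
  set.seed(79)
  for (trial in 1:15) {
    scores <- sample(0:2, 15, replace = TRUE)
    run <- rep(0L, 5)
    early <- c(scores[1:2], run, scores[3:15])
    late <- c(scores[1:10], run, scores[11:15])
    expect_lte(raw_score(apply_discontinuation(early, "FS")$retained),
               raw_score(apply_discontinuation(late, "FS")$retained))
  }
})

test_that("ceiling can be driven by the gold stream instead", {
  corpus <- tiny_corpus(c(1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 2L), subtest = "EV")
  corpus$item_score <- c(1L, 1L, 0L, 0L, 0L, 0L, 0L, 0L, 2L)
  tab <- toy_norm_table()
  on_pred <- score_reports(corpus, tab, ceiling_on = "scored")
  on_gold <- score_reports(corpus, tab, ceiling_on = "gold")
  none <- score_reports(corpus, tab, ceiling_on = "none")
  expect_equal(on_pred$subtest_reports$raw, 4L)   # no 7-run in predictions
  expect_equal(on_gold$subtest_reports$raw, 2L)   # gold run truncates at 8
  expect_equal(none$subtest_reports$raw, 4L)
})
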