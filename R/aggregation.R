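#' Apply a subtest's discontinuation rule to ordered item scores
#'
#' Scanning in administration order, the administration ends at the item
#' that completes the first run of `discontinuation_run` consecutive zeros
#' (7 for EV, 5 for FS and RS); items after that are dropped. WS has no
#' discontinuation rule and passes through unchanged. Idempotent: applying
#' the rule twice equals applying it once.
#'
#' @param item_scores Integer vector of item scores in administration order.
#' @param subtest Subtest code.
#'
#' @return List with `retained` (scores up to and including the
#'   discontinuation point) and `discontinued_at` (0-based index of the item
#'   completing the zero run, or `NA` if the rule never fired).
#' @export
#' @examples
#' apply_discontinuation(c(1, 0, 0, 0, 0, 0, 0, 0, 2), "EV")
apply_discontinuation <- function(item_scores, subtest) {
  params <- subtest_params(subtest)
  if (!all(item_scores %in% params$score_classes)) {
    stop_data("item scores outside ", subtest, " score classes {",
              paste(params$score_classes, collapse = ","), "}")
  }
  run <- params$discontinuation_run
  if (is.na(run) || length(item_scores) == 0) {
    return(list(retained = item_scores, discontinued_at = NA_integer_))
  }
  zeros <- 0L
  for (i in seq_along(item_scores)) {
    zeros <- if (item_scores[i] == 0L) zeros + 1L else 0L
    if (zeros >= run) {
      return(list(retained = item_scores[seq_len(i)],
                  discontinued_at = i - 1L))
    }
  }
  list(retained = item_scores, discontinued_at = NA_integer_)
}

#' Raw score: sum of retained item scores
#'
#' @param retained_scores Integer vector of item scores after
#'   discontinuation.
#' @return Integer sum (0 for an empty administration).
#' @export
raw_score <- function(retained_scores) {
  as.integer(sum(retained_scores))
}

#' Convert a raw score to an age-normed scaled score
#'
#' Looks up the scaled score (1-19) for a raw score in the age band covering
#' `age_months`. Age bands are half-open `[min, max)` in months, so a child
#' exactly on a boundary falls in the upper band.
#'
#' @param raw Integer raw score.
#' @param age_months Child's age in months.
#' @param subtest Subtest code.
#' @param table A `norm_table`.
#' @return Integer scaled score in 1-19.
#' @export
scaled_score <- function(raw, age_months, subtest, table) {
  st <- table$subtest_tables
  rows <- st[st$subtest == subtest & st$age_min_months <= age_months &
               age_months < st$age_max_months, ]
  if (nrow(rows) == 0) {
    stop_data("norm table has no ", subtest, " band covering age ",
              age_months, " months")
  }
  hit <- rows[rows$raw_min <= raw & raw <= rows$raw_max, ]
  if (nrow(hit) == 0) {
    stop_data("norm table ", subtest, " band [", rows$age_min_months[1], ",",
              rows$age_max_months[1], ") does not cover raw score ", raw)
  }
  as.integer(hit$scaled[1])
}

#' Expressive Language Index composite from three scaled scores
#'
#' Sums the FS, RS and WS scaled scores (EV never contributes) and looks up
#' the composite (45-155) in the ELI table. All three scaled scores must be
#' present; nothing is imputed.
#'
#' @param scaled_fs,scaled_rs,scaled_ws Integer scaled scores in 1-19.
#' @param table A `norm_table`.
#' @return Integer ELI composite in 45-155.
#' @export
eli_composite <- function(scaled_fs, scaled_rs, scaled_ws, table) {
  for (s in c(scaled_fs, scaled_rs, scaled_ws)) {
    if (length(s) != 1 || is.na(s) || s < 1 || s > 19) {
      stop_data("eli_composite needs all three of FS, RS, WS scaled scores in 1-19")
    }
  }
  total <- scaled_fs + scaled_rs + scaled_ws
  et <- table$eli_table
  hit <- et[et$sum_min <= total & total <= et$sum_max, ]
  if (nrow(hit) == 0) {
    stop_data("ELI table does not cover scaled sum ", total)
  }
  as.integer(hit$eli[1])
}

#' Aggregate item scores into raw, scaled, and composite tiers
#'
#' The deterministic summarization stage of the scoring system: for each
#' child x subtest administration, applies the discontinuation rule to the
#' chosen score stream, sums retained item scores into a raw score, converts
#' it to an age-normed scaled score, and derives the ELI composite for every
#' child with FS, RS and WS scaled scores.
#'
#' @param scored_corpus Corpus tibble with an `item_score` column (predicted
#'   or gold item scores in administration order).
#' @param table A `norm_table`.
#' @param ceiling_on Which stream governs discontinuation: `"scored"`
#'   (default; the `item_score` column being aggregated) or `"gold"` (the
#'   `gold_score` column, replicating manual administration), or `"none"` to
#'   score all administered items.
#'
#' @return List with `subtest_reports` (tibble: `child_id`, `subtest`,
#'   `age_months`, `n_items`, `discontinued_at`, `raw`, `scaled`) and
#'   `eli_reports` (tibble: `child_id`, `scaled_sum`, `eli`).
#' @export
score_reports <- function(scored_corpus, table, ceiling_on = c("scored", "gold", "none")) {
  ceiling_on <- match.arg(ceiling_on)
  stopifnot("item_score" %in% names(scored_corpus))
  corpus <- sort_corpus(scored_corpus)
  keys <- unique(corpus[, c("child_id", "subtest", "age_months")])
  sub_rows <- lapply(seq_len(nrow(keys)), function(i) {
    rows <- corpus[corpus$child_id == keys$child_id[i] &
                     corpus$subtest == keys$subtest[i], ]
    scores <- as.integer(rows$item_score)
    disc_at <- NA_integer_
    if (ceiling_on == "scored") {
      res <- apply_discontinuation(scores, keys$subtest[i])
      retained <- res$retained
      disc_at <- res$discontinued_at
    } else if (ceiling_on == "gold") {
      res <- apply_discontinuation(as.integer(rows$gold_score),
                                   keys$subtest[i])
      retained <- scores[seq_along(res$retained)]
      disc_at <- res$discontinued_at
    } else {
      retained <- scores
    }
    raw <- raw_score(retained)
    tibble::tibble(
      child_id = keys$child_id[i], subtest = keys$subtest[i],
      age_months = keys$age_months[i], n_items = length(retained),
      discontinued_at = disc_at, raw = raw,
      scaled = scaled_score(raw, keys$age_months[i], keys$subtest[i], table)
    )
  })
  subtest_reports <- dplyr::bind_rows(sub_rows)
  eli_rows <- list()
  for (cid in unique(subtest_reports$child_id)) {
    mine <- subtest_reports[subtest_reports$child_id == cid, ]
    if (all(c("FS", "RS", "WS") %in% mine$subtest)) {
      s <- setNames(mine$scaled, mine$subtest)
      eli_rows[[length(eli_rows) + 1L]] <- tibble::tibble(
        child_id = cid,
        scaled_sum = as.integer(s["FS"] + s["RS"] + s["WS"]),
        eli = eli_composite(s["FS"], s["RS"], s["WS"], table)
      )
    }
  }
  eli_reports <- if (length(eli_rows) > 0) {
    dplyr::bind_rows(eli_rows)
  } else {
    tibble::tibble(child_id = character(), scaled_sum = integer(),
                   eli = integer())
  }
  list(subtest_reports = subtest_reports, eli_reports = eli_reports)
}

#' Write score reports to delimited text
#'
#' One row per child x subtest plus one ELI row per child, as
#' tab-separated text.
#'
#' @param reports Result of [score_reports()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_score_reports <- function(reports, path) {
  sub <- reports$subtest_reports
  eli <- reports$eli_reports
  out <- rbind(
    data.frame(child_id = sub$child_id, row_type = "subtest",
               subtest = sub$subtest, raw = sub$raw, scaled = sub$scaled,
               eli = NA_integer_, discontinued_at = sub$discontinued_at),
    if (nrow(eli) > 0) {
      data.frame(child_id = eli$child_id, row_type = "eli",
                 subtest = NA_character_, raw = NA_integer_,
                 scaled = eli$scaled_sum, eli = eli$eli,
                 discontinued_at = NA_integer_)
    }
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
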