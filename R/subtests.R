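#' Subtest parameters
#'
#' Fixed per-subtest scoring parameters for the four expressive-language
#' subtests: Expressive Vocabulary (EV), Word Structure (WS), Recalling
#' Sentences (RS) and Formulated Sentences (FS).
#'
#' Each subtest has a set of permitted item scores, an optional
#' discontinuation (ceiling) rule expressed as a run length of consecutive
#' zero-scored items after which administration halts, and a default number
#' of items. The raw-score scale upper bound is `max(score_classes) *
#' max_items` (EV 0-54, FS 0-48, RS 0-96, WS 0-32).
#'
#' @param code Subtest code: one of `"EV"`, `"WS"`, `"RS"`, `"FS"`.
#' @param max_items Optional override of the default item count.
#'
#' @return A list with elements `code`, `score_classes` (integer vector),
#'   `discontinuation_run` (integer or `NA`), `max_items`, and `raw_max`.
#' @export
#' @examples
#' subtest_params("EV")$discontinuation_run  # 7
#' subtest_params("WS")$score_classes       # 0 1
subtest_params <- function(code, max_items = NULL) {
  code <- match.arg(code, c("EV", "WS", "RS", "FS"))
  base <- switch(code,
    EV = list(score_classes = 0:2, discontinuation_run = 7L, max_items = 27L),
    WS = list(score_classes = 0:1, discontinuation_run = NA_integer_, max_items = 32L),
    RS = list(score_classes = 0:3, discontinuation_run = 5L, max_items = 32L),
    FS = list(score_classes = 0:2, discontinuation_run = 5L, max_items = 24L)
  )
  if (!is.null(max_items)) {
    stopifnot(is.numeric(max_items), max_items >= 1)
    base$max_items <- as.integer(max_items)
  }
  c(list(code = code), base,
    list(raw_max = as.integer(max(base$score_classes)) * base$max_items))
}

#' Subtest codes
#'
#' @return Character vector `c("EV", "WS", "RS", "FS")`.
#' @export
subtest_codes <- function() c("EV", "WS", "RS", "FS")

corpus_columns <- function() {
  c("child_id", "age_months", "subtest", "item_index", "stimulus_id",
    "prompt_text", "response_text", "transcript_kind", "gold_score")
}

#' Validate a transcript corpus
#'
#' Checks the structural invariants of a corpus of item responses: known
#' subtest codes and transcript kinds, non-empty prompts, gold scores inside
#' each subtest's permitted score classes, non-negative ages, and per
#' administration (one `child_id` x `subtest` x `transcript_kind` group)
#' item indices that run 0, 1, 2, ... without gaps or duplicates.
#'
#' Violations are returned, not raised, so callers can report all problems at
#' once.
#'
#' @param corpus A corpus tibble (see [read_corpus()] for the schema).
#'
#' @return A tibble of violations with columns `child_id`, `subtest`,
#'   `field`, and `message`; zero rows when the corpus is valid.
#' @export
validate_corpus <- function(corpus) {
  viol <- list()
  add <- function(child_id, subtest, field, message) {
    viol[[length(viol) + 1L]] <<- tibble::tibble(
      child_id = as.character(child_id), subtest = as.character(subtest),
      field = field, message = message
    )
  }
  missing_cols <- setdiff(setdiff(corpus_columns(), "gold_score"), names(corpus))
  if (length(missing_cols) > 0) {
    add(NA, NA, "columns",
        paste0("missing columns: ", paste(missing_cols, collapse = ", ")))
    return(dplyr::bind_rows(viol))
  }
  if (nrow(corpus) == 0) return(empty_violations())

  bad_sub <- !corpus$subtest %in% subtest_codes()
  for (i in which(bad_sub)) {
    add(corpus$child_id[i], corpus$subtest[i], "subtest",
        paste0("unknown subtest code '", corpus$subtest[i], "'"))
  }
  bad_kind <- !corpus$transcript_kind %in% c("clean", "verbatim")
  for (i in which(bad_kind)) {
    add(corpus$child_id[i], corpus$subtest[i], "transcript_kind",
        paste0("unknown transcript_kind '", corpus$transcript_kind[i], "'"))
  }
  for (i in which(is.na(corpus$prompt_text) | corpus$prompt_text == "")) {
    add(corpus$child_id[i], corpus$subtest[i], "prompt_text",
        "prompt_text must be non-empty")
  }
  for (i in which(corpus$age_months < 0 | is.na(corpus$age_months))) {
    add(corpus$child_id[i], corpus$subtest[i], "age_months",
        "age_months must be a non-negative integer")
  }
  if ("gold_score" %in% names(corpus)) {
    for (code in subtest_codes()) {
      classes <- subtest_params(code)$score_classes
      rows <- which(corpus$subtest == code & !is.na(corpus$gold_score))
      bad <- rows[!corpus$gold_score[rows] %in% classes]
      for (i in bad) {
        add(corpus$child_id[i], code, "gold_score",
            paste0("gold_score ", corpus$gold_score[i],
                   " outside score classes {",
                   paste(classes, collapse = ","), "}"))
      }
    }
  }
  grp <- split(
    seq_len(nrow(corpus)),
    paste(corpus$child_id, corpus$subtest, corpus$transcript_kind, sep = "\r")
  )
  for (idx in grp) {
    got <- sort(corpus$item_index[idx])
    want <- seq(0L, length(idx) - 1L)
    if (!identical(as.integer(got), want)) {
      add(corpus$child_id[idx[1]], corpus$subtest[idx[1]], "item_index",
          paste0("item_index values {", paste(got, collapse = ","),
                 "} are not consecutive from 0"))
    }
  }
  if (length(viol) == 0) empty_violations() else dplyr::bind_rows(viol)
}

empty_violations <- function() {
  tibble::tibble(child_id = character(), subtest = character(),
                 field = character(), message = character())
}
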