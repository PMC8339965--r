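#' Tokenize a transcript string
#'
#' Lowercases, strips punctuation (keeping word-internal apostrophes, so
#' "I'm" stays one token), and splits on whitespace. Deterministic; the same
#' normalization feeds the edit-distance scorer, the synthetic generator, and
#' every classifier backend.
#'
#' @param text Character scalar.
#' @return Character vector of tokens (length 0 for empty/blank input).
#' @export
#' @examples
#' normalize_tokens("The dog, ran!")  # "the" "dog" "ran"
normalize_tokens <- function(text) {
  if (is.na(text) || !nzchar(text)) return(character(0))
  x <- tolower(enc2utf8(text))
  # drop everything that is not a letter, digit, apostrophe or space
  x <- gsub("[^\\p{L}\\p{N}' ]+", " ", x, perl = TRUE)
  toks <- strsplit(trimws(x), "\\s+")[[1]]
  # strip leading/trailing apostrophes so only internal ones survive
  toks <- gsub("^'+|'+$", "", toks)
  toks[nzchar(toks)]
}

#' Collapse adjacent repeated tokens
#'
#' Repeated words are not counted as errors when scoring sentence repetition,
#' so maximal runs of identical adjacent tokens are reduced to a single
#' token before alignment. Applied to a fixpoint, token-level restarts
#' ("the the the dog") collapse fully; non-adjacent duplicates ("a b a") are
#' legitimate content and are kept.
#'
#' @param tokens Character vector of tokens.
#' @return Character vector with adjacent runs collapsed.
#' @export
#' @examples
#' collapse_repetitions(c("the", "the", "dog"))  # "the" "dog"
collapse_repetitions <- function(tokens) {
  if (length(tokens) <= 1) return(tokens)
  tokens[c(TRUE, tokens[-1] != tokens[-length(tokens)])]
}

#' Align a response against a target sentence
#'
#' Unit-cost Levenshtein alignment at the token level, returning operation
#' counts rather than just the distance: insertions (extra response tokens),
#' deletions (omitted target tokens), substitutions, and correct tokens.
#' These counts are both the basis of the rule score for Recalling Sentences
#' and the feature vector of the RS baseline classifier, so ties among
#' minimum-cost alignments are broken deterministically: substitution is
#' preferred over an insertion+deletion pair, and the backtrace examines
#' diagonal, then up (insertion), then left (deletion).
#'
#' @param response_tokens Character vector (the child's response).
#' @param target_tokens Character vector (the target sentence).
#'
#' @return A list of class `edit_op_counts` with elements `insertions`,
#'   `deletions`, `substitutions`, `correct`, `total_errors`. Invariants:
#'   `correct + deletions + substitutions == length(target_tokens)` and
#'   `correct + insertions + substitutions == length(response_tokens)`.
#' @export
#' @examples
#' align_tokens(c("the", "dog"), c("the", "big", "dog"))$deletions  # 1
align_tokens <- function(response_tokens, target_tokens) {
  m <- length(response_tokens)
  n <- length(target_tokens)
  D <- matrix(0L, m + 1L, n + 1L)
  D[, 1L] <- 0:m
  D[1L, ] <- 0:n
  if (m > 0 && n > 0) {
    for (i in 1:m) {
      ri <- response_tokens[i]
      for (j in 1:n) {
        sub_cost <- if (ri == target_tokens[j]) 0L else 1L
        D[i + 1L, j + 1L] <- min(D[i, j] + sub_cost,      # diagonal
                                 D[i, j + 1L] + 1L,       # insertion
                                 D[i + 1L, j] + 1L)       # deletion
      }
    }
  }
  ins <- del <- sub <- cor <- 0L
  i <- m; j <- n
  while (i > 0 || j > 0) {
    here <- D[i + 1L, j + 1L]
    if (i > 0 && j > 0) {
      sub_cost <- if (response_tokens[i] == target_tokens[j]) 0L else 1L
      if (here == D[i, j] + sub_cost) {
        if (sub_cost == 0L) cor <- cor + 1L else sub <- sub + 1L
        i <- i - 1L; j <- j - 1L
        next
      }
    }
    if (i > 0 && here == D[i, j + 1L] + 1L) {
      ins <- ins + 1L
      i <- i - 1L
    } else {
      del <- del + 1L
      j <- j - 1L
    }
  }
  structure(
    list(insertions = ins, deletions = del, substitutions = sub,
         correct = cor, total_errors = ins + del + sub),
    class = "edit_op_counts"
  )
}

#' Default error-count to RS score map
#'
#' Recalling Sentences items are scored 0-3 from the number of errors
#' (omissions, substitutions, additions) in the repetition. The published
#' scale states the 0-3 range but not the thresholds; this default follows
#' the standard sentence-recall convention — 0 errors scores 3, 1 error
#' scores 2, 2-3 errors score 1, 4 or more score 0 — and is overridable
#' everywhere a score map is accepted.
#'
#' @return A data frame with columns `max_errors` (inclusive upper bound,
#'   `Inf` for the open-ended 0 tier) and `score`, descending in score.
#' @export
default_rs_score_map <- function() {
  data.frame(max_errors = c(0, 1, 3, Inf), score = c(3L, 2L, 1L, 0L))
}

validate_rs_score_map <- function(score_map) {
  if (!all(c("max_errors", "score") %in% names(score_map))) {
    stop_data("score map needs columns max_errors and score")
  }
  if (!identical(sort(as.integer(score_map$score)), 0:3)) {
    stop_data("score map scores must be exactly {0,1,2,3}")
  }
  sm <- score_map[order(-score_map$score), ]
  if (any(diff(sm$max_errors) <= 0)) {
    stop_data("score map thresholds must be strictly increasing")
  }
  if (!is.infinite(sm$max_errors[nrow(sm)])) {
    stop_data("score map's lowest tier must be open-ended (max_errors = Inf)")
  }
  sm
}

#' Score one Recalling Sentences item
#'
#' Normalizes both texts, collapses adjacent repetitions in the response
#' (repetitions are not errors), aligns against the target, and maps the
#' total error count to a 0-3 item score.
#'
#' @param response_text The child's response.
#' @param target_text The target sentence (the prompt).
#' @param score_map Error-to-score map; see [default_rs_score_map()].
#' @return Integer item score in 0-3.
#' @export
#' @examples
#' rs_item_score("the the quick fox", "the quick fox")  # 3: repetition is free
rs_item_score <- function(response_text, target_text,
                          score_map = default_rs_score_map()) {
  sm <- validate_rs_score_map(score_map)
  ops <- align_tokens(collapse_repetitions(normalize_tokens(response_text)),
                      normalize_tokens(target_text))
  as.integer(sm$score[match(TRUE, ops$total_errors <= sm$max_errors)])
}

#' Edit-operation features for the RS baseline classifier
#'
#' The correctness features of the sentence-repetition baseline: counts of
#' insertions, deletions, and substitutions from the token alignment, plus
#' the number of correct words, in that fixed order.
#'
#' @inheritParams rs_item_score
#' @return Named numeric vector `c(insertions, deletions, substitutions,
#'   correct)`.
#' @export
rs_features <- function(response_text, target_text) {
  ops <- align_tokens(collapse_repetitions(normalize_tokens(response_text)),
                      normalize_tokens(target_text))
  c(insertions = ops$insertions, deletions = ops$deletions,
    substitutions = ops$substitutions, correct = ops$correct)
}
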