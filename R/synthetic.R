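#' Configuration for the synthetic transcript generator
#'
#' The generator emulates the structure of child expressive-language
#' transcript corpora that scoring systems consume: four subtests with their
#' item-score scales, clean vs. verbatim transcript variants where verbatim
#' adds prefatory/trailing chatter, Recalling Sentences responses with a
#' controlled number of scored errors plus uncounted adjacent repetitions,
#' and terminal all-zero runs that exercise the discontinuation rules.
#' Linguistic realism is a non-goal: scorers only ever see token patterns
#' (exact match, partial match, error counts, chatter), so exemplars are
#' built from a small synthetic word list.
#'
#' @param seed Integer seed; fully determines the generated corpora.
#' @param n_children Number of children.
#' @param score_dist Named list of per-subtest probability vectors over that
#'   subtest's score classes (lowest score first).
#' @param chatter_prob Probability that a verbatim response gains chatter.
#' @param rs_error_mix Probability vector over (insertion, deletion,
#'   substitution) used when injecting RS errors.
#' @param rs_repetition_prob Probability of injecting an uncounted adjacent
#'   repetition into an RS response.
#' @param zero_run_prob Probability that a child's administration of a
#'   subtest with a discontinuation rule enters a terminal all-zero run.
#' @param td_prob Probability a child carries the "TD" group tag (otherwise
#'   "nonTD"); used only for stratified evaluation.
#' @param rs_score_map Error-to-score map used to pick how many errors to
#'   inject for a given gold RS score; see [default_rs_score_map()].
#' @param max_items Optional named list of per-subtest item-count overrides.
#'
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             n_children = 25L,
                             score_dist = list(
                               EV = c(0.15, 0.20, 0.65),
                               WS = c(0.25, 0.75),
                               RS = c(0.15, 0.20, 0.25, 0.40),
                               FS = c(0.20, 0.25, 0.55)
                             ),
                             chatter_prob = 0.8,
                             rs_error_mix = c(insertion = 0.25,
                                              deletion = 0.40,
                                              substitution = 0.35),
                             rs_repetition_prob = 0.15,
                             zero_run_prob = 0.15,
                             td_prob = 0.7,
                             rs_score_map = default_rs_score_map(),
                             max_items = list()) {
  for (code in subtest_codes()) {
    p <- score_dist[[code]]
    k <- length(subtest_params(code)$score_classes)
    if (is.null(p) || length(p) != k) {
      stop_data("score_dist$", code, " must have ", k, " probabilities")
    }
    if (abs(sum(p) - 1) > 1e-9 || any(p < 0)) {
      stop_data("score_dist$", code, " must be a probability vector summing to 1")
    }
  }
  if (abs(sum(rs_error_mix) - 1) > 1e-9 || any(rs_error_mix < 0) ||
      length(rs_error_mix) != 3) {
    stop_data("rs_error_mix must be 3 non-negative probabilities summing to 1")
  }
  for (p in c(chatter_prob, rs_repetition_prob, zero_run_prob, td_prob)) {
    if (p < 0 || p > 1) stop_data("probabilities must lie in [0, 1]")
  }
  structure(
    list(seed = as.integer(seed), n_children = as.integer(n_children),
         score_dist = score_dist, chatter_prob = chatter_prob,
         rs_error_mix = rs_error_mix, rs_repetition_prob = rs_repetition_prob,
         zero_run_prob = zero_run_prob, td_prob = td_prob,
         rs_score_map = rs_score_map, max_items = max_items),
    class = "generator_config"
  )
}

# Pool of short pronounceable pseudo-words, unique, deterministic in the
# current RNG state.
make_word_pool <- function(n) {
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t", "v", "z")
  vow <- c("a", "e", "i", "o", "u")
  syl <- as.vector(outer(cons, vow, paste0))
  words <- character(0)
  while (length(words) < n) {
    batch <- vapply(seq_len(n), function(i) {
      paste(sample(syl, sample(2:3, 1), replace = TRUE), collapse = "")
    }, character(1))
    words <- unique(c(words, batch))
  }
  words[seq_len(n)]
}

chatter_phrases <- function() {
  list(
    prefix = c("um", "i think", "i think that one's", "well", "uh",
               "let me see", "hmm", "that looks like", "maybe it's"),
    suffix = c("yeah", "i guess", "right", "or something")
  )
}

#' Build a stimulus bank for one subtest
#'
#' For EV, WS, and FS each stimulus carries a prompt plus at least one
#' exemplar response per score class, with exemplars for distinct classes
#' built from disjoint vocabulary pools (so gold scores are correct by
#' construction and corpora are vocabulary-separable for classifiers).
#' Canonical-style items lead each bank: EV's first stimulus is "lime" with
#' full credit for "lime", partial credit for the under-specific "fruit";
#' WS's first frame expects the inflected form "fixed" with the bare stem
#' "fix" earning no credit. For RS each stimulus is a target sentence of 6-9
#' distinct tokens; exemplars per class are generated by injecting the
#' class-typical number of errors.
#'
#' @param subtest Subtest code.
#' @param n_stimuli Number of stimuli (defaults to the subtest's item count).
#' @param seed Integer seed.
#'
#' @return A list of class `stimulus_bank` with elements `subtest` and
#'   `stimuli` (a list of `stimulus_id`, `prompt`, `exemplars` — the latter a
#'   list keyed by score class).
#' @export
build_stimulus_bank <- function(subtest,
                                n_stimuli = subtest_params(subtest)$max_items,
                                seed = 1L) {
  subtest <- match.arg(subtest, subtest_codes())
  stopifnot(n_stimuli >= 1)
  with_seed(derive_seed(seed, "bank", subtest), {
    stimuli <- switch(subtest,
      EV = build_ev_bank(n_stimuli),
      WS = build_ws_bank(n_stimuli),
      FS = build_fs_bank(n_stimuli),
      RS = build_rs_bank(n_stimuli)
    )
  })
  structure(list(subtest = subtest, stimuli = stimuli), class = "stimulus_bank")
}

build_ev_bank <- function(n) {
  real <- list(c("lime", "fruit"), c("pirate", "person"), c("hammer", "tool"),
               c("ladder", "object"), c("violin", "instrument"))
  pool <- make_word_pool(3 * n + 30)
  targets <- pool[seq_len(n)]
  cats <- paste0(pool[n + seq_len(n)], "kind")      # class-1 pool
  unrel <- paste0(pool[2 * n + seq_len(n)], "zz")   # class-0 pool
  for (i in seq_len(min(n, length(real)))) {
    targets[i] <- real[[i]][1]
    cats[i] <- real[[i]][2]
  }
  lapply(seq_len(n), function(i) {
    list(
      stimulus_id = sprintf("EV%02d", i),
      prompt = targets[i],
      exemplars = list(
        `0` = c(unrel[i], paste("zonky", unrel[i])),
        `1` = c(cats[i], paste("somekind", cats[i])),
        `2` = c(targets[i], paste("little", targets[i]))
      )
    )
  })
}

build_ws_bank <- function(n) {
  pool <- make_word_pool(2 * n + 20)
  stems <- paste0(pool[seq_len(n)], "t")
  nouns <- pool[n + seq_len(n)]
  stems[1] <- "fix"
  nouns[1] <- "car"
  lapply(seq_len(n), function(i) {
    inflected <- paste0(stems[i], "ed")
    list(
      stimulus_id = sprintf("WS%02d", i),
      prompt = paste("here is the", nouns[i], "that the woman", inflected),
      exemplars = list(
        `0` = c(stems[i], paste0(stems[i], "ing")),
        `1` = c(inflected, paste("she", inflected))
      )
    )
  })
}

build_fs_bank <- function(n) {
  real <- c("safely", "because", "before", "until", "although")
  pool <- make_word_pool(7 * n + 20)
  targets <- paste0(pool[seq_len(n)], "ly")
  targets[seq_len(min(n, length(real)))] <- real[seq_len(min(n, length(real)))]
  f2 <- matrix(paste0(pool[n + seq_len(4 * n)], "o"), ncol = 4)     # class-2 pool
  f1 <- paste0(pool[5 * n + seq_len(n)], "u")                       # class-1 pool
  f0 <- paste0(pool[6 * n + seq_len(n)], "iz")                      # class-0 pool
  lapply(seq_len(n), function(i) {
    list(
      stimulus_id = sprintf("FS%02d", i),
      prompt = targets[i],
      exemplars = list(
        `0` = c(f0[i], paste(f0[i], "umm")),
        `1` = c(paste(f1[i], targets[i]), paste(targets[i], f1[i])),
        `2` = c(paste(f2[i, 1], f2[i, 2], targets[i], f2[i, 3]),
                paste(f2[i, 4], targets[i], f2[i, 2], f2[i, 3]))
      )
    )
  })
}

build_rs_bank <- function(n) {
  pool <- make_word_pool(7 * n)
  lapply(seq_len(n), function(i) {
    len <- sample(6:9, 1)
    words <- pool[(i - 1) * 7 + seq_len(len - 2)]
    target <- c("the", words[1], words[2], "a", words[seq(3, len - 2)])
    target_text <- paste(target, collapse = " ")
    exemplars <- lapply(c(`0` = 4L, `1` = 2L, `2` = 1L, `3` = 0L), function(k) {
      paste(inject_rs_errors(target, k, c(0.25, 0.40, 0.35), 0),
            collapse = " ")
    })
    list(stimulus_id = sprintf("RS%02d", i), prompt = target_text,
         exemplars = exemplars[order(names(exemplars))])
  })
}

#' Inject a controlled number of scored errors into a target sentence
#'
#' Builds a Recalling Sentences response from the target by applying exactly
#' `k_errors` scored operations (insertions of fresh out-of-vocabulary
#' tokens, deletions of target tokens, substitutions by fresh tokens),
#' optionally followed by an adjacent repetition of one token, which the
#' scorer collapses and which therefore never changes the error count. The
#' result is re-checked against the alignment scorer; on an accidental
#' collision (for example a deletion that makes two identical target tokens
#' adjacent) the operations are re-sampled.
#'
#' @param target_tokens Character vector, the target sentence tokens.
#' @param k_errors Number of scored errors to inject (>= 0).
#' @param mix Probability vector over (insertion, deletion, substitution).
#' @param repetition_prob Probability of injecting one adjacent repetition.
#' @param seed Optional integer seed; if `NULL` the current RNG stream is
#'   used.
#'
#' @return Character vector of response tokens whose alignment against the
#'   target (after repetition collapse) has exactly `k_errors` total errors.
#' @export
inject_rs_errors <- function(target_tokens, k_errors, mix,
                             repetition_prob = 0, seed = NULL) {
  if (!is.null(seed)) {
    return(with_seed(seed, inject_rs_errors(target_tokens, k_errors, mix,
                                            repetition_prob)))
  }
  stopifnot(k_errors >= 0, length(mix) == 3, all(mix >= 0))
  n <- length(target_tokens)
  if (mix[1] == 0 && k_errors > n) {
    stop_data("cannot inject ", k_errors, " errors into a ", n,
              "-token target without insertions")
  }
  for (attempt in seq_len(200)) {
    resp <- target_tokens
    if (k_errors > 0) {
      types <- sample(c("ins", "del", "sub"), k_errors, replace = TRUE,
                      prob = mix)
      n_del <- sum(types == "del")
      n_sub <- sum(types == "sub")
      n_ins <- sum(types == "ins")
      if (n_del + n_sub > n) next  # infeasible draw, re-sample the mix
      touch <- sample(n, n_del + n_sub)
      del_pos <- touch[seq_len(n_del)]
      sub_pos <- setdiff(touch, del_pos)
      if (n_sub > 0) {
        resp[sub_pos] <- sprintf("zq%dx%d", sample(99999, n_sub), seq_len(n_sub))
      }
      if (n_del > 0) resp <- resp[-del_pos]
      if (n_ins > 0) {
        for (j in seq_len(n_ins)) {
          at <- sample(length(resp) + 1L, 1)
          resp <- append(resp, sprintf("wq%dy%d", sample(99999, 1), j),
                         after = at - 1L)
        }
      }
    }
    if (length(resp) > 0 && runif(1) < repetition_prob) {
      at <- sample(length(resp), 1)
      resp <- append(resp, resp[at], after = at)
    }
    got <- align_tokens(collapse_repetitions(resp), target_tokens)$total_errors
    if (got == k_errors) return(resp)
  }
  stop_data("could not inject exactly ", k_errors, " errors into target '",
            paste(target_tokens, collapse = " "), "'")
}

# Number of errors to inject for a gold RS score: a draw from the score's
# error band under the map (capped so deletions stay feasible).
rs_errors_for_score <- function(score, score_map, target_len) {
  sm <- validate_rs_score_map(score_map)
  row <- which(sm$score == score)
  lo <- if (row == 1) 0 else sm$max_errors[row - 1] + 1
  hi <- sm$max_errors[row]
  if (is.infinite(hi)) hi <- lo + 2
  hi <- min(hi, target_len)
  lo <- min(lo, hi)
  as.integer(if (lo == hi) lo else sample(lo:hi, 1))
}

apply_chatter <- function(text, chatter_prob) {
  if (runif(1) >= chatter_prob) return(text)
  ph <- chatter_phrases()
  out <- paste(sample(ph$prefix, 1), text)
  if (runif(1) < 0.3) out <- paste(out, sample(ph$suffix, 1))
  trimws(out)
}

#' Generate paired clean and verbatim transcript corpora
#'
#' Simulates full administrations of the four subtests for `n_children`
#' children, producing two corpora that share gold item scores: a clean
#' corpus (the scored response only) and a verbatim corpus (the same
#' response with prefatory/trailing chatter added with probability
#' `chatter_prob`). Gold scores are correct by construction — EV/WS/FS
#' responses are drawn from pre-labeled exemplar banks, RS responses are
#' built by [inject_rs_errors()] so the rule scorer reproduces the gold
#' score exactly on the clean variant. Administrations stop when a subtest's
#' discontinuation rule fires on the gold scores; with probability
#' `zero_run_prob` a terminal all-zero run is forced so corpora exercise the
#' rule.
#'
#' @param config A [generator_config()].
#'
#' @return A list with elements `clean` and `verbatim`, each a corpus tibble
#'   (see [read_corpus()]) with an extra `group` column, plus `banks`, the
#'   per-subtest stimulus banks used.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  banks <- lapply(setNames(subtest_codes(), subtest_codes()), function(code) {
    n_items <- config$max_items[[code]] %||% subtest_params(code)$max_items
    build_stimulus_bank(code, n_items, config$seed)
  })
  rows <- list()
  with_seed(derive_seed(config$seed, "corpus"), {
    for (ci in seq_len(config$n_children)) {
      child_id <- sprintf("c%04d", ci)
      age <- sample(60:119, 1)
      group <- if (runif(1) < config$td_prob) "TD" else "nonTD"
      for (code in subtest_codes()) {
        params <- subtest_params(code)
        bank <- banks[[code]]
        n_items <- length(bank$stimuli)
        run <- params$discontinuation_run
        force_zero_from <- Inf
        if (!is.na(run) && runif(1) < config$zero_run_prob) {
          force_zero_from <- sample(seq_len(max(1, n_items - run + 1)), 1)
        }
        classes <- params$score_classes
        zeros <- 0L
        for (ii in seq_len(n_items)) {
          gold <- if (ii >= force_zero_from) {
            0L
          } else {
            sample(classes, 1, prob = config$score_dist[[code]])
          }
          stim <- bank$stimuli[[ii]]
          if (code == "RS") {
            target <- normalize_tokens(stim$prompt)
            k <- rs_errors_for_score(gold, config$rs_score_map, length(target))
            clean_resp <- paste(
              inject_rs_errors(target, k, config$rs_error_mix,
                               config$rs_repetition_prob),
              collapse = " ")
          } else {
            ex <- stim$exemplars[[as.character(gold)]]
            clean_resp <- if (length(ex) == 1) ex else sample(ex, 1)
          }
          verb_resp <- apply_chatter(clean_resp, config$chatter_prob)
          rows[[length(rows) + 1L]] <- tibble::tibble(
            child_id = child_id, age_months = age, subtest = code,
            item_index = ii - 1L, stimulus_id = stim$stimulus_id,
            prompt_text = stim$prompt,
            response_text = c(clean_resp, verb_resp),
            transcript_kind = c("clean", "verbatim"),
            gold_score = as.integer(gold), group = group
          )
          zeros <- if (gold == 0L) zeros + 1L else 0L
          if (!is.na(run) && zeros >= run) break
        }
      }
    }
  })
  all_rows <- dplyr::bind_rows(rows)
  list(
    clean = sort_corpus(all_rows[all_rows$transcript_kind == "clean", ]),
    verbatim = sort_corpus(all_rows[all_rows$transcript_kind == "verbatim", ]),
    banks = banks
  )
}
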