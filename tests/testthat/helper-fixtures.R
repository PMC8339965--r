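# Shared fixtures, built in code at test time.

# Independent minimum-edit-distance oracle: memoized top-down recursion over
# prefix lengths, cost only (no backtrace). Structurally different from the
# package's bottom-up tabulation with operation counts.
oracle_edit_distance <- function(a, b) {
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i == 0) return(j)
    if (j == 0) return(i)
    key <- paste0(i, ",", j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    res <- min(rec(i - 1, j - 1) + (a[i] != b[j]),
               rec(i - 1, j) + 1,
               rec(i, j - 1) + 1)
    memo[[key]] <- res
    res
  }
  rec(length(a), length(b))
}

# All token sequences of length 0..max_len over the given alphabet.
all_sequences <- function(alphabet, max_len) {
  out <- list(character(0))
  for (len in seq_len(max_len)) {
    grid <- do.call(expand.grid,
                    c(rep(list(alphabet), len), stringsAsFactors = FALSE))
    out <- c(out, lapply(seq_len(nrow(grid)), function(i) {
      unname(unlist(grid[i, ]))
    }))
  }
  out
}

# Minimal corpus: one child, one subtest, n items with the given gold scores.
tiny_corpus <- function(gold, subtest = "EV", child_id = "c1",
                        age_months = 72L, kind = "clean") {
  n <- length(gold)
  tibble::tibble(
    child_id = child_id, age_months = age_months, subtest = subtest,
    item_index = seq_len(n) - 1L,
    stimulus_id = sprintf("%s%02d", subtest, seq_len(n)),
    prompt_text = paste0("prompt", seq_len(n)),
    response_text = paste0("resp", seq_len(n)),
    transcript_kind = kind, gold_score = as.integer(gold)
  )
}

# Toy norm table: one age band [60, 120) per subtest, three raw intervals
# mapping to scaled 1 / 10 / 19; ELI table mapping sums around 30 to 100.
toy_norm_table <- function() {
  bands <- lapply(subtest_codes(), function(code) {
    raw_max <- subtest_params(code)$raw_max
    cut1 <- floor(raw_max / 3)
    cut2 <- floor(2 * raw_max / 3)
    tibble::tibble(
      subtest = code, age_min_months = 60L, age_max_months = 120L,
      raw_min = c(0L, cut1 + 1L, cut2 + 1L),
      raw_max = c(cut1, cut2, raw_max),
      scaled = c(1L, 10L, 19L)
    )
  })
  eli <- tibble::tibble(sum_min = c(3L, 25L, 36L),
                        sum_max = c(24L, 35L, 57L),
                        eli = c(55L, 100L, 145L))
  norm_table(dplyr::bind_rows(bands), eli)
}

# Small built norm table for pipeline-closure style tests.
small_built_norms <- function(seed = 7L) {
  build_norm_tables(reference_population(norms_config(n_per_band = 4000L),
                                         seed = seed))
}
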