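#' Read a transcript corpus from line-delimited JSON
#'
#' One JSON object per line, UTF-8, with fields `child_id`, `age_months`,
#' `subtest`, `item_index`, `stimulus_id`, `prompt_text`, `response_text`,
#' `transcript_kind`, and optional `gold_score`. Unknown fields (for example
#' a `group` tag used by stratified evaluation) are preserved as extra
#' columns and survive a write/read round trip. An absent `gold_score`
#' becomes `NA`.
#'
#' Line-delimited records rather than columnar text keep free-text child
#' responses (commas, quotes, apostrophes) unambiguous; [read_corpus_tsv()]
#' is a convenience import shim.
#'
#' @param path Path to the corpus file.
#'
#' @return A tibble sorted by `child_id`, `subtest`, `transcript_kind`,
#'   `item_index`.
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) stop_data("corpus file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(empty_corpus())
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(
      jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
      error = function(e) {
        stop_data("malformed corpus record at line ", i, ": ",
                  conditionMessage(e))
      }
    )
    need <- setdiff(setdiff(corpus_columns(), "gold_score"), names(rec))
    if (length(need) > 0) {
      stop_data("corpus record at line ", i, " is missing field(s): ",
                paste(need, collapse = ", "))
    }
    if (is.null(rec$gold_score)) rec$gold_score <- NA_integer_
    recs[[i]] <- tibble::as_tibble(rec)
  }
  corpus <- dplyr::bind_rows(recs)
  corpus$age_months <- as.integer(corpus$age_months)
  corpus$item_index <- as.integer(corpus$item_index)
  corpus$gold_score <- as.integer(corpus$gold_score)
  key <- paste(corpus$child_id, corpus$subtest, corpus$transcript_kind,
               corpus$item_index, sep = "\r")
  if (anyDuplicated(key)) {
    first_dup <- which(duplicated(key))[1]
    stop_data("duplicate (child_id, subtest, item_index) at line ", first_dup,
              ": ", corpus$child_id[first_dup], "/", corpus$subtest[first_dup],
              "/", corpus$item_index[first_dup])
  }
  sort_corpus(corpus)
}

#' Write a transcript corpus as line-delimited JSON
#'
#' Inverse of [read_corpus()]: `read_corpus(write_corpus(x, f))` equals `x`
#' field-for-field. `NA` gold scores are omitted from the record rather than
#' written as null.
#'
#' @param corpus Corpus tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  viol <- validate_corpus(corpus)
  if (nrow(viol) > 0) {
    stop_data("corpus fails validation (", nrow(viol), " violation(s)); ",
              "first: ", viol$message[1])
  }
  corpus <- sort_corpus(corpus)
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_len(nrow(corpus))) {
    rec <- as.list(corpus[i, ])
    rec <- rec[!vapply(rec, function(v) length(v) == 1 && is.na(v), logical(1))]
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA),
               con, useBytes = TRUE)
  }
  invisible(path)
}

#' Import a corpus from tab-separated text
#'
#' Convenience shim for corpora prepared in spreadsheets. Columns as in
#' [read_corpus()]; an empty `gold_score` cell means absent.
#'
#' @param path Path to a TSV file with a header row.
#' @return A corpus tibble.
#' @export
read_corpus_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", quote = "", comment.char = "",
                          stringsAsFactors = FALSE, encoding = "UTF-8")
  df$gold_score <- if ("gold_score" %in% names(df)) {
    as.integer(df$gold_score)
  } else {
    NA_integer_
  }
  df$age_months <- as.integer(df$age_months)
  df$item_index <- as.integer(df$item_index)
  sort_corpus(tibble::as_tibble(df))
}

sort_corpus <- function(corpus) {
  corpus[order(corpus$child_id, corpus$subtest, corpus$transcript_kind,
               corpus$item_index), , drop = FALSE]
}

empty_corpus <- function() {
  tibble::tibble(
    child_id = character(), age_months = integer(), subtest = character(),
    item_index = integer(), stimulus_id = character(),
    prompt_text = character(), response_text = character(),
    transcript_kind = character(), gold_score = integer()
  )
}

#' Construct a norm table object
#'
#' A norm table holds the two lookup stages of norm-referenced scoring:
#' per-subtest raw-to-scaled conversion within half-open age bands
#' `[age_min_months, age_max_months)`, and the scaled-sum-to-composite
#' (Expressive Language Index, ELI) lookup. Scaled scores live on 1-19 and
#' the composite on 45-155. The ELI is derived from the FS + RS + WS scaled
#' sum, so the composite table must cover sums 3 through 57.
#'
#' @param subtest_tables Tibble with columns `subtest`, `age_min_months`,
#'   `age_max_months`, `raw_min`, `raw_max`, `scaled`.
#' @param eli_table Tibble with columns `sum_min`, `sum_max`, `eli`.
#'
#' @return An object of class `norm_table`.
#' @export
norm_table <- function(subtest_tables, eli_table) {
  obj <- structure(
    list(subtest_tables = tibble::as_tibble(subtest_tables),
         eli_table = tibble::as_tibble(eli_table)),
    class = "norm_table"
  )
  validate_norm_table(obj)
  obj
}

#' Validate a norm table
#'
#' Enforces the lookup-table invariants: within each subtest x age band the
#' raw intervals are disjoint, contiguous and cover the full raw scale
#' 0..raw_max; scaled values lie in 1-19 and are non-decreasing in raw;
#' the ELI table covers scaled sums 3-57 contiguously with ELI values in
#' 45-155, non-decreasing in the sum.
#'
#' @param table A `norm_table` object.
#' @return `table`, invisibly; errors name the first offending band/interval.
#' @export
validate_norm_table <- function(table) {
  st <- table$subtest_tables
  need <- c("subtest", "age_min_months", "age_max_months",
            "raw_min", "raw_max", "scaled")
  if (!all(need %in% names(st))) {
    stop_data("norm table missing columns: ",
              paste(setdiff(need, names(st)), collapse = ", "))
  }
  if (any(!st$subtest %in% subtest_codes())) {
    stop_data("norm table has unknown subtest code(s): ",
              paste(unique(setdiff(st$subtest, subtest_codes())), collapse = ", "))
  }
  if (any(st$scaled < 1 | st$scaled > 19)) {
    stop_data("scaled score outside 1-19 in norm table")
  }
  bands <- split(st, paste(st$subtest, st$age_min_months, sep = "\r"))
  for (band in bands) {
    band <- band[order(band$raw_min), ]
    code <- band$subtest[1]
    raw_max <- subtest_params(code)$raw_max
    lab <- paste0(code, " band [", band$age_min_months[1], ",",
                  band$age_max_months[1], ")")
    if (band$raw_min[1] != 0) {
      stop_data("norm table ", lab, ": coverage gap, raw 0-",
                band$raw_min[1] - 1, " unmapped")
    }
    if (nrow(band) > 1) {
      gap <- which(band$raw_min[-1] != band$raw_max[-nrow(band)] + 1)
      if (length(gap) > 0) {
        g <- gap[1]
        stop_data("norm table ", lab, ": gap or overlap between raw interval ",
                  band$raw_min[g], "-", band$raw_max[g], " and ",
                  band$raw_min[g + 1], "-", band$raw_max[g + 1])
      }
      if (any(diff(band$scaled) < 0)) {
        stop_data("norm table ", lab, ": scaled not non-decreasing in raw")
      }
    }
    if (band$raw_max[nrow(band)] != raw_max) {
      stop_data("norm table ", lab, ": coverage ends at raw ",
                band$raw_max[nrow(band)], ", expected ", raw_max)
    }
    if (any(band$raw_max < band$raw_min)) {
      stop_data("norm table ", lab, ": empty raw interval")
    }
  }
  et <- table$eli_table
  need_eli <- c("sum_min", "sum_max", "eli")
  if (!all(need_eli %in% names(et))) {
    stop_data("ELI table missing columns: ",
              paste(setdiff(need_eli, names(et)), collapse = ", "))
  }
  et <- et[order(et$sum_min), ]
  if (nrow(et) == 0 || et$sum_min[1] > 3 || et$sum_max[nrow(et)] < 57) {
    stop_data("ELI table must cover scaled sums 3 through 57")
  }
  if (nrow(et) > 1 && any(et$sum_min[-1] != et$sum_max[-nrow(et)] + 1)) {
    stop_data("ELI table has a gap or overlap in scaled-sum intervals")
  }
  if (any(et$eli < 45 | et$eli > 155)) {
    stop_data("ELI value outside 45-155 in norm table")
  }
  if (nrow(et) > 1 && any(diff(et$eli) < 0)) {
    stop_data("ELI not non-decreasing in scaled sum")
  }
  invisible(table)
}

#' Read a norm table from delimited text
#'
#' One TSV file with a `section` column: rows with `section == "scaled"` give
#' the per-subtest raw-to-scaled bands (`subtest`, `age_min_months`,
#' `age_max_months`, `raw_min`, `raw_max`, `scaled`); rows with
#' `section == "eli"` give the composite lookup, reusing `raw_min`/`raw_max`
#' as the scaled-sum interval and `scaled` as the ELI value.
#'
#' @param path Path to the TSV file.
#' @return A validated `norm_table`.
#' @export
read_norm_table <- function(path) {
  if (!file.exists(path)) stop_data("norm table file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!"section" %in% names(df)) stop_data("norm table file lacks a 'section' column")
  sc <- df[df$section == "scaled", ]
  el <- df[df$section == "eli", ]
  norm_table(
    subtest_tables = tibble::tibble(
      subtest = sc$subtest,
      age_min_months = as.integer(sc$age_min_months),
      age_max_months = as.integer(sc$age_max_months),
      raw_min = as.integer(sc$raw_min), raw_max = as.integer(sc$raw_max),
      scaled = as.integer(sc$scaled)
    ),
    eli_table = tibble::tibble(
      sum_min = as.integer(el$raw_min), sum_max = as.integer(el$raw_max),
      eli = as.integer(el$scaled)
    )
  )
}

#' Write a norm table to delimited text
#'
#' @param table A `norm_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [read_norm_table()] for the file schema.
#' @export
write_norm_table <- function(table, path) {
  validate_norm_table(table)
  st <- table$subtest_tables
  et <- table$eli_table
  out <- rbind(
    data.frame(section = "scaled", subtest = st$subtest,
               age_min_months = st$age_min_months,
               age_max_months = st$age_max_months,
               raw_min = st$raw_min, raw_max = st$raw_max, scaled = st$scaled),
    data.frame(section = "eli", subtest = "ELI",
               age_min_months = NA_integer_, age_max_months = NA_integer_,
               raw_min = et$sum_min, raw_max = et$sum_max, scaled = et$eli)
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
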