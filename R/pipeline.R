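#' Run the full scoring pipeline
#'
#' Wires the stages end to end: obtain a corpus (simulate one, or read a
#' line-delimited corpus file), obtain norm tables (build synthetic ones, or
#' read a table file), run the repeated cross-validated scoring evaluation
#' when gold scores are present, aggregate the final repetition's predicted
#' item scores into score reports, and write every artifact with a manifest
#' (seed, config hash, package version). Configuration is one document with
#' per-stage sections; all values have defaults.
#'
#' ```
#' simulate: seed, n_children, transcript_kind   # or corpus: <path>
#' norms:    seed                                 # or path: <path>
#' scoring:  backend, n_folds, n_repetitions, seed
#' output:   dir
#' ```
#'
#' @param config A nested list, or the path to a YAML file holding one.
#'
#' @return Invisibly, a list with `corpus`, `norm_table`, `eval_report`
#'   (or `NULL` when no gold scores), `score_reports`, and `paths` of the
#'   written artifacts.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_data("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  out_dir <- config$output$dir %||% tempfile("elscore_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  # norm tables first: tier aggregation is impossible without them, so fail
  # before any training starts
  if (!is.null(config$norms$path)) {
    table <- read_norm_table(config$norms$path)
  } else {
    norm_seed <- config$norms$seed %||% 42L
    table <- build_norm_tables(reference_population(norms_config(),
                                                    seed = norm_seed))
  }
  paths$norm_table <- file.path(out_dir, "norm_table.tsv")
  write_norm_table(table, paths$norm_table)

  if (!is.null(config$simulate$corpus)) {
    corpus <- read_corpus(config$simulate$corpus)
  } else {
    gen <- generator_config(seed = config$simulate$seed %||% 1L,
                            n_children = config$simulate$n_children %||% 25L)
    kind <- config$simulate$transcript_kind %||% "clean"
    both <- generate_corpus(gen)
    corpus <- both[[kind]]
    paths$corpus_clean <- file.path(out_dir, "corpus_clean.jsonl")
    paths$corpus_verbatim <- file.path(out_dir, "corpus_verbatim.jsonl")
    write_corpus(both$clean, paths$corpus_clean)
    write_corpus(both$verbatim, paths$corpus_verbatim)
  }
  viol <- validate_corpus(corpus)
  if (nrow(viol) > 0) {
    stop_data("corpus fails validation; first violation: ", viol$message[1])
  }

  backend <- config$scoring$backend %||% "ngram"
  seed <- config$scoring$seed %||% 1L
  report <- NULL
  if (!any(is.na(corpus$gold_score))) {
    econf <- eval_config(n_folds = config$scoring$n_folds %||% 5L,
                         n_repetitions = config$scoring$n_repetitions %||% 1L,
                         seed = seed)
    report <- cross_validate(corpus, backend, train_config(seed = seed),
                             econf, table)
    paths$eval_summary <- file.path(out_dir, "eval_summary.tsv")
    utils::write.table(report$summary, paths$eval_summary, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    last <- report$predictions[report$predictions$rep ==
                                 max(report$predictions$rep), ]
    scored <- corpus
    key <- paste(corpus$child_id, corpus$subtest, corpus$item_index)
    scored$item_score <- last$predicted[match(key, paste(last$child_id,
                                                         last$subtest,
                                                         last$item_index))]
  } else {
    scored <- corpus
    scored$item_score <- scored$gold_score
    stop_data("corpus has items without gold scores; train/score on ",
              "pre-fitted models is available through fit_scorer()/",
              "predict_item_scores() directly")
  }
  reports <- score_reports(scored, table)
  paths$score_reports <- file.path(out_dir, "score_reports.tsv")
  write_score_reports(reports, paths$score_reports)

  manifest <- list(
    package_version = as.character(utils::packageVersion("elscore")),
    seed = seed, backend = backend,
    config_hash = str_hash(paste(deparse(config), collapse = "")),
    n_children = length(unique(corpus$child_id)),
    n_items = nrow(corpus)
  )
  paths$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE)

  invisible(list(corpus = corpus, norm_table = table, eval_report = report,
                 score_reports = reports, paths = paths))
}
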