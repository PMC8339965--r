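#' Evaluation configuration
#'
#' Defaults mirror the published protocol: 5-fold cross-validation repeated
#' over 20 reshuffles of the data set, with the mean (and SD) over
#' repetitions reported. Averaging for precision/recall defaults to
#' support-weighted, under which recall equals accuracy identically; macro
#' averaging is available.
#'
#' @param n_folds Number of folds (>= 2; default 5).
#' @param n_repetitions Number of shuffled repetitions (default 20).
#' @param averaging `"weighted"` (default) or `"macro"`.
#' @param seed Base seed; repetition r uses `seed + r`.
#' @param subgroup_key Optional corpus column for stratified reporting.
#'
#' @return A list of class `eval_config`.
#' @export
eval_config <- function(n_folds = 5L, n_repetitions = 20L,
                        averaging = c("weighted", "macro"), seed = 1L,
                        subgroup_key = NULL) {
  averaging <- match.arg(averaging)
  stopifnot(n_folds >= 2, n_repetitions >= 1)
  structure(list(n_folds = as.integer(n_folds),
                 n_repetitions = as.integer(n_repetitions),
                 averaging = averaging, seed = as.integer(seed),
                 subgroup_key = subgroup_key),
            class = "eval_config")
}

#' Item-level classification metrics
#'
#' Accuracy is the fraction of exact matches. Precision and recall are
#' averaged per class, either unweighted over classes (`macro`) or weighted
#' by gold-class support (`weighted`; support-weighted recall equals
#' accuracy). Classes absent from both gold and predicted values are
#' excluded; a class never predicted contributes precision 0.
#'
#' @param gold,predicted Equal-length vectors of scores in a common class
#'   set.
#' @param averaging `"weighted"` or `"macro"`.
#'
#' @return Named numeric vector `c(accuracy, precision, recall)`.
#' @export
classification_metrics <- function(gold, predicted,
                                   averaging = c("weighted", "macro")) {
  averaging <- match.arg(averaging)
  if (length(gold) != length(predicted)) {
    stop_data("gold and predicted have different lengths (",
              length(gold), " vs ", length(predicted), ")")
  }
  if (length(gold) == 0) stop_data("need at least one prediction")
  classes <- sort(union(unique(gold), unique(predicted)))
  acc <- mean(gold == predicted)
  prec <- rec <- sup <- numeric(length(classes))
  for (i in seq_along(classes)) {
    c_ <- classes[i]
    tp <- sum(gold == c_ & predicted == c_)
    prec[i] <- if (sum(predicted == c_) > 0) tp / sum(predicted == c_) else 0
    rec[i] <- if (sum(gold == c_) > 0) tp / sum(gold == c_) else 0
    sup[i] <- sum(gold == c_)
  }
  if (averaging == "macro") {
    c(accuracy = acc, precision = mean(prec), recall = mean(rec))
  } else {
    w <- sup / sum(sup)
    c(accuracy = acc, precision = sum(w * prec), recall = sum(w * rec))
  }
}

#' Mean absolute error between gold and predicted scores at one tier
#'
#' Aligns the two frames on the tier's identity columns — `(child_id,
#' subtest, item_index)` for the item tier, `(child_id, subtest)` for raw
#' and scaled, `child_id` for the ELI — and returns the mean absolute
#' difference of the tier's value column (`item_score`, `raw`, `scaled`,
#' `eli`). The item tier pools all items.
#'
#' @param gold,predicted Data frames carrying the tier's columns (item-tier:
#'   a scored corpus; raw/scaled: `subtest_reports`; eli: `eli_reports`).
#' @param tier One of `"item"`, `"raw"`, `"scaled"`, `"eli"`.
#'
#' @return Non-negative mean absolute error.
#' @export
tier_mae <- function(gold, predicted, tier = c("item", "raw", "scaled", "eli")) {
  tier <- match.arg(tier)
  keys <- switch(tier,
    item = c("child_id", "subtest", "item_index"),
    raw = c("child_id", "subtest"),
    scaled = c("child_id", "subtest"),
    eli = "child_id"
  )
  value <- switch(tier, item = "item_score", raw = "raw", scaled = "scaled",
                  eli = "eli")
  g <- gold[, c(keys, value)]
  p <- predicted[, c(keys, value)]
  names(g)[length(g)] <- "gold_value"
  names(p)[length(p)] <- "pred_value"
  m <- merge(as.data.frame(g), as.data.frame(p), by = keys)
  if (nrow(m) != nrow(g) || nrow(m) != nrow(p)) {
    stop_data("gold and predicted reports are misaligned at the ", tier,
              " tier (", nrow(g), " vs ", nrow(p), " rows, ", nrow(m),
              " matched)")
  }
  mean(abs(m$gold_value - m$pred_value))
}

#' Spearman rank correlation
#'
#' Rank correlation with average-rank tie handling. When either vector has
#' zero variance the correlation is undefined; `NA` is returned as a
#' sentinel rather than raising, and report summaries exclude such
#' repetitions with a count.
#'
#' @param gold,predicted Equal-length numeric vectors, length >= 3.
#' @return Correlation in `[-1, 1]`, or `NA` if undefined.
#' @export
spearman_rho <- function(gold, predicted) {
  if (length(gold) != length(predicted)) {
    stop_data("gold and predicted have different lengths")
  }
  if (length(gold) < 3) stop_data("need at least 3 observations")
  if (sd(gold) == 0 || sd(predicted) == 0) return(NA_real_)
  cor(gold, predicted, method = "spearman")
}

# Assign children to folds for one repetition: shuffle, then deal
# round-robin so folds are balanced, disjoint, and exhaustive.
fold_assignment <- function(children, n_folds, seed) {
  shuffled <- with_seed(derive_seed(seed, "folds"), sample(children))
  rep_len(seq_len(n_folds), length(children))[match(children, shuffled)]
}

#' Repeated k-fold cross-validated scoring evaluation
#'
#' The evaluation harness of the scoring system: for each repetition the
#' children are reshuffled and partitioned into folds (folds split children,
#' not items, so no child contributes to both training and test of a fold);
#' per fold, one scorer per subtest is trained on the training children and
#' predicts the test children's items. Per repetition the harness computes
#' item-level accuracy, precision, recall, MAE, and Spearman correlation per
#' subtest on the concatenated test folds, then aggregates item scores
#' through [score_reports()] to compute raw, scaled, and ELI tier MAE and
#' correlations against the gold-derived tiers. The report gives the mean
#' and SD over repetitions.
#'
#' @param corpus A gold-scored corpus tibble (one transcript kind).
#' @param backend Backend name (see [scorer_spec()]) applied to every
#'   subtest, or a named list mapping subtest codes to backend names.
#' @param tconfig A [train_config()].
#' @param econfig An [eval_config()].
#' @param table A `norm_table` for the tier aggregation.
#' @param ceiling_on Discontinuation stream passed to [score_reports()] for
#'   the predicted tiers (default `"scored"`).
#'
#' @return An object of class `eval_report`: list with `per_rep` (long
#'   tibble: `rep`, `subtest`, `tier`, `metric`, `value`), `summary` (mean,
#'   sd, and `n_excluded` undefined-correlation repetitions per metric),
#'   `predictions` (per-item gold and predicted scores for every
#'   repetition), and `manifest`.
#' @export
cross_validate <- function(corpus, backend, tconfig = train_config(),
                           econfig = eval_config(), table = NULL,
                           ceiling_on = "scored") {
  stopifnot(inherits(econfig, "eval_config"))
  if (any(is.na(corpus$gold_score))) {
    stop_data("cross-validation requires gold scores on every item")
  }
  subtests <- sort(unique(corpus$subtest))
  backends <- if (is.list(backend)) backend else
    setNames(as.list(rep(backend, length(subtests))), subtests)
  for (code in subtests) {
    n_children <- length(unique(corpus$child_id[corpus$subtest == code]))
    if (n_children < econfig$n_folds) {
      stop_data("subtest ", code, " has ", n_children,
                " children but ", econfig$n_folds, " folds were requested")
    }
  }
  children <- sort(unique(corpus$child_id))
  per_rep <- list()
  pred_rows <- list()
  for (rep_i in seq_len(econfig$n_repetitions)) {
    rep_seed <- econfig$seed + rep_i
    folds <- fold_assignment(children, econfig$n_folds, rep_seed)
    pred <- rep(NA_integer_, nrow(corpus))
    for (f in seq_len(econfig$n_folds)) {
      test_children <- children[folds == f]
      test_rows <- corpus$child_id %in% test_children
      for (code in subtests) {
        tr_rows <- !test_rows & corpus$subtest == code
        te_rows <- test_rows & corpus$subtest == code
        if (!any(te_rows)) next
        cfg <- tconfig
        cfg$seed <- derive_seed(rep_seed, "fold", f, code)
        scorer <- fit_scorer(scorer_spec(backends[[code]], code),
                             corpus[tr_rows, ], cfg)
        pred[te_rows] <- predict_item_scores(scorer, corpus[te_rows, ])
      }
    }
    scored <- corpus
    scored$item_score <- pred
    pred_rows[[rep_i]] <- tibble::tibble(
      rep = rep_i, child_id = scored$child_id, subtest = scored$subtest,
      item_index = scored$item_index, gold = scored$gold_score,
      predicted = pred,
      group = if ("group" %in% names(scored)) scored$group else NA_character_
    )
    per_rep[[rep_i]] <- rep_metrics(scored, table, econfig$averaging,
                                    ceiling_on, rep_i)
  }
  per_rep <- dplyr::bind_rows(per_rep)
  summary <- summarize_report(per_rep)
  structure(
    list(per_rep = per_rep, summary = summary,
         predictions = dplyr::bind_rows(pred_rows),
         manifest = list(seed = econfig$seed, n_folds = econfig$n_folds,
                         n_repetitions = econfig$n_repetitions,
                         backends = backends,
                         averaging = econfig$averaging)),
    class = "eval_report"
  )
}

# Metrics for one repetition on a corpus with item_score predictions.
rep_metrics <- function(scored, table, averaging, ceiling_on, rep_i) {
  out <- list()
  add <- function(subtest, tier, metric, value) {
    out[[length(out) + 1L]] <<- tibble::tibble(
      rep = rep_i, subtest = subtest, tier = tier, metric = metric,
      value = value)
  }
  for (code in sort(unique(scored$subtest))) {
    rows <- scored[scored$subtest == code, ]
    cm <- classification_metrics(rows$gold_score, rows$item_score, averaging)
    for (m in names(cm)) add(code, "item", m, unname(cm[m]))
    add(code, "item", "mae", mean(abs(rows$gold_score - rows$item_score)))
    add(code, "item", "spearman", spearman_rho(rows$gold_score,
                                               rows$item_score))
  }
  if (!is.null(table)) {
    gold_scored <- scored
    gold_scored$item_score <- gold_scored$gold_score
    gold_rep <- score_reports(gold_scored, table, ceiling_on = "scored")
    pred_rep <- score_reports(scored, table, ceiling_on = ceiling_on)
    for (code in sort(unique(scored$subtest))) {
      g <- gold_rep$subtest_reports[gold_rep$subtest_reports$subtest == code, ]
      p <- pred_rep$subtest_reports[pred_rep$subtest_reports$subtest == code, ]
      for (tier in c("raw", "scaled")) {
        add(code, tier, "mae", tier_mae(g, p, tier))
        add(code, tier, "spearman",
            spearman_rho(g[[tier]], p[[tier]][match(g$child_id, p$child_id)]))
      }
    }
    if (nrow(gold_rep$eli_reports) >= 3 && nrow(pred_rep$eli_reports) >= 3) {
      g <- gold_rep$eli_reports
      p <- pred_rep$eli_reports
      add("ELI", "eli", "mae", tier_mae(g, p, "eli"))
      add("ELI", "eli", "spearman",
          spearman_rho(g$eli, p$eli[match(g$child_id, p$child_id)]))
    }
  }
  dplyr::bind_rows(out)
}

summarize_report <- function(per_rep) {
  dplyr::summarise(
    dplyr::group_by(per_rep, .data$subtest, .data$tier, .data$metric),
    mean = mean(.data$value[!is.na(.data$value)]),
    sd = if (sum(!is.na(.data$value)) > 1) sd(.data$value[!is.na(.data$value)]) else NA_real_,
    n_reps = dplyr::n(),
    n_excluded = sum(is.na(.data$value)),
    .groups = "drop"
  )
}

#' Stratified (subgroup) item-level metrics
#'
#' Recomputes item-level accuracy, precision, and recall separately per
#' subgroup over the predictions already made by [cross_validate()] — no
#' retraining — mirroring stratified reporting such as typically-developing
#' vs. not. Groups with no test items are omitted with a warning.
#'
#' @param report An `eval_report` whose corpus carried the subgroup column.
#' @param averaging `"weighted"` or `"macro"`.
#'
#' @return Tibble with `group`, `subtest`, `metric`, `mean`, `sd`.
#' @export
subgroup_report <- function(report, averaging = c("weighted", "macro")) {
  averaging <- match.arg(averaging)
  preds <- report$predictions
  if (all(is.na(preds$group))) {
    stop_data("corpus carried no subgroup column; nothing to stratify")
  }
  out <- list()
  for (grp in sort(unique(preds$group))) {
    rows_g <- preds[preds$group == grp, ]
    if (nrow(rows_g) == 0) {
      warning("subgroup ", grp, " has no test items; omitted", call. = FALSE)
      next
    }
    for (code in sort(unique(rows_g$subtest))) {
      for (rep_i in sort(unique(rows_g$rep))) {
        rows <- rows_g[rows_g$subtest == code & rows_g$rep == rep_i, ]
        cm <- classification_metrics(rows$gold, rows$predicted, averaging)
        out[[length(out) + 1L]] <- tibble::tibble(
          group = grp, subtest = code, rep = rep_i,
          metric = names(cm), value = unname(cm))
      }
    }
  }
  long <- dplyr::bind_rows(out)
  dplyr::summarise(
    dplyr::group_by(long, .data$group, .data$subtest, .data$metric),
    mean = mean(.data$value), sd = if (dplyr::n() > 1) sd(.data$value) else NA_real_,
    .groups = "drop"
  )
}
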