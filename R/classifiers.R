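#' Training configuration for item classifiers
#'
#' Defaults follow the training protocol of the scoring system: 10% of the
#' data held out for validation, training stopped when validation loss fails
#' to improve for four consecutive epochs with the best-loss state restored,
#' and an L2 penalty on the weights. Optimizer step size and batch size are
#' conventional fine-tuning settings, configurable here.
#'
#' @param validation_fraction Fraction of training pairs held out for
#'   validation (default 0.10).
#' @param patience_epochs Consecutive non-improving epochs tolerated
#'   (default 4).
#' @param l2_weight L2 regularization coefficient on weight matrices
#'   (default 0.01).
#' @param max_epochs Epoch cap for iterative backends (default 50).
#' @param learning_rate Adam step size (default 0.005; the MLP uses this
#'   directly, small attention models train well with it from scratch).
#' @param batch_size Minibatch size (default 16).
#' @param seed Integer seed controlling initialization, the validation
#'   split, and epoch shuffles.
#'
#' @return A list of class `train_config`.
#' @export
train_config <- function(validation_fraction = 0.10, patience_epochs = 4L,
                         l2_weight = 0.01, max_epochs = 50L,
                         learning_rate = 0.005, batch_size = 16L, seed = 1L) {
  stopifnot(validation_fraction > 0, validation_fraction < 1,
            patience_epochs >= 1, l2_weight >= 0, max_epochs >= 1,
            learning_rate > 0, batch_size >= 1)
  structure(
    list(validation_fraction = validation_fraction,
         patience_epochs = as.integer(patience_epochs),
         l2_weight = l2_weight, max_epochs = as.integer(max_epochs),
         learning_rate = learning_rate, batch_size = as.integer(batch_size),
         seed = as.integer(seed)),
    class = "train_config"
  )
}

#' Specify an item-scorer backend for one subtest
#'
#' All backends share one fit/predict contract ([fit_scorer()],
#' [predict_item_scores()]):
#' \describe{
#'   \item{`attention`}{A small self-attention prompt-response pair encoder
#'     with a softmax head, trained from random initialization with the full
#'     protocol (validation holdout, L2, patience early stopping). The
#'     architectural counterpart of fine-tuned transformer pair
#'     classification, at a size that trains in seconds on one CPU.}
#'   \item{`svm_mean_embedding`}{SVM on the 300-dimensional mean word
#'     embedding of the response (the EV/WS baseline family).}
#'   \item{`svm_edit_features`}{SVM on alignment correctness features
#'     (insertions, deletions, substitutions, correct words) against the
#'     target sentence; RS only.}
#'   \item{`mlp_static_embedding`}{MLP on a static (not fine-tuned) sentence
#'     embedding of the response (the FS baseline family).}
#'   \item{`ngram`}{Lightweight nearest-profile model over response n-grams
#'     and prompt-overlap features; deterministic, training-free beyond
#'     storing profiles.}
#' }
#'
#' @param backend One of `"attention"`, `"svm_mean_embedding"`,
#'   `"svm_edit_features"`, `"mlp_static_embedding"`, `"ngram"`.
#' @param subtest Subtest code the scorer is for.
#'
#' @return A list of class `scorer_spec` with `backend`, `subtest`,
#'   `classes`, `n_classes`.
#' @export
scorer_spec <- function(backend, subtest) {
  backend <- match.arg(backend, c("attention", "svm_mean_embedding",
                                  "svm_edit_features", "mlp_static_embedding",
                                  "ngram"))
  subtest <- match.arg(subtest, subtest_codes())
  if (backend == "svm_edit_features" && subtest != "RS") {
    stop_data("svm_edit_features is only valid for the RS subtest")
  }
  classes <- subtest_params(subtest)$score_classes
  structure(list(backend = backend, subtest = subtest, classes = classes,
                 n_classes = length(classes)),
            class = "scorer_spec")
}

#' Encode a prompt-response pair for the attention backend
#'
#' Produces the token-id sequence `<cls> prompt <sep> response` with segment
#' flags (1 for the prompt side including the markers, 2 for the response),
#' mirroring the special-token pair encoding used by transformer pair
#' classifiers. Over-length input is truncated response-last: response
#' tokens are dropped from the end first, then prompt tokens if the prompt
#' alone exceeds the budget. Deterministic for fixed text and vocabulary.
#'
#' @param prompt_text Prompt string.
#' @param response_text Response string (may be empty).
#' @param vocab Named integer vector mapping tokens to ids; must contain
#'   `<cls>`, `<sep>`, `<unk>`.
#' @param max_len Maximum sequence length (>= 8).
#'
#' @return List with `ids`, `segments`, `tokens`.
#' @export
encode_pair <- function(prompt_text, response_text, vocab, max_len = 32L) {
  stopifnot(max_len >= 8)
  p <- normalize_tokens(prompt_text)
  r <- normalize_tokens(response_text)
  budget <- max_len - 2L  # <cls> and <sep>
  if (length(p) > budget) p <- p[seq_len(budget)]
  r_room <- budget - length(p)
  if (length(r) > r_room) r <- r[seq_len(r_room)]
  tokens <- c("<cls>", p, "<sep>", r)
  ids <- unname(vocab[tokens])
  ids[is.na(ids)] <- unname(vocab["<unk>"])
  segments <- c(rep(1L, length(p) + 2L), rep(2L, length(r)))
  list(ids = as.integer(ids), segments = segments, tokens = tokens)
}

build_vocab <- function(texts) {
  toks <- unique(unlist(lapply(texts, normalize_tokens)))
  all <- c("<cls>", "<sep>", "<unk>", "<pad>", toks)
  setNames(seq_along(all), all)
}

# Random validation split with stratified fallback when a class would be
# missing from the training portion.
split_validation <- function(labels, fraction, seed) {
  n <- length(labels)
  n_val <- max(1L, round(n * fraction))
  with_seed(derive_seed(seed, "valsplit"), {
    val <- sample(n, n_val)
    if (!all(unique(labels) %in% labels[-val])) {
      warning("random validation split would empty a class; ",
              "falling back to a stratified split", call. = FALSE)
      val <- integer(0)
      for (cl in unique(labels)) {
        idx <- which(labels == cl)
        take <- min(length(idx) - 1L, max(0L, round(length(idx) * fraction)))
        if (take > 0) val <- c(val, sample(idx, take))
      }
      if (length(val) == 0) val <- sample(n, 1)
    }
    sort(val)
  })
}

#' Fit an item scorer
#'
#' Trains the backend named in `spec` on gold-scored prompt-response pairs.
#' Iterative backends (attention, MLP) hold out a validation fraction,
#' train with Adam plus an L2 penalty, stop when validation loss has not
#' improved for `patience_epochs` epochs, and restore the best-loss state;
#' the per-epoch train/validation losses are kept in the training log. SVM
#' and n-gram backends fit in one shot and log nothing.
#'
#' @param spec A [scorer_spec()].
#' @param pairs Tibble with columns `prompt_text`, `response_text`,
#'   `gold_score` (all gold scores must lie in the subtest's score classes,
#'   and at least two classes must be present).
#' @param config A [train_config()].
#' @param provider Embedding provider for the embedding-based baselines
#'   (default: a hash provider seeded from `config$seed`).
#'
#' @return An object of class `el_scorer` supporting
#'   [predict_item_scores()], with elements `spec`, `log` (tibble of
#'   per-epoch losses for iterative backends), and `manifest`.
#' @export
fit_scorer <- function(spec, pairs, config = train_config(),
                       provider = NULL) {
  stopifnot(inherits(spec, "scorer_spec"), inherits(config, "train_config"))
  if (nrow(pairs) < 2) stop_data("need at least 2 training pairs")
  gold <- pairs$gold_score
  if (any(is.na(gold)) || !all(gold %in% spec$classes)) {
    stop_data("gold scores must all lie in {",
              paste(spec$classes, collapse = ","), "}")
  }
  if (length(unique(gold)) < 2) {
    stop_data("training data contains a single class; cannot fit a classifier")
  }
  labels <- match(gold, spec$classes)
  if (is.null(provider) &&
      spec$backend %in% c("svm_mean_embedding", "mlp_static_embedding")) {
    provider <- hash_embedding_provider(300L, config$seed)
  }
  fitted <- switch(spec$backend,
    attention = fit_attention_backend(spec, pairs, labels, config),
    svm_mean_embedding = fit_svm_backend(spec, pairs, labels, config,
                                         svm_embed_features(provider)),
    svm_edit_features = fit_svm_backend(spec, pairs, labels, config,
                                        svm_edit_feature_fn()),
    mlp_static_embedding = fit_mlp_backend(spec, pairs, labels, config,
                                           provider),
    ngram = fit_ngram_backend(spec, pairs, labels)
  )
  fitted$spec <- spec
  fitted$manifest <- list(
    backend = spec$backend, subtest = spec$subtest, seed = config$seed,
    n_train = nrow(pairs),
    data_hash = str_hash(paste(pairs$prompt_text, pairs$response_text,
                               gold, collapse = "\n"))
  )
  class(fitted) <- "el_scorer"
  fitted
}

#' Predict item scores for prompt-response pairs
#'
#' @param scorer A fitted `el_scorer`.
#' @param pairs Tibble with `prompt_text` and `response_text` (and, if
#'   present, a `subtest` column which must match the scorer's subtest).
#'
#' @return Integer vector of item scores, one per row of `pairs`, each in
#'   the subtest's score classes; deterministic for a fitted model.
#' @export
predict_item_scores <- function(scorer, pairs) {
  stopifnot(inherits(scorer, "el_scorer"))
  if ("subtest" %in% names(pairs) && nrow(pairs) > 0 &&
      !all(pairs$subtest == scorer$spec$subtest)) {
    stop_data("pairs are for subtest(s) ",
              paste(unique(pairs$subtest), collapse = ","),
              " but scorer was fitted for ", scorer$spec$subtest)
  }
  if (nrow(pairs) == 0) return(integer(0))
  idx <- scorer$predict_fn(pairs)
  as.integer(scorer$spec$classes[idx])
}

# ---- attention backend ----

fit_attention_backend <- function(spec, pairs, labels, config) {
  max_len <- 32L
  vocab <- build_vocab(c(pairs$prompt_text, pairs$response_text))
  enc <- lapply(seq_len(nrow(pairs)), function(i) {
    encode_pair(pairs$prompt_text[i], pairs$response_text[i], vocab, max_len)
  })
  val <- split_validation(labels, config$validation_fraction, config$seed)
  tr <- setdiff(seq_along(labels), val)
  params <- with_seed(derive_seed(config$seed, "attn-init"),
                      attn_init(length(vocab), spec$n_classes,
                                max_len = max_len))
  state <- list(params = params, opt = adam_init(params))

  step_fn <- function(state, epoch) {
    order <- with_seed(derive_seed(config$seed, "epoch", epoch),
                       sample(tr))
    train_loss <- 0
    for (start in seq(1, length(order), by = config$batch_size)) {
      batch <- order[start:min(start + config$batch_size - 1, length(order))]
      grads <- zero_like(state$params)
      for (i in batch) {
        fb <- attn_forward(state$params, enc[[i]]$ids, enc[[i]]$segments,
                           labels[i], want_grads = TRUE)
        train_loss <- train_loss + fb$loss
        for (k in names(grads)) grads[[k]] <- grads[[k]] + fb$grads[[k]]
      }
      grads <- lapply(grads, function(gr) gr / length(batch))
      grads <- add_l2(grads, state$params, config$l2_weight, length(batch))
      upd <- adam_step(state$params, grads, state$opt, config$learning_rate)
      state$params <- upd$params
      state$opt <- upd$opt
    }
    val_loss <- mean(vapply(val, function(i) {
      attn_forward(state$params, enc[[i]]$ids, enc[[i]]$segments,
                   labels[i])$loss
    }, numeric(1)))
    list(state = state, train_loss = train_loss / length(tr),
         val_loss = val_loss)
  }

  res <- train_iterative(state, step_fn, config$max_epochs,
                         config$patience_epochs)
  params_best <- res$state$params
  list(
    log = res$log, best_epoch = res$best_epoch, stop_epoch = res$stop_epoch,
    vocab = vocab, params = params_best,
    predict_fn = function(newpairs) {
      vapply(seq_len(nrow(newpairs)), function(i) {
        e <- encode_pair(newpairs$prompt_text[i], newpairs$response_text[i],
                         vocab, max_len)
        which.max(attn_forward(params_best, e$ids, e$segments)$probs)
      }, integer(1))
    }
  )
}

# ---- MLP on static sentence embeddings ----

fit_mlp_backend <- function(spec, pairs, labels, config, provider) {
  X <- t(vapply(pairs$response_text, mean_embedding_features,
                numeric(provider$dim), provider = provider))
  val <- split_validation(labels, config$validation_fraction, config$seed)
  tr <- setdiff(seq_along(labels), val)
  params <- with_seed(derive_seed(config$seed, "mlp-init"),
                      mlp_init(provider$dim, spec$n_classes))
  state <- list(params = params, opt = adam_init(params))
  lr <- config$learning_rate

  step_fn <- function(state, epoch) {
    order <- with_seed(derive_seed(config$seed, "epoch", epoch), sample(tr))
    train_loss <- 0
    for (start in seq(1, length(order), by = config$batch_size)) {
      batch <- order[start:min(start + config$batch_size - 1, length(order))]
      grads <- zero_like(state$params)
      for (i in batch) {
        fb <- mlp_forward(state$params, X[i, ], labels[i], want_grads = TRUE)
        train_loss <- train_loss + fb$loss
        for (k in names(grads)) grads[[k]] <- grads[[k]] + fb$grads[[k]]
      }
      grads <- lapply(grads, function(gr) gr / length(batch))
      grads <- add_l2(grads, state$params, config$l2_weight, length(batch))
      upd <- adam_step(state$params, grads, state$opt, lr)
      state$params <- upd$params
      state$opt <- upd$opt
    }
    val_loss <- mean(vapply(val, function(i) {
      mlp_forward(state$params, X[i, ], labels[i])$loss
    }, numeric(1)))
    list(state = state, train_loss = train_loss / length(tr),
         val_loss = val_loss)
  }

  res <- train_iterative(state, step_fn, config$max_epochs,
                         config$patience_epochs)
  params_best <- res$state$params
  list(
    log = res$log, best_epoch = res$best_epoch, stop_epoch = res$stop_epoch,
    params = params_best, provider = provider,
    predict_fn = function(newpairs) {
      vapply(seq_len(nrow(newpairs)), function(i) {
        x <- mean_embedding_features(newpairs$response_text[i], provider)
        which.max(mlp_forward(params_best, x)$probs)
      }, integer(1))
    }
  )
}

# ---- SVM backends ----

svm_embed_features <- function(provider) {
  function(pairs) {
    t(vapply(pairs$response_text, mean_embedding_features,
             numeric(provider$dim), provider = provider))
  }
}

svm_edit_feature_fn <- function() {
  function(pairs) {
    t(vapply(seq_len(nrow(pairs)), function(i) {
      rs_features(pairs$response_text[i], pairs$prompt_text[i])
    }, numeric(4)))
  }
}

fit_svm_backend <- function(spec, pairs, labels, config, feature_fn) {
  X <- feature_fn(pairs)
  y <- factor(labels, levels = seq_len(spec$n_classes))
  model <- with_seed(derive_seed(config$seed, "svm"),
                     e1071::svm(X, y, kernel = "linear", scale = FALSE))
  list(
    log = tibble::tibble(epoch = integer(), train_loss = numeric(),
                         val_loss = numeric()),
    model = model,
    predict_fn = function(newpairs) {
      as.integer(as.character(predict(model, feature_fn(newpairs))))
    }
  )
}

# ---- lightweight n-gram nearest-profile backend ----

ngram_profile <- function(prompt_text, response_text) {
  p <- normalize_tokens(prompt_text)
  r <- normalize_tokens(response_text)
  feats <- character(0)
  if (length(r) > 0) {
    feats <- c(paste0("r:", r),
               if (length(r) > 1) paste0("rb:", head(r, -1), "_", r[-1]),
               paste0("hit:", r[r %in% p]))
    miss <- setdiff(p, r)
    if (length(miss) > 0) feats <- c(feats, paste0("gap:", miss))
  } else {
    feats <- c("empty", paste0("gap:", p))
  }
  tab <- table(feats)
  setNames(as.numeric(tab), names(tab))
}

cosine_named <- function(a, b) {
  common <- intersect(names(a), names(b))
  if (length(common) == 0) return(0)
  sum(a[common] * b[common]) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
}

fit_ngram_backend <- function(spec, pairs, labels) {
  profiles <- lapply(seq_len(nrow(pairs)), function(i) {
    ngram_profile(pairs$prompt_text[i], pairs$response_text[i])
  })
  list(
    log = tibble::tibble(epoch = integer(), train_loss = numeric(),
                         val_loss = numeric()),
    profiles = profiles, labels = labels,
    predict_fn = function(newpairs) {
      vapply(seq_len(nrow(newpairs)), function(i) {
        q <- ngram_profile(newpairs$prompt_text[i], newpairs$response_text[i])
        sims <- vapply(profiles, cosine_named, numeric(1), a = q)
        labels[which.max(sims)]  # ties: lowest training index
      }, integer(1))
    }
  )
}
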