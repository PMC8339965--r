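#' Deterministic hash-projection word-embedding provider
#'
#' The SVM and MLP baseline classifiers consume fixed-dimensional word
#' vectors (300 dimensions by convention for static word embeddings). This
#' provider maps every token to a reproducible pseudo-random Gaussian vector
#' keyed by a hash of the token string, so the package trains and tests with
#' no embedding download; a pre-trained embedding file can be plugged in via
#' [file_embedding_provider()]. Hash vectors carry no semantics — two
#' related words are no closer than two unrelated ones — which is sufficient
#' for the vocabulary-separable synthetic corpora the package tests on.
#'
#' @param dim Embedding dimensionality (default 300).
#' @param seed Integer seed; the same seed always yields the same vectors.
#'
#' @return An embedding provider: a list with `dim` and `lookup(tokens)`,
#'   the latter returning a `length(tokens) x dim` matrix.
#' @export
hash_embedding_provider <- function(dim = 300L, seed = 1L) {
  cache <- new.env(parent = emptyenv())
  lookup <- function(tokens) {
    out <- matrix(0, length(tokens), dim)
    for (i in seq_along(tokens)) {
      tok <- tokens[i]
      if (is.null(cache[[tok]])) {
        cache[[tok]] <- with_seed(derive_seed(seed, "emb", tok),
                                  rnorm(dim) / sqrt(dim))
      }
      out[i, ] <- cache[[tok]]
    }
    out
  }
  structure(list(dim = as.integer(dim), lookup = lookup),
            class = "embedding_provider")
}

#' Word-embedding provider backed by a vectors file
#'
#' Reads whitespace-delimited text in the common word-vectors layout (one
#' token followed by its components per line). Out-of-vocabulary tokens map
#' to the zero vector.
#'
#' @param path Path to the vectors file.
#' @return An embedding provider; see [hash_embedding_provider()].
#' @export
file_embedding_provider <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  parts <- strsplit(lines[nzchar(lines)], "\\s+")
  dim <- length(parts[[1]]) - 1L
  vecs <- do.call(rbind, lapply(parts, function(p) as.numeric(p[-1])))
  rownames(vecs) <- vapply(parts, `[[`, character(1), 1)
  lookup <- function(tokens) {
    out <- matrix(0, length(tokens), dim)
    hit <- tokens %in% rownames(vecs)
    if (any(hit)) out[hit, ] <- vecs[tokens[hit], , drop = FALSE]
    out
  }
  structure(list(dim = dim, lookup = lookup), class = "embedding_provider")
}

#' Mean word-embedding feature vector for a response
#'
#' The feature representation of the EV/WS baseline classifiers: the
#' arithmetic mean of the embedding vectors of all tokens in the response.
#' An empty response (and any out-of-vocabulary-only response under a file
#' provider) yields the zero vector, so the mean is always defined.
#'
#' @param response_text Response string.
#' @param provider An embedding provider.
#' @return Numeric vector of length `provider$dim`.
#' @export
mean_embedding_features <- function(response_text, provider) {
  tokens <- normalize_tokens(response_text)
  if (length(tokens) == 0) return(numeric(provider$dim))
  colMeans(provider$lookup(tokens))
}
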