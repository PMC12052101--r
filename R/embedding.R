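#' Skip-gram embedding hyperparameters
#'
#' The training contract for the coherence experiments: 128-dimensional
#' skip-gram vectors, context window 10, every token kept (`min_count = 1`,
#' so concept identifiers seen even once are embedded), 5 negative samples
#' per positive context word, learning rate decaying linearly from 0.03 to
#' 0.0001, and frequency subsampling at 1e-3. Epochs default to 5. All are
#' overridable; `window` values of 2, 5 and 10 span the usual sweep.
#'
#' @param dim Embedding dimension (> 0).
#' @param window Maximum context window size (>= 1).
#' @param min_count Minimum corpus frequency for a token to be embedded.
#' @param negative Negative samples per positive context word.
#' @param alpha,min_alpha Initial and final learning rate
#'   (`alpha > min_alpha > 0`).
#' @param sample Subsampling threshold for frequent tokens; 0 disables.
#' @param epochs Training passes over the corpus.
#' @param seed Integer seed; training is single-threaded and run-to-run
#'   deterministic for a fixed seed.
#' @return A list of class `embedding_params`.
#' @export
embedding_params <- function(dim = 128, window = 10, min_count = 1,
                             negative = 5, alpha = 0.03, min_alpha = 1e-4,
                             sample = 1e-3, epochs = 5, seed = 1L) {
  if (dim < 1) rlang::abort("`dim` must be positive")
  if (window < 1) rlang::abort("`window` must be >= 1")
  if (!(alpha > min_alpha && min_alpha > 0)) {
    rlang::abort("need alpha > min_alpha > 0")
  }
  if (negative < 1) rlang::abort("`negative` must be >= 1")
  structure(
    list(dim = as.integer(dim), window = as.integer(window),
         min_count = as.integer(min_count), negative = as.integer(negative),
         alpha = alpha, min_alpha = min_alpha, sample = sample,
         epochs = as.integer(epochs), seed = as.integer(seed)),
    class = "embedding_params"
  )
}

#' Train skip-gram embeddings on a corpus
#'
#' Runs the package's single-threaded skip-gram negative-sampling trainer.
#' The vocabulary is exactly the corpus tokens with frequency at least
#' `min_count`; tokens below the cutoff are dropped from the training
#' stream. Vectors are reproducible for a fixed seed and configuration on a
#' given platform (bitwise identity across platforms is not promised —
#' floating-point training).
#'
#' @param x A non-empty [corpus()].
#' @param params An [embedding_params()] object.
#' @return An `embedding_space`: a numeric matrix (tokens x dim) with token
#'   rownames and a `params` attribute.
#' @export
train_embeddings <- function(x, params = embedding_params()) {
  stopifnot(inherits(x, "corpus"), inherits(params, "embedding_params"))
  if (sum(lengths(x)) == 0L) rlang::abort("cannot embed an empty corpus")
  freq <- count_frequencies(x)
  kept <- freq[freq$count >= params$min_count, ]
  if (nrow(kept) == 0L) rlang::abort("no token reaches `min_count`")
  vocab <- kept$token
  idx <- stats::setNames(seq_along(vocab) - 1L, vocab)
  docs <- purrr::map(x, function(doc) {
    i <- idx[doc]
    unname(i[!is.na(i)])
  })
  docs <- purrr::keep(docs, function(d) length(d) > 0L)
  mat <- .sgns_train(docs, kept$count, params$dim, params$window,
                     params$negative, params$alpha, params$min_alpha,
                     params$sample, params$epochs, params$seed)
  rownames(mat) <- vocab
  new_embedding_space(mat, params)
}

new_embedding_space <- function(mat, params) {
  structure(mat, params = params, class = c("embedding_space", class(mat)))
}

#' @export
print.embedding_space <- function(x, ...) {
  cat(sprintf("<embedding_space: %d tokens x %d dims>\n", nrow(x), ncol(x)))
  invisible(x)
}

#' Tokens present in an embedding space
#' @param space An `embedding_space`.
#' @return Character vector of embedded tokens.
#' @export
space_vocab <- function(space) rownames(space)

#' Save / load an embedding space in word2vec text format
#'
#' The interchange format: a header line `vocab_size dim`, then one line per
#' token with the token followed by its vector components. Values are
#' written with full precision (17 significant digits) so a round trip
#' restores the vectors exactly.
#'
#' @param space An `embedding_space`.
#' @param path File path.
#' @return `path` invisibly ([save_space()]); an `embedding_space`
#'   ([load_space()]).
#' @export
save_space <- function(space, path) {
  stopifnot(inherits(space, "embedding_space"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(space), ncol(space)), con)
  body <- vapply(seq_len(nrow(space)), function(i) {
    paste(rownames(space)[i],
          paste(formatC(space[i, ], format = "g", digits = 17),
                collapse = " "))
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' @rdname save_space
#' @export
load_space <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) < 1L) rlang::abort(sprintf("empty embedding file: %s", path))
  hdr <- suppressWarnings(as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]]))
  if (length(hdr) != 2L || anyNA(hdr)) {
    rlang::abort(sprintf("malformed word2vec header in %s", path))
  }
  if (length(lines) - 1L != hdr[1]) {
    rlang::abort(sprintf("truncated embedding file: header promises %d rows, found %d",
                         hdr[1], length(lines) - 1L))
  }
  parts <- strsplit(trimws(lines[-1]), "\\s+")
  if (any(lengths(parts) != hdr[2] + 1L)) {
    rlang::abort(sprintf("malformed vector row in %s", path))
  }
  mat <- do.call(rbind, purrr::map(parts, function(p) as.numeric(p[-1])))
  if (anyNA(mat)) rlang::abort(sprintf("non-numeric vector entries in %s", path))
  rownames(mat) <- vapply(parts, `[[`, character(1), 1L)
  new_embedding_space(mat, NULL)
}
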