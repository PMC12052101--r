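#' Construct a tokenized corpus
#'
#' A corpus is an ordered list of documents, each an ordered character vector
#' of lowercase single tokens. Upstream preprocessing (concept-identifier
#' collapsing, lemmatization, stop-word removal) is assumed already done;
#' tokens are taken as given and never re-normalized here.
#'
#' @param documents List of character vectors (one per document).
#' @param source_label Free-text provenance label.
#' @return An object of class `corpus`.
#' @export
corpus <- function(documents = list(), source_label = "unknown") {
  stopifnot(is.list(documents))
  bad <- purrr::map_lgl(documents, function(d) any(grepl("\\s", d)))
  if (any(bad)) {
    rlang::abort(sprintf(
      "tokens must not contain whitespace (first offending document: %d)",
      which(bad)[1]
    ))
  }
  structure(
    purrr::map(documents, as.character),
    source_label = source_label,
    class = "corpus"
  )
}

#' @export
print.corpus <- function(x, ...) {
  cat(sprintf(
    "<corpus: %d documents, %d tokens, source: %s>\n",
    length(x), sum(lengths(x)), attr(x, "source_label") %||% "unknown"
  ))
  invisible(x)
}

#' Read a corpus from a one-document-per-line text file
#'
#' Each non-empty line becomes one document; tokens are split on runs of
#' whitespace. Blank lines are skipped and counted in the attached load
#' report (`attr(x, "load_report")`). An input yielding zero documents is
#' flagged (`empty = TRUE`) with a warning rather than silently returned.
#'
#' @param path Path to a UTF-8 text file.
#' @param source_label Provenance label; defaults to the file name.
#' @return A [corpus()] with a `load_report` attribute
#'   (`n_lines`, `n_documents`, `n_blank_skipped`, `empty`).
#' @export
read_corpus <- function(path, source_label = basename(path)) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("corpus file not found: %s", path))
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  blank <- !nzchar(trimws(lines))
  docs <- strsplit(trimws(lines[!blank]), "\\s+")
  out <- corpus(docs, source_label = source_label)
  report <- list(
    n_lines = length(lines),
    n_documents = length(docs),
    n_blank_skipped = sum(blank),
    empty = length(docs) == 0L
  )
  attr(out, "load_report") <- report
  if (report$empty) {
    rlang::warn(sprintf("corpus read from %s contains zero documents", path))
  }
  out
}

#' Write a corpus to a one-document-per-line text file
#'
#' Inverse of [read_corpus()]: tokens joined by single spaces, one document
#' per line. Round-tripping preserves token sequences exactly.
#'
#' @param x A [corpus()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(x, path) {
  stopifnot(inherits(x, "corpus"))
  writeLines(vapply(x, paste, character(1), collapse = " "), path, useBytes = TRUE)
  invisible(path)
}

#' Count token frequencies across a corpus
#'
#' Every occurrence counts: multiple occurrences of a token within one
#' document are counted multiple times. The mean frequency mu is the mean of
#' the per-type counts, i.e. total token occurrences divided by vocabulary
#' size; it is the default anchor for the replacement threshold.
#'
#' @param x A [corpus()].
#' @return A tibble of class `freq_table` with columns `token` and `count`,
#'   sorted by descending count then token, and attributes `total_tokens`,
#'   `vocab_size`, `mean_frequency`.
#' @export
count_frequencies <- function(x) {
  stopifnot(inherits(x, "corpus"))
  toks <- unlist(x, use.names = FALSE)
  if (length(toks) == 0L) {
    rlang::warn("empty corpus: frequency table is empty and mean frequency is 0")
    tab <- tibble::tibble(token = character(), count = integer())
    return(new_freq_table(tab, total_tokens = 0L, vocab_size = 0L,
                          mean_frequency = 0))
  }
  counts <- table(toks)
  tab <- tibble::tibble(
    token = names(counts),
    count = as.integer(counts)
  ) |>
    dplyr::arrange(dplyr::desc(count), token)
  new_freq_table(
    tab,
    total_tokens = length(toks),
    vocab_size = nrow(tab),
    mean_frequency = length(toks) / nrow(tab)
  )
}

new_freq_table <- function(tab, total_tokens, vocab_size, mean_frequency) {
  structure(
    tab,
    total_tokens = as.integer(total_tokens),
    vocab_size = as.integer(vocab_size),
    mean_frequency = mean_frequency,
    class = c("freq_table", class(tibble::tibble()))
  )
}

#' Total token occurrences recorded in a frequency table
#' @param x A `freq_table`.
#' @return Integer count of all token occurrences.
#' @export
total_tokens <- function(x) attr(x, "total_tokens")

#' Vocabulary size (distinct tokens) of a frequency table
#' @param x A `freq_table`.
#' @return Integer number of distinct tokens.
#' @export
vocab_size <- function(x) attr(x, "vocab_size")

#' Mean per-type token frequency (mu)
#'
#' `total_tokens / vocab_size`: the mean of the overall frequency taken over
#' distinct tokens. This is the quantity the default replacement threshold
#' is anchored to; on a large biomedical corpus it is small (hundreds)
#' because the vocabulary is heavy-tailed.
#'
#' @param x A `freq_table`.
#' @return A single number; 0 (with a warning at construction) for an empty
#'   corpus.
#' @export
mean_frequency <- function(x) attr(x, "mean_frequency")

#' Look up counts for tokens in a frequency table
#'
#' @param x A `freq_table`.
#' @param tokens Character vector of tokens.
#' @return Integer vector of counts; tokens absent from the corpus get 0.
#' @export
token_count <- function(x, tokens) {
  i <- match(tokens, x$token)
  out <- x$count[i]
  out[is.na(i)] <- 0L
  as.integer(out)
}

#' Write a frequency table as TSV
#'
#' `token<TAB>count`, sorted by descending count then token (the order the
#' table already carries).
#'
#' @param x A `freq_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frequencies <- function(x, path) {
  utils::write.table(
    as.data.frame(x[, c("token", "count")]),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}
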