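#' Create a synonym resource
#'
#' A synonym resource maps a word to its synonym pool: the union of the
#' word's synonym sets across all senses and parts of speech. Lookups are
#' pure and deterministic. Pools are normalized on construction with the
#' rules a tokenized corpus imposes:
#'
#' * members are lowercased;
#' * members containing whitespace, underscores, apostrophes or hyphens are
#'   dropped (multiword or punctuated lemmas can never match a single
#'   corpus token);
#' * duplicates are collapsed.
#'
#' The shipped backend is a table (TSV file or data frame). A table exported
#' from a lexical database such as WordNet passes through the same
#' normalization, so the two sources are interchangeable; `backend_label`
#' records which one a resource came from.
#'
#' @param x Either a path to a TSV file with lines
#'   `word<TAB>member1,member2,...`, or a data frame with columns `word` and
#'   `members` (comma-separated string or list of character vectors).
#' @param backend_label Provenance label, e.g. `"fixture"` or `"wordnet"`.
#' @return An object of class `synonym_resource`.
#' @export
synonym_resource <- function(x, backend_label = "fixture") {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) rlang::abort(sprintf("synonym table not found: %s", x))
    lines <- readLines(x, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    short <- lengths(parts) < 2L
    if (any(short)) {
      rlang::abort(sprintf("malformed synonym table line %d (need word<TAB>members)",
                           which(short)[1]))
    }
    tab <- tibble::tibble(
      word = vapply(parts, `[[`, character(1), 1L),
      members = purrr::map(parts, function(p) strsplit(p[[2]], ",", fixed = TRUE)[[1]])
    )
  } else {
    tab <- tibble::as_tibble(x)
    stopifnot(all(c("word", "members") %in% names(tab)))
    if (is.character(tab$members)) {
      tab$members <- strsplit(tab$members, ",", fixed = TRUE)
    }
  }
  tab$word <- tolower(trimws(tab$word))
  tab$members <- purrr::map(tab$members, normalize_pool)
  if (anyDuplicated(tab$word)) {
    tab <- tab |>
      dplyr::group_by(.data$word) |>
      dplyr::summarise(members = list(sort(unique(unlist(.data$members)))),
                       .groups = "drop")
  }
  lookup <- new.env(parent = emptyenv())
  purrr::walk2(tab$word, tab$members, function(w, m) assign(w, m, envir = lookup))
  structure(
    list(lookup = lookup, words = tab$word, backend_label = backend_label),
    class = "synonym_resource"
  )
}

# lowercase, drop multiword/underscore/apostrophe/hyphen lemmas, dedupe, sort
normalize_pool <- function(members) {
  m <- tolower(trimws(members))
  m <- m[nzchar(m)]
  m <- m[!grepl("[\\s_'-]", m, perl = TRUE)]
  sort(unique(m))
}

#' @export
print.synonym_resource <- function(x, ...) {
  cat(sprintf("<synonym_resource: %d words, backend: %s>\n",
              length(x$words), x$backend_label))
  invisible(x)
}

#' Look up the synonym pool of a word
#'
#' Returns the normalized pool for `word`: all single-token synonyms across
#' every sense, the word itself included when the resource lists it. A word
#' absent from the resource gets an empty pool, not an error — in the
#' replacement algorithm such words are simply retained.
#'
#' @param resource A [synonym_resource()].
#' @param word A lowercase single token.
#' @return Character vector of pool members (possibly empty), sorted.
#' @export
get_pool <- function(resource, word) {
  stopifnot(inherits(resource, "synonym_resource"))
  if (length(word) != 1L || !is.character(word)) {
    rlang::abort("`word` must be a single token")
  }
  get0(word, envir = resource$lookup, ifnotfound = character(0))
}

#' Path to the bundled fixture synonym table
#'
#' A small TSV resource used in examples and tests. It encodes two classic
#' pools — the "measure" pool (measure, step, quantity, amount, bill,
#' measurement, standard, criterion, touchstone, meter, metre, cadence, bar)
#' and the numeral pool (13, thirteen, xiii) — each member mapping to the
#' full pool.
#'
#' @return File path of the TSV inside the installed package.
#' @export
fixture_synonym_path <- function() {
  system.file("extdata", "synonyms_fixture.tsv", package = "synnorm",
              mustWork = TRUE)
}
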