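#' Default replacement threshold from the mean token frequency
#'
#' The canonical threshold is the mean per-type frequency mu of the corpus
#' (see [mean_frequency()]); a multiplier scales it for sensitivity sweeps.
#' Multipliers of 0.5, 1, 2 and 4 span the usual operating range: low
#' thresholds replace fewer words, high thresholds risk over-replacing.
#'
#' @param freq A `freq_table` from [count_frequencies()]; must be non-empty.
#' @param multiplier Positive scale factor applied to mu (default 1).
#' @return The threshold tau = multiplier * mu.
#' @export
default_threshold <- function(freq, multiplier = 1) {
  stopifnot(inherits(freq, "freq_table"))
  if (vocab_size(freq) == 0L) {
    rlang::abort("cannot derive a threshold from an empty frequency table")
  }
  if (!is.numeric(multiplier) || length(multiplier) != 1L || multiplier <= 0) {
    rlang::abort("`multiplier` must be a single positive number")
  }
  multiplier * mean_frequency(freq)
}

#' Build an infrequent-word to most-frequent-synonym replacement plan
#'
#' Implements the frequency-guided normalization heuristic. Candidates are
#' the corpus tokens with frequency strictly below the threshold tau,
#' excluding protected tokens (by default, biomedical concept-identifier
#' tokens). For each candidate `w` with a non-empty synonym pool, the target
#' is the pool member with the highest corpus frequency (`smax`); pool
#' members absent from the corpus count 0, and frequency ties break
#' lexicographically so the plan is deterministic. The mapping `w -> smax`
#' is kept only when `f(smax) >= tau` — a candidate all of whose synonyms
#' are themselves infrequent is presumed to carry specific, discriminating
#' meaning and is retained unchanged, as are candidates with no synonyms.
#'
#' Because every source has `f < tau` and every target `f >= tau`, the
#' source and target sets are disjoint: replacement chains are impossible
#' and applying a plan is idempotent.
#'
#' @param freq A `freq_table` of the corpus to be normalized.
#' @param resource A [synonym_resource()].
#' @param tau Positive frequency threshold (see [default_threshold()]).
#' @param protect Which tokens may never be replaced: a regular expression
#'   (default `"^(cid_|mesh|ncbigene)"`, matching common concept-identifier
#'   conventions), a predicate function over tokens, or `NULL` to protect
#'   nothing.
#' @return A tibble of class `replacement_plan` with columns `source`,
#'   `target`, `f_source`, `f_target` (sorted by source) and attributes
#'   `threshold`, `n_candidates`, `n_replaced`,
#'   `n_retained_all_infrequent`, `n_empty_pool`, `n_protected`,
#'   `vocab_size`.
#' @export
build_replacement_plan <- function(freq, resource,
                                   tau = default_threshold(freq),
                                   protect = "^(cid_|mesh|ncbigene)") {
  stopifnot(inherits(freq, "freq_table"), inherits(resource, "synonym_resource"))
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0) {
    rlang::abort("`tau` must be a single positive number")
  }
  is_protected <- protect_predicate(protect)

  infrequent <- freq$token[freq$count < tau]
  protected <- is_protected(infrequent)
  candidates <- infrequent[!protected]

  pools <- purrr::map(candidates, function(w) get_pool(resource, w))
  has_pool <- lengths(pools) > 0L

  pick <- purrr::map2(candidates[has_pool], pools[has_pool], function(w, pool) {
    f <- token_count(freq, pool)
    # ties at the maximum break to the lexicographically smallest member;
    # pools are sorted, so the first maximum is that member
    best <- which.max(f)
    list(target = pool[best], f_target = f[best])
  })
  target <- purrr::map_chr(pick, "target")
  f_target <- purrr::map_int(pick, "f_target")
  keep <- f_target >= tau & target != candidates[has_pool]

  mapping <- tibble::tibble(
    source = candidates[has_pool][keep],
    target = target[keep],
    f_source = token_count(freq, candidates[has_pool][keep]),
    f_target = f_target[keep]
  ) |>
    dplyr::arrange(.data$source)

  structure(
    mapping,
    threshold = tau,
    n_candidates = length(candidates),
    n_replaced = nrow(mapping),
    n_retained_all_infrequent = sum(has_pool) - sum(keep),
    n_empty_pool = sum(!has_pool),
    n_protected = sum(protected),
    vocab_size = vocab_size(freq),
    class = c("replacement_plan", class(tibble::tibble()))
  )
}

protect_predicate <- function(protect) {
  if (is.null(protect)) {
    function(tokens) rep(FALSE, length(tokens))
  } else if (is.function(protect)) {
    function(tokens) vapply(tokens, protect, logical(1), USE.NAMES = FALSE)
  } else if (is.character(protect) && length(protect) == 1L) {
    function(tokens) grepl(protect, tokens)
  } else {
    rlang::abort("`protect` must be NULL, a regex, or a predicate function")
  }
}

#' @export
print.replacement_plan <- function(x, ...) {
  cat(sprintf(
    "<replacement_plan: %d replacements, tau = %.4g, %d candidates (%d all-infrequent, %d no-pool, %d protected)>\n",
    attr(x, "n_replaced"), attr(x, "threshold"), attr(x, "n_candidates"),
    attr(x, "n_retained_all_infrequent"), attr(x, "n_empty_pool"),
    attr(x, "n_protected")
  ))
  NextMethod()
}

#' @describeIn build_replacement_plan `tidy()` returns the source/target
#'   mapping as a plain tibble.
#' @param x A `replacement_plan`.
#' @param ... Unused.
#' @export
tidy.replacement_plan <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("source", "target", "f_source", "f_target")])
}

#' @describeIn build_replacement_plan `glance()` returns a one-row tibble of
#'   the threshold and audit counts.
#' @export
glance.replacement_plan <- function(x, ...) {
  tibble::tibble(
    threshold = attr(x, "threshold"),
    n_candidates = attr(x, "n_candidates"),
    n_replaced = attr(x, "n_replaced"),
    n_retained_all_infrequent = attr(x, "n_retained_all_infrequent"),
    n_empty_pool = attr(x, "n_empty_pool"),
    n_protected = attr(x, "n_protected"),
    pct_vocab_replaced = 100 * attr(x, "n_replaced") / attr(x, "vocab_size")
  )
}

#' Apply a replacement plan to a corpus
#'
#' Single-pass substitution: every occurrence of a source token is replaced
#' 1:1 by its target; all other tokens, document order and per-document
#' token counts are untouched. The plan is held fixed — frequencies are not
#' recomputed during application. If the plan's vocabulary size differs from
#' the corpus's, a message notes the mismatch (the plan was probably built
#' from a different corpus).
#'
#' @param x A [corpus()].
#' @param plan A `replacement_plan`.
#' @return A new [corpus()] with `"+synnorm"` appended to the source label.
#' @export
apply_replacement <- function(x, plan) {
  stopifnot(inherits(x, "corpus"), inherits(plan, "replacement_plan"))
  nv <- length(unique(unlist(x, use.names = FALSE)))
  if (!is.null(attr(plan, "vocab_size")) && nv != attr(plan, "vocab_size")) {
    rlang::inform(sprintf(
      "plan vocabulary (%d) differs from corpus vocabulary (%d); was the plan built from this corpus?",
      attr(plan, "vocab_size"), nv
    ))
  }
  if (nrow(plan) == 0L) {
    out <- x
  } else {
    map <- stats::setNames(plan$target, plan$source)
    out <- purrr::map(x, function(doc) {
      i <- match(doc, names(map))
      hit <- !is.na(i)
      doc[hit] <- unname(map[i[hit]])
      doc
    })
  }
  corpus(out, source_label = paste0(attr(x, "source_label") %||% "unknown",
                                    "+synnorm"))
}

#' Export / import a replacement plan as TSV
#'
#' Four tab-separated columns: `source`, `target`, `f_source`, `f_target`,
#' with a header line. [read_plan()] restores the mapping; audit counts are
#' carried in a sidecar of the TSV header comment and recomputed where
#' possible.
#'
#' @param plan A `replacement_plan`.
#' @param path Output path.
#' @return `path` invisibly ([write_plan()]); a `replacement_plan`
#'   ([read_plan()]).
#' @export
write_plan <- function(plan, path) {
  stopifnot(inherits(plan, "replacement_plan"))
  hdr <- sprintf(
    "# tau=%.10g n_candidates=%d n_retained_all_infrequent=%d n_empty_pool=%d n_protected=%d vocab_size=%d",
    attr(plan, "threshold"), attr(plan, "n_candidates"),
    attr(plan, "n_retained_all_infrequent"), attr(plan, "n_empty_pool"),
    attr(plan, "n_protected"), attr(plan, "vocab_size")
  )
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(as.data.frame(tidy(plan)), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_plan
#' @export
read_plan <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) == 0L || !startsWith(lines[1], "# tau=")) {
    rlang::abort(sprintf("not a replacement-plan TSV: %s", path))
  }
  meta <- as.list(stats::setNames(
    as.numeric(sub(".*=", "", strsplit(sub("^# ", "", lines[1]), " ")[[1]])),
    sub("=.*", "", strsplit(sub("^# ", "", lines[1]), " ")[[1]])
  ))
  body <- utils::read.table(text = lines[-1], sep = "\t", header = TRUE,
                            colClasses = c("character", "character",
                                           "integer", "integer"))
  structure(
    tibble::as_tibble(body),
    threshold = meta$tau,
    n_candidates = as.integer(meta$n_candidates),
    n_replaced = nrow(body),
    n_retained_all_infrequent = as.integer(meta$n_retained_all_infrequent),
    n_empty_pool = as.integer(meta$n_empty_pool),
    n_protected = as.integer(meta$n_protected),
    vocab_size = as.integer(meta$vocab_size),
    class = c("replacement_plan", class(tibble::tibble()))
  )
}
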