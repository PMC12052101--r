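#' Read concept sets from a GMT file
#'
#' GMT is the tab-separated gene-set format used by MSigDB: each line is
#' `name<TAB>description<TAB>member1<TAB>member2...`. Members are lowercased
#' to match the corpus token convention and duplicated members within a line
#' are collapsed (with a warning). Category labels (e.g. MeSH vs the MSigDB
#' collections Biocarta/KEGG/GO-BP/PID) are not part of GMT; supply them via
#' `category_map`, a named character vector from set name to category, or
#' leave them `"other"`.
#'
#' @param path Path to a GMT file.
#' @param category_map Optional named character vector `set name ->
#'   category`.
#' @return A tibble with columns `name`, `category`, `members` (list of
#'   character vectors) and `description`.
#' @export
read_gmt <- function(path, category_map = NULL) {
  if (!file.exists(path)) rlang::abort(sprintf("GMT file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(tibble::tibble(name = character(), category = character(),
                          members = list(), description = character()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(parts) < 3L
  if (any(short)) {
    rlang::abort(sprintf("GMT line %d has fewer than 3 fields", which(short)[1]))
  }
  members <- purrr::map(parts, function(p) tolower(p[-(1:2)]))
  dup <- purrr::map_lgl(members, function(m) anyDuplicated(m) > 0L)
  if (any(dup)) {
    rlang::warn(sprintf("duplicate members collapsed in %d set(s)", sum(dup)))
    members <- purrr::map(members, unique)
  }
  name <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(name)) {
    rlang::abort(sprintf("duplicate set name: %s", name[duplicated(name)][1]))
  }
  category <- if (is.null(category_map)) {
    rep("other", length(name))
  } else {
    dplyr::coalesce(unname(category_map[name]), "other")
  }
  tibble::tibble(
    name = name,
    category = category,
    members = members,
    description = vapply(parts, `[[`, character(1), 2L)
  )
}

#' Write concept sets to a GMT file
#'
#' @param sets A concept-set tibble (see [read_gmt()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  desc <- if ("description" %in% names(sets)) sets$description else sets$category
  lines <- purrr::pmap_chr(
    list(sets$name, desc, sets$members),
    function(n, d, m) paste(c(n, d, m), collapse = "\t")
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Filter concept sets against two embedding vocabularies
#'
#' A set is evaluable only through members embedded in *both* spaces, so
#' each set is restricted to the members present in both vocabularies and
#' dropped entirely when fewer than `min_members` remain. The default
#' minimum of 5 reflects the view that a coherence comparison over fewer
#' than C(5,2) = 10 member pairs is too noisy to interpret.
#'
#' @param sets Concept-set tibble (see [read_gmt()]).
#' @param vocab_a,vocab_b Character vectors: the vocabularies of the two
#'   spaces being compared.
#' @param min_members Minimum surviving members (>= 2; default 5).
#' @return The filtered tibble, members restricted to the shared-present
#'   subset, plus an `n_present` column.
#' @export
filter_sets <- function(sets, vocab_a, vocab_b, min_members = 5) {
  if (min_members < 2) rlang::abort("`min_members` must be >= 2")
  shared <- intersect(vocab_a, vocab_b)
  out <- sets |>
    dplyr::mutate(members = purrr::map(.data$members, intersect, y = shared),
                  n_present = lengths(.data$members)) |>
    dplyr::filter(.data$n_present >= min_members)
  out
}

#' Mean pairwise cosine distance within a set of embedded tokens
#'
#' Cosine distance is `1 - cosine similarity`, so it lies in \[0, 2\] and
#' smaller means more coherent. The mean is taken over all n(n-1)/2
#' unordered pairs of distinct members. Invariant to rescaling any vector
#' by a positive factor.
#'
#' @param space An `embedding_space`.
#' @param members Character vector of tokens, all present in `space`, with
#'   at least 2 members.
#' @return A single number in \[0, 2\].
#' @export
mean_pairwise_distance <- function(space, members) {
  d <- pairwise_distances(space, members)
  mean(d)
}

# Vector of cosine distances for all unordered pairs of `members`, ordered
# by column-major upper triangle (pair (i,j), i < j).
pairwise_distances <- function(space, members) {
  missing <- setdiff(members, rownames(space))
  if (length(missing) > 0L) {
    rlang::abort(sprintf("members absent from space: %s",
                         paste(utils::head(missing, 3), collapse = ", ")))
  }
  if (length(members) < 2L) {
    rlang::abort("need at least 2 members for pairwise distances")
  }
  v <- space[members, , drop = FALSE]
  v <- v / sqrt(rowSums(v^2))
  sim <- tcrossprod(v)
  1 - sim[upper.tri(sim)]
}

#' Compare one concept set's coherence between two embedding spaces
#'
#' Computes the cosine-distance list over the same member pairs in each
#' space and tests the paired per-pair differences with a two-sided t-test
#' (the pairs are matched across spaces, so pairing is the natural design;
#' set `paired = FALSE` for Welch's unpaired test). The winner is the space
#' with the smaller mean intra-set distance; `significant` flags p below
#' `alpha`. If the paired differences have zero variance the t-test is
#' degenerate: p is reported as 1 with `degenerate = TRUE` (identical
#' spaces fall out as ties this way).
#'
#' @param space_a,space_b Two `embedding_space` objects.
#' @param members Character vector of set members present in both spaces.
#' @param set_name Label carried into the result.
#' @param alpha Significance level (default 0.05).
#' @param paired Use the paired t-test (default) or Welch's unpaired.
#' @return A one-row tibble: `set_name`, `n_present`, `mean_dist_a`,
#'   `mean_dist_b`, `t_stat`, `p_value`, `winner` (`"a"`, `"b"` or
#'   `"tie"`), `significant`, `degenerate`.
#' @export
compare_set <- function(space_a, space_b, members, set_name = "set",
                        alpha = 0.05, paired = TRUE) {
  da <- pairwise_distances(space_a, members)
  db <- pairwise_distances(space_b, members)
  diffs <- da - db
  degenerate <- stats::sd(diffs) == 0 || length(diffs) < 2L
  if (degenerate) {
    t_stat <- 0
    p <- 1
  } else if (paired) {
    ht <- stats::t.test(da, db, paired = TRUE)
    t_stat <- unname(ht$statistic)
    p <- ht$p.value
  } else {
    ht <- stats::t.test(da, db, paired = FALSE)
    t_stat <- unname(ht$statistic)
    p <- ht$p.value
  }
  ma <- mean(da)
  mb <- mean(db)
  winner <- if (ma < mb) "a" else if (mb < ma) "b" else "tie"
  tibble::tibble(
    set_name = set_name,
    n_present = length(members),
    mean_dist_a = ma,
    mean_dist_b = mb,
    t_stat = t_stat,
    p_value = p,
    winner = winner,
    significant = !degenerate && p < alpha,
    degenerate = degenerate
  )
}

#' Compare every concept set between two embedding spaces
#'
#' Applies [filter_sets()] then [compare_set()] to each survivor.
#'
#' @param space_a,space_b Two `embedding_space` objects.
#' @param sets Concept-set tibble (see [read_gmt()]).
#' @param min_members Passed to [filter_sets()].
#' @param alpha,paired Passed to [compare_set()].
#' @return A tibble of class `set_comparisons`: one row per surviving set
#'   with the [compare_set()] columns plus `category`.
#' @export
compare_sets <- function(space_a, space_b, sets, min_members = 5,
                         alpha = 0.05, paired = TRUE) {
  kept <- filter_sets(sets, space_vocab(space_a), space_vocab(space_b),
                      min_members = min_members)
  rows <- purrr::map2(kept$name, kept$members, function(nm, mem) {
    compare_set(space_a, space_b, mem, set_name = nm, alpha = alpha,
                paired = paired)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) > 0L) {
    out <- dplyr::left_join(out, kept[, c("name", "category")],
                            by = c(set_name = "name")) |>
      dplyr::relocate("category", .after = "set_name")
  } else {
    out <- tibble::tibble(
      set_name = character(), category = character(), n_present = integer(),
      mean_dist_a = double(), mean_dist_b = double(), t_stat = double(),
      p_value = double(), winner = character(), significant = logical(),
      degenerate = logical()
    )
  }
  structure(out, class = c("set_comparisons", class(tibble::tibble())))
}

#' Summarize set comparisons per category
#'
#' Tallies, for each concept-set category, how many sets each space won —
#' among significant comparisons only and among all comparisons — plus tie
#' counts and percentages of the category's sets. Wins plus losses plus
#' ties always equal the number of sets.
#'
#' @param results A `set_comparisons` tibble from [compare_sets()].
#' @param labels Length-2 named character vector renaming the spaces in the
#'   output columns, e.g. `c(a = "pm", b = "wn")`.
#' @return A tibble with one row per category: `category`, `n_sets`,
#'   `n_concepts`, `<a>_better_sig`, `<b>_better_sig`, `<a>_better_all`,
#'   `<b>_better_all`, `ties`, and matching `pct_` columns.
#' @export
summarize_comparisons <- function(results, labels = c(a = "a", b = "b")) {
  stopifnot(all(c("a", "b") %in% names(labels)))
  if (nrow(results) == 0L) {
    out <- tibble::tibble(category = character(), n_sets = integer(),
                          n_concepts = integer())
    return(out)
  }
  out <- results |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(
      n_sets = dplyr::n(),
      n_concepts = sum(.data$n_present),
      a_better_sig = sum(.data$winner == "a" & .data$significant),
      b_better_sig = sum(.data$winner == "b" & .data$significant),
      a_better_all = sum(.data$winner == "a"),
      b_better_all = sum(.data$winner == "b"),
      ties = sum(.data$winner == "tie"),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      pct_a_better_sig = 100 * .data$a_better_sig / .data$n_sets,
      pct_b_better_sig = 100 * .data$b_better_sig / .data$n_sets,
      pct_a_better_all = 100 * .data$a_better_all / .data$n_sets,
      pct_b_better_all = 100 * .data$b_better_all / .data$n_sets
    )
  names(out) <- gsub("a_better", paste0(labels[["a"]], "_better"), names(out))
  names(out) <- gsub("b_better", paste0(labels[["b"]], "_better"), names(out))
  out
}

#' Distribution diagnostics for two embedding spaces
#'
#' Checks that normalization did not warp the overall geometry: samples
#' `n_pairs` unordered distinct-token pairs uniformly (with replacement)
#' from each space independently, computes their cosine distances, and
#' returns the two ECDFs evaluated on the shared sorted grid of all sampled
#' distances, Q-Q quantile pairs, and the two-sample Kolmogorov-Smirnov
#' statistic (the maximum ECDF gap). The default of 10,000 pairs
#' characterizes the distributions well at desk scale; scale it up for
#' large corpora.
#'
#' @param space_a,space_b Two `embedding_space` objects with >= 2 tokens.
#' @param n_pairs Number of sampled pairs per space (>= 1).
#' @param seed Integer seed for the pair sampling.
#' @param n_quantiles Number of Q-Q points (default 99: percentiles).
#' @return A list of class `distribution_check`: `grid`, `ecdf_a`,
#'   `ecdf_b`, `qq` (tibble `prob`, `q_a`, `q_b`), `ks_stat`, `n_pairs`.
#' @export
distribution_check <- function(space_a, space_b, n_pairs = 10000, seed = 1L,
                               n_quantiles = 99) {
  if (n_pairs < 1) rlang::abort("`n_pairs` must be >= 1")
  if (nrow(space_a) < 2L || nrow(space_b) < 2L) {
    rlang::abort("each space needs at least 2 tokens")
  }
  # the same seeded index stream drives both samples: identical spaces give
  # identical distance samples (KS exactly 0), and for spaces sharing a
  # vocabulary the comparison is variance-matched
  da <- withr::with_seed(seed, sample_pair_distances(space_a, n_pairs))
  db <- withr::with_seed(seed, sample_pair_distances(space_b, n_pairs))
  grid <- sort(unique(c(da, db)))
  Fa <- stats::ecdf(da)(grid)
  Fb <- stats::ecdf(db)(grid)
  probs <- seq_len(n_quantiles) / (n_quantiles + 1)
  qq <- tibble::tibble(
    prob = probs,
    q_a = stats::quantile(da, probs, names = FALSE, type = 7),
    q_b = stats::quantile(db, probs, names = FALSE, type = 7)
  )
  structure(
    list(grid = grid, ecdf_a = Fa, ecdf_b = Fb, qq = qq,
         ks_stat = max(abs(Fa - Fb)), n_pairs = as.integer(n_pairs),
         distances_a = da, distances_b = db),
    class = "distribution_check"
  )
}

# n cosine distances between uniformly sampled distinct-token pairs
sample_pair_distances <- function(space, n) {
  v <- space / sqrt(rowSums(space^2))
  i <- sample.int(nrow(v), n, replace = TRUE)
  j <- sample.int(nrow(v), n, replace = TRUE)
  while (any(same <- i == j)) {
    j[same] <- sample.int(nrow(v), sum(same), replace = TRUE)
  }
  1 - rowSums(v[i, , drop = FALSE] * v[j, , drop = FALSE])
}

#' @export
print.distribution_check <- function(x, ...) {
  cat(sprintf("<distribution_check: %d pairs per space, KS = %.4f>\n",
              x$n_pairs, x$ks_stat))
  invisible(x)
}
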