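# Independent brute-force oracles and random-instance generators.
# Everything here is written naively on purpose: plain loops, no reuse of
# the package's vectorized implementation paths.

# random corpus over a small alphabet ------------------------------------
random_corpus <- function(n_docs = 10, vocab = paste0("w", 1:15),
                          len_range = c(3, 12)) {
  docs <- lapply(seq_len(n_docs), function(i) {
    sample(vocab, sample(len_range[1]:len_range[2], 1), replace = TRUE)
  })
  corpus(docs, source_label = "random")
}

# random synonym resource: pools over corpus vocab plus some alien tokens
random_resource <- function(vocab, n_pools = 5, pool_size = 4) {
  universe <- c(vocab, paste0("alien", 1:5))
  words <- sample(vocab, min(length(vocab), n_pools * 2))
  pools <- lapply(seq_len(n_pools), function(i) {
    sample(universe, pool_size)
  })
  # each pool is attached to a couple of lookup words (pool may or may not
  # contain the word itself, as in a real lexical database)
  tab <- data.frame(
    word = words[seq_len(min(length(words), n_pools))],
    members = vapply(pools[seq_len(min(length(words), n_pools))],
                     paste, character(1), collapse = ","),
    stringsAsFactors = FALSE
  )
  synonym_resource(tab, backend_label = "fixture")
}

# single-pass tally oracle for frequencies --------------------------------
oracle_tally <- function(co) {
  counts <- new.env(parent = emptyenv())
  for (doc in co) {
    for (tok in doc) {
      cur <- get0(tok, envir = counts, ifnotfound = 0L)
      assign(tok, cur + 1L, envir = counts)
    }
  }
  toks <- ls(counts)
  stats::setNames(vapply(toks, get, integer(1), envir = counts), toks)
}

# exhaustive per-token re-derivation of the replacement plan ---------------
# For every distinct corpus token independently: decide candidacy, scan the
# whole pool for the frequency argmax (lexicographic tie-break), apply the
# frequent-target rule. Returns a sorted source -> target data frame.
oracle_plan <- function(co, resource, tau, protect_regex = "^(cid_|mesh|ncbigene)") {
  counts <- oracle_tally(co)
  f <- function(tok) if (tok %in% names(counts)) counts[[tok]] else 0L
  src <- character(0)
  tgt <- character(0)
  for (w in sort(names(counts))) {
    if (f(w) >= tau) next
    if (!is.null(protect_regex) && grepl(protect_regex, w)) next
    pool <- get_pool(resource, w)
    if (length(pool) == 0) next
    best <- NULL
    best_f <- -1L
    for (s in sort(pool)) {
      if (f(s) > best_f) {
        best <- s
        best_f <- f(s)
      }
    }
    if (best_f >= tau && !identical(best, w)) {
      src <- c(src, w)
      tgt <- c(tgt, best)
    }
  }
  data.frame(source = src, target = tgt, stringsAsFactors = FALSE)
}

# O(n^2) double-loop mean pairwise cosine distance -------------------------
oracle_mean_pairwise <- function(mat) {
  n <- nrow(mat)
  total <- 0
  pairs <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      u <- mat[i, ]
      v <- mat[j, ]
      cosine <- sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
      total <- total + (1 - cosine)
      pairs <- pairs + 1
    }
  }
  total / pairs
}

# closed-form paired t statistic and two-sided p --------------------------
oracle_paired_t <- function(x, y) {
  d <- x - y
  n <- length(d)
  t_stat <- mean(d) / (stats::sd(d) / sqrt(n))
  list(t = t_stat, p = 2 * stats::pt(-abs(t_stat), df = n - 1))
}

# two-sample KS statistic by direct definition ----------------------------
oracle_ks <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  fa <- vapply(grid, function(g) mean(a <= g), numeric(1))
  fb <- vapply(grid, function(g) mean(b <= g), numeric(1))
  max(abs(fa - fb))
}

# small deterministic embedding space for evaluation tests ----------------
toy_space <- function(tokens, dim = 6, seed = 1) {
  withr::with_seed(seed, {
    mat <- matrix(rnorm(length(tokens) * dim), nrow = length(tokens))
  })
  rownames(mat) <- tokens
  synnorm:::new_embedding_space(mat, NULL)
}
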