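test_that("GMT lines parse into named, lowercased sets", {
  path <- withr::local_tempfile(lines = c(
    "SETX\tdesc\tG1\tg2\tg3",
    "SETY\tother desc\tg4\tg5"
  ))
  sets <- read_gmt(path)
  expect_equal(sets$name, c("SETX", "SETY"))
  expect_equal(sets$members[[1]], c("g1", "g2", "g3"))
  expect_equal(sets$category, c("other", "other"))
  withmap <- read_gmt(path, category_map = c(SETX = "K"))
  expect_equal(withmap$category, c("K", "other"))
})

test_that("GMT parsing flags short lines, duplicates and empty files", {
  bad <- withr::local_tempfile(lines = c("SETX\tdesc\tg1", "LONELY\tdesc"))
  expect_error(read_gmt(bad), "line 2")
  dup <- withr::local_tempfile(lines = "SETX\tdesc\tg1\tg1\tg2")
  expect_warning(sets <- read_gmt(dup), "duplicate")
  expect_equal(sets$members[[1]], c("g1", "g2"))
  empty <- withr::local_tempfile(lines = character(0))
  expect_equal(nrow(read_gmt(empty)), 0L)
})

test_that("GMT files round-trip through write_gmt", {
  path <- withr::local_tempfile(lines = "SETX\tdesc\tg1\tg2\tg3\tg4\tg5")
  sets <- read_gmt(path)
  out <- withr::local_tempfile()
  write_gmt(sets, out)
  expect_equal(read_gmt(out), sets)
})

test_that("set filtering keeps only sets with enough shared-present members", {
  sets <- tibble::tibble(
    name = c("BIG_SPARSE", "BOUNDARY", "RICH"),
    category = "other",
    members = list(
      c(paste0("absent", 1:97), "g1", "g2", "g3"), # 100 members, 3 present
      paste0("g", 1:5),                            # exactly at the floor
      paste0("g", 1:8)
    )
  )
  vocab_a <- paste0("g", 1:8)
  vocab_b <- c(paste0("g", 1:8), "extra")
  kept <- filter_sets(sets, vocab_a, vocab_b, min_members = 5)
  expect_setequal(kept$name, c("BOUNDARY", "RICH"))
  expect_equal(kept$n_present, c(5L, 8L))
  expect_error(filter_sets(sets, vocab_a, vocab_b, min_members = 1), ">= 2")
})

test_that("set filtering agrees with a brute-force membership count", {
  withr::with_seed(31, {
    for (i in 1:25) {
      universe <- paste0("m", 1:40)
      sets <- tibble::tibble(
        name = paste0("S", 1:10),
        category = "other",
        members = replicate(10, sample(universe, sample(3:15, 1)),
                            simplify = FALSE)
      )
      va <- sample(universe, 25)
      vb <- sample(universe, 25)
      kept <- filter_sets(sets, va, vb, min_members = 4)
      expected <- vapply(sets$members, function(m) {
        n <- 0L
        for (tok in m) if (tok %in% va && tok %in% vb) n <- n + 1L
        n >= 4L
      }, logical(1))
      expect_setequal(kept$name, sets$name[expected])
    }
  })
})

test_that("mean pairwise distance matches hand values and the double loop", {
  mat <- rbind(v1 = c(1, 0, 0), v2 = c(2, 0, 0), v3 = c(0, 3, 0))
  sp <- synnorm:::new_embedding_space(mat, NULL)
  # identical directions: distance 0; orthogonal: distance 1
  expect_equal(mean_pairwise_distance(sp, c("v1", "v2")), 0)
  expect_equal(mean_pairwise_distance(sp, c("v1", "v3")), 1)
  withr::with_seed(17, {
    for (i in 1:20) {
      sp2 <- toy_space(paste0("r", 1:6), dim = 5, seed = i)
      got <- mean_pairwise_distance(sp2, rownames(sp2))
      expect_equal(got, oracle_mean_pairwise(unclass(sp2)), tolerance = 1e-12)
      expect_gte(got, 0)
      expect_lte(got, 2)
    }
  })
  expect_error(mean_pairwise_distance(sp, "v1"), "at least 2")
  expect_error(mean_pairwise_distance(sp, c("v1", "nope")), "absent")
})

test_that("pairwise distances are invariant to positive per-vector rescaling", {
  sp <- toy_space(paste0("r", 1:7), dim = 6, seed = 4)
  scaled <- unclass(sp) * stats::runif(7, 0.1, 10)
  sp2 <- synnorm:::new_embedding_space(scaled, NULL)
  expect_equal(mean_pairwise_distance(sp, rownames(sp)),
               mean_pairwise_distance(sp2, rownames(sp2)),
               tolerance = 1e-12)
})

test_that("identical or rescaled spaces compare as ties", {
  sp <- toy_space(paste0("g", 1:6), dim = 8, seed = 9)
  res <- compare_set(sp, sp, rownames(sp), set_name = "self")
  expect_equal(res$winner, "tie")
  expect_true(res$degenerate)
  expect_equal(res$p_value, 1)
  doubled <- synnorm:::new_embedding_space(unclass(sp) * 2, NULL)
  res2 <- compare_set(sp, doubled, rownames(sp))
  expect_equal(res2$winner, "tie")
  expect_false(res2$significant)
})

test_that("the paired t-test matches the closed form to 1e-10", {
  withr::with_seed(77, {
    for (i in 1:100) {
      members <- paste0("g", 1:sample(5:9, 1))
      sa <- toy_space(members, dim = 6, seed = i)
      # inject a mean shift onto space B distances by perturbing vectors
      sb <- synnorm:::new_embedding_space(
        unclass(sa) + matrix(rnorm(length(sa), sd = 0.3), nrow = nrow(sa)),
        NULL
      )
      res <- compare_set(sa, sb, members)
      da <- synnorm:::pairwise_distances(sa, members)
      db <- synnorm:::pairwise_distances(sb, members)
      ref <- oracle_paired_t(da, db)
      expect_equal(res$t_stat, ref$t, tolerance = 1e-10)
      expect_equal(res$p_value, ref$p, tolerance = 1e-10)
      expect_equal(res$winner, if (mean(da) < mean(db)) "a" else "b")
      # antisymmetry under swapping the spaces
      swapped <- compare_set(sb, sa, members)
      expect_equal(swapped$t_stat, -res$t_stat, tolerance = 1e-10)
      expect_equal(swapped$p_value, res$p_value, tolerance = 1e-10)
      expect_equal(swapped$winner, if (res$winner == "a") "b" else "a")
    }
  })
})

test_that("the unpaired option runs Welch's test", {
  members <- paste0("g", 1:6)
  sa <- toy_space(members, dim = 6, seed = 1)
  sb <- toy_space(members, dim = 6, seed = 2)
  res <- compare_set(sa, sb, members, paired = FALSE)
  da <- synnorm:::pairwise_distances(sa, members)
  db <- synnorm:::pairwise_distances(sb, members)
  ref <- stats::t.test(da, db)
  expect_equal(res$t_stat, unname(ref$statistic))
  expect_equal(res$p_value, ref$p.value)
})

test_that("category summaries tally wins, losses and ties exactly", {
  results <- structure(tibble::tibble(
    set_name = paste0("s", 1:10),
    category = rep(c("K", "M"), each = 5),
    n_present = 5L,
    mean_dist_a = 0.5, mean_dist_b = 0.4,
    t_stat = 1, p_value = 0.5,
    winner = c("a", "b", "b", "b", "tie", "a", "a", "b", "b", "b"),
    significant = c(FALSE, TRUE, TRUE, FALSE, FALSE,
                    TRUE, FALSE, FALSE, FALSE, TRUE),
    degenerate = FALSE
  ), class = c("set_comparisons", class(tibble::tibble())))
  sm <- summarize_comparisons(results, labels = c(a = "pm", b = "wn"))
  k <- sm[sm$category == "K", ]
  expect_equal(k$wn_better_sig, 2L)
  expect_equal(k$wn_better_all, 3L)
  expect_equal(k$pm_better_all, 1L)
  expect_equal(k$ties, 1L)
  expect_equal(k$pm_better_all + k$wn_better_all + k$ties, k$n_sets)
  m <- sm[sm$category == "M", ]
  expect_equal(m$pm_better_sig, 1L)
  expect_equal(m$wn_better_sig, 1L)
  expect_equal(m$pct_wn_better_all, 60)
  # empty input gives an empty summary
  expect_equal(nrow(summarize_comparisons(results[0, ])), 0L)
})

test_that("random summaries agree with a brute-force tally", {
  withr::with_seed(55, {
    for (i in 1:20) {
      n <- sample(5:30, 1)
      results <- structure(tibble::tibble(
        set_name = paste0("s", 1:n),
        category = sample(c("M", "B", "K"), n, replace = TRUE),
        n_present = sample(5:10, n, replace = TRUE),
        mean_dist_a = runif(n), mean_dist_b = runif(n),
        t_stat = rnorm(n), p_value = runif(n),
        winner = sample(c("a", "b", "tie"), n, replace = TRUE,
                        prob = c(.45, .45, .1)),
        significant = sample(c(TRUE, FALSE), n, replace = TRUE),
        degenerate = FALSE
      ), class = c("set_comparisons", class(tibble::tibble())))
      sm <- summarize_comparisons(results)
      for (categ in unique(results$category)) {
        rows <- results[results$category == categ, ]
        srow <- sm[sm$category == categ, ]
        expect_equal(srow$n_sets, nrow(rows))
        expect_equal(srow$a_better_all, sum(rows$winner == "a"))
        expect_equal(srow$b_better_sig,
                     sum(rows$winner == "b" & rows$significant))
        expect_equal(srow$a_better_all + srow$b_better_all + srow$ties,
                     srow$n_sets)
      }
    }
  })
})

test_that("distribution diagnostics are exact on identical spaces", {
  sp <- toy_space(paste0("t", 1:30), dim = 8, seed = 21)
  chk <- distribution_check(sp, sp, n_pairs = 500, seed = 10)
  expect_equal(chk$ks_stat, 0)
  expect_equal(chk$ecdf_a, chk$ecdf_b)
})

test_that("the KS statistic matches the reference implementation", {
  withr::with_seed(13, {
    for (i in 1:20) {
      sa <- toy_space(paste0("t", 1:25), dim = 6, seed = i)
      sb <- toy_space(paste0("t", 1:25), dim = 6, seed = i + 100)
      chk <- distribution_check(sa, sb, n_pairs = 400, seed = i)
      ref <- suppressWarnings(
        stats::ks.test(chk$distances_a, chk$distances_b)
      )
      expect_equal(chk$ks_stat, unname(ref$statistic), tolerance = 1e-12)
      expect_equal(chk$ks_stat, oracle_ks(chk$distances_a, chk$distances_b),
                   tolerance = 1e-12)
    }
  })
})

test_that("ECDFs are proper distribution functions on the grid", {
  sa <- toy_space(paste0("t", 1:20), dim = 5, seed = 3)
  sb <- toy_space(paste0("t", 1:20), dim = 5, seed = 4)
  chk <- distribution_check(sa, sb, n_pairs = 300, seed = 2)
  for (F in list(chk$ecdf_a, chk$ecdf_b)) {
    expect_true(all(diff(F) >= 0))
    expect_gte(min(F), 0)
    expect_equal(max(F), 1)
  }
  expect_true(all(diff(chk$qq$q_a) >= 0))
  expect_error(distribution_check(sa, sb, n_pairs = 0), "n_pairs")
})
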