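#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot distribution diagnostics
#'
#' `type = "ecdf"` overlays the two sampled cosine-distance ECDFs;
#' `type = "qq"` draws the empirical Q-Q plot against the identity line.
#' Close ECDF overlap and Q-Q points hugging the diagonal mean the
#' normalization left the global geometry of the space intact.
#'
#' @param object A [distribution_check()] result.
#' @param type `"ecdf"` or `"qq"`.
#' @param labels Length-2 character vector naming the two spaces.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.distribution_check <- function(object, type = c("ecdf", "qq"),
                                        labels = c("space A", "space B"),
                                        ...) {
  type <- match.arg(type)
  if (type == "ecdf") {
    df <- tibble::tibble(
      distance = rep(object$grid, 2),
      ecdf = c(object$ecdf_a, object$ecdf_b),
      space = rep(labels, each = length(object$grid))
    )
    ggplot2::ggplot(df, ggplot2::aes(.data$distance, .data$ecdf,
                                     colour = .data$space)) +
      ggplot2::geom_step() +
      ggplot2::labs(
        x = "cosine distance", y = "empirical CDF",
        title = sprintf("Sampled pairwise-distance ECDFs (KS = %.4f)",
                        object$ks_stat)
      ) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$qq, ggplot2::aes(.data$q_a, .data$q_b)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
      ggplot2::geom_point() +
      ggplot2::labs(x = sprintf("%s quantiles", labels[1]),
                    y = sprintf("%s quantiles", labels[2]),
                    title = "Q-Q plot of sampled pairwise distances") +
      ggplot2::theme_minimal()
  }
}

#' Plot per-set coherence comparisons
#'
#' Scatter of each concept set's mean intra-set cosine distance in space A
#' (x) versus space B (y). Points below the diagonal are sets where space B
#' is more coherent; filled points are significant at the comparison's
#' alpha.
#'
#' @param object A `set_comparisons` tibble from [compare_sets()].
#' @param labels Length-2 character vector naming the two spaces.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.set_comparisons <- function(object, labels = c("space A", "space B"),
                                     ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$mean_dist_a, .data$mean_dist_b,
                                       colour = .data$category,
                                       alpha = .data$significant)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::scale_alpha_manual(values = c(`FALSE` = 0.35, `TRUE` = 1)) +
    ggplot2::labs(x = sprintf("mean intra-set distance, %s", labels[1]),
                  y = sprintf("mean intra-set distance, %s", labels[2])) +
    ggplot2::theme_minimal()
}

#' Plot an end-to-end experiment summary
#'
#' Bar chart of per-category win counts (all comparisons and
#' significant-only) for the original versus normalized spaces.
#'
#' @param object A `synnorm_experiment` from [run_experiment()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.synnorm_experiment <- function(object, ...) {
  long <- object$summary |>
    dplyr::select("category", "orig_better_sig", "norm_better_sig",
                  "orig_better_all", "norm_better_all") |>
    tidyr::pivot_longer(-"category", names_to = "measure",
                        values_to = "n") |>
    tidyr::separate_wider_regex(
      "measure", c(space = "orig|norm", "_better_", scope = "sig|all")
    ) |>
    dplyr::mutate(
      space = dplyr::recode(.data$space, orig = "original",
                            norm = "normalized"),
      scope = dplyr::recode(.data$scope, sig = "significant only",
                            all = "all comparisons")
    )
  ggplot2::ggplot(long, ggplot2::aes(.data$category, .data$n,
                                     fill = .data$space)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~scope) +
    ggplot2::labs(x = "concept-set category", y = "sets won") +
    ggplot2::theme_minimal()
}
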