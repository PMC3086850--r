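#' Tidy a fitted copy-number HMM
#'
#' @param x A `cna_hmm`.
#' @param ... Unused.
#' @return One row per transition: `chrom`, `from`, `to`, `probability`,
#'   plus per-state initial probabilities with `from = NA`.
#' @export
#' @exportS3Method generics::tidy
tidy.cna_hmm <- function(x, ...) {
  purrr::map_dfr(names(x$chromosomes), function(chrom) {
    p <- x$chromosomes[[chrom]]
    trans <- as_tibble(p$transition, rownames = "from") |>
      tidyr::pivot_longer(-"from", names_to = "to",
                          values_to = "probability") |>
      mutate(chrom = chrom, .before = 1)
    init <- tibble(chrom = chrom, from = NA_character_,
                   to = names(p$initial),
                   probability = unname(p$initial))
    bind_rows(init, trans)
  })
}

#' @rdname tidy.cna_hmm
#' @return For `glance`: a one-row tibble with the model dimensions.
#' @export
#' @exportS3Method generics::glance
glance.cna_hmm <- function(x, ...) {
  tibble(n_states = 9L, n_symbols = 3L,
         n_chromosomes = length(x$chromosomes),
         pseudocount = x$pseudocount)
}

#' Tidy a cross-validation result
#'
#' @param x A `cna_loocv` from [loocv()].
#' @param ... Unused.
#' @return The per-chromosome fold-averaged metric tibble.
#' @export
#' @exportS3Method generics::tidy
tidy.cna_loocv <- function(x, ...) x$metrics

#' @rdname tidy.cna_loocv
#' @return For `glance`: one row per method and label with genome-wide
#'   fold-averaged sensitivity, specificity and accuracy.
#' @export
#' @exportS3Method generics::glance
glance.cna_loocv <- function(x, ...) {
  x$metrics |>
    filter(.data$chrom == "genome") |>
    select("method", "label", "sensitivity_mean", "specificity_mean",
           "accuracy_mean", "n_folds")
}

#' Tidy an association test result
#'
#' @param x A `cna_assoc` from [region_test()].
#' @param ... Unused.
#' @return One row per permutation (`statistic`), with the observed value
#'   repeated in `observed`.
#' @export
#' @exportS3Method generics::tidy
tidy.cna_assoc <- function(x, ...) {
  tibble(permutation = seq_along(x$permuted), statistic = x$permuted,
         observed = x$observed)
}

#' @rdname tidy.cna_assoc
#' @return For `glance`: a one-row summary with the empirical p-value.
#' @export
#' @exportS3Method generics::glance
glance.cna_assoc <- function(x, ...) {
  tibble(direction = x$direction, n_aberrant = x$n_aberrant,
         n_wildtype = x$n_wildtype, n_excluded = x$n_excluded,
         n_probes = x$n_probes, observed_statistic = x$observed,
         n_perm = x$n_perm, empirical_p = x$empirical_p)
}

#' Plot cross-validated sensitivity against specificity
#'
#' One point per method and label at genome-wide fold means, the standard
#' way to compare the HMM against the expression-only baselines.
#'
#' @param object A `cna_loocv`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.cna_loocv <- function(object, ...) {
  gw <- object$metrics |> filter(.data$chrom == "genome")
  ggplot2::ggplot(gw, ggplot2::aes(x = .data$specificity_mean,
                                   y = .data$sensitivity_mean,
                                   colour = .data$method,
                                   shape = .data$label)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Specificity (fold mean)",
                  y = "Sensitivity (fold mean)",
                  shape = "Label", colour = "Method") +
    ggplot2::theme_minimal()
}

#' Plot the permutation null against the observed statistic
#'
#' @param object A `cna_assoc`.
#' @param ... Unused.
#' @return A ggplot object: histogram of permuted statistics with the
#'   observed statistic marked.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.cna_assoc <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$statistic)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red") +
    ggplot2::labs(x = "Sum of log p-values (permutations)", y = "Count",
                  subtitle = sprintf("empirical p = %.4g", object$empirical_p)) +
    ggplot2::theme_minimal()
}

#' Bar chart of per-cytoband gain/loss frequencies
#'
#' Gains plotted upward and losses downward per cytoband, faceted by
#' chromosome.
#'
#' @param freq Tibble from [cytoband_frequencies()] or [summarize_truth()].
#' @return A ggplot object.
#' @export
plot_cytoband_frequencies <- function(freq) {
  long <- freq |>
    mutate(cytoband = factor(.data$cytoband, levels = unique(.data$cytoband))) |>
    tidyr::pivot_longer(c("n_gain", "n_loss"), names_to = "label",
                        values_to = "n") |>
    mutate(n = ifelse(.data$label == "n_loss", -.data$n, .data$n),
           label = ifelse(.data$label == "n_gain", "gain", "loss"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cytoband, y = .data$n,
                                     fill = .data$label)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::scale_fill_manual(values = c(gain = "firebrick",
                                          loss = "steelblue")) +
    ggplot2::labs(x = "Cytoband", y = "Samples with aberration") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
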