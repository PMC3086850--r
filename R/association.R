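#' Permutation test for regional expression change
#'
#' Tests whether a recurrent predicted abnormality region shows coordinated
#' expression change between the samples harboring it and the wild-type
#' samples.  Per region probe a one-sided two-sample t-test compares
#' aberrant vs wild-type expression, in the dosage direction (aberrant >
#' wild-type for gains, aberrant < wild-type for losses).  The region
#' statistic is the sum of the natural-log p-values; smaller means a more
#' coordinated shift.  Group labels are then permuted across the analysed
#' samples, preserving group sizes; the empirical p-value is
#' `(1 + #\{permuted statistic <= observed\}) / (n_perm + 1)`, so it is
#' never exactly zero.
#'
#' Samples marked `excluded` (for example, samples harboring both a gain
#' and a loss in the region) take part in neither group nor the
#' permutations.  The base of the log only shifts the statistic
#' monotonically and leaves the empirical p-value unchanged.
#'
#' @param expr Expression tibble (`probe_id` + sample columns) or matrix.
#' @param groups Tibble (`sample_id`, `group`) with `group` in
#'   `aberrant` / `wildtype` / `excluded`, or a named character vector.
#' @param direction `"gain"` or `"loss"`: the dosage direction tested.
#' @param probes Character vector of region probe ids; alternatively give
#'   `region` + `annotation`.
#' @param region Optional list `(chrom, start, end)` selecting probes whose
#'   midpoint falls in the interval.
#' @param annotation Required with `region`.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Optional integer seed.
#' @param var_equal Use the pooled-variance t-test instead of the default
#'   unequal-variance (Welch) test.
#' @return Object of class `cna_assoc`: `observed` statistic, `permuted`
#'   statistics, `empirical_p`, group sizes and the per-probe p-values.
#' @export
region_test <- function(expr, groups, direction = c("gain", "loss"),
                        probes = NULL, region = NULL, annotation = NULL,
                        n_perm = 1000, seed = NULL, var_equal = FALSE) {
  direction <- match.arg(direction)
  E <- if (is.matrix(expr)) expr else expr_matrix(expr)
  if (is.null(probes)) {
    if (is.null(region) || is.null(annotation)) {
      abort("give either `probes` or `region` + `annotation`")
    }
    mid <- (annotation$start + annotation$end) / 2
    probes <- annotation$probe_id[annotation$chrom == region$chrom &
                                    mid >= region$start & mid < region$end]
  }
  probes <- intersect(probes, rownames(E))
  if (length(probes) < 1) abort("no region probes found in the expression matrix")

  if (!is.data.frame(groups)) {
    groups <- tibble(sample_id = names(groups), group = unname(groups))
  }
  bad <- setdiff(unique(groups$group), c("aberrant", "wildtype", "excluded"))
  if (length(bad) > 0) abort(paste0("unknown group(s): ", paste(bad, collapse = ", ")))
  ab <- groups$sample_id[groups$group == "aberrant"]
  wt <- groups$sample_id[groups$group == "wildtype"]
  if (length(ab) < 2 || length(wt) < 2) {
    abort("need at least 2 samples in each of aberrant and wildtype")
  }
  X <- E[probes, c(ab, wt), drop = FALSE]
  n_ab <- length(ab)
  n_all <- ncol(X)

  stat_for <- function(ab_idx) {
    p <- welch_one_sided_p(X[, ab_idx, drop = FALSE],
                           X[, setdiff(seq_len(n_all), ab_idx), drop = FALSE],
                           direction = direction, var_equal = var_equal)
    sum(log(p))
  }
  run <- function() {
    observed <- stat_for(seq_len(n_ab))
    permuted <- vapply(seq_len(n_perm), function(i) {
      stat_for(sample.int(n_all, n_ab))
    }, numeric(1))
    list(observed = observed, permuted = permuted)
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())

  p_probe <- welch_one_sided_p(X[, seq_len(n_ab), drop = FALSE],
                               X[, -seq_len(n_ab), drop = FALSE],
                               direction = direction, var_equal = var_equal)
  if (any(p_probe == 1 & apply(X, 1, sd) == 0)) {
    inform("zero-variance probe(s) in the region; their p-values set to 1")
  }
  structure(list(
    observed = res$observed,
    permuted = res$permuted,
    empirical_p = (1 + sum(res$permuted <= res$observed)) / (n_perm + 1),
    n_aberrant = n_ab, n_wildtype = length(wt), n_excluded =
      sum(groups$group == "excluded"),
    n_probes = length(probes), n_perm = n_perm, direction = direction,
    probe_p = setNames(p_probe, probes), seed = seed
  ), class = "cna_assoc")
}

## Vectorized one-sided two-sample t-test p-values, one row of X/Y per
## probe.  direction "gain": alternative mean(X) > mean(Y); "loss": <.
## Probes with zero variance in both groups get p = 1 (uninformative).
welch_one_sided_p <- function(X, Y, direction = "gain", var_equal = FALSE) {
  n1 <- ncol(X); n2 <- ncol(Y)
  m1 <- rowMeans(X); m2 <- rowMeans(Y)
  v1 <- rowSums((X - m1)^2) / (n1 - 1)
  v2 <- rowSums((Y - m2)^2) / (n2 - 1)
  if (var_equal) {
    sp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(m1))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t <- (m1 - m2) / se
  p <- if (direction == "gain") pt(t, df, lower.tail = FALSE) else pt(t, df)
  # zero variance in both groups: the test is undefined; such probes are
  # treated as uninformative (p = 1)
  p[se == 0] <- 1
  unname(p)
}

#' @export
print.cna_assoc <- function(x, ...) {
  cat("<cna_assoc>", x$direction, "region,", x$n_probes, "probes;",
      x$n_aberrant, "aberrant vs", x$n_wildtype, "wild-type samples\n")
  cat(sprintf("  observed sum-log-p = %.3f; empirical p = %.4g (%d permutations)\n",
              x$observed, x$empirical_p, x$n_perm))
  invisible(x)
}

#' Write an association test result
#'
#' @param x A `cna_assoc` object.
#' @param path Output TSV path.
#' @param region_name Label for the region column.
#' @return `path`, invisibly.
#' @export
write_assoc_report <- function(x, path, region_name = "region") {
  readr::write_tsv(glance(x) |> mutate(region = region_name, .before = 1),
                   path, progress = FALSE)
  invisible(path)
}
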