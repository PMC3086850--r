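#' One-vs-rest contingency counts for a copy-number label
#'
#' Tallies the 2x2 table for one target label (gain or loss) between
#' predicted and true per-probe labels: a true positive is a probe called
#' the label by both, a false positive by prediction only, and so on.
#'
#' @param pred,truth Character matrices or vectors of equal shape over
#'   `+`/`-`/`o`.
#' @param label Target label, `"+"` or `"-"`.
#' @return A tibble row `label`, `tp`, `fp`, `tn`, `fn`.
#' @export
contingency_counts <- function(pred, truth, label = c("+", "-")) {
  label <- match.arg(label)
  if (!identical(dim(pred), dim(truth)) || length(pred) != length(truth)) {
    abort("pred and truth differ in shape")
  }
  p <- pred == label
  t <- truth == label
  tibble(label = label,
         tp = sum(p & t), fp = sum(p & !t),
         tn = sum(!p & !t), fn = sum(!p & t))
}

#' Sensitivity, specificity and accuracy from a contingency table
#'
#' `Sensitivity = TP/(TP+FN)`, `Specificity = TN/(TN+FP)`,
#' `Accuracy = (TP+TN)/(TP+TN+FP+FN)`.  A metric with a zero denominator is
#' returned as `NA` (undefined), never imputed as 0.
#'
#' @param counts Tibble row from [contingency_counts()] (columns `tp`, `fp`,
#'   `tn`, `fn`).
#' @return The input with `sensitivity`, `specificity`, `accuracy` columns
#'   appended.
#' @export
cna_metrics <- function(counts) {
  counts |>
    mutate(
      sensitivity = ifelse(.data$tp + .data$fn > 0,
                           .data$tp / (.data$tp + .data$fn), NA_real_),
      specificity = ifelse(.data$tn + .data$fp > 0,
                           .data$tn / (.data$tn + .data$fp), NA_real_),
      accuracy = ifelse(.data$tp + .data$fp + .data$tn + .data$fn > 0,
                        (.data$tp + .data$tn) /
                          (.data$tp + .data$fp + .data$tn + .data$fn),
                        NA_real_)
    )
}

#' Leave-one-out cross-validation of copy-number prediction
#'
#' For each held-out sample: per-probe reference medians are computed on the
#' training cohort only; training samples are symbolized against them and
#' superimposed on their projected CGH truth to train per-chromosome HMMs;
#' the held-out sample is symbolized against the same training medians,
#' decoded, and scored against its own projected truth.  The raw (`rgep`)
#' and smoothed (`sgep`) expression baselines are scored on the same folds.
#' Metrics are reported per chromosome and genome-wide, as mean and sd over
#' folds and as pooled counts over all folds.
#'
#' @param expr Expression tibble (`probe_id` + sample columns) or matrix.
#' @param segments Segment tibble (`sample_id`, `chrom`, `start`, `end`,
#'   `label`) giving the CGH truth.
#' @param annotation The matching [genome_annotation()].
#' @param config A [discretization_config()].
#' @param decoder `"viterbi"` or `"posterior"` for the HMM method.
#' @param cutoff Posterior cutoff when `decoder = "posterior"`.
#' @param pseudocount Additive smoothing for [train_hmm()].
#' @param lod_cutoff Cytoband LOD cutoff for the `sgep` baseline.
#' @param methods Subset of `c("hmm", "rgep", "sgep")` to score; `"hmm"`
#'   is the HMM method.
#' @param min_aberrant Minimum number of aberrant training samples per
#'   (chromosome, label) below which a warning row is recorded; chromosomes
#'   with rare aberrations have too little training signal.
#' @return An object of class `cna_loocv`: `metrics` (per-fold mean/sd
#'   tibble), `pooled` (metrics on counts pooled over folds), `folds`
#'   (per-fold per-label contingency tibble), `calls` (per-method predicted
#'   label matrix, each column predicted with its own fold's model),
#'   `truth`, and `insufficient_training` (warning tibble).
#' @export
loocv <- function(expr, segments, annotation,
                  config = discretization_config(),
                  decoder = c("viterbi", "posterior"), cutoff = 0.5,
                  pseudocount = 0.5, lod_cutoff = 2,
                  methods = c("hmm", "rgep", "sgep"),
                  min_aberrant = 3) {
  decoder <- match.arg(decoder)
  methods <- match.arg(methods, several.ok = TRUE)
  E <- if (is.matrix(expr)) expr else expr_matrix(expr)
  n <- ncol(E)
  if (n < 3) abort("LOOCV needs at least 3 samples")
  samples <- colnames(E)
  truth <- project_segments(segments, annotation, samples = samples)
  idx <- ann_chrom_index(annotation)

  calls <- lapply(methods, function(m)
    matrix(NA_character_, nrow(E), n, dimnames = dimnames(E)))
  names(calls) <- methods
  warn_rows <- list()

  for (f in seq_len(n)) {
    train_cols <- setdiff(seq_len(n), f)
    med <- apply(E[, train_cols, drop = FALSE], 1, median)
    if (config$scale == "linear" && any(med <= 0)) {
      abort(sprintf("non-positive training median for probe '%s'",
                    rownames(E)[which(med <= 0)[1]]))
    }
    S_test <- symbolize(E[, f, drop = FALSE], config, reference = med)

    if ("hmm" %in% methods) {
      S_train <- symbolize(E[, train_cols, drop = FALSE], config,
                           reference = med)
      model <- train_hmm(S_train, truth[, train_cols, drop = FALSE],
                         annotation, pseudocount = pseudocount)
      calls$hmm[, f] <- decode_matrix(model, S_test, annotation,
                                       decoder, cutoff)$labels[, 1]
      # flag (chromosome, label) pairs with too few aberrant training samples
      for (chrom in names(idx)) {
        tr <- truth[idx[[chrom]], train_cols, drop = FALSE]
        for (lab in c("+", "-")) {
          n_ab <- sum(colSums(tr == lab) > 0)
          if (n_ab < min_aberrant) {
            warn_rows[[length(warn_rows) + 1]] <-
              tibble(fold = samples[f], chrom = chrom, label = lab,
                     n_aberrant_training = n_ab)
          }
        }
      }
    }
    if ("rgep" %in% methods) {
      calls$rgep[, f] <- rgep(S_test)[, 1]
    }
    if ("sgep" %in% methods) {
      bc <- sgep(S_test, annotation, lod_cutoff = lod_cutoff)
      calls$sgep[, f] <- cytoband_calls_to_probes(bc, annotation)[, 1]
    }
  }

  scope_rows <- function(pred_col, truth_col, fold, method) {
    per_chrom <- purrr::map_dfr(names(idx), function(chrom) {
      i <- idx[[chrom]]
      bind_rows(contingency_counts(pred_col[i], truth_col[i], "+"),
                contingency_counts(pred_col[i], truth_col[i], "-")) |>
        mutate(chrom = chrom)
    })
    genome <- bind_rows(contingency_counts(pred_col, truth_col, "+"),
                        contingency_counts(pred_col, truth_col, "-")) |>
      mutate(chrom = "genome")
    bind_rows(per_chrom, genome) |>
      mutate(fold = fold, method = method)
  }
  folds <- purrr::map_dfr(methods, function(meth) {
    purrr::map_dfr(seq_len(n), function(f) {
      scope_rows(calls[[meth]][, f], truth[, f], samples[f], meth)
    })
  }) |>
    cna_metrics()

  metrics <- folds |>
    group_by(.data$method, .data$chrom, .data$label) |>
    summarise(across(c("sensitivity", "specificity", "accuracy"),
                     list(mean = ~mean(.x, na.rm = TRUE),
                          sd = ~sd(.x, na.rm = TRUE))),
              n_folds = n(), .groups = "drop")

  pooled <- folds |>
    group_by(.data$method, .data$chrom, .data$label) |>
    summarise(across(c("tp", "fp", "tn", "fn"), sum), .groups = "drop") |>
    cna_metrics()

  structure(list(metrics = metrics, pooled = pooled, folds = folds,
                 calls = calls, truth = truth,
                 insufficient_training = if (length(warn_rows))
                   distinct(bind_rows(warn_rows), .data$chrom, .data$label,
                            .keep_all = TRUE)
                 else tibble(fold = character(), chrom = character(),
                             label = character(),
                             n_aberrant_training = integer()),
                 decoder = decoder, cutoff = cutoff,
                 pseudocount = pseudocount, lod_cutoff = lod_cutoff),
            class = "cna_loocv")
}

#' @export
print.cna_loocv <- function(x, ...) {
  cat("<cna_loocv>", length(unique(x$folds$fold)), "folds;",
      "decoder:", x$decoder, "\n")
  gw <- x$metrics[x$metrics$chrom == "genome", ]
  print(gw[c("method", "label", "sensitivity_mean", "specificity_mean",
             "accuracy_mean")])
  invisible(x)
}

#' Write the cross-validation report
#'
#' @param x A `cna_loocv` object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_loocv_report <- function(x, path) {
  out <- x$metrics |>
    select("chrom", "label", "method",
           sensitivity_mean = "sensitivity_mean",
           sensitivity_sd = "sensitivity_sd",
           specificity_mean = "specificity_mean",
           specificity_sd = "specificity_sd",
           accuracy_mean = "accuracy_mean",
           accuracy_sd = "accuracy_sd")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Pearson correlation between per-cytoband frequency profiles
#'
#' Correlates two methods' cytoband gain/loss frequency vectors
#' (concatenated over the shared cytoband list) — the agreement statistic
#' used when comparing decoders, cutoffs or methods at cytoband resolution.
#'
#' @param freq_a,freq_b Tibbles from [cytoband_frequencies()] over the same
#'   cytobands, or plain numeric vectors of equal length.
#' @return Pearson correlation coefficient, or `NA` with a warning if
#'   either vector has zero variance.
#' @export
frequency_correlation <- function(freq_a, freq_b) {
  vec <- function(f) {
    if (is.numeric(f)) return(f)
    stopifnot(all(c("n_gain", "n_loss") %in% names(f)))
    c(f$n_gain, f$n_loss)
  }
  a <- vec(freq_a)
  b <- vec(freq_b)
  if (length(a) != length(b)) abort("frequency vectors differ in length")
  if (sd(a) == 0 || sd(b) == 0) {
    warn("zero variance in a frequency vector; correlation undefined")
    return(NA_real_)
  }
  cor(a, b)
}
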