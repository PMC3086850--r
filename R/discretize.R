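#' Discretization thresholds
#'
#' Configuration for converting continuous measurements into the discrete
#' alphabets of the model.  Expression is cut at a fold change relative to
#' the per-probe cohort median (default 1.5-fold); CGH tumor/normal signal
#' ratios are cut at 1.25 (gain) and 0.75 (loss).  All comparisons are
#' strict, so boundary values fall in the neutral class.
#'
#' @param fold_threshold Fold change above/below the cohort median calling
#'   high/low expression; must be > 1.  Default 1.5.
#' @param gain_ratio CGH signal ratio above which a region is a gain; > 1.
#'   Default 1.25.
#' @param loss_ratio CGH signal ratio below which a region is a loss; < 1.
#'   Default 0.75.
#' @param scale Expression scale: `"linear"` intensities or `"log2"` values.
#' @return A list of class `discretization_config`.
#' @export
discretization_config <- function(fold_threshold = 1.5, gain_ratio = 1.25,
                                  loss_ratio = 0.75,
                                  scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  if (!(fold_threshold > 1)) abort("fold_threshold must be > 1")
  if (!(loss_ratio < 1 && 1 < gain_ratio)) {
    abort("need loss_ratio < 1 < gain_ratio")
  }
  structure(list(fold_threshold = fold_threshold, gain_ratio = gain_ratio,
                 loss_ratio = loss_ratio, scale = scale),
            class = "discretization_config")
}

#' Discretize expression into H/L/M symbols
#'
#' Each value is compared with its probe's cohort median: the ratio
#' `r = value / median` (or `2^(value - median)` on the log2 scale) maps to
#' `H` if `r > fold_threshold`, `L` if `r < 1/fold_threshold`, else `M`.
#' The mapping depends only on each probe's own row, so rescaling a probe by
#' a positive constant leaves its symbols unchanged.
#'
#' @param expr Expression tibble (`probe_id` + one numeric column per sample)
#'   or a probes-by-samples numeric matrix.
#' @param config A [discretization_config()].
#' @param reference Optional per-probe reference medians (named numeric
#'   vector, names = probe ids).  Used in cross-validation to symbolize a
#'   held-out sample against training-cohort medians; default is the median
#'   across the supplied samples.
#' @return A tibble (`probe_id` + per-sample symbol columns) when `expr` is
#'   a tibble, or a character matrix when `expr` is a matrix.
#' @export
#' @examples
#' expr <- tibble::tibble(probe_id = "p1", s1 = 3.2, s2 = 2.0, s3 = 1.0)
#' symbolize(expr)  # medians 2.0 -> symbols H, M, L
symbolize <- function(expr, config = discretization_config(),
                      reference = NULL) {
  tbl_in <- !is.matrix(expr)
  m <- if (tbl_in) expr_matrix(expr) else expr
  med <- if (is.null(reference)) apply(m, 1, median) else
    unname(reference[rownames(m)])
  if (anyNA(med)) abort("reference medians missing for some probes")
  if (config$scale == "linear") {
    if (any(m <= 0)) abort("linear-scale expression values must be > 0")
    bad <- which(med <= 0)
    if (length(bad) > 0) {
      abort(sprintf("non-positive cohort median for probe '%s'",
                    rownames(m)[bad[1]]))
    }
    r <- m / med
  } else {
    r <- 2^(m - med)
  }
  sym <- matrix("M", nrow(m), ncol(m), dimnames = dimnames(m))
  sym[r > config$fold_threshold] <- "H"
  sym[r < 1 / config$fold_threshold] <- "L"
  if (tbl_in) matrix_to_tbl(sym) else sym
}

#' Threshold a CGH signal ratio into a copy-number label
#'
#' @param ratio Tumor/normal signal ratio; must be > 0.
#' @param config A [discretization_config()].
#' @return `"+"` if `ratio > gain_ratio`, `"-"` if `ratio < loss_ratio`,
#'   else `"o"` (boundaries inclusive of neither).
#' @export
#' @examples
#' label_ratio(1.30)  # "+"
#' label_ratio(1.25)  # "o": thresholds are strict
label_ratio <- function(ratio, config = discretization_config()) {
  if (!is.numeric(ratio) || length(ratio) != 1 || is.na(ratio) || ratio <= 0) {
    abort("ratio must be a single positive number")
  }
  if (ratio > config$gain_ratio) "+"
  else if (ratio < config$loss_ratio) "-"
  else "o"
}

#' Project segments onto probes
#'
#' Marks each probe with the label of the segment containing its midpoint;
#' probes whose midpoint lies outside every segment are normal (`"o"`).
#' Should opposite-label segments both contain a probe's midpoint, the
#' segment with the greater base-pair overlap with the probe wins; an exact
#' tie gives `"o"`.
#'
#' @param segments Segment tibble (`sample_id`, `chrom`, `start`, `end`,
#'   `label`), 0-based half-open.
#' @param annotation A [genome_annotation()].
#' @param samples Optional character vector fixing the output sample columns
#'   (defaults to the samples present in `segments`).
#' @return A probes-by-samples character matrix over `+`/`-`/`o`, rows in
#'   annotation order.
#' @export
project_segments <- function(segments, annotation, samples = NULL) {
  samples <- samples %||% unique(segments$sample_id)
  m <- matrix("o", nrow(annotation), length(samples),
              dimnames = list(annotation$probe_id, samples))
  if (nrow(segments) == 0 || length(samples) == 0) return(m)

  unknown <- setdiff(unique(segments$chrom), unique(annotation$chrom))
  if (length(unknown) > 0) {
    warn(paste0("segments on chromosome(s) absent from annotation, skipped: ",
                paste(unknown, collapse = ", ")))
  }
  mid <- (annotation$start + annotation$end) / 2
  segs <- segments[segments$sample_id %in% samples &
                     segments$chrom %in% annotation$chrom, , drop = FALSE]
  if (nrow(segs) == 0) return(m)

  overlap <- matrix(0, nrow(annotation), length(samples),
                    dimnames = list(annotation$probe_id, samples))
  best <- overlap   # overlap of the currently winning label
  for (i in seq_len(nrow(segs))) {
    hit <- which(annotation$chrom == segs$chrom[i] &
                   mid >= segs$start[i] & mid < segs$end[i])
    if (length(hit) == 0) next
    s <- segs$sample_id[i]
    ov <- pmin(annotation$end[hit], segs$end[i]) -
      pmax(annotation$start[hit], segs$start[i])
    cur <- m[hit, s]
    lab <- segs$label[i]
    for (k in seq_along(hit)) {
      p <- hit[k]
      if (cur[k] == "o" && best[p, s] == 0) {
        m[p, s] <- lab; best[p, s] <- ov[k]
      } else if (cur[k] == lab) {
        best[p, s] <- max(best[p, s], ov[k])
      } else {
        # opposite labels both cover the midpoint: larger bp overlap wins
        if (ov[k] > best[p, s]) {
          m[p, s] <- lab; best[p, s] <- ov[k]
        } else if (ov[k] == best[p, s]) {
          m[p, s] <- "o"
        }
      }
    }
  }
  m
}
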