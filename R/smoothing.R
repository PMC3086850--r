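#' Multinomial log-of-odds score for a cytoband
#'
#' Scores how strongly a cytoband's mix of per-probe labels departs from the
#' same sample's genome-wide background.  Under the alternative the
#' multinomial label proportions are the cytoband's own MLE
#' `theta1_j = n_j / n`; under the null they are the background proportions
#' `theta0_j = N_j / N`.  The score is the base-10 log likelihood ratio
#' `LOD = sum_j n_j log10(theta1_j / theta0_j)` with the convention
#' `0 * log(.) = 0`; multinomial coefficients cancel and are omitted.  The
#' score is always >= 0 and equals 0 exactly when the cytoband proportions
#' match the background.
#'
#' @param n_plus,n_minus,n_o Probe counts by label on the cytoband.
#' @param N_plus,N_minus,N_o Genome-wide background counts, same sample.
#' @return The LOD score (non-negative).  If the background lacks a label
#'   that the cytoband shows, `Inf` is returned with a warning.
#' @export
#' @examples
#' lod_score(9, 0, 1, 100, 100, 800)  # ~7.69
lod_score <- function(n_plus, n_minus, n_o, N_plus, N_minus, N_o) {
  n_j <- c(n_plus, n_minus, n_o)
  N_j <- c(N_plus, N_minus, N_o)
  if (any(n_j < 0) || any(N_j < 0)) abort("counts must be >= 0")
  n <- sum(n_j)
  N <- sum(N_j)
  if (n < 1) abort("cytoband has no probes")
  if (N < n) abort("background smaller than cytoband")
  active <- n_j > 0
  if (any(active & N_j == 0)) {
    warn("background lacks a label present on the cytoband; LOD is infinite")
    return(Inf)
  }
  theta1 <- n_j / n
  theta0 <- N_j / N
  sum(n_j[active] * log10(theta1[active] / theta0[active]))
}

#' Smooth per-probe calls into cytoband-level calls
#'
#' Tallies per-probe labels on each cytoband, scores each cytoband against
#' the sample's genome-wide label counts with [lod_score()], and calls a
#' gain or loss where the score reaches the cutoff.  The direction is the
#' majority aberrant label; an exact tie yields no call.
#'
#' @param calls Probes-by-samples character matrix over `+`/`-`/`o`, or a
#'   calls tibble (`probe_id` + sample columns), aligned to `annotation`.
#' @param annotation The matching [genome_annotation()].
#' @param lod_cutoff LOD score at or above which a cytoband is called;
#'   default 2.
#' @return A tibble `sample_id`, `chrom`, `cytoband`, `n_plus`, `n_minus`,
#'   `n_o`, `lod`, `call` (`+`, `-` or `none`), cytobands in genome order.
#' @export
call_cytobands <- function(calls, annotation, lod_cutoff = 2) {
  m <- if (is.matrix(calls)) calls else expr_matrix_chr(calls)
  if (nrow(m) != nrow(annotation)) abort("calls not aligned to annotation")
  band <- factor(paste(annotation$chrom, annotation$cytoband, sep = "\r"),
                 levels = unique(paste(annotation$chrom, annotation$cytoband,
                                       sep = "\r")))
  band_chrom <- annotation$chrom[!duplicated(band)]
  band_name <- annotation$cytoband[!duplicated(band)]
  purrr::map_dfr(colnames(m), function(s) {
    lab <- m[, s]
    bg <- c(sum(lab == "+"), sum(lab == "-"), sum(lab == "o"))
    np <- tapply(lab == "+", band, sum)
    nm <- tapply(lab == "-", band, sum)
    no <- tapply(lab == "o", band, sum)
    lod <- vapply(seq_along(np), function(k) {
      lod_score(np[k], nm[k], no[k], bg[1], bg[2], bg[3])
    }, numeric(1))
    call <- rep("none", length(np))
    call[lod >= lod_cutoff & np > nm] <- "+"
    call[lod >= lod_cutoff & nm > np] <- "-"
    tibble(sample_id = s, chrom = band_chrom, cytoband = band_name,
           n_plus = as.integer(np), n_minus = as.integer(nm),
           n_o = as.integer(no), lod = lod, call = call)
  })
}

#' Raw expression-to-copy-number baseline (rGEP)
#'
#' Maps expression symbols to copy-number labels with no model: high
#' expression to gain (`H` -> `+`), low to loss (`L` -> `-`), medium to
#' normal (`M` -> `o`), elementwise.
#'
#' @param symbols Symbol tibble or matrix over `H`/`L`/`M`.
#' @return Object of the same shape over `+`/`-`/`o`.
#' @export
rgep <- function(symbols) {
  tbl_in <- !is.matrix(symbols)
  m <- if (tbl_in) expr_matrix_chr(symbols) else symbols
  out <- matrix(c("H" = "+", "L" = "-", "M" = "o")[m], nrow(m), ncol(m),
                dimnames = dimnames(m))
  if (any(is.na(out))) abort("unknown expression symbol")
  if (tbl_in) matrix_to_tbl(out) else out
}

#' Smoothed expression baseline (sGEP)
#'
#' [rgep()] followed by cytoband-level smoothing with [call_cytobands()]:
#' the second comparator method, which shares the smoothing step with the
#' HMM pipeline but skips the model.
#'
#' @inheritParams call_cytobands
#' @param symbols Symbol tibble or matrix.
#' @return Cytoband call tibble as from [call_cytobands()].
#' @export
sgep <- function(symbols, annotation, lod_cutoff = 2) {
  call_cytobands(rgep(symbols), annotation, lod_cutoff = lod_cutoff)
}

#' Expand cytoband calls back to per-probe labels
#'
#' Assigns every probe the call of its cytoband (`none` -> `o`), giving a
#' probe-level label matrix comparable with per-probe predictions.
#'
#' @param band_calls Tibble from [call_cytobands()] or [sgep()].
#' @param annotation The matching [genome_annotation()].
#' @return Probes-by-samples character matrix.
#' @export
cytoband_calls_to_probes <- function(band_calls, annotation) {
  samples <- unique(band_calls$sample_id)
  m <- matrix("o", nrow(annotation), length(samples),
              dimnames = list(annotation$probe_id, samples))
  key <- paste(annotation$chrom, annotation$cytoband, sep = "\r")
  for (s in samples) {
    bc <- band_calls[band_calls$sample_id == s & band_calls$call != "none", ,
                     drop = FALSE]
    if (nrow(bc) == 0) next
    hit <- match(key, paste(bc$chrom, bc$cytoband, sep = "\r"))
    m[!is.na(hit), s] <- bc$call[hit[!is.na(hit)]]
  }
  m
}

#' Per-cytoband gain/loss frequencies
#'
#' Counts, for each cytoband, the samples harboring at least one probe with
#' each aberrant label — the summary plotted as cytoband frequency profiles.
#'
#' @param calls Probes-by-samples character matrix or calls tibble.
#' @param annotation The matching [genome_annotation()].
#' @return Tibble `chrom`, `cytoband`, `n_gain`, `n_loss` in genome order.
#' @export
cytoband_frequencies <- function(calls, annotation) {
  m <- if (is.matrix(calls)) calls else expr_matrix_chr(calls)
  key <- paste(annotation$chrom, annotation$cytoband, sep = "\r")
  band <- factor(key, levels = unique(key))
  gain <- apply(m == "+", 2, function(x) tapply(x, band, any))
  loss <- apply(m == "-", 2, function(x) tapply(x, band, any))
  if (is.null(dim(gain))) {  # single cytoband
    gain <- matrix(gain, nrow = 1)
    loss <- matrix(loss, nrow = 1)
  }
  tibble(chrom = annotation$chrom[!duplicated(band)],
         cytoband = annotation$cytoband[!duplicated(band)],
         n_gain = as.integer(rowSums(gain)),
         n_loss = as.integer(rowSums(loss)))
}
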