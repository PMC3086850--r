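#' Configuration for the synthetic paired-cohort generator
#'
#' Describes a cohort with recurrent per-chromosome copy-number hotspots and
#' a dosage effect coupling copy number to expression.  The defaults sketch
#' a lymphoma-like profile — a handful of hotspots at 15-30% population
#' frequency, gains on two chromosomes and losses on two others — but the
#' frequencies and effect sizes are this package's choices for a realistic
#' regime, not measurements from any cohort.
#'
#' @param n_samples Cohort size; default 100.
#' @param chromosomes Tibble (`chrom`, `n_probes`) defining the genome;
#'   default six chromosomes of 120 probes.
#' @param n_cytobands Cytobands per chromosome (equal-sized runs); default 8.
#' @param probe_spacing Distance between probe starts in bp; default 10000.
#' @param probe_length Probe length in bp; default 1000.
#' @param hotspots Tibble (`chrom`, `label`, `band_lo`, `band_hi`,
#'   `frequency`): each hotspot spans cytobands `band_lo`..`band_hi`
#'   (1-based indices) and is present in a sample with `frequency`.
#' @param segment_jitter Uniform jitter (bp) applied independently to each
#'   realized segment end; default half a cytoband.
#' @param dosage_effect Expected expression fold change for a probe in a
#'   gain (> 1); losses use its reciprocal.  Default 2 (one extra copy of a
#'   diploid locus).
#' @param concordance Probability that a probe inside a CNA expresses the
#'   dosage effect; default 0.7.
#' @param noise_sd Standard deviation of multiplicative log-normal noise on
#'   the natural-log scale; default 0.25.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of the
#'   per-probe baseline intensities; defaults `log(100)` and 1.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_samples = 100,
                          chromosomes = tibble(chrom = paste0("chr", 1:6),
                                               n_probes = 120L),
                          n_cytobands = 8L,
                          probe_spacing = 10000,
                          probe_length = 1000,
                          hotspots = tibble(
                            chrom = c("chr1", "chr3", "chr5", "chr6"),
                            label = c("+", "+", "-", "-"),
                            band_lo = c(5L, 6L, 1L, 7L),
                            band_hi = c(8L, 8L, 3L, 8L),
                            frequency = c(0.30, 0.20, 0.25, 0.15)
                          ),
                          segment_jitter = NULL,
                          dosage_effect = 2,
                          concordance = 0.7,
                          noise_sd = 0.25,
                          baseline_meanlog = log(100),
                          baseline_sdlog = 1) {
  if (any(hotspots$frequency < 0 | hotspots$frequency > 1)) {
    abort("hotspot frequencies must lie in [0, 1]")
  }
  if (!(dosage_effect > 1)) abort("dosage_effect must be > 1")
  if (concordance < 0 || concordance > 1) abort("concordance must lie in [0, 1]")
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  if (!all(hotspots$chrom %in% chromosomes$chrom)) {
    abort("hotspot chromosome not in the genome")
  }
  if (any(hotspots$band_lo > hotspots$band_hi) ||
      any(hotspots$band_lo < 1) || any(hotspots$band_hi > n_cytobands)) {
    abort("hotspot cytoband span outside the chromosome")
  }
  # opposite-label hotspots must not overlap on one chromosome
  ov <- hotspots |>
    inner_join(hotspots, by = "chrom", relationship = "many-to-many",
               suffix = c("", ".y")) |>
    filter(.data$label != .data$label.y,
           .data$band_lo <= .data$band_hi.y, .data$band_lo.y <= .data$band_hi)
  if (nrow(ov) > 0) abort("overlapping opposite-label hotspots on one chromosome")
  structure(list(n_samples = n_samples, chromosomes = chromosomes,
                 n_cytobands = n_cytobands, probe_spacing = probe_spacing,
                 probe_length = probe_length, hotspots = hotspots,
                 segment_jitter = segment_jitter %||%
                   (probe_spacing * max(chromosomes$n_probes) / n_cytobands / 2),
                 dosage_effect = dosage_effect, concordance = concordance,
                 noise_sd = noise_sd, baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog),
            class = "cohort_config")
}

## Annotation implied by a cohort_config: equal-sized cytobands named
## p<k>/q<k> from pter to qter (e.g. "1p4" ... "1q4" on chr1).
config_annotation <- function(cfg) {
  purrr::map_dfr(seq_len(nrow(cfg$chromosomes)), function(ci) {
    chrom <- cfg$chromosomes$chrom[ci]
    m <- cfg$chromosomes$n_probes[ci]
    band_of <- pmin(ceiling(seq_len(m) / (m / cfg$n_cytobands)),
                    cfg$n_cytobands)
    half <- cfg$n_cytobands / 2
    band_name <- ifelse(band_of <= half,
                        paste0("p", ceiling(half) - band_of + 1),
                        paste0("q", band_of - floor(half)))
    tibble(probe_id = sprintf("%s_p%04d", chrom, seq_len(m)),
           chrom = chrom,
           start = (seq_len(m) - 1) * cfg$probe_spacing,
           end = (seq_len(m) - 1) * cfg$probe_spacing + cfg$probe_length,
           cytoband = paste0(sub("chr", "", chrom), band_name))
  }) |>
    genome_annotation()
}

#' Generate a synthetic paired expression/CGH cohort
#'
#' Simulates, with known ground truth, the data regime the model is built
#' for: recurrent chromosomal hotspots realized as per-sample segments whose
#' ends jitter around the hotspot cytobands, and expression that follows
#' copy number through a dosage effect.  A probe inside a CNA expresses the
#' dosage fold change with probability `concordance`; all probes carry
#' multiplicative log-normal noise around a per-probe baseline.
#'
#' @param config A [cohort_config()].
#' @param seed Optional integer seed; the cohort is fully reproducible
#'   per seed.
#' @return Object of class `cna_cohort`: `expression` (tibble), `segments`
#'   (tibble), `annotation` ([genome_annotation()]), `truth` (per-probe
#'   label matrix from [project_segments()]), `config`, `seed`.
#' @export
simulate_cohort <- function(config = cohort_config(), seed = NULL) {
  run <- function() {
    ann <- config_annotation(config)
    samples <- sprintf("s%03d", seq_len(config$n_samples))
    band_bp <- function(chrom, lo, hi) {
      i <- which(ann$chrom == chrom)
      bands <- unique(ann$cytoband[i])
      in_span <- ann$cytoband[i] %in% bands[lo:hi]
      c(min(ann$start[i][in_span]), max(ann$end[i][in_span]))
    }
    chrom_bp <- function(chrom) {
      i <- which(ann$chrom == chrom)
      c(min(ann$start[i]), max(ann$end[i]))
    }

    seg_rows <- list()
    for (s in samples) {
      for (h in seq_len(nrow(config$hotspots))) {
        hs <- config$hotspots[h, ]
        if (runif(1) >= hs$frequency) next
        span <- band_bp(hs$chrom, hs$band_lo, hs$band_hi)
        lim <- chrom_bp(hs$chrom)
        start <- max(lim[1], span[1] + runif(1, -1, 1) * config$segment_jitter)
        end <- min(lim[2], span[2] + runif(1, -1, 1) * config$segment_jitter)
        if (start >= end) next
        seg_rows[[length(seg_rows) + 1]] <-
          tibble(sample_id = s, chrom = hs$chrom, start = start, end = end,
                 label = hs$label)
      }
    }
    segments <- if (length(seg_rows)) normalize_segments(bind_rows(seg_rows))
    else tibble(sample_id = character(), chrom = character(),
                start = numeric(), end = numeric(), label = character())

    truth <- project_segments(segments, ann, samples = samples)

    baseline <- rlnorm(nrow(ann), config$baseline_meanlog,
                       config$baseline_sdlog)
    fac <- matrix(1, nrow(ann), length(samples))
    in_cna <- truth != "o"
    if (any(in_cna)) {
      hit <- rbinom(sum(in_cna), 1, config$concordance) == 1
      eff <- ifelse(truth[in_cna] == "+", config$dosage_effect,
                    1 / config$dosage_effect)
      fac[in_cna] <- ifelse(hit, eff, 1)
    }
    noise <- if (config$noise_sd > 0)
      matrix(exp(rnorm(length(fac), 0, config$noise_sd)), nrow(fac))
    else 1
    E <- baseline * fac * noise
    dimnames(E) <- list(ann$probe_id, samples)

    structure(list(expression = matrix_to_tbl_num(E), segments = segments,
                   annotation = ann, truth = truth, config = config,
                   seed = seed),
              class = "cna_cohort")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

## Numeric matrix -> tibble with probe_id column.
matrix_to_tbl_num <- function(m) {
  bind_cols(tibble(probe_id = rownames(m)), as_tibble(m))
}

#' @export
print.cna_cohort <- function(x, ...) {
  cat("<cna_cohort>", ncol(x$truth), "samples,", nrow(x$annotation),
      "probes on", length(unique(x$annotation$chrom)), "chromosomes\n")
  cat("  segments:", nrow(x$segments), "; aberrant probe fraction:",
      sprintf("%.3f", mean(x$truth != "o")), "\n")
  invisible(x)
}

#' Summarize ground-truth labels per cytoband
#'
#' Per-cytoband counts of samples harboring each aberrant label — the
#' frequency table mirrored by cytoband frequency profiles.
#'
#' @param truth Per-probe label matrix (or calls tibble).
#' @param annotation The matching [genome_annotation()].
#' @return Tibble `chrom`, `cytoband`, `n_gain`, `n_loss`.
#' @export
summarize_truth <- function(truth, annotation) {
  cytoband_frequencies(truth, annotation)
}

#' Write a cohort to the standard file set
#'
#' Writes `expression.tsv`, `segments.tsv`, `annotation.tsv` and
#' `truth_calls.tsv` into a directory using the package writers, so the
#' files round-trip through the package readers.
#'
#' @param cohort A `cna_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_expression(cohort$expression, file.path(dir, "expression.tsv"))
  write_segments(cohort$segments, file.path(dir, "segments.tsv"))
  write_annotation(cohort$annotation, file.path(dir, "annotation.tsv"))
  write_calls(cohort$truth, file.path(dir, "truth_calls.tsv"))
  invisible(dir)
}
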