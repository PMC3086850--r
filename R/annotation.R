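#' Genome annotation of expression probes
#'
#' Validates and orders a probe annotation table.  The annotation fixes the
#' probe order of every downstream object: expression values, symbols and
#' copy-number labels are all aligned to it, and each chromosome's probe run
#' defines the chain over which its hidden Markov model operates.  Inter-probe
#' distances play no role in the model; only the order matters.
#'
#' Coordinates are interpreted 0-based half-open throughout the package
#' (BED convention).
#'
#' @param x A data frame with columns `probe_id`, `chrom`, `start`, `end`,
#'   `cytoband`.
#' @return A tibble of class `genome_annotation`, sorted by chromosome
#'   (natural order), then `start` ascending, ties broken by `probe_id`.
#' @details Invariants enforced: `start < end`; no duplicate `probe_id`;
#'   each probe maps to exactly one cytoband; cytobands partition each
#'   chromosome's probe list into contiguous runs.
#' @export
#' @examples
#' ann <- genome_annotation(data.frame(
#'   probe_id = c("p1", "p2"), chrom = "chr1",
#'   start = c(0, 1000), end = c(500, 1500), cytoband = "1p1"
#' ))
genome_annotation <- function(x) {
  required <- c("probe_id", "chrom", "start", "end", "cytoband")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("annotation is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  ann <- as_tibble(x)[required]
  ann$probe_id <- as.character(ann$probe_id)
  ann$chrom    <- as.character(ann$chrom)
  ann$cytoband <- as.character(ann$cytoband)
  ann$start    <- as.numeric(ann$start)
  ann$end      <- as.numeric(ann$end)

  if (nrow(ann) == 0) abort("annotation has no probes")
  bad <- which(!(ann$start < ann$end))
  if (length(bad) > 0) {
    abort(paste0("start >= end for probe(s): ",
                 paste(head(ann$probe_id[bad], 5), collapse = ", ")))
  }
  multi_band <- ann |>
    distinct(.data$probe_id, .data$cytoband) |>
    count(.data$probe_id) |>
    filter(.data$n > 1)
  if (nrow(multi_band) > 0) {
    abort(paste0("probe(s) with ambiguous cytoband membership: ",
                 paste(head(multi_band$probe_id, 5), collapse = ", ")))
  }
  dup <- ann$probe_id[duplicated(ann$probe_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate probe id(s): ",
                 paste(head(unique(dup), 5), collapse = ", ")))
  }

  ann <- ann |>
    mutate(.chrom_rank = chrom_rank(.data$chrom)) |>
    arrange(.data$.chrom_rank, .data$start, .data$probe_id) |>
    select(-".chrom_rank")

  # cytobands must be contiguous runs within each chromosome
  split_runs <- ann |>
    group_by(.data$chrom) |>
    summarise(ok = length(rle(.data$cytoband)$values) ==
                n_distinct(.data$cytoband), .groups = "drop") |>
    filter(!.data$ok)
  if (nrow(split_runs) > 0) {
    abort(paste0("cytobands are not contiguous on chromosome(s): ",
                 paste(split_runs$chrom, collapse = ", ")))
  }

  class(ann) <- c("genome_annotation", class(tibble()))
  ann
}

## Natural chromosome order: chr1 < chr2 < ... < chr10 < chrX; anything
## non-numeric after the numeric ones, alphabetically.
chrom_rank <- function(chrom) {
  stripped <- sub("^chr", "", chrom)
  num <- suppressWarnings(as.numeric(stripped))
  lex <- match(chrom, sort(unique(chrom)))
  ifelse(is.na(num), 1e6 + lex, num)
}

#' Read a probe annotation table
#'
#' Reads a tab-delimited annotation file with columns `probe_id`, `chrom`,
#' `start`, `end`, `cytoband` (header required, `#` comment lines allowed)
#' and validates it with [genome_annotation()].
#'
#' @param path Path to the TSV file.
#' @return A `genome_annotation` tibble.
#' @export
read_annotation <- function(path) {
  ann <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  genome_annotation(ann)
}

#' Write a probe annotation table
#'
#' @param ann A `genome_annotation`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  readr::write_tsv(as_tibble(ann), path, progress = FALSE)
  invisible(path)
}

## Row indices per chromosome, in annotation order.
ann_chrom_index <- function(ann) {
  split(seq_len(nrow(ann)), factor(ann$chrom, unique(ann$chrom)))
}

## Drop chromosomes listed in `exclude` (a character vector, possibly empty).
filter_chromosomes <- function(ann, exclude = character()) {
  if (length(exclude) == 0) return(ann)
  out <- ann[!(ann$chrom %in% exclude), , drop = FALSE]
  if (nrow(out) == 0) abort("all chromosomes excluded")
  class(out) <- class(ann)
  out
}
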