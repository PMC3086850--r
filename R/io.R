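#' Read an expression matrix
#'
#' Reads a tab-delimited expression file: header row of sample ids, first
#' column of probe ids, numeric body of linear-scale intensities (or log2
#' values with `scale = "log2"`).  Probes are reordered to match the
#' annotation; probes absent from the annotation are dropped with a message
#' reporting the count.
#'
#' @param path Path to the TSV file (`#` comment lines allowed).
#' @param annotation A [genome_annotation()] defining probe order.
#' @param scale `"linear"` (all values must be > 0) or `"log2"`.
#' @return A tibble with a `probe_id` column followed by one numeric column
#'   per sample, rows in annotation order.  The number of probes dropped for
#'   missing annotation is attached as attribute `"n_dropped"`.
#' @export
read_expression <- function(path, annotation, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  raw <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (nrow(raw) == 0 || ncol(raw) < 2) abort("empty expression matrix")
  names(raw)[1] <- "probe_id"
  if (anyDuplicated(raw$probe_id)) {
    dup <- unique(raw$probe_id[duplicated(raw$probe_id)])
    abort(paste0("duplicate probe id(s) in expression file: ",
                 paste(head(dup, 5), collapse = ", ")))
  }
  if (anyDuplicated(names(raw)[-1])) abort("duplicate sample ids in header")

  body <- raw[-1]
  for (j in seq_along(body)) {
    vals <- suppressWarnings(as.numeric(body[[j]]))
    bad <- which(is.na(vals) & !is.na(body[[j]]))
    if (length(bad) > 0) {
      abort(sprintf("non-numeric value '%s' at probe '%s', sample '%s'",
                    body[[j]][bad[1]], raw$probe_id[bad[1]], names(body)[j]))
    }
    if (anyNA(vals)) {
      abort(sprintf("missing value at probe '%s', sample '%s'",
                    raw$probe_id[which(is.na(vals))[1]], names(body)[j]))
    }
    body[[j]] <- vals
  }
  expr <- bind_cols(tibble(probe_id = raw$probe_id), body)

  if (scale == "linear" && any(as.matrix(expr[-1]) <= 0)) {
    abort("linear-scale expression values must be > 0")
  }

  keep <- expr$probe_id %in% annotation$probe_id
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    inform(sprintf("dropped %d probe(s) absent from the annotation", n_dropped))
  }
  expr <- expr[keep, , drop = FALSE]
  if (nrow(expr) == 0) abort("no probes shared with the annotation")
  expr <- expr[match(intersect(annotation$probe_id, expr$probe_id),
                     expr$probe_id), , drop = FALSE]
  attr(expr, "n_dropped") <- n_dropped
  attr(expr, "scale") <- scale
  expr
}

#' Write an expression matrix
#'
#' @param expr Expression tibble (`probe_id` + one column per sample).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  readr::write_tsv(expr, path, progress = FALSE)
  invisible(path)
}

## Expression tibble -> numeric matrix (probes x samples), rownames probe_id.
expr_matrix <- function(expr) {
  m <- as.matrix(expr[-1])
  rownames(m) <- expr$probe_id
  m
}

## Character matrix (probes x samples) -> tibble with probe_id column.
matrix_to_tbl <- function(m) {
  bind_cols(tibble(probe_id = rownames(m)), as_tibble(m))
}

#' Read per-sample copy-number segments
#'
#' Reads a BED-like tab-delimited file of CGH segments: columns `sample_id`,
#' `chrom`, `start`, `end` and either a label column (`+`/`-` or
#' `gain`/`loss`) or a numeric tumor/normal signal-ratio column, which is
#' thresholded with [label_ratio()] (segments thresholded to normal are
#' dropped).  Coordinates are 0-based half-open.  Same-label overlapping or
#' abutting segments of a sample are merged.
#'
#' @param path Path to the TSV file (header required, `#` comments allowed).
#' @param config A [discretization_config()]; used only when the fifth column
#'   is a numeric ratio.
#' @return A tibble `sample_id`, `chrom`, `start`, `end`, `label` with labels
#'   in `+`/`-`; genome outside segments is implicitly normal.
#' @export
read_segments <- function(path, config = discretization_config()) {
  segs <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                          progress = FALSE,
                          col_types = readr::cols(.default = readr::col_character()))
  if (nrow(segs) == 0) {
    return(tibble(sample_id = character(), chrom = character(),
                  start = numeric(), end = numeric(), label = character()))
  }
  if (ncol(segs) < 5) abort("segment file needs 5 columns: sample_id, chrom, start, end, label-or-ratio")
  names(segs)[1:5] <- c("sample_id", "chrom", "start", "end", "value")
  segs$start <- as.numeric(segs$start)
  segs$end   <- as.numeric(segs$end)
  if (anyNA(segs$start) || anyNA(segs$end)) abort("non-numeric segment coordinates")
  bad <- which(segs$start >= segs$end)
  if (length(bad) > 0) {
    abort(sprintf("segment start >= end at line %d", bad[1]))
  }

  ratio <- suppressWarnings(as.numeric(segs$value))
  if (!anyNA(ratio)) {
    segs$label <- vapply(ratio, label_ratio, character(1), config = config)
    segs <- segs[segs$label != "o", , drop = FALSE]
  } else {
    map <- c("+" = "+", "-" = "-", "gain" = "+", "loss" = "-")
    lab <- map[tolower(segs$value)]
    if (anyNA(lab)) {
      abort(sprintf("unknown segment label '%s'", segs$value[which(is.na(lab))[1]]))
    }
    segs$label <- unname(lab)
  }
  normalize_segments(segs[c("sample_id", "chrom", "start", "end", "label")])
}

## Merge same-label overlapping or abutting segments within each sample.
normalize_segments <- function(segs) {
  if (nrow(segs) == 0) return(as_tibble(segs))
  segs |>
    arrange(.data$sample_id, .data$label, .data$chrom, .data$start, .data$end) |>
    group_by(.data$sample_id, .data$label, .data$chrom) |>
    mutate(.run = cumsum(.data$start > lag(cummax(.data$end), default = -Inf))) |>
    group_by(.data$sample_id, .data$label, .data$chrom, .data$.run) |>
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop") |>
    select("sample_id", "chrom", "start", "end", "label") |>
    arrange(.data$sample_id, .data$chrom, .data$start)
}

#' Write copy-number segments
#'
#' @param segs Segment tibble as returned by [read_segments()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segs, path) {
  readr::write_tsv(segs, path, progress = FALSE)
  invisible(path)
}

#' Write per-probe copy-number calls
#'
#' Writes a long TSV (`probe_id`, `sample_id`, `label`) of per-probe calls.
#'
#' @param calls Either a probes-by-samples character matrix over `+`/`-`/`o`
#'   or a tibble with `probe_id` plus one column per sample.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path) {
  if (is.matrix(calls)) calls <- matrix_to_tbl(calls)
  long <- tidyr::pivot_longer(calls, -"probe_id",
                              names_to = "sample_id", values_to = "label")
  readr::write_tsv(long, path, progress = FALSE)
  invisible(path)
}

#' Read per-probe copy-number calls
#'
#' @param path TSV written by [write_calls()].
#' @return A tibble with `probe_id` plus one column per sample.
#' @export
read_calls <- function(path) {
  long <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                          progress = FALSE,
                          col_types = readr::cols(.default = readr::col_character()))
  tidyr::pivot_wider(long, names_from = "sample_id", values_from = "label")
}

#' Write predicted calls as BED segments
#'
#' Run-length merges adjacent same-label probes per sample and chromosome and
#' writes one BED-like line per aberrant run: `chrom`, `start` (first probe
#' start), `end` (last probe end), `label`, `sample_id`.  Normal (`o`) runs
#' are not written; an all-normal matrix yields an empty file (header only).
#'
#' @param calls Probes-by-samples character matrix or calls tibble.
#' @param annotation The matching [genome_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls_bed <- function(calls, annotation, path) {
  if (!is.matrix(calls)) calls <- expr_matrix_chr(calls)
  stopifnot(nrow(calls) == nrow(annotation))
  idx <- ann_chrom_index(annotation)
  rows <- list()
  for (s in colnames(calls)) {
    for (chrom in names(idx)) {
      i <- idx[[chrom]]
      r <- rle(calls[i, s])
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      keep <- r$values != "o"
      if (!any(keep)) next
      rows[[length(rows) + 1]] <- tibble(
        chrom = chrom,
        start = annotation$start[i][starts[keep]],
        end = annotation$end[i][ends[keep]],
        label = r$values[keep],
        sample_id = s
      )
    }
  }
  out <- if (length(rows)) bind_rows(rows) else
    tibble(chrom = character(), start = numeric(), end = numeric(),
           label = character(), sample_id = character())
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

## Calls tibble -> character matrix.
expr_matrix_chr <- function(tbl) {
  m <- as.matrix(tbl[-1])
  mode(m) <- "character"
  rownames(m) <- tbl$probe_id
  m
}

#' Serialize a trained model to a text file
#'
#' Writes a self-describing, tab-separated text serialization of a fitted
#' [train_hmm()] model: the state space, alphabet, pseudocount, any recorded
#' thresholds, and per-chromosome initial and transition distributions.
#' Probabilities are printed with `%.17g`, so [read_model()] reproduces them
#' bit for bit.
#'
#' @param model A `cna_hmm` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "cna_hmm"))
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- function(x) sprintf("%.17g", x)
  w <- function(...) writeLines(paste(..., sep = "\t"), con)
  writeLines("# hmmCNA model v1", con)
  w("states", paste(hmm_states(), collapse = " "))
  w("alphabet", paste(cna_symbols, collapse = " "))
  w("pseudocount", fmt(model$pseudocount))
  for (key in names(model$config)) {
    w("param", key, as.character(model$config[[key]]))
  }
  for (chrom in names(model$chromosomes)) {
    p <- model$chromosomes[[chrom]]
    w("chromosome", chrom)
    w("initial", paste(fmt(p$initial), collapse = "\t"))
    for (k in seq_len(9)) {
      w("transition", hmm_states()[k], paste(fmt(p$transition[k, ]), collapse = "\t"))
    }
  }
  invisible(path)
}

#' Read a serialized model
#'
#' @param path File written by [write_model()].
#' @return A `cna_hmm` object; `read_model(write_model(m)) == m`.
#' @export
read_model <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  states <- NULL
  chroms <- list()
  cur <- NULL
  pseudocount <- NA_real_
  config <- list()
  trans_rows <- NULL
  flush_chrom <- function() {
    if (!is.null(cur)) {
      chroms[[cur$name]] <<- list(initial = cur$initial, transition = cur$transition)
    }
  }
  for (f in fields) {
    key <- f[[1]]
    if (key == "states") {
      states <- strsplit(f[[2]], " ", fixed = TRUE)[[1]]
      if (!identical(states, hmm_states())) abort("unexpected state space in model file")
    } else if (key == "alphabet") {
      if (!identical(strsplit(f[[2]], " ", fixed = TRUE)[[1]], cna_symbols)) {
        abort("unexpected alphabet in model file")
      }
    } else if (key == "pseudocount") {
      pseudocount <- as.numeric(f[[2]])
    } else if (key == "param") {
      val <- suppressWarnings(as.numeric(f[[3]]))
      config[[f[[2]]]] <- if (is.na(val)) f[[3]] else val
    } else if (key == "chromosome") {
      flush_chrom()
      cur <- list(name = f[[2]],
                  initial = setNames(rep(NA_real_, 9), hmm_states()),
                  transition = matrix(NA_real_, 9, 9,
                                      dimnames = list(hmm_states(), hmm_states())))
    } else if (key == "initial") {
      cur$initial[] <- as.numeric(f[-1])
    } else if (key == "transition") {
      cur$transition[f[[2]], ] <- as.numeric(f[-(1:2)])
    } else {
      abort(sprintf("unknown model file record '%s'", key))
    }
  }
  flush_chrom()
  if (length(chroms) == 0) abort("model file contains no chromosomes")
  new_cna_hmm(chroms, pseudocount = pseudocount, config = config)
}
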