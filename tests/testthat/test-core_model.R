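test_that("annotation is validated and sorted into genome order", {
  unsorted <- tibble::tibble(
    probe_id = c("b", "a", "c", "d"),
    chrom = c("chr2", "chr1", "chr1", "chr2"),
    start = c(500, 2000, 0, 100),
    end = c(900, 2500, 800, 400),
    cytoband = c("2b1", "1b1", "1b1", "2b1")
  )
  ann <- genome_annotation(unsorted)
  expect_equal(ann$probe_id, c("c", "a", "d", "b"))

  # per-chromosome index lengths from a 10-probe, 2-chromosome fixture
  ann2 <- make_annotation(n = 6, chroms = "chr1") |>
    dplyr::bind_rows(make_annotation(n = 4, chroms = "chr2")) |>
    genome_annotation()
  idx <- hmmCNA:::ann_chrom_index(ann2)
  expect_equal(lengths(idx), c(chr1 = 6L, chr2 = 4L))

  expect_error(genome_annotation(dplyr::mutate(unsorted, end = start)),
               "start >= end")
  expect_error(
    genome_annotation(tibble::tibble(
      probe_id = c("a", "a"), chrom = "chr1", start = c(0, 0),
      end = c(10, 10), cytoband = c("1b1", "1b2")
    )),
    "ambiguous cytoband"
  )
  expect_error(
    genome_annotation(tibble::tibble(
      probe_id = c("a", "a"), chrom = "chr1", start = c(0, 100),
      end = c(10, 110), cytoband = "1b1"
    )),
    "duplicate probe"
  )
  # cytobands must form contiguous runs along a chromosome
  expect_error(
    genome_annotation(tibble::tibble(
      probe_id = c("a", "b", "c"), chrom = "chr1",
      start = c(0, 100, 200), end = c(10, 110, 210),
      cytoband = c("1b1", "1b2", "1b1")
    )),
    "not contiguous"
  )
})

test_that("expression reader round-trips, drops unannotated probes, rejects bad cells", {
  ann <- make_annotation(n = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("probe_id\ts1\ts2",
               "chr1_g002\t2.5\t3.5",
               "chr1_g001\t1.0\t2.0",
               "chr1_g003\t4.0\t0.5"), path)
  expr <- read_expression(path, ann)
  expect_equal(dim(expr), c(3L, 3L))
  expect_equal(expr$probe_id, ann$probe_id)  # reordered to annotation order
  expect_equal(expr$s1, c(1.0, 2.5, 4.0))

  # probe absent from the annotation is dropped with a message
  writeLines(c("probe_id\ts1\ts2",
               "chr1_g001\t1.0\t2.0",
               "nope\t9\t9",
               "chr1_g002\t2.5\t3.5"), path)
  expect_message(expr2 <- read_expression(path, ann), "dropped 1")
  expect_equal(dim(expr2), c(2L, 3L))
  expect_equal(attr(expr2, "n_dropped"), 1L)

  writeLines(c("probe_id\ts1", "chr1_g001\tNaNister"), path)
  expect_error(read_expression(path, ann), "non-numeric.*chr1_g001.*s1")
  writeLines(c("probe_id\ts1", "chr1_g001\t-2"), path)
  expect_error(read_expression(path, ann), "must be > 0")
  writeLines(c("probe_id\ts1", "chr1_g001\t1", "chr1_g001\t2"), path)
  expect_error(read_expression(path, ann), "duplicate probe")
})

test_that("segment reader merges same-label runs and thresholds ratio columns", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tchrom\tstart\tend\tlabel",
               "s1\tchr1\t0\t1000\t+",
               "s1\tchr1\t1000\t2000\tgain",
               "s1\tchr1\t5000\t6000\tloss"), path)
  segs <- read_segments(path)
  expect_equal(nrow(segs), 2L)   # abutting gains merged
  expect_equal(segs$start[segs$label == "+"], 0)
  expect_equal(segs$end[segs$label == "+"], 2000)

  # numeric ratio column: 1.30 -> gain, 1.0 -> dropped as normal
  writeLines(c("sample_id\tchrom\tstart\tend\tratio",
               "s1\tchr1\t0\t1000\t1.30",
               "s1\tchr1\t1000\t2000\t1.00",
               "s1\tchr1\t3000\t4000\t0.60"), path)
  segs2 <- read_segments(path)
  expect_equal(segs2$label, c("+", "-"))

  writeLines(c("sample_id\tchrom\tstart\tend\tlabel",
               "s1\tchr1\t1000\t1000\t+"), path)
  expect_error(read_segments(path), "start >= end")
  writeLines(c("sample_id\tchrom\tstart\tend\tlabel",
               "s1\tchr1\t0\t1000\tamplification"), path)
  expect_error(read_segments(path), "unknown segment label")

  # empty file -> zero segments, all-normal genome
  writeLines("sample_id\tchrom\tstart\tend\tlabel", path)
  empty <- read_segments(path)
  expect_equal(nrow(empty), 0L)
  proj <- project_segments(empty, make_annotation(4), samples = "s1")
  expect_true(all(proj == "o"))
})

test_that("call writers emit long TSV and run-length merged BED", {
  ann <- make_annotation(n = 4)
  calls <- matrix(c("+", "+", "o", "-",
                    "o", "o", "o", "o"), ncol = 2,
                  dimnames = list(ann$probe_id, c("s1", "s2")))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  bed <- withr::local_tempfile(fileext = ".bed")
  write_calls(calls, tsv)
  back <- read_calls(tsv)
  expect_equal(hmmCNA:::expr_matrix_chr(back), calls)

  write_calls_bed(calls, ann, bed)
  lines <- readr::read_tsv(bed, show_col_types = FALSE)
  # two aberrant runs for s1 (probes 1-2 merged; probe 4), none for s2
  expect_equal(nrow(lines), 2L)
  run <- lines[lines$label == "+", ]
  expect_equal(run$start, 0)      # first probe start
  expect_equal(run$end, 11000)    # second probe end
  expect_true(all(lines$sample_id == "s1"))

  write_calls_bed(matrix("o", 4, 1, dimnames = list(ann$probe_id, "s1")),
                  ann, bed)
  expect_equal(nrow(readr::read_tsv(bed, show_col_types = FALSE)), 0L)
})

test_that("model serialization round-trips bit for bit", {
  ann <- make_annotation(n = 6, chroms = c("chr1", "chr2"))
  withr::with_seed(7, {
    S <- matrix(sample(c("H", "L", "M"), 12 * 3, TRUE), 12, 3,
                dimnames = list(ann$probe_id, paste0("s", 1:3)))
    L <- matrix(sample(c("+", "-", "o"), 12 * 3, TRUE), 12, 3,
                dimnames = dimnames(S))
  })
  model <- train_hmm(S, L, ann, pseudocount = 0.5)
  path <- withr::local_tempfile(fileext = ".txt")
  write_model(model, path)
  back <- read_model(path)
  for (chrom in names(model$chromosomes)) {
    expect_identical(back$chromosomes[[chrom]]$transition,
                     model$chromosomes[[chrom]]$transition)
    expect_identical(back$chromosomes[[chrom]]$initial,
                     model$chromosomes[[chrom]]$initial)
  }
  expect_identical(back$pseudocount, model$pseudocount)

  # decoding with a model lacking the queried chromosome names it
  ann3 <- make_annotation(n = 3, chroms = "chr9")
  S9 <- matrix("M", 3, 1, dimnames = list(ann3$probe_id, "s1"))
  expect_error(hmmCNA:::decode_matrix(model, S9, ann3), "chr9")
})

test_that("generated cohorts survive a full write/read round trip", {
  cohort <- simulate_cohort(
    cohort_config(n_samples = 5,
                  chromosomes = tibble::tibble(chrom = c("chr1", "chr2"),
                                               n_probes = 24L),
                  n_cytobands = 4L,
                  hotspots = tibble::tibble(chrom = c("chr1", "chr2"),
                                            label = c("+", "-"),
                                            band_lo = c(3L, 1L),
                                            band_hi = c(4L, 2L),
                                            frequency = 0.5)),
    seed = 11
  )
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  ann <- read_annotation(file.path(dir, "annotation.tsv"))
  expect_equal(as.data.frame(ann), as.data.frame(cohort$annotation))
  expr <- read_expression(file.path(dir, "expression.tsv"), ann)
  expect_equal(expr$probe_id, cohort$expression$probe_id)
  expect_equal(as.matrix(expr[-1]), as.matrix(cohort$expression[-1]),
               tolerance = 1e-12)
  segs <- read_segments(file.path(dir, "segments.tsv"))
  expect_equal(as.data.frame(segs), as.data.frame(cohort$segments),
               tolerance = 1e-12)
})
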