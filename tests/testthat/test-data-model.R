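test_that("expression table round-trips through TSV with ids preserved", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "expr.tsv")
  tbl <- tibble::tibble(
    gene_id = c("g1", "g2", "g3"),
    s1 = c(1.5, 2, 3), s2 = c(4, 5, 6), s3 = c(7, 8, 9), s4 = c(0.1, 0.2, 0.3)
  )
  readr::write_tsv(tbl, path)
  m <- read_expression_table(path)
  expect_identical(dim(m), c(3L, 4L))
  expect_identical(rownames(m), c("g1", "g2", "g3"))
  expect_identical(colnames(m), c("s1", "s2", "s3", "s4"))
  expect_equal(m["g2", "s2"], 5)
})

test_that("malformed expression tables are rejected with informative errors", {
  dir <- withr::local_tempdir()
  header_only <- file.path(dir, "empty.tsv")
  writeLines("gene_id\ts1\ts2", header_only)
  expect_error(read_expression_table(header_only), "no genes",
               class = "longsamgsr_validation_error")

  dup <- file.path(dir, "dup.tsv")
  writeLines(c("gene_id\ts1\ts2", "g1\t1\t2", "g1\t3\t4"), dup)
  expect_error(read_expression_table(dup), "duplicate gene",
               class = "longsamgsr_validation_error")

  badcell <- file.path(dir, "bad.tsv")
  writeLines(c("gene_id\ts1\ts2", "g1\t1\toops"), badcell)
  err <- expect_error(read_expression_table(badcell),
                      class = "longsamgsr_parse_error")
  expect_match(conditionMessage(err), "g1")
  expect_match(conditionMessage(err), "s2")
})

test_that("NA cells become mask = FALSE, values elsewhere intact", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "na.tsv")
  writeLines(c("gene_id\ta.1\tb.1", "g1\t1.5\tNA", "g2\t2\t3"), path)
  m <- read_expression_table(path)
  design <- tibble::tibble(sample_id = c("a.1", "b.1"),
                           subject_id = c("a", "b"),
                           time_index = c(1L, 1L), phenotype = c(1L, 0L))
  # relax the per-time class-size invariant by duplicating subjects
  design2 <- dplyr::bind_rows(
    design,
    dplyr::mutate(design, sample_id = paste0(sample_id, "x"),
                  subject_id = paste0(subject_id, "x"))
  )
  m2 <- cbind(m, m[, 1, drop = FALSE], m[, 2, drop = FALSE])
  colnames(m2) <- design2$sample_id
  ds <- assemble_dataset(m2, design2)
  expect_false(ds$mask["g1", "b", 1])
  expect_true(ds$mask["g2", "b", 1])
  expect_equal(ds$expr["g2", "b", 1], 3)
})

test_that("assemble lays samples out by (subject, time) with explicit missingness", {
  ds <- make_eset(G = 4, n1 = 3, n0 = 2, T = 2, seed = 7)
  parts <- disassemble(ds)
  # full data: all mask true
  reassembled <- assemble_dataset(
    as.matrix(tibble::column_to_rownames(parts$expression, "gene_id")),
    parts$design
  )
  expect_true(all(reassembled$mask))
  expect_identical(dim(reassembled$expr), c(4L, 5L, 2L))

  # drop subject B's time-2 sample entirely
  design_miss <- dplyr::filter(parts$design,
                               !(subject_id == ds$subject_ids[2] & time_index == 2))
  ds2 <- assemble_dataset(
    as.matrix(tibble::column_to_rownames(parts$expression, "gene_id")),
    design_miss
  )
  expect_false(any(ds2$mask[, ds$subject_ids[2], 2]))
  expect_true(all(ds2$mask[, ds$subject_ids[1], ]))
  expect_equal(ds2$expr[, ds$subject_ids[1], 1], ds$expr[, 1, 1],
               ignore_attr = TRUE)
})

test_that("inconsistent phenotype and out-of-range time index are rejected", {
  design <- tibble::tibble(
    sample_id = c("x1", "x2"), subject_id = c("a", "a"),
    time_index = c(1L, 2L), phenotype = c(0L, 1L)
  )
  expect_error(validate_design(design), "inconsistent phenotype",
               class = "longsamgsr_validation_error")

  ds <- make_eset(G = 3, n1 = 2, n0 = 2, T = 2, seed = 1)
  parts <- disassemble(ds)
  raw <- as.matrix(tibble::column_to_rownames(parts$expression, "gene_id"))
  expect_error(assemble_dataset(raw, parts$design, n_time = 1),
               "outside", class = "longsamgsr_validation_error")
})

test_that("disassemble / assemble round-trips exactly", {
  ds <- make_eset(G = 6, n1 = 3, n0 = 4, T = 3, seed = 11)
  # knock out one (subject, time) sample
  ds$mask[, 2, 3] <- FALSE
  parts <- disassemble(ds)
  raw <- as.matrix(tibble::column_to_rownames(parts$expression, "gene_id"))
  ds2 <- assemble_dataset(raw, parts$design)
  expect_equal(ds2$expr[ds2$mask], ds$expr[ds$mask])
  expect_identical(unname(ds2$mask), unname(ds$mask))
  expect_identical(unname(ds2$labels), unname(ds$labels))

  # per-time class counts from the mask equal those from the design table
  cnt_mask <- longsamgsr:::class_counts_per_time(ds2)
  cnt_design <- with(parts$design, table(phenotype, time_index))
  expect_equal(unname(as.vector(cnt_mask)), unname(as.vector(cnt_design)))
})

test_that("tidy long format converts to and from the container", {
  ds <- make_eset(G = 3, n1 = 2, n0 = 2, T = 2, seed = 5)
  df <- as_tibble(ds)
  expect_named(df, c("gene_id", "subject_id", "time_index", "phenotype", "value"))
  expect_equal(nrow(df), 3 * 4 * 2)
  ds2 <- as_longitudinal_eset(df)
  expect_equal(unname(ds2$expr), unname(ds$expr))
  expect_identical(unname(ds2$labels), unname(ds$labels))
})
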