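#' Longitudinal expression container
#'
#' A `longitudinal_eset` holds an aligned gene x subject x time expression
#' tensor for a case/control time-course experiment, together with an explicit
#' missingness mask and subject-level binary phenotype labels. Expression is
#' assumed to be on a log-like, already-normalized scale; the package performs
#' no normalization of its own.
#'
#' @param expr numeric array of dimension (genes, subjects, time points);
#'   values where `mask` is `FALSE` are ignored.
#' @param labels integer vector of subject-level phenotypes (1 = diseased /
#'   complicated, 0 = control / uncomplicated), one per subject, or `NULL` for
#'   an unlabeled base pool (e.g. simulator output before outcomes are drawn).
#' @param mask logical array, same dimension as `expr`, `TRUE` where a
#'   measurement exists. Defaults to "observed wherever finite".
#' @param gene_ids,subject_ids,time_ids identifiers for the three axes;
#'   defaults are taken from `dimnames(expr)` or generated.
#'
#' @return An object of class `longitudinal_eset` with fields `expr`, `mask`,
#'   `labels`, `gene_ids`, `subject_ids`, `time_ids`.
#' @export
longitudinal_eset <- function(expr, labels = NULL, mask = NULL,
                              gene_ids = NULL, subject_ids = NULL,
                              time_ids = NULL) {
  if (!is.array(expr) || length(dim(expr)) != 3L) {
    abort_validation("`expr` must be a 3-d array (gene, subject, time).")
  }
  dn <- dimnames(expr)
  gene_ids <- gene_ids %||% dn[[1]] %||% paste0("gene", seq_len(dim(expr)[1]))
  subject_ids <- subject_ids %||% dn[[2]] %||% paste0("subj", seq_len(dim(expr)[2]))
  time_ids <- time_ids %||% dn[[3]] %||% paste0("t", seq_len(dim(expr)[3]))
  if (is.null(mask)) mask <- is.finite(expr)
  storage.mode(expr) <- "double"
  dimnames(expr) <- dimnames(mask) <- list(gene_ids, subject_ids, time_ids)
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    names(labels) <- subject_ids
  }
  ds <- structure(
    list(expr = expr, mask = mask, labels = labels,
         gene_ids = as.character(gene_ids),
         subject_ids = as.character(subject_ids),
         time_ids = as.character(time_ids)),
    class = "longitudinal_eset"
  )
  validate_eset(ds)
  ds
}

#' Validate a longitudinal expression set
#'
#' Checks the structural invariants: positive dimensions, finite expression
#' wherever the mask is `TRUE`, subject-level labels in \{0, 1\}, and (for
#' labeled data) at least two subjects of each class with data at every time
#' point, which downstream pooled standard deviations require.
#'
#' @param ds a `longitudinal_eset`.
#' @return `ds`, invisibly; aborts with a validation error otherwise.
#' @export
validate_eset <- function(ds) {
  dm <- dim(ds$expr)
  if (dm[1] < 1L || dm[3] < 1L) abort_validation("need at least 1 gene and 1 time point.")
  if (!identical(dim(ds$mask), dm)) abort_validation("`mask` and `expr` dimensions differ.")
  if (any(!is.finite(ds$expr[ds$mask]))) {
    abort_validation("non-finite expression value where mask is TRUE.")
  }
  if (!is.null(ds$labels)) {
    if (length(ds$labels) != dm[2]) abort_validation("one label per subject required.")
    if (!all(ds$labels %in% c(0L, 1L))) abort_validation("labels must be 0 or 1.")
    if (dm[2] < 4L) abort_validation("need at least 4 subjects (2 per class).")
    cnt <- class_counts_per_time(ds)
    if (any(cnt < 2L)) {
      bad <- which(cnt < 2L, arr.ind = TRUE)
      abort_validation(sprintf(
        "fewer than 2 subjects with data in class %s at time point %s.",
        rownames(cnt)[bad[1, 1]], ds$time_ids[bad[1, 2]]
      ))
    }
  }
  invisible(ds)
}

# 2 x T matrix of per-time subject counts with any data, by class.
class_counts_per_time <- function(ds, labels = ds$labels) {
  T <- dim(ds$expr)[3]
  has_data <- apply(ds$mask, c(2, 3), any)  # n x T
  out <- rbind(
    `0` = colSums(has_data[labels == 0L, , drop = FALSE]),
    `1` = colSums(has_data[labels == 1L, , drop = FALSE])
  )
  colnames(out) <- ds$time_ids
  out
}

#' @export
print.longitudinal_eset <- function(x, ...) {
  dm <- dim(x$expr)
  cat(sprintf("<longitudinal_eset> %d genes x %d subjects x %d time points\n",
              dm[1], dm[2], dm[3]))
  if (is.null(x$labels)) {
    cat("  unlabeled (base pool)\n")
  } else {
    cat(sprintf("  phenotype: %d diseased / %d control\n",
                sum(x$labels == 1L), sum(x$labels == 0L)))
  }
  miss <- 1 - mean(x$mask)
  if (miss > 0) cat(sprintf("  missing cells: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' Subset a longitudinal expression set
#'
#' @param ds a `longitudinal_eset`.
#' @param genes,subjects indices or identifiers; `NULL` keeps all.
#' @return a `longitudinal_eset` restricted to the requested genes/subjects.
#' @export
subset_eset <- function(ds, genes = NULL, subjects = NULL) {
  gi <- if (is.null(genes)) seq_along(ds$gene_ids) else resolve_idx(genes, ds$gene_ids, "gene")
  si <- if (is.null(subjects)) seq_along(ds$subject_ids) else resolve_idx(subjects, ds$subject_ids, "subject")
  longitudinal_eset(
    ds$expr[gi, si, , drop = FALSE],
    labels = if (is.null(ds$labels)) NULL else ds$labels[si],
    mask = ds$mask[gi, si, , drop = FALSE],
    gene_ids = ds$gene_ids[gi], subject_ids = ds$subject_ids[si],
    time_ids = ds$time_ids
  )
}

resolve_idx <- function(x, ids, what) {
  if (is.character(x)) {
    idx <- match(x, ids)
    if (anyNA(idx)) abort_validation(sprintf("unknown %s id: %s", what, x[is.na(idx)][1]))
    idx
  } else {
    x <- as.integer(x)
    if (any(x < 1L | x > length(ids))) abort_validation(sprintf("%s index out of range.", what))
    x
  }
}

#' Read a genes-by-samples expression table
#'
#' Parses a delimited text table with gene identifiers in the first column and
#' one column per sample (header row of sample ids). `NA` or empty cells mark
#' missing measurements; any other non-numeric cell is a parse error that names
#' the offending gene and sample.
#'
#' @param path path to the file.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return numeric matrix with gene ids as rownames, sample ids as colnames;
#'   missing cells are `NA`.
#' @export
read_expression_table <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  reader <- if (dialect == "tsv") readr::read_tsv else readr::read_csv
  raw <- reader(path, col_types = readr::cols(.default = readr::col_character()),
                progress = FALSE)
  if (nrow(raw) == 0L) abort_validation(sprintf("no genes: %s has a header but no data rows.", path))
  if (ncol(raw) < 2L) abort_validation(sprintf("%s has no sample columns.", path))
  gene_ids <- as.character(raw[[1]])
  if (anyDuplicated(gene_ids)) {
    abort_validation(sprintf("duplicate gene id(s): %s",
                             paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", ")))
  }
  body <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  bad <- which(is.na(num) & !(is.na(body) | body %in% c("NA", "NaN", "")), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    abort_parse(sprintf(
      "non-numeric cell '%s' at gene '%s', sample '%s' in %s",
      body[bad[1, 1], bad[1, 2]], gene_ids[bad[1, 1]],
      colnames(body)[bad[1, 2]], path
    ))
  }
  rownames(num) <- gene_ids
  colnames(num) <- colnames(body)
  num
}

#' Read a sample design table
#'
#' Expects a tab-delimited file with header
#' `sample_id  subject_id  time_index  phenotype`, one row per sample column of
#' the expression table. `time_index` is 1-based; `phenotype` is 0/1 and must
#' be constant within a subject.
#'
#' @param path path to the TSV file.
#' @return a tibble with the four columns, validated.
#' @export
read_design_table <- function(path) {
  design <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    subject_id = readr::col_character(),
    time_index = readr::col_integer(),
    phenotype = readr::col_integer()
  ), progress = FALSE)
  validate_design(design)
}

validate_design <- function(design) {
  design <- tibble::as_tibble(design)
  need <- c("sample_id", "subject_id", "time_index", "phenotype")
  if (!all(need %in% names(design))) {
    abort_validation(sprintf("design table must have columns: %s",
                             paste(need, collapse = ", ")))
  }
  design$subject_id <- as.character(design$subject_id)
  design$sample_id <- as.character(design$sample_id)
  design$time_index <- as.integer(design$time_index)
  design$phenotype <- as.integer(design$phenotype)
  if (anyDuplicated(design[c("subject_id", "time_index")])) {
    abort_validation("duplicate (subject_id, time_index) pair in design table.")
  }
  if (anyDuplicated(design$sample_id)) {
    abort_validation("duplicate sample_id in design table.")
  }
  if (any(design$time_index < 1L, na.rm = TRUE)) {
    abort_validation("time_index must be a positive 1-based integer.")
  }
  if (!all(design$phenotype %in% c(0L, 1L))) {
    abort_validation("phenotype must be 0 or 1.")
  }
  pheno_n <- tapply(design$phenotype, design$subject_id, function(x) length(unique(x)))
  if (any(pheno_n > 1L)) {
    abort_validation(sprintf("subject '%s' has inconsistent phenotype values.",
                             names(pheno_n)[pheno_n > 1L][1]))
  }
  design
}

#' Assemble a longitudinal dataset from an expression matrix and design table
#'
#' Lays a genes-by-samples matrix out as a (gene, subject, time) tensor using
#' the design table's `(subject_id, time_index)` assignment. Subjects missing a
#' time point get `mask = FALSE` there; time points are ordered by the 1-based
#' `time_index`, never by lexical sort of labels.
#'
#' @param raw numeric matrix from [read_expression_table()].
#' @param design design table (data frame) as from [read_design_table()].
#' @param n_time total number of time points `T`; defaults to
#'   `max(design$time_index)`.
#' @return a [longitudinal_eset()].
#' @export
assemble_dataset <- function(raw, design, n_time = NULL) {
  design <- validate_design(design)
  missing_cols <- setdiff(design$sample_id, colnames(raw))
  if (length(missing_cols) > 0L) {
    abort_validation(sprintf("design sample_id(s) not in expression table: %s",
                             paste(missing_cols, collapse = ", ")))
  }
  T <- as.integer(n_time %||% max(design$time_index))
  if (any(design$time_index > T)) {
    abort_validation(sprintf("time_index %d outside 1..%d.",
                             max(design$time_index), T))
  }
  subjects <- unique(design$subject_id)
  G <- nrow(raw)
  expr <- array(NA_real_, c(G, length(subjects), T))
  mask <- array(FALSE, c(G, length(subjects), T))
  si <- match(design$subject_id, subjects)
  for (r in seq_len(nrow(design))) {
    v <- raw[, design$sample_id[r]]
    expr[, si[r], design$time_index[r]] <- v
    mask[, si[r], design$time_index[r]] <- !is.na(v)
  }
  labels <- design$phenotype[match(subjects, design$subject_id)]
  longitudinal_eset(expr, labels = labels, mask = mask,
                    gene_ids = rownames(raw), subject_ids = subjects,
                    time_ids = paste0("t", seq_len(T)))
}

#' Disassemble a dataset back into an expression table and design table
#'
#' Inverse of [assemble_dataset()]: emits the wide genes-by-samples tibble
#' (one column per observed (subject, time) sample, named
#' `<subject>.<time_index>`) and the matching design tibble.
#'
#' @param ds a labeled `longitudinal_eset`.
#' @return list with elements `expression` (tibble, first column `gene_id`)
#'   and `design` (tibble).
#' @export
disassemble <- function(ds) {
  stopifnot(inherits(ds, "longitudinal_eset"))
  if (is.null(ds$labels)) abort_validation("cannot disassemble an unlabeled dataset.")
  n <- length(ds$subject_ids); T <- length(ds$time_ids)
  present <- apply(ds$mask, c(2, 3), any)
  rows <- which(present, arr.ind = TRUE)
  rows <- rows[order(rows[, 1], rows[, 2]), , drop = FALSE]
  design <- tibble::tibble(
    sample_id = paste0(ds$subject_ids[rows[, 1]], ".", rows[, 2]),
    subject_id = ds$subject_ids[rows[, 1]],
    time_index = as.integer(rows[, 2]),
    phenotype = as.integer(ds$labels[rows[, 1]])
  )
  cols <- lapply(seq_len(nrow(design)), function(r) {
    v <- ds$expr[, rows[r, 1], rows[r, 2]]
    v[!ds$mask[, rows[r, 1], rows[r, 2]]] <- NA_real_
    v
  })
  names(cols) <- design$sample_id
  expression <- tibble::tibble(gene_id = ds$gene_ids, !!!cols)
  list(expression = expression, design = design)
}

#' Tidy long-format view of a longitudinal dataset
#'
#' @param x a `longitudinal_eset`.
#' @param ... unused.
#' @return a tibble with columns `gene_id`, `subject_id`, `time_index`,
#'   `phenotype` (NA for unlabeled data), `value` (`NA` where the measurement
#'   is missing).
#' @export
as_tibble.longitudinal_eset <- function(x, ...) {
  dm <- dim(x$expr)
  v <- x$expr
  v[!x$mask] <- NA_real_
  tibble::tibble(
    gene_id = rep(x$gene_ids, times = dm[2] * dm[3]),
    subject_id = rep(rep(x$subject_ids, each = dm[1]), times = dm[3]),
    time_index = rep(seq_len(dm[3]), each = dm[1] * dm[2]),
    phenotype = if (is.null(x$labels)) NA_integer_ else
      rep(rep(as.integer(x$labels), each = dm[1]), times = dm[3]),
    value = as.vector(v)
  )
}

#' Build a longitudinal dataset from a tidy data frame
#'
#' The data-frame-first entry point: `df` must have columns `gene_id`,
#' `subject_id`, `time_index`, `phenotype`, `value`, one row per observed
#' measurement (missing cells simply absent, or `value = NA`).
#'
#' @param df a data frame in long format.
#' @param ... unused.
#' @return a [longitudinal_eset()].
#' @export
as_longitudinal_eset <- function(df, ...) {
  UseMethod("as_longitudinal_eset")
}

#' @export
as_longitudinal_eset.longitudinal_eset <- function(df, ...) df

#' @export
as_longitudinal_eset.data.frame <- function(df, ...) {
  need <- c("gene_id", "subject_id", "time_index", "phenotype", "value")
  if (!all(need %in% names(df))) {
    abort_validation(sprintf("long-format input needs columns: %s",
                             paste(need, collapse = ", ")))
  }
  genes <- unique(as.character(df$gene_id))
  subjects <- unique(as.character(df$subject_id))
  T <- max(as.integer(df$time_index))
  expr <- array(NA_real_, c(length(genes), length(subjects), T))
  gi <- match(as.character(df$gene_id), genes)
  si <- match(as.character(df$subject_id), subjects)
  ti <- as.integer(df$time_index)
  expr[cbind(gi, si, ti)] <- df$value
  lab_df <- unique(df[, c("subject_id", "phenotype")])
  if (anyDuplicated(lab_df$subject_id)) {
    abort_validation("a subject has more than one phenotype value.")
  }
  labels <- as.integer(lab_df$phenotype[match(subjects, as.character(lab_df$subject_id))])
  longitudinal_eset(expr, labels = labels, gene_ids = genes,
                    subject_ids = subjects, time_ids = paste0("t", seq_len(T)))
}
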