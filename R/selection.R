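#' Gene-set statistic for one gene's trajectory
#'
#' The longitudinal gene-set statistic is the sum of squared SAM statistics
#' over a gene's available time points: the gene's whole trajectory is treated
#' as one gene set.
#'
#' @param d_row numeric vector of per-time SAM statistics (`NA` =
#'   unavailable time point).
#' @return a non-negative scalar.
#' @export
samgs_statistic <- function(d_row) {
  if (all(is.na(d_row))) {
    abort_insufficient("no available time point for this gene.")
  }
  sum(d_row^2, na.rm = TRUE)
}

#' Subject-level label permutations
#'
#' Generates `B` relabelings of the subject-level phenotype vector that
#' preserve the class sizes. A subject's whole trajectory moves between
#' classes as a unit, so within-subject temporal correlation is preserved
#' under the null. If `B` is at least the number of distinct relabelings,
#' the full set is enumerated instead (exhaustive mode).
#'
#' @param labels subject-level 0/1 vector.
#' @param B requested number of permutations (>= 1).
#' @param seed integer seed; the result is deterministic given the seed.
#' @return an `n x B'` 0/1 matrix (one column per relabeling) with attribute
#'   `exhaustive` (`TRUE` when all distinct relabelings are enumerated, in
#'   which case `B'` may be smaller than `B`).
#' @export
generate_permutations <- function(labels, B, seed = 1L) {
  labels <- as.integer(labels)
  n <- length(labels)
  n1 <- sum(labels == 1L)
  if (n1 == 0L || n1 == n) abort_validation("both classes must be present.")
  if (B < 1L) abort_config("`B` must be >= 1.")
  total <- choose(n, n1)
  if (is.finite(total) && B >= total) {
    combos <- utils::combn(n, n1)
    Z <- matrix(0, n, ncol(combos))
    Z[cbind(as.vector(combos), rep(seq_len(ncol(combos)), each = n1))] <- 1
    rlang::inform(sprintf(
      "B = %d >= %d distinct relabelings; using exhaustive enumeration.",
      B, ncol(Z)), class = "longsamgsr_exhaustive")
    attr(Z, "exhaustive") <- TRUE
    return(Z)
  }
  Z <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      z <- numeric(n)
      z[sample.int(n, n1)] <- 1
      z
    }, numeric(n))
  })
  attr(Z, "exhaustive") <- FALSE
  Z
}

#' Permutation p-value
#'
#' Monte-Carlo mode uses the add-one estimator
#' `p = (1 + #\{null >= observed\}) / (B + 1)`, which never returns zero.
#' Exhaustive mode (all distinct relabelings enumerated, the observed one
#' among them) uses the exact proportion `#\{null >= observed\} / B`.
#' Ties count against significance in both modes.
#'
#' @param observed observed statistic.
#' @param null_row numeric vector of permutation statistics.
#' @param exhaustive was `null_row` an exhaustive enumeration?
#' @return a p-value in (0, 1].
#' @export
permutation_pvalue <- function(observed, null_row, exhaustive = FALSE) {
  hits <- sum(null_row >= observed)
  if (exhaustive) hits / length(null_row) else (1 + hits) / (length(null_row) + 1)
}

#' Multiple-testing adjusted q-values
#'
#' Default policy is Benjamini-Hochberg step-up (monotone, parameter-free);
#' `"storey"` applies Storey's pi0 estimate at lambda = 0.5 on top of the
#' BH-style step-up, which can be less conservative when many genes are null.
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @param policy `"bh"` or `"storey"`.
#' @return q-values, same length and order as `pvalues`.
#' @export
compute_qvalues <- function(pvalues, policy = c("bh", "storey")) {
  policy <- match.arg(policy)
  q <- stats::p.adjust(pvalues, method = "BH")
  if (policy == "storey") {
    lambda <- 0.5
    ok <- !is.na(pvalues)
    pi0 <- min(1, mean(pvalues[ok] > lambda) / (1 - lambda))
    q <- pmin(1, q * pi0)
  }
  q
}

#' Screen genes by permutation-tested trajectory statistics
#'
#' Step 1 of the longitudinal gene-set reduction algorithm: computes every
#' gene's trajectory statistic (sum of squared per-time SAM statistics), its
#' p-value from `B` subject-level label permutations (the per-time fudge
#' constants are re-estimated within every permutation), adjusts for multiple
#' testing, and returns the genes with `q <= q_cutoff`. The permutation set,
#' per-permutation null statistics and per-permutation fudge constants are
#' retained so the reduction step can reuse exactly the same null.
#'
#' @param ds a labeled [longitudinal_eset()] (or a long-format data frame
#'   accepted by [as_longitudinal_eset()]).
#' @param B number of permutations (default 1000). Note the granularity
#'   constraint: the smallest attainable q-value is about `G / (B + 1)`, so
#'   `B` must be large relative to `G / q_cutoff` for any gene to pass.
#' @param q_cutoff q-value threshold for selection (default 0.05).
#' @param seed integer seed for the permutation draw.
#' @param s0_policy,qvalue_policy see [fudge_factor()] and [compute_qvalues()].
#' @return an object of class `samgsr_selection`; `tidy()` gives the per-gene
#'   table (gene_id, samgs, pvalue, qvalue, selected), `glance()` a one-row
#'   summary.
#' @export
select_genes <- function(ds, B = 1000L, q_cutoff = 0.05, seed = 1L,
                         s0_policy = c("median", "percentile"),
                         qvalue_policy = c("bh", "storey")) {
  s0_policy <- match.arg(s0_policy)
  qvalue_policy <- match.arg(qvalue_policy)
  ds <- as_longitudinal_eset(ds)
  validate_eset(ds)
  if (is.null(ds$labels)) abort_validation("`ds` must be labeled.")
  if (!is.numeric(B) || B < 1L) abort_config("`B` must be >= 1.")
  if (q_cutoff <= 0 || q_cutoff >= 1) abort_config("`q_cutoff` must be in (0, 1).")

  sam <- sam_matrix(ds, s0_policy = s0_policy, quiet = TRUE)
  n_bad <- sum(is.na(sam$d))
  if (n_bad > 0L) {
    rlang::inform(sprintf("%d (gene, time) cell(s) unavailable (< 2 samples in a class).",
                          n_bad))
  }
  avail <- rowSums(!is.na(sam$d))

  Z <- generate_permutations(ds$labels, B, seed)
  exhaustive <- attr(Z, "exhaustive")
  # observed labels ride along as the first column so that observed and null
  # statistics share one arithmetic path: exact ties (e.g. the identity
  # relabeling in exhaustive mode) then count exactly
  Z_all <- cbind(as.numeric(ds$labels == 1L), Z)
  eng <- sam_engine(ds$expr, ds$mask, Z_all, s0_policy = s0_policy,
                    keep_d = FALSE)
  samgs <- ifelse(avail > 0L, eng$samgs[, 1], NA_real_)
  null_stats <- eng$samgs[, -1, drop = FALSE]  # G x B'
  null <- list(s0 = eng$s0[, -1, drop = FALSE])

  pvalues <- rep(NA_real_, length(samgs))
  ok <- !is.na(samgs)
  hits <- rowSums(null_stats[ok, , drop = FALSE] >= samgs[ok])
  pvalues[ok] <- if (exhaustive) hits / ncol(Z) else (1 + hits) / (ncol(Z) + 1)
  qvalues <- rep(NA_real_, length(samgs))
  qvalues[ok] <- compute_qvalues(pvalues[ok], policy = qvalue_policy)
  selected <- which(!is.na(qvalues) & qvalues <= q_cutoff)

  structure(
    list(
      table = tibble::tibble(
        gene_id = ds$gene_ids,
        samgs = samgs,
        pvalue = pvalues,
        qvalue = qvalues,
        selected = seq_along(samgs) %in% selected
      ),
      selected = selected,
      sam = sam,
      null_stats = null_stats,
      null_s0 = null$s0,
      permutations = Z,
      exhaustive = exhaustive,
      params = list(B = ncol(Z), q_cutoff = q_cutoff, seed = seed,
                    s0_policy = s0_policy, qvalue_policy = qvalue_policy)
    ),
    class = "samgsr_selection"
  )
}

#' @export
print.samgsr_selection <- function(x, ...) {
  cat(sprintf(
    "<samgsr_selection> %d genes screened, %d selected at q <= %g (B = %d%s)\n",
    nrow(x$table), length(x$selected), x$params$q_cutoff, x$params$B,
    if (x$exhaustive) ", exhaustive" else ""))
  invisible(x)
}

#' @rdname select_genes
#' @param x a `samgsr_selection`.
#' @param ... unused.
#' @export
tidy.samgsr_selection <- function(x, ...) x$table

#' @rdname select_genes
#' @export
glance.samgsr_selection <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$table),
    n_selected = length(x$selected),
    B = x$params$B,
    exhaustive = x$exhaustive,
    q_cutoff = x$params$q_cutoff,
    min_qvalue = suppressWarnings(min(x$table$qvalue, na.rm = TRUE))
  )
}

#' Per-time-point SAM q-values
#'
#' The cross-sectional comparator to trajectory-level screening: for every
#' gene and time point separately, the squared SAM statistic is compared to
#' its own permutation null (the same stored subject-level permutations and
#' per-permutation fudge constants as the trajectory test), and the resulting
#' p-values are FDR-adjusted across genes within each time point. A gene that
#' is significant here is detectable by a single-time-point analysis; genes
#' whose association only accumulates over time are not.
#'
#' @param sel a `samgsr_selection` from [select_genes()].
#' @param ds the dataset the selection was computed on.
#' @param qvalue_policy see [compute_qvalues()].
#' @param chunk_size permutations processed per block (bounds memory at
#'   roughly `G * T * chunk_size` doubles).
#' @return a list with G x T matrices `pvalue` and `qvalue`.
#' @export
timepoint_qvalues <- function(sel, ds, qvalue_policy = c("bh", "storey"),
                              chunk_size = 2000L) {
  qvalue_policy <- match.arg(qvalue_policy)
  stopifnot(inherits(sel, "samgsr_selection"))
  ds <- as_longitudinal_eset(ds)
  G <- length(ds$gene_ids)
  T <- length(ds$time_ids)
  B <- ncol(sel$permutations)
  obs2 <- sel$sam$d^2  # G x T
  hits <- matrix(0, G, T)
  for (start in seq(1L, B, by = chunk_size)) {
    cols <- start:min(start + chunk_size - 1L, B)
    eng <- sam_engine(ds$expr, ds$mask,
                      sel$permutations[, cols, drop = FALSE],
                      s0_override = sel$null_s0[, cols, drop = FALSE],
                      keep_d = TRUE)
    for (t in seq_len(T)) {
      nd2 <- eng$d[[t]]^2
      hits[, t] <- hits[, t] + rowSums(nd2 >= obs2[, t], na.rm = TRUE)
    }
  }
  p <- if (sel$exhaustive) hits / B else (1 + hits) / (B + 1)
  p[is.na(obs2)] <- NA_real_
  dimnames(p) <- list(ds$gene_ids, ds$time_ids)
  q <- apply(p, 2, compute_qvalues, policy = qvalue_policy)
  dimnames(q) <- dimnames(p)
  list(pvalue = p, qvalue = q)
}
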