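#' Full longitudinal gene-set reduction pipeline
#'
#' Runs the complete workflow on a labeled dataset: permutation screening of
#' trajectory statistics ([select_genes()]), optional cross-validated tuning
#' of the reduction cutoff ([tune_ck()]), and per-gene reduction to core time
#' points ([reduce_all()]). Returns a fitted object whose `tidy()` method is
#' the final (gene, time point) feature table.
#'
#' @param ds a labeled [longitudinal_eset()] or long-format data frame
#'   accepted by [as_longitudinal_eset()].
#' @param B number of permutations.
#' @param q_cutoff screening q-value threshold.
#' @param ck fixed reduction cutoff; `NULL` (default) tunes it on `grid` by
#'   `folds`-fold cross-validation.
#' @param grid,folds tuning controls, see [tune_ck()].
#' @param seed integer seed used for permutations, folds and fold-level
#'   permutation draws.
#' @param s0_policy,qvalue_policy see [fudge_factor()] and [compute_qvalues()].
#' @param cost linear-SVM regularization constant used during tuning.
#' @return an object of class `samgsr_fit` with components `selection`,
#'   `tuning` (`NULL` when `ck` was fixed), `reduction`, `features`.
#' @export
samgsr <- function(ds, B = 1000L, q_cutoff = 0.05, ck = NULL,
                   grid = seq(0.05, 0.5, by = 0.05), folds = 5L, seed = 1L,
                   s0_policy = c("median", "percentile"),
                   qvalue_policy = c("bh", "storey"), cost = 1) {
  s0_policy <- match.arg(s0_policy)
  qvalue_policy <- match.arg(qvalue_policy)
  ds <- as_longitudinal_eset(ds)
  sel <- select_genes(ds, B = B, q_cutoff = q_cutoff, seed = seed,
                      s0_policy = s0_policy, qvalue_policy = qvalue_policy)
  tuning <- NULL
  if (is.null(ck)) {
    tuning <- tune_ck(ds, grid = grid, folds = folds, seed = seed, B = B,
                      q_cutoff = q_cutoff, s0_policy = s0_policy,
                      qvalue_policy = qvalue_policy, cost = cost)
    ck <- tuning$best_cutoff
  }
  red <- reduce_all(sel, ds, c_cutoff = ck)
  structure(
    list(selection = sel, tuning = tuning, reduction = red,
         features = red$features,
         params = list(B = sel$params$B, q_cutoff = q_cutoff, ck = ck,
                       seed = seed, s0_policy = s0_policy,
                       qvalue_policy = qvalue_policy)),
    class = "samgsr_fit"
  )
}

#' @export
print.samgsr_fit <- function(x, ...) {
  cat(sprintf(
    "<samgsr_fit> %d gene(s) selected -> %d (gene, time) feature(s) at c_cutoff = %g%s\n",
    length(x$selection$selected), nrow(x$features), x$params$ck,
    if (is.null(x$tuning)) " (fixed)" else " (tuned by CV)"))
  invisible(x)
}

#' @rdname samgsr
#' @param x a `samgsr_fit`.
#' @param ... unused.
#' @export
tidy.samgsr_fit <- function(x, ...) x$features

#' @rdname samgsr
#' @export
glance.samgsr_fit <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$selection$table),
    n_selected = length(x$selection$selected),
    n_features = nrow(x$features),
    union_genes = length(unique(x$features$gene_id)),
    ck = x$params$ck,
    tuned = !is.null(x$tuning),
    B = x$params$B,
    q_cutoff = x$params$q_cutoff
  )
}
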