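#' Reduce one selected gene's trajectory to its core time points
#'
#' Step 2 of the algorithm: time points are ranked by decreasing `|d_t|`
#' (ties broken toward the smaller time index; unavailable time points are
#' placed last and can never enter the core). For k = 1..T'-1 (T' = number of
#' available time points), `c_k` is the permutation p-value of the residual
#' subset's statistic, the sum of `d_t^2` over time points *not* among the top
#' k, computed against the same stored permutations (and their stored fudge
#' constants) used at selection. The core size `k_star` is the smallest k with
#' `c_k > c_cutoff`; if no such k exists the whole available trajectory is
#' kept.
#'
#' @param gene gene id or index; must be in `sel$selected`.
#' @param sel a `samgsr_selection` from [select_genes()].
#' @param ds the dataset the selection was computed on.
#' @param c_cutoff residual p-value cutoff in (0, 1).
#' @param null_d optional precomputed per-permutation d values for this gene
#'   (T x B matrix); computed on the fly when `NULL`.
#' @return an object of class `reduced_gene`: fields `gene_id`, `ordering`
#'   (time indices by decreasing `|d|`), `c` (residual p-values), `k_star`,
#'   `core_timepoints`, `d_row`.
#' @export
reduce_gene <- function(gene, sel, ds, c_cutoff = 0.05, null_d = NULL) {
  stopifnot(inherits(sel, "samgsr_selection"))
  ds <- as_longitudinal_eset(ds)
  gi <- if (is.character(gene)) match(gene, ds$gene_ids) else as.integer(gene)
  if (is.na(gi) || gi < 1L || gi > length(ds$gene_ids)) {
    abort_validation("unknown gene.")
  }
  if (!(gi %in% sel$selected)) {
    abort_validation(sprintf("gene '%s' is not in the selected set.", ds$gene_ids[gi]))
  }
  if (c_cutoff <= 0 || c_cutoff >= 1) abort_config("`c_cutoff` must be in (0, 1).")
  if (is.null(null_d)) {
    null_d <- null_d_array(ds, gi, sel)[1, , , drop = FALSE]
    dim(null_d) <- dim(null_d)[2:3]
  }
  reduce_gene_core(gi, sel, ds, c_cutoff, null_d)
}

# null_d: T x B matrix of permutation d values for this gene.
reduce_gene_core <- function(gi, sel, ds, c_cutoff, null_d) {
  d_row <- unname(sel$sam$d[gi, ])
  T <- length(d_row)
  avail <- which(!is.na(d_row))
  # order: available by decreasing |d| (ties -> smaller time index), then
  # unavailable time points last
  ord_avail <- avail[order(-abs(d_row[avail]), avail)]
  ordering <- c(ord_avail, setdiff(seq_len(T), avail))
  T_eff <- length(ord_avail)
  c_k <- numeric(0)
  k_star <- T_eff
  if (T_eff > 1L) {
    c_k <- rep(NA_real_, T_eff - 1L)
    for (k in seq_len(T_eff - 1L)) {
      resid <- ord_avail[(k + 1L):T_eff]
      obs <- sum(d_row[resid]^2)
      nd <- null_d[resid, , drop = FALSE]
      null_stat <- colSums(nd^2, na.rm = TRUE)
      c_k[k] <- permutation_pvalue(obs, null_stat, exhaustive = sel$exhaustive)
      if (c_k[k] > c_cutoff) {
        k_star <- k
        break
      }
    }
    c_k <- c_k[!is.na(c_k)]
  }
  structure(
    list(gene_id = ds$gene_ids[gi], gene_index = gi,
         ordering = ordering, c = c_k, k_star = k_star,
         core_timepoints = sort(ord_avail[seq_len(k_star)]),
         d_row = d_row),
    class = "reduced_gene"
  )
}

#' @export
print.reduced_gene <- function(x, ...) {
  cat(sprintf("<reduced_gene> %s: core time points {%s} (k* = %d of %d available)\n",
              x$gene_id, paste(x$core_timepoints, collapse = ", "),
              x$k_star, sum(!is.na(x$d_row))))
  invisible(x)
}

# Per-permutation d values for a gene subset, using the stored permutations
# and the stored full-panel fudge constants (s0 must not be re-estimated on
# the subset).
null_d_array <- function(ds, genes, sel) {
  sub_expr <- ds$expr[genes, , , drop = FALSE]
  sub_mask <- ds$mask[genes, , , drop = FALSE]
  eng <- sam_engine(sub_expr, sub_mask, sel$permutations,
                    s0_override = sel$null_s0, keep_d = TRUE)
  T <- dim(ds$expr)[3]
  B <- ncol(sel$permutations)
  out <- array(NA_real_, c(length(genes), T, B))
  for (t in seq_len(T)) out[, t, ] <- eng$d[[t]]
  out
}

#' Reduce every selected gene and emit the feature table
#'
#' Applies [reduce_gene()] to each gene in the selected set and assembles the
#' final feature table of (gene, time point) pairs: a gene is "selected at
#' time t" exactly when t lies in its core subset.
#'
#' @inheritParams reduce_gene
#' @return an object of class `samgsr_reduction`: `reduced` (list of
#'   `reduced_gene`), `features` (tibble with columns `gene_id`,
#'   `time_index`, `d_value`, `rank_within_gene`), `c_cutoff`. `tidy()`
#'   returns the feature table.
#' @export
reduce_all <- function(sel, ds, c_cutoff = 0.05) {
  stopifnot(inherits(sel, "samgsr_selection"))
  ds <- as_longitudinal_eset(ds)
  empty <- tibble::tibble(gene_id = character(), time_index = integer(),
                          d_value = double(), rank_within_gene = integer())
  if (length(sel$selected) == 0L) {
    rlang::warn("no genes selected; feature table is empty.",
                class = "longsamgsr_empty_selection")
    return(structure(list(reduced = list(), features = empty, c_cutoff = c_cutoff),
                     class = "samgsr_reduction"))
  }
  nd <- null_d_array(ds, sel$selected, sel)
  reduced <- lapply(seq_along(sel$selected), function(i) {
    ndi <- nd[i, , , drop = FALSE]
    dim(ndi) <- dim(nd)[2:3]
    reduce_gene_core(sel$selected[i], sel, ds, c_cutoff, ndi)
  })
  features <- purrr::map_dfr(reduced, function(r) {
    core <- r$core_timepoints
    tibble::tibble(
      gene_id = r$gene_id,
      time_index = as.integer(core),
      d_value = r$d_row[core],
      rank_within_gene = match(core, r$ordering)
    )
  })
  structure(list(reduced = reduced, features = features, c_cutoff = c_cutoff),
            class = "samgsr_reduction")
}

#' @export
print.samgsr_reduction <- function(x, ...) {
  cat(sprintf("<samgsr_reduction> %d genes -> %d (gene, time) features at c_cutoff = %g\n",
              length(x$reduced), nrow(x$features), x$c_cutoff))
  invisible(x)
}

#' @rdname reduce_all
#' @param x a `samgsr_reduction`.
#' @param ... unused.
#' @export
tidy.samgsr_reduction <- function(x, ...) x$features

#' Per-time-point gene lists from a feature table
#'
#' @param features feature table (tibble with `gene_id`, `time_index`).
#' @param n_time total number of time points.
#' @return list of length `n_time`, each a character vector of gene ids.
#' @export
features_by_time <- function(features, n_time) {
  lapply(seq_len(n_time), function(t) {
    unique(features$gene_id[features$time_index == t])
  })
}

#' Tune the reduction cutoff by stratified cross-validation
#'
#' Evaluates every candidate cutoff on the default grid 0.05, 0.10, ..., 0.50
#' by 5-fold cross-validation at the subject level, stratified by phenotype.
#' Within each training fold the screening step is re-run from scratch (so
#' selection bias cannot leak into the CV error), the fold's selected genes
#' are reduced at the candidate cutoff, per-time-point linear SVMs are fit on
#' the fold's training subjects, and the held-out subjects' averaged posterior
#' probabilities give the fold misclassification error. A fold whose training
#' feature table is empty contributes the uninformative error 0.5. The best
#' cutoff is the argmin of the mean CV error, ties broken toward the smallest
#' cutoff (fewer features).
#'
#' @param ds a labeled [longitudinal_eset()].
#' @param grid candidate cutoffs (default `seq(0.05, 0.5, by = 0.05)`).
#' @param folds number of CV folds (default 5).
#' @param seed integer seed controlling fold assignment and fold-level
#'   permutation draws.
#' @param B,q_cutoff,s0_policy,qvalue_policy passed to [select_genes()] inside
#'   each fold.
#' @param cost linear-SVM regularization constant.
#' @return an object of class `samgsr_tuning`: `cv` (tibble cutoff/cv_error),
#'   `best_cutoff`, `fold_assignments`, `seed`.
#' @export
tune_ck <- function(ds, grid = seq(0.05, 0.5, by = 0.05), folds = 5L,
                    seed = 1L, B = 1000L, q_cutoff = 0.05,
                    s0_policy = c("median", "percentile"),
                    qvalue_policy = c("bh", "storey"), cost = 1) {
  s0_policy <- match.arg(s0_policy)
  qvalue_policy <- match.arg(qvalue_policy)
  ds <- as_longitudinal_eset(ds)
  validate_eset(ds)
  if (is.null(ds$labels)) abort_validation("`ds` must be labeled.")
  if (folds < 2L) abort_config("`folds` must be >= 2.")
  if (any(grid <= 0 | grid >= 1)) abort_config("grid cutoffs must be in (0, 1).")
  if (min(table(ds$labels)) < folds) {
    abort_validation("each class needs at least `folds` subjects.")
  }
  n <- length(ds$subject_ids)
  fold_of <- integer(n)
  with_seed(seed, {
    for (cl in c(0L, 1L)) {
      idx <- which(ds$labels == cl)
      fold_of[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  err <- matrix(NA_real_, nrow = folds, ncol = length(grid))
  for (f in seq_len(folds)) {
    test_idx <- which(fold_of == f)
    train <- subset_eset(ds, subjects = setdiff(seq_len(n), test_idx))
    test <- subset_eset(ds, subjects = test_idx)
    sel_f <- suppressMessages(
      select_genes(train, B = B, q_cutoff = q_cutoff, seed = seed + f,
                   s0_policy = s0_policy, qvalue_policy = qvalue_policy)
    )
    for (j in seq_along(grid)) {
      red <- withCallingHandlers(
        reduce_all(sel_f, train, c_cutoff = grid[j]),
        longsamgsr_empty_selection = function(w) invokeRestart("muffleWarning")
      )
      if (nrow(red$features) == 0L) {
        err[f, j] <- 0.5
        rlang::inform(sprintf("fold %d, cutoff %g: empty feature table, error set to 0.5.",
                              f, grid[j]))
        next
      }
      clf <- fit_timepoint_classifiers(train, red$features, cost = cost)
      post <- average_posteriors(predict_posteriors(clf, test))
      err[f, j] <- misclassification_error(post, test$labels[names(post)])
    }
  }
  cv_error <- colMeans(err)
  best <- grid[which.min(cv_error)]  # which.min returns the first (smallest) argmin
  structure(
    list(cv = tibble::tibble(cutoff = grid, cv_error = cv_error),
         best_cutoff = best,
         fold_assignments = stats::setNames(fold_of, ds$subject_ids),
         fold_errors = err, seed = seed,
         params = list(B = B, q_cutoff = q_cutoff, folds = folds, cost = cost)),
    class = "samgsr_tuning"
  )
}

#' @export
print.samgsr_tuning <- function(x, ...) {
  cat(sprintf("<samgsr_tuning> best cutoff %g (CV error %.3f) over %d candidates\n",
              x$best_cutoff, min(x$cv$cv_error), nrow(x$cv)))
  invisible(x)
}

#' @rdname tune_ck
#' @param x a `samgsr_tuning`.
#' @param ... unused.
#' @export
tidy.samgsr_tuning <- function(x, ...) x$cv

#' @rdname tune_ck
#' @export
glance.samgsr_tuning <- function(x, ...) {
  tibble::tibble(best_cutoff = x$best_cutoff,
                 best_cv_error = min(x$cv$cv_error),
                 folds = x$params$folds, B = x$params$B)
}
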