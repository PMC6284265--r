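#' Pooled standard deviation of two sample vectors
#'
#' The two-class pooled standard deviation that forms the denominator of the
#' SAM statistic: `s = sqrt(a * (SS_d + SS_c))` with
#' `a = (1/n_d + 1/n_c) / (n_d + n_c - 2)`, where `SS` are within-class sums of
#' squared deviations from the class mean.
#'
#' @param values_d,values_c numeric vectors for the diseased and control
#'   classes; `NA`s are dropped (available-case analysis).
#' @return a non-negative scalar.
#' @export
pooled_sd <- function(values_d, values_c) {
  values_d <- values_d[!is.na(values_d)]
  values_c <- values_c[!is.na(values_c)]
  nd <- length(values_d); nc <- length(values_c)
  if (nd < 2L || nc < 2L) {
    abort_insufficient(sprintf(
      "pooled SD needs >= 2 values per class (got %d and %d).", nd, nc))
  }
  a <- (1 / nd + 1 / nc) / (nd + nc - 2)
  ss <- sum((values_d - mean(values_d))^2) + sum((values_c - mean(values_c))^2)
  sqrt(a * ss)
}

#' Per-time-point fudge constant for the SAM denominator
#'
#' The small positive constant `s0` added to the pooled SD stabilizes SAM
#' statistics of near-zero-variance genes. Two policies are offered:
#' `"median"` (default) takes the median of the per-gene pooled SDs at the
#' time point, which is parameter-free and scale-equivariant; `"percentile"`
#' runs the classical percentile search, picking the SD-quantile that
#' minimizes the coefficient of variation of the spread of the resulting SAM
#' statistics across SD bins.
#'
#' @param s_column numeric vector of G pooled SDs at one time point (`NA` =
#'   unavailable cell).
#' @param d_numerators mean differences for the same genes; required by the
#'   percentile policy only.
#' @param policy `"median"` or `"percentile"`.
#' @return a strictly positive scalar (floored at machine-epsilon scale when
#'   all SDs are zero).
#' @export
fudge_factor <- function(s_column, d_numerators = NULL,
                         policy = c("median", "percentile")) {
  policy <- match.arg(policy)
  s <- s_column[!is.na(s_column)]
  if (length(s) == 0L) abort_validation("no available pooled SDs.")
  s0 <- if (policy == "median" || length(s) < 10L) {
    stats::median(s)
  } else {
    if (is.null(d_numerators)) {
      abort_config("percentile policy needs `d_numerators`.")
    }
    num <- d_numerators[!is.na(s_column)]
    s0_percentile(s, num)
  }
  max(s0, sqrt(.Machine$double.eps))
}

# Percentile search: candidate s0 = alpha-quantiles of s; choose the candidate
# minimizing the coefficient of variation of mad(d) across deciles of s.
s0_percentile <- function(s, num) {
  alphas <- seq(0, 1, by = 0.05)
  cands <- stats::quantile(s, alphas, names = FALSE, type = 7)
  bins <- cut(rank(s, ties.method = "first"), breaks = 10, labels = FALSE)
  cv <- vapply(cands, function(s0) {
    d <- num / (s + s0)
    v <- tapply(d, bins, stats::mad)
    m <- mean(v)
    if (!is.finite(m) || m == 0) Inf else stats::sd(v) / m
  }, numeric(1))
  cands[which.min(cv)]
}

#' SAM statistic for one gene at one time point
#'
#' `d = (mean(values_d) - mean(values_c)) / (pooled_sd + s0)`, the moderated
#' two-sample statistic with the diseased class in the numerator's positive
#' direction.
#'
#' @inheritParams pooled_sd
#' @param s0 positive fudge constant for this time point.
#' @return a scalar.
#' @export
sam_statistic <- function(values_d, values_c, s0) {
  s <- pooled_sd(values_d, values_c)
  (mean(values_d, na.rm = TRUE) - mean(values_c, na.rm = TRUE)) / (s + s0)
}

# Vectorized engine: per-gene, per-time SAM quantities for one or many
# class-membership columns at once.
#
# expr/mask: G x n x T arrays; Z: n x B matrix with Z[i,b] = 1 if subject i is
# in the diseased class under labeling b. Returns, per time point, G x B
# matrices (as a list) or accumulated sums of squares. `s0_override` (T x B)
# skips s0 estimation -- used when recomputing d for a gene subset, where s0
# must stay the full-panel estimate.
sam_engine <- function(expr, mask, Z, s0_policy = "median",
                       s0_override = NULL, keep_d = TRUE) {
  dm <- dim(expr)
  G <- dm[1]; n <- dm[2]; T <- dm[3]
  Z <- as.matrix(Z)
  B <- ncol(Z)
  Zc <- 1 - Z
  samgs <- matrix(0, G, B)
  n_avail <- matrix(0L, G, B)
  s0 <- matrix(NA_real_, T, B)
  d_list <- if (keep_d) vector("list", T) else NULL
  s_list <- if (keep_d) vector("list", T) else NULL
  md_list <- if (keep_d) vector("list", T) else NULL
  mc_list <- if (keep_d) vector("list", T) else NULL
  for (t in seq_len(T)) {
    X <- expr[, , t, drop = FALSE]; dim(X) <- c(G, n)
    M <- mask[, , t, drop = FALSE]; dim(M) <- c(G, n)
    Mnum <- M * 1
    X0 <- X; X0[!M] <- 0
    XM2 <- X0 * X0
    nd <- Mnum %*% Z; nc <- Mnum %*% Zc
    sum_d <- X0 %*% Z; sum_c <- X0 %*% Zc
    sq_d <- XM2 %*% Z; sq_c <- XM2 %*% Zc
    ok <- nd >= 2 & nc >= 2
    mean_d <- sum_d / nd; mean_c <- sum_c / nc
    ss <- (sq_d - nd * mean_d^2) + (sq_c - nc * mean_c^2)
    ss[ss < 0] <- 0  # guard tiny negative values from cancellation
    a <- (1 / nd + 1 / nc) / (nd + nc - 2)
    s <- sqrt(a * ss)
    s[!ok] <- NA_real_
    num <- mean_d - mean_c
    if (is.null(s0_override)) {
      if (identical(s0_policy, "median")) {
        s0_t <- apply(s, 2, stats::median, na.rm = TRUE)
      } else {
        s0_t <- vapply(seq_len(B), function(b) {
          keep <- !is.na(s[, b])
          s0_percentile(s[keep, b], num[keep, b])
        }, numeric(1))
      }
      s0_t <- pmax(s0_t, sqrt(.Machine$double.eps))
    } else {
      s0_t <- s0_override[t, ]
    }
    s0[t, ] <- s0_t
    d <- num / (s + rep(s0_t, each = G))
    d[!ok] <- NA_real_
    d2 <- d * d
    d2[!ok] <- 0  # unavailable cells contribute 0 to SAMGS sums
    samgs <- samgs + d2
    n_avail <- n_avail + (ok * 1L)
    if (keep_d) {
      d_list[[t]] <- d; s_list[[t]] <- s
      md <- mean_d; md[nd < 1] <- NA_real_
      mc <- mean_c; mc[nc < 1] <- NA_real_
      md_list[[t]] <- md; mc_list[[t]] <- mc
    }
  }
  list(samgs = samgs, n_avail = n_avail, s0 = s0,
       d = d_list, s = s_list, mean_d = md_list, mean_c = mc_list)
}

#' Per-gene, per-time-point SAM statistic matrix
#'
#' Computes the G x T matrix of SAM statistics `d[g, t]` for a labeled
#' longitudinal dataset, with the pooled SD and fudge constant estimated
#' separately at every time point (measurement variability may differ over
#' time). Computation is available-case per (gene, time) cell: a cell with
#' fewer than two measured subjects in either class is flagged unavailable
#' (`NA`), contributes zero to downstream sums, and is counted in a warning.
#'
#' @param ds a labeled [longitudinal_eset()].
#' @param labels subject-level 0/1 vector; defaults to `ds$labels`. Passing
#'   permuted labels here is what drives the permutation test.
#' @param s0_policy fudge-constant policy, see [fudge_factor()].
#' @param quiet suppress the unavailable-cell warning.
#' @return an object of class `sam_matrix` with matrices `d`, `s`, `mean_d`,
#'   `mean_c` (G x T) and the length-T vector `s0`.
#' @export
sam_matrix <- function(ds, labels = ds$labels,
                       s0_policy = c("median", "percentile"), quiet = FALSE) {
  s0_policy <- match.arg(s0_policy)
  stopifnot(inherits(ds, "longitudinal_eset"))
  if (is.null(labels)) abort_validation("dataset is unlabeled and no `labels` given.")
  if (length(labels) != length(ds$subject_ids)) {
    abort_validation("`labels` must have one entry per subject.")
  }
  if (length(unique(labels)) < 2L) abort_validation("both classes must be present.")
  Z <- matrix(as.numeric(labels == 1L), ncol = 1)
  eng <- sam_engine(ds$expr, ds$mask, Z, s0_policy = s0_policy, keep_d = TRUE)
  T <- length(ds$time_ids)
  to_mat <- function(lst) {
    m <- do.call(cbind, lapply(lst, function(x) x[, 1]))
    dimnames(m) <- list(ds$gene_ids, ds$time_ids)
    m
  }
  d <- to_mat(eng$d)
  n_bad <- sum(is.na(d))
  if (n_bad > 0L && !quiet) {
    rlang::warn(sprintf(
      "%d (gene, time) cell(s) have < 2 samples in a class and are excluded.",
      n_bad), class = "longsamgsr_unavailable_cells")
  }
  structure(
    list(d = d, s = to_mat(eng$s), s0 = stats::setNames(eng$s0[, 1], ds$time_ids),
         mean_d = to_mat(eng$mean_d), mean_c = to_mat(eng$mean_c),
         s0_policy = s0_policy),
    class = "sam_matrix"
  )
}

#' @export
print.sam_matrix <- function(x, ...) {
  cat(sprintf("<sam_matrix> %d genes x %d time points (s0 policy: %s)\n",
              nrow(x$d), ncol(x$d), x$s0_policy))
  cat("  s0:", paste(signif(x$s0, 4), collapse = " "), "\n")
  invisible(x)
}

#' @rdname sam_matrix
#' @param x a `sam_matrix`.
#' @param ... unused.
#' @export
tidy.sam_matrix <- function(x, ...) {
  tibble::tibble(
    gene_id = rep(rownames(x$d), times = ncol(x$d)),
    time_index = rep(seq_len(ncol(x$d)), each = nrow(x$d)),
    d = as.vector(x$d),
    s = as.vector(x$s),
    mean_d = as.vector(x$mean_d),
    mean_c = as.vector(x$mean_c)
  )
}
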