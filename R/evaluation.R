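#' Fit per-time-point linear SVM classifiers with posterior calibration
#'
#' For every time point with a nonempty gene list, fits a linear support
#' vector machine on that time point's expression restricted to the selected
#' genes, then calibrates posterior probabilities of the diseased class by a
#' sigmoid fit (logistic regression of the training labels on the SVM decision
#' values). Time points with empty gene lists are marked uninformative and
#' later contribute a constant posterior 0.5.
#'
#' @param train a labeled [longitudinal_eset()].
#' @param features feature table (tibble `gene_id`, `time_index`) or a list of
#'   per-time gene-id vectors.
#' @param cost SVM regularization constant (default 1).
#' @return an object of class `timepoint_classifiers` with one slot per time
#'   point (`NULL` = uninformative).
#' @export
fit_timepoint_classifiers <- function(train, features, cost = 1) {
  train <- as_longitudinal_eset(train)
  if (is.null(train$labels)) abort_validation("`train` must be labeled.")
  T <- length(train$time_ids)
  gene_lists <- if (is.data.frame(features)) features_by_time(features, T) else features
  if (length(gene_lists) != T) abort_validation("one gene list per time point required.")
  models <- vector("list", T)
  for (t in seq_len(T)) {
    genes <- gene_lists[[t]]
    if (length(genes) == 0L) next
    gi <- resolve_idx(genes, train$gene_ids, "gene")
    ok_subj <- which(apply(train$mask[gi, , t, drop = FALSE], 2, all))
    y <- train$labels[ok_subj]
    if (length(unique(y)) < 2L || min(table(y)) < 2L) {
      abort_insufficient(sprintf(
        "time point %d: need >= 2 training subjects per class.", t))
    }
    x <- t(matrix(train$expr[gi, ok_subj, t], nrow = length(gi)))
    colnames(x) <- train$gene_ids[gi]
    fit <- e1071::svm(x, factor(y, levels = c(0, 1)), kernel = "linear",
                      cost = cost, scale = FALSE)
    dv <- as.numeric(attr(stats::predict(fit, x, decision.values = TRUE),
                          "decision.values"))
    platt <- suppressWarnings(
      stats::glm(y ~ dv, family = stats::binomial(), data = data.frame(y = y, dv = dv))
    )
    models[[t]] <- list(svm = fit, platt = platt, genes = train$gene_ids[gi])
  }
  structure(list(models = models, n_time = T, cost = cost),
            class = "timepoint_classifiers")
}

#' Posterior probability matrix for a dataset
#'
#' Scores every subject at every time point with the fitted per-time-point
#' classifiers. Subjects missing the required measurements at a time point get
#' `NA` there; uninformative time points (no selected genes) contribute 0.5
#' for every subject.
#'
#' @param clf a `timepoint_classifiers` object.
#' @param ds dataset to score.
#' @return subjects x T matrix of diseased-class posterior probabilities.
#' @export
predict_posteriors <- function(clf, ds) {
  stopifnot(inherits(clf, "timepoint_classifiers"))
  ds <- as_longitudinal_eset(ds)
  n <- length(ds$subject_ids)
  out <- matrix(NA_real_, n, clf$n_time,
                dimnames = list(ds$subject_ids, ds$time_ids))
  for (t in seq_len(clf$n_time)) {
    m <- clf$models[[t]]
    if (is.null(m)) {
      out[, t] <- 0.5
      next
    }
    gi <- match(m$genes, ds$gene_ids)
    if (anyNA(gi)) abort_validation("dataset lacks genes used by the classifier.")
    ok_subj <- which(apply(ds$mask[gi, , t, drop = FALSE], 2, all))
    if (length(ok_subj) == 0L) next
    x <- t(matrix(ds$expr[gi, ok_subj, t], nrow = length(gi)))
    colnames(x) <- m$genes
    dv <- as.numeric(attr(stats::predict(m$svm, x, decision.values = TRUE),
                          "decision.values"))
    out[ok_subj, t] <- stats::predict(m$platt, newdata = data.frame(dv = dv),
                                      type = "response")
  }
  out
}

#' Average posterior probabilities over time
#'
#' Arithmetic mean of each subject's available per-time posteriors; subjects
#' with no available posterior are dropped with a warning.
#'
#' @param probs subjects x T numeric matrix (`NA` = unavailable).
#' @return named per-subject vector of averaged posteriors.
#' @export
average_posteriors <- function(probs) {
  n_avail <- rowSums(!is.na(probs))
  if (any(n_avail == 0L)) {
    rlang::warn(sprintf("%d subject(s) have no available posterior; dropped.",
                        sum(n_avail == 0L)))
    probs <- probs[n_avail > 0L, , drop = FALSE]
  }
  rowMeans(probs, na.rm = TRUE)
}

#' Generalized Brier score
#'
#' Mean squared difference between the posterior probability of the diseased
#' class and the 0/1 label. Ranges over \[0, 1\]; 0 is optimal.
#'
#' @param posterior per-subject probabilities of the diseased class.
#' @param labels 0/1 labels aligned with `posterior`.
#' @return a scalar in \[0, 1\].
#' @export
gbs <- function(posterior, labels) {
  check_metric_input(posterior, labels)
  mean((posterior - labels)^2)
}

#' Belief confusion metric
#'
#' Mean posterior probability assigned to each subject's true class,
#' `label * p + (1 - label) * (1 - p)`. Ranges over \[0, 1\]; 1 is optimal.
#'
#' @inheritParams gbs
#' @return a scalar in \[0, 1\].
#' @export
bcm <- function(posterior, labels) {
  check_metric_input(posterior, labels)
  mean(labels * posterior + (1 - labels) * (1 - posterior))
}

#' Area under the precision-recall curve
#'
#' Step-wise (non-interpolated) summation over score thresholds with the
#' diseased class as positive: `sum over thresholds of
#' (recall_i - recall_(i-1)) * precision_i`, tied scores handled as one
#' threshold. Invariant to strictly monotone transforms of the scores.
#'
#' @inheritParams gbs
#' @return a scalar in \[0, 1\].
#' @export
aupr <- function(posterior, labels) {
  check_metric_input(posterior, labels)
  P <- sum(labels == 1)
  if (P == 0L) abort_validation("no positive subjects; AUPR undefined.")
  ord <- order(posterior, decreasing = TRUE)
  y <- labels[ord]
  scores <- posterior[ord]
  last <- c(scores[-1] != scores[-length(scores)], TRUE)  # end of each tie group
  tp <- cumsum(y)[last]
  np <- seq_along(y)[last]
  precision <- tp / np
  recall <- tp / P
  sum(diff(c(0, recall)) * precision)
}

#' Misclassification error at a probability threshold
#'
#' Fraction of subjects whose thresholded posterior (`posterior >= threshold`
#' predicts diseased) disagrees with the label.
#'
#' @inheritParams gbs
#' @param threshold decision threshold (default 0.5).
#' @return a scalar in \[0, 1\].
#' @export
misclassification_error <- function(posterior, labels, threshold = 0.5) {
  check_metric_input(posterior, labels)
  mean((posterior >= threshold) != (labels == 1))
}

check_metric_input <- function(posterior, labels) {
  if (length(posterior) != length(labels)) {
    abort_validation("`posterior` and `labels` must have the same length.")
  }
  if (!all(labels %in% c(0, 1))) abort_validation("labels must be 0 or 1.")
  if (any(!is.finite(posterior)) || any(posterior < 0 | posterior > 1)) {
    abort_validation("posteriors must lie in [0, 1].")
  }
  invisible(TRUE)
}

#' Train/test performance report for a feature table
#'
#' Fits the per-time-point classifiers on the training set, scores the test
#' set, averages the posteriors over time, and computes the four performance
#' statistics: misclassification error and generalized Brier score (0 optimal),
#' belief confusion metric and area under the precision-recall curve
#' (1 optimal).
#'
#' @param train,test labeled [longitudinal_eset()] objects sharing gene ids.
#' @param features feature table (`gene_id`, `time_index`).
#' @param cost SVM regularization constant.
#' @return an object of class `performance_report`: `metrics` (one-row
#'   tibble: error, gbs, bcm, aupr), `posteriors` (per-subject tibble), and
#'   directionality metadata. `glance()` returns the metrics row; `tidy()` a
#'   long metric table with an `optimum` column.
#' @export
evaluate_features <- function(train, test, features, cost = 1) {
  train <- as_longitudinal_eset(train)
  test <- as_longitudinal_eset(test)
  if (is.null(test$labels)) abort_validation("`test` must be labeled.")
  clf <- fit_timepoint_classifiers(train, features, cost = cost)
  probs <- predict_posteriors(clf, test)
  post <- average_posteriors(probs)
  y <- test$labels[names(post)]
  structure(
    list(
      metrics = tibble::tibble(
        error = misclassification_error(post, y),
        gbs = gbs(post, y),
        bcm = bcm(post, y),
        aupr = aupr(post, y)
      ),
      optimum = c(error = 0, gbs = 0, bcm = 1, aupr = 1),
      posteriors = tibble::tibble(subject_id = names(post),
                                  phenotype = as.integer(y),
                                  posterior = unname(post)),
      classifiers = clf
    ),
    class = "performance_report"
  )
}

#' @export
print.performance_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<performance_report> error %.3f | GBS %.3f | BCM %.3f | AUPR %.3f\n",
              m$error, m$gbs, m$bcm, m$aupr))
  invisible(x)
}

#' @rdname evaluate_features
#' @param x a `performance_report`.
#' @param ... unused.
#' @export
glance.performance_report <- function(x, ...) x$metrics

#' @rdname evaluate_features
#' @export
tidy.performance_report <- function(x, ...) {
  tibble::tibble(
    metric = names(x$metrics),
    value = as.numeric(x$metrics[1, ]),
    optimum = unname(x$optimum[names(x$metrics)])
  )
}
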