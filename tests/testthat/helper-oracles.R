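# Independent scalar-loop oracles, deliberately written with none of the
# package's vectorized machinery: plain double loops and textbook formulas.

oracle_pooled_sd <- function(xd, xc) {
  xd <- xd[!is.na(xd)]; xc <- xc[!is.na(xc)]
  nd <- length(xd); nc <- length(xc)
  a <- (1 / nd + 1 / nc) / (nd + nc - 2)
  sqrt(a * (sum((xd - mean(xd))^2) + sum((xc - mean(xc))^2)))
}

# full G x T SAM matrix by per-cell loops; s0 = median of the pooled-SD column
oracle_sam_matrix <- function(expr, mask, labels) {
  G <- dim(expr)[1]; T <- dim(expr)[3]
  d <- s <- matrix(NA_real_, G, T)
  num <- matrix(NA_real_, G, T)
  for (t in seq_len(T)) {
    for (g in seq_len(G)) {
      xd <- expr[g, labels == 1L, t][mask[g, labels == 1L, t]]
      xc <- expr[g, labels == 0L, t][mask[g, labels == 0L, t]]
      if (length(xd) < 2 || length(xc) < 2) next
      s[g, t] <- oracle_pooled_sd(xd, xc)
      num[g, t] <- mean(xd) - mean(xc)
    }
    s0 <- max(median(s[, t], na.rm = TRUE), sqrt(.Machine$double.eps))
    for (g in seq_len(G)) {
      if (!is.na(s[g, t])) d[g, t] <- num[g, t] / (s[g, t] + s0)
    }
  }
  list(d = d, s = s)
}

oracle_samgs <- function(d_row) sum(d_row^2, na.rm = TRUE)

# exhaustive permutation p-values for every gene by enumerating all
# class-size-preserving relabelings
oracle_exhaustive_pvalues <- function(expr, mask, labels) {
  n <- length(labels)
  combos <- utils::combn(n, sum(labels == 1L))
  stats <- sapply(seq_len(ncol(combos)), function(j) {
    lab <- rep(0L, n); lab[combos[, j]] <- 1L
    d <- oracle_sam_matrix(expr, mask, lab)$d
    apply(d, 1, oracle_samgs)
  })  # G x n_combos
  obs <- apply(oracle_sam_matrix(expr, mask, labels)$d, 1, oracle_samgs)
  rowMeans(stats >= obs)
}
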