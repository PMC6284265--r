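# shared fixture: one gene shifted only at time 3, screened in
make_single_time_fixture <- function(shift = 5, seed = 51) {
  ds <- make_eset(G = 50, n1 = 10, n0 = 10, T = 5, seed = seed)
  ds <- add_mean_shift(ds, 1, 3, shift)
  sel <- select_genes(ds, B = 3000, q_cutoff = 0.05, seed = seed)
  list(ds = ds, sel = sel)
}

test_that("a gene significant at a single time point reduces to that time", {
  fx <- make_single_time_fixture()
  expect_true(1 %in% fx$sel$selected)
  rg <- reduce_gene(1, fx$sel, fx$ds, c_cutoff = 0.05)
  expect_equal(rg$ordering[1], 3)
  expect_equal(rg$k_star, 1)
  expect_equal(rg$core_timepoints, 3)
  expect_gt(rg$c[1], 0.05)
})

test_that("a gene strong at every time point keeps its whole trajectory", {
  ds <- make_eset(G = 50, n1 = 10, n0 = 10, T = 4, seed = 53)
  for (t in 1:4) ds <- add_mean_shift(ds, 1, t, 5)
  sel <- select_genes(ds, B = 3000, seed = 53)
  rg <- reduce_gene(1, sel, ds, c_cutoff = 0.05)
  expect_equal(rg$k_star, 4)
  expect_equal(rg$core_timepoints, 1:4)
  expect_true(all(rg$c <= 0.05))
})

test_that("T = 2 reduction takes exactly one of two branches", {
  # branch 1: only time 1 carries signal -> residual {2} is null -> core {1}
  ds1 <- make_eset(G = 50, n1 = 10, n0 = 10, T = 2, seed = 103)
  ds1 <- add_mean_shift(ds1, 1, 1, 5)
  sel1 <- select_genes(ds1, B = 3000, seed = 103)
  rg1 <- reduce_gene(1, sel1, ds1, c_cutoff = 0.05)
  expect_equal(rg1$core_timepoints, 1)

  # branch 2: both time points carry signal -> core {1, 2}
  ds2 <- make_eset(G = 50, n1 = 10, n0 = 10, T = 2, seed = 57)
  ds2 <- add_mean_shift(ds2, 1, 1, 5)
  ds2 <- add_mean_shift(ds2, 1, 2, 5)
  sel2 <- select_genes(ds2, B = 3000, seed = 57)
  rg2 <- reduce_gene(1, sel2, ds2, c_cutoff = 0.05)
  expect_equal(rg2$core_timepoints, c(1, 2))
})

test_that("reduction respects ordering, size bounds and cutoff monotonicity", {
  ds <- make_eset(G = 60, n1 = 12, n0 = 12, T = 5, seed = 61)
  ds <- add_mean_shift(ds, 1, 2, 4)
  ds <- add_mean_shift(ds, 1, 4, 2.5)
  ds <- add_mean_shift(ds, 2, 5, 4)
  sel <- select_genes(ds, B = 4000, seed = 61)
  expect_gte(length(sel$selected), 1)
  grid <- seq(0.05, 0.5, by = 0.05)
  k_prev <- NULL
  for (ck in grid) {
    red <- reduce_all(sel, ds, c_cutoff = ck)
    for (rg in red$reduced) {
      dabs <- abs(rg$d_row)
      core <- rg$core_timepoints
      non_core <- setdiff(which(!is.na(rg$d_row)), core)
      # monotone-entry rule: the weakest core member beats the strongest
      # non-core member
      if (length(non_core) > 0) {
        expect_gte(min(dabs[core]), max(dabs[non_core]))
      }
      expect_lte(length(core), 5)
      expect_gte(rg$k_star, 1)
    }
    k_now <- vapply(red$reduced, `[[`, numeric(1), "k_star")
    if (!is.null(k_prev)) expect_true(all(k_now >= k_prev))
    k_prev <- k_now
  }
})

test_that("reduce_gene guards its preconditions", {
  fx <- make_single_time_fixture()
  not_selected <- setdiff(seq_len(50), fx$sel$selected)[1]
  expect_error(reduce_gene(not_selected, fx$sel, fx$ds),
               class = "longsamgsr_validation_error")
  expect_error(reduce_gene(1, fx$sel, fx$ds, c_cutoff = 0),
               class = "longsamgsr_config_error")
})

test_that("empty selections yield an empty feature table with a warning", {
  ds <- make_eset(G = 20, n1 = 5, n0 = 5, T = 3, seed = 63)
  sel <- select_genes(ds, B = 100, seed = 63)  # global null, nothing passes
  expect_length(sel$selected, 0)
  expect_warning(red <- reduce_all(sel, ds), class = "longsamgsr_empty_selection")
  expect_equal(nrow(red$features), 0)
})

test_that("a reduced gene emits one feature row per core time point", {
  fx <- make_single_time_fixture()
  red <- reduce_all(fx$sel, fx$ds, c_cutoff = 0.05)
  feats <- red$features
  g1 <- dplyr::filter(feats, gene_id == fx$ds$gene_ids[1])
  expect_equal(g1$time_index, 3L)
  expect_equal(g1$rank_within_gene, 1L)
  expect_equal(g1$d_value, fx$sel$sam$d[1, 3], ignore_attr = TRUE)
})

test_that("cross-validated tuning is deterministic and breaks ties downward", {
  ds <- make_eset(G = 30, n1 = 10, n0 = 10, T = 3, seed = 71)
  for (t in 1:3) ds <- add_mean_shift(ds, 1, t, 6)  # separable at any cutoff
  tn1 <- suppressMessages(
    tune_ck(ds, grid = c(0.05, 0.2, 0.4), folds = 5, seed = 71, B = 2000)
  )
  tn2 <- suppressMessages(
    tune_ck(ds, grid = c(0.05, 0.2, 0.4), folds = 5, seed = 71, B = 2000)
  )
  expect_identical(tn1$cv, tn2$cv)
  # a perfectly separating gene gives identical CV error everywhere:
  # the tie must break toward the smallest cutoff
  if (length(unique(tn1$cv$cv_error)) == 1L) {
    expect_equal(tn1$best_cutoff, 0.05)
  }
  expect_true(tn1$best_cutoff %in% c(0.05, 0.2, 0.4))
  expect_true(all(tn1$cv$cv_error >= 0 & tn1$cv$cv_error <= 1))

  tn_single <- suppressMessages(
    tune_ck(ds, grid = 0.3, folds = 5, seed = 71, B = 2000)
  )
  expect_equal(tn_single$best_cutoff, 0.3)
  expect_equal(nrow(tn_single$cv), 1)
})
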