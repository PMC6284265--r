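test_that("the base pool reproduces the requested temporal correlation", {
  lag1 <- function(ds) {
    x <- ds$expr
    a <- as.vector(x[, , -dim(x)[3]])
    b <- as.vector(x[, , -1])
    # correlate deviations from each gene's own mean
    mu <- apply(x, 1, mean)
    a <- a - rep(mu, times = length(a) / dim(x)[1])
    b <- b - rep(mu, times = length(b) / dim(x)[1])
    cor(a, b)
  }
  ds0 <- generate_base_expression(G = 500, n = 50, T = 5, rho = 0, seed = 2)
  expect_lt(abs(lag1(ds0)), 0.05)
  ds8 <- generate_base_expression(G = 500, n = 50, T = 5, rho = 0.8, seed = 2)
  expect_lt(abs(lag1(ds8) - 0.8), 0.05)
})

test_that("base generation is deterministic given the seed", {
  a <- generate_base_expression(G = 20, n = 10, T = 3, seed = 5)
  b <- generate_base_expression(G = 20, n = 10, T = 3, seed = 5)
  c <- generate_base_expression(G = 20, n = 10, T = 3, seed = 6)
  expect_identical(a$expr, b$expr)
  expect_false(identical(a$expr, c$expr))
})

test_that("correlation blocks induce inter-gene correlation", {
  ds <- generate_base_expression(G = 40, n = 60, T = 4, rho = 0.5, seed = 9,
                                 n_blocks = 2, block_size = 10, block_rho = 0.7)
  in_block <- cor(ds$expr[1, , 2], ds$expr[2, , 2])
  out_block <- cor(ds$expr[25, , 2], ds$expr[26, , 2])
  expect_gt(in_block, 0.3)
  expect_lt(abs(out_block), 0.5)
})

test_that("zero covariates give probability one half", {
  expr <- array(0, c(2, 10, 2))
  expr[2, , ] <- rnorm(20)
  base <- longitudinal_eset(expr)
  design <- simulation_design(
    tibble::tibble(gene_id = "gene1", time_index = 1L, beta = 3)
  )
  y <- simulate_outcome(base, design, seed = 4, scaling = "raw")
  expect_true(all(attr(y, "p") == 0.5))
})

test_that("outcome labels obey the logistic model in the large-sample limit", {
  base <- generate_base_expression(G = 3, n = 10000, T = 5, seed = 13)
  design <- simulation_design(tibble::tibble(
    gene_id = c(rep("gene1", 4), "gene2"),
    time_index = c(1L, 2L, 3L, 4L, 3L),
    beta = c(0.18, 0.57, 0.29, 0.41, 1.02)
  ))
  y <- simulate_outcome(base, design, seed = 13)
  p <- attr(y, "p")
  # law of large numbers: realized label mean tracks the mean probability
  expect_lt(abs(mean(y) - mean(p)), 0.02)
  # the logit is symmetric around zero on standardized covariates
  expect_lt(abs(mean(y) - 0.5), 0.03)
})

test_that("strongly signed coefficients drive labels toward the covariate sign", {
  base <- generate_base_expression(G = 2, n = 2000, T = 2, seed = 15)
  design <- simulation_design(
    tibble::tibble(gene_id = "gene1", time_index = 1L, beta = 50)
  )
  y <- simulate_outcome(base, design, seed = 15)
  x <- scale(base$expr[1, , 1])
  expect_gt(mean((y == 1) == (x > 0)), 0.95)
})

test_that("scenario builders produce the documented causal structure", {
  sc1 <- build_scenario1(seed = 3, n_noise = 98)
  expect_length(sc1$dataset$gene_ids, 100)
  expect_identical(dim(sc1$dataset$expr), c(100L, 43L, 5L))
  expect_equal(nrow(sc1$design$causal_terms), 5)
  expect_equal(sort(unique(sc1$design$causal_terms$gene_id)),
               c("causalA", "causalB"))
  expect_equal(sc1$design$causal_terms$beta,
               c(0.18, 0.57, 0.29, 0.41, 1.02))
  # causal genes are never part of the noise pool
  expect_equal(sum(sc1$dataset$gene_ids %in% c("causalA", "causalB")), 2)

  sc2 <- build_scenario2(seed = 3, n_noise = 98)
  expect_equal(sc2$design$causal_terms$time_index, c(1L, 5L))
  expect_equal(sc2$design$causal_terms$beta, c(0.56, -0.91))

  # fresh noise per replicate: different seeds give different base pools
  sc1b <- build_scenario1(seed = 4, n_noise = 98)
  expect_false(identical(sc1$dataset$expr, sc1b$dataset$expr))
})

test_that("a real base pool is subsampled with raw covariates", {
  pool <- generate_base_expression(G = 60, n = 43, T = 5, seed = 21)
  sc <- build_scenario1(seed = 21, n_noise = 20, base = pool,
                        causal_genes = c("gene3", "gene7"))
  expect_length(sc$dataset$gene_ids, 22)
  expect_true(all(c("gene3", "gene7") %in% sc$dataset$gene_ids))
  expect_error(build_scenario1(seed = 1, base = pool),
               class = "longsamgsr_config_error")
})

test_that("replicate studies aggregate selection frequencies deterministically", {
  cfg <- list(R = 1L, seed = 101, B = 300, ck = 0.05, n_noise = 28, n = 24)
  res <- suppressWarnings(
    run_replicates("joint", R = cfg$R, seed = cfg$seed, B = cfg$B,
                   ck = cfg$ck, n_noise = cfg$n_noise, n = cfg$n)
  )
  expect_s3_class(res, "samgsr_replicates")
  expect_true(all(res$freq$pct %in% c(0, 100)))
  expect_equal(res$R_effective, 1)
  res2 <- suppressWarnings(
    run_replicates("joint", R = cfg$R, seed = cfg$seed, B = cfg$B,
                   ck = cfg$ck, n_noise = cfg$n_noise, n = cfg$n)
  )
  expect_identical(res$freq, res2$freq)
  expect_true(all(res$n_per_time$avg_n_genes >= 0))
})

test_that("simulated datasets satisfy the container invariants", {
  for (seed in c(31, 32)) {
    sc <- build_scenario2(seed = seed, n_noise = 18, n = 30)
    expect_silent(validate_eset(sc$dataset))
    expect_true(all(table(sc$dataset$labels) >= 2))
  }
})
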