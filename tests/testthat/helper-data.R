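# Fixtures built in code: small labeled datasets with known structure.

# iid normal expression, n1 diseased + n0 control subjects.
make_eset <- function(G = 5, n1 = 3, n0 = 3, T = 2, seed = 1, sd = 1,
                      missing = NULL) {
  set.seed(seed)
  n <- n1 + n0
  expr <- array(rnorm(G * n * T, mean = 7, sd = sd), c(G, n, T))
  if (!is.null(missing)) expr[missing] <- NA_real_
  longitudinal_eset(expr, labels = rep(c(1L, 0L), c(n1, n0)))
}

# write a dataset to disk as the canonical TSV pair, return the two paths
write_fixture <- function(ds, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  parts <- disassemble(ds)
  expr_path <- file.path(dir, "expr.tsv")
  design_path <- file.path(dir, "design.tsv")
  readr::write_tsv(parts$expression, expr_path)
  readr::write_tsv(parts$design, design_path)
  list(expr = expr_path, design = design_path, dir = dir)
}
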