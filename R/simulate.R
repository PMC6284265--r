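#' Generate a synthetic longitudinal expression base pool
#'
#' Draws an unlabeled genes x subjects x time-points tensor mimicking summary
#' microarray expression values: each gene has its own mean and standard
#' deviation drawn from log-normal hyperpriors (log-scale intensities around
#' 7 with gene SDs around 0.5), and each subject's trajectory follows a
#' stationary AR(1) process across time with lag-1 correlation `rho`,
#' reproducing the within-gene temporal dependence that motivates treating a
#' trajectory as a gene set. Optionally, blocks of genes share a latent
#' subject-level trajectory, injecting inter-gene correlation (redundant
#' features).
#'
#' @param G,n,T numbers of genes, subjects and time points.
#' @param rho within-gene lag-1 temporal correlation in \[0, 1).
#' @param seed integer seed; output is deterministic given the seed.
#' @param mean_meanlog,mean_sdlog log-normal hyperprior of gene means.
#' @param sd_meanlog,sd_sdlog log-normal hyperprior of gene SDs.
#' @param n_blocks,block_size,block_rho inter-gene correlation blocks: the
#'   first `n_blocks * block_size` genes are grouped into blocks whose members
#'   share a fraction `block_rho` of their variance through a common latent
#'   trajectory (0 blocks by default).
#' @return an unlabeled [longitudinal_eset()].
#' @export
generate_base_expression <- function(G, n, T, rho = 0.6, seed = 1L,
                                     mean_meanlog = log(7), mean_sdlog = 0.15,
                                     sd_meanlog = log(0.5), sd_sdlog = 0.4,
                                     n_blocks = 0L, block_size = 10L,
                                     block_rho = 0.7) {
  if (rho < 0 || rho >= 1) abort_config("`rho` must be in [0, 1).")
  with_seed(seed, {
    mu <- stats::rlnorm(G, mean_meanlog, mean_sdlog)
    sig <- stats::rlnorm(G, sd_meanlog, sd_sdlog)
    e <- ar1_noise(G, n, T, rho)
    if (n_blocks > 0L) {
      latent <- ar1_noise(n_blocks, n, T, rho)
      for (b in seq_len(n_blocks)) {
        idx <- ((b - 1L) * block_size + 1L):(b * block_size)
        idx <- idx[idx <= G]
        for (g in idx) {
          e[g, , ] <- sqrt(block_rho) * latent[b, , ] +
            sqrt(1 - block_rho) * e[g, , ]
        }
      }
    }
    expr <- mu + sig * array(e, dim(e))  # mu, sig recycle along gene axis
    longitudinal_eset(expr)
  })
}

# Standardized stationary AR(1) innovations, dimension (m, n, T).
ar1_noise <- function(m, n, T, rho) {
  e <- array(NA_real_, c(m, n, T))
  e[, , 1] <- stats::rnorm(m * n)
  if (T > 1L) {
    for (t in 2:T) {
      e[, , t] <- rho * e[, , t - 1] + sqrt(1 - rho^2) * stats::rnorm(m * n)
    }
  }
  e
}

#' Specify the causal structure of a simulated outcome
#'
#' @param causal_terms tibble/data frame with columns `gene_id`, `time_index`,
#'   `beta` (finite, nonzero coefficients of the logit model).
#' @param intercept intercept of the logit (default 0).
#' @return an object of class `simulation_design`.
#' @export
simulation_design <- function(causal_terms, intercept = 0) {
  causal_terms <- tibble::as_tibble(causal_terms)
  need <- c("gene_id", "time_index", "beta")
  if (!all(need %in% names(causal_terms))) {
    abort_validation(sprintf("causal_terms needs columns: %s", paste(need, collapse = ", ")))
  }
  if (any(!is.finite(causal_terms$beta)) || any(causal_terms$beta == 0)) {
    abort_validation("coefficients must be finite and nonzero.")
  }
  structure(list(causal_terms = causal_terms, intercept = intercept),
            class = "simulation_design")
}

#' @export
print.simulation_design <- function(x, ...) {
  cat(sprintf("<simulation_design> %d causal (gene, time) term(s), intercept %g\n",
              nrow(x$causal_terms), x$intercept))
  invisible(x)
}

#' Simulate a binary phenotype from a logit on gene-time covariates
#'
#' Each subject's probability of the diseased class is
#' `p_i = logistic(intercept + sum over terms of beta * X(gene, time, i))`,
#' and the label is a Bernoulli draw with that probability. Covariate scaling
#' controls how expression enters the logit: `"standardize"` (default,
#' recommended for synthetic bases) centers and scales each covariate to unit
#' SD so coefficients are per-SD effects; `"center"` subtracts the covariate
#' mean but keeps raw units (the workable reading for real log-intensity
#' bases, since a no-intercept logit on uncentered intensities around 7
#' saturates at p = 1); `"raw"` plugs values in untouched. Degenerate draws
#' (fewer than two subjects in a class) are resampled up to `max_retries`
#' times along the same seeded stream.
#'
#' @param base an unlabeled (or labeled) [longitudinal_eset()].
#' @param design a [simulation_design()].
#' @param seed integer seed.
#' @param scaling covariate scaling: `"standardize"`, `"center"` or `"raw"`.
#' @param max_retries resampling budget for degenerate outcome vectors.
#' @return integer 0/1 label vector named by subject, with attribute `p`
#'   (the subject-level probabilities).
#' @export
simulate_outcome <- function(base, design, seed = 1L,
                             scaling = c("standardize", "center", "raw"),
                             max_retries = 25L) {
  scaling <- match.arg(scaling)
  stopifnot(inherits(base, "longitudinal_eset"), inherits(design, "simulation_design"))
  terms <- design$causal_terms
  gi <- match(terms$gene_id, base$gene_ids)
  if (anyNA(gi)) abort_validation("causal gene absent from the base dataset.")
  if (any(terms$time_index < 1L | terms$time_index > length(base$time_ids))) {
    abort_validation("causal time index outside the base's time range.")
  }
  X <- vapply(seq_len(nrow(terms)),
              function(j) base$expr[gi[j], , terms$time_index[j]],
              numeric(length(base$subject_ids)))
  X <- matrix(X, ncol = nrow(terms))
  X <- switch(scaling,
              standardize = scale(X),
              center = scale(X, scale = FALSE),
              raw = X)
  logit <- drop(X %*% terms$beta) + design$intercept
  p <- stats::plogis(logit)
  labels <- with_seed(seed, {
    y_ok <- NULL
    for (try in seq_len(max_retries)) {
      y <- stats::rbinom(length(p), 1L, p)
      if (min(tabulate(y + 1L, 2L)) >= 2L) {
        y_ok <- y
        break
      }
    }
    y_ok
  })
  if (is.null(labels)) {
    abort_validation(sprintf(
      "degenerate outcome vector after %d retries (class probabilities too extreme).",
      max_retries))
  }
  names(labels) <- base$subject_ids
  attr(labels, "p") <- p
  labels
}

#' Shift one gene's expression for the diseased class
#'
#' Utility for constructing datasets with a known standardized effect: adds
#' `delta` times the gene's observed SD (at that time point) to the
#' measurements of diseased subjects at `time_index`.
#'
#' @param ds a labeled [longitudinal_eset()].
#' @param gene gene id or index.
#' @param time_index time point to shift.
#' @param delta effect size in SD units.
#' @return the modified dataset.
#' @export
add_mean_shift <- function(ds, gene, time_index, delta) {
  gi <- resolve_idx(gene, ds$gene_ids, "gene")
  if (is.null(ds$labels)) abort_validation("`ds` must be labeled.")
  v <- ds$expr[gi, , time_index]
  sdv <- stats::sd(v[ds$mask[gi, , time_index]])
  shift <- delta * sdv
  sel <- ds$labels == 1L
  ds$expr[gi, sel, time_index] <- ds$expr[gi, sel, time_index] + shift
  ds
}

# Shared scaffolding for the two study scenarios.
build_scenario <- function(terms_fun, seed, n_noise = 998L, n = 43L, T = 5L,
                           beta_scale = 1, base = NULL, causal_genes = NULL,
                           scaling = NULL, rho = 0.6, ...) {
  if (is.null(base)) {
    base <- generate_base_expression(G = n_noise + 2L, n = n, T = T,
                                     rho = rho, seed = seed, ...)
    causal <- c("causalA", "causalB")
    base$gene_ids[1:2] <- causal
    dimnames(base$expr)[[1]] <- dimnames(base$mask)[[1]] <- base$gene_ids
    scaling <- scaling %||% "standardize"
  } else {
    if (is.null(causal_genes) || length(causal_genes) != 2L) {
      abort_config("with a real base pool, supply exactly 2 `causal_genes` ids.")
    }
    causal <- causal_genes
    noise_pool <- setdiff(base$gene_ids, causal)
    noise <- with_seed(seed, sample(noise_pool, n_noise))
    base <- subset_eset(base, genes = c(causal, noise))
    # keep raw units but absorb the location (no-intercept logit)
    scaling <- scaling %||% "center"
  }
  design <- simulation_design(terms_fun(causal, beta_scale))
  labels <- simulate_outcome(base, design, seed = seed, scaling = scaling)
  dataset <- longitudinal_eset(base$expr, labels = labels, mask = base$mask,
                               gene_ids = base$gene_ids,
                               subject_ids = base$subject_ids,
                               time_ids = base$time_ids)
  list(dataset = dataset, design = design)
}

#' Study scenario 1: joint-over-time effect plus a single-time effect
#'
#' Two causal genes among `n_noise` noise genes: gene A carries a joint
#' association accumulated over time points 1-4 (coefficients 0.18, 0.57,
#' 0.29, 0.41) and gene B acts only at time point 3 (coefficient 1.02).
#' By default a fresh synthetic base pool of `n_noise + 2` genes is drawn per
#' call (so noise genes differ between replicates) and covariates are
#' standardized; passing a real expression pool via `base` samples `n_noise`
#' noise genes from it and centers covariates in raw units.
#'
#' @param seed integer seed (controls the base pool, noise-gene draw and
#'   outcome draw).
#' @param n_noise number of noise genes (default 998).
#' @param n,T subjects and time points (defaults 43 and 5).
#' @param beta_scale multiplier applied to all coefficients (effect-size
#'   dial for power studies; 1 = the reference values).
#' @param base optional base pool [longitudinal_eset()]; `NULL` = synthetic.
#' @param causal_genes ids of the two causal genes when `base` is supplied.
#' @param scaling covariate scaling in the logit, see [simulate_outcome()]
#'   (default: standardize for synthetic bases, center for real pools).
#' @param rho temporal correlation of the synthetic base.
#' @param ... further arguments to [generate_base_expression()].
#' @return list with `dataset` (labeled [longitudinal_eset()]) and `design`
#'   (the [simulation_design()]).
#' @export
build_scenario1 <- function(seed = 1L, n_noise = 998L, n = 43L, T = 5L,
                            beta_scale = 1, base = NULL, causal_genes = NULL,
                            scaling = NULL, rho = 0.6, ...) {
  terms_fun <- function(causal, scale) {
    tibble::tibble(
      gene_id = c(rep(causal[1], 4L), causal[2]),
      time_index = c(1L, 2L, 3L, 4L, 3L),
      beta = c(0.18, 0.57, 0.29, 0.41, 1.02) * scale
    )
  }
  build_scenario(terms_fun, seed = seed, n_noise = n_noise, n = n, T = T,
                 beta_scale = beta_scale, base = base,
                 causal_genes = causal_genes, scaling = scaling,
                 rho = rho, ...)
}

#' Study scenario 2: two single-time effects of opposite sign
#'
#' Gene A acts at time point 1 (coefficient 0.56) and gene B at time point 5
#' (coefficient -0.91). Other arguments as in [build_scenario1()].
#'
#' @inheritParams build_scenario1
#' @return list with `dataset` and `design`.
#' @export
build_scenario2 <- function(seed = 1L, n_noise = 998L, n = 43L, T = 5L,
                            beta_scale = 1, base = NULL, causal_genes = NULL,
                            scaling = NULL, rho = 0.6, ...) {
  terms_fun <- function(causal, scale) {
    tibble::tibble(
      gene_id = causal,
      time_index = c(1L, 5L),
      beta = c(0.56, -0.91) * scale
    )
  }
  build_scenario(terms_fun, seed = seed, n_noise = n_noise, n = n, T = T,
                 beta_scale = beta_scale, base = base,
                 causal_genes = causal_genes, scaling = scaling,
                 rho = rho, ...)
}

#' Replicate study: selection frequencies over simulated datasets
#'
#' Builds `R` replicate datasets from a scenario, runs the full selection +
#' reduction pipeline on each, and aggregates: the percentage of replicates
#' in which each causal gene is selected at each time point, the average
#' number of genes selected per time point, and the average size of the union
#' of selected genes. Replicates are seeded individually (`seed + r`), so the
#' summary does not depend on execution order; a failed replicate is recorded
#' and excluded with a warning.
#'
#' @param scenario `"joint"` (scenario 1), `"opposite"` (scenario 2), or a
#'   function `(seed) -> list(dataset, design)`.
#' @param R number of replicates (default 50).
#' @param seed base seed.
#' @param B,q_cutoff,s0_policy,qvalue_policy screening parameters, see
#'   [select_genes()].
#' @param ck fixed reduction cutoff; set `tune = TRUE` to tune it by CV
#'   within every replicate instead.
#' @param tune,grid,folds,cost cross-validation tuning controls.
#' @param ... passed to the scenario builder (e.g. `n_noise`, `beta_scale`).
#' @return an object of class `samgsr_replicates`: `freq` (tibble gene_id x
#'   time_index x pct), `n_per_time` (average selected genes per time point),
#'   `avg_union`, `R_effective`, `failures`.
#' @export
run_replicates <- function(scenario = c("joint", "opposite"), R = 50L,
                           seed = 1L, B = 1000L, q_cutoff = 0.05, ck = 0.05,
                           tune = FALSE, grid = seq(0.05, 0.5, by = 0.05),
                           folds = 5L, cost = 1, ...) {
  builder <- if (is.function(scenario)) {
    scenario
  } else {
    scenario <- match.arg(scenario)
    fn <- if (scenario == "joint") build_scenario1 else build_scenario2
    function(s) fn(seed = s, ...)
  }
  per_rep <- vector("list", R)
  failures <- 0L
  T_global <- NULL
  causal_terms <- NULL
  for (r in seq_len(R)) {
    res <- tryCatch({
      sc <- builder(seed + r)
      ds <- sc$dataset
      T <- length(ds$time_ids)
      sel <- suppressMessages(
        select_genes(ds, B = B, q_cutoff = q_cutoff, seed = seed + r)
      )
      ck_r <- ck
      if (tune) {
        tn <- tune_ck(ds, grid = grid, folds = folds, seed = seed + r,
                      B = B, q_cutoff = q_cutoff, cost = cost)
        ck_r <- tn$best_cutoff
      }
      red <- suppressWarnings(reduce_all(sel, ds, c_cutoff = ck_r))
      causal <- unique(sc$design$causal_terms$gene_id)
      hit <- matrix(FALSE, length(causal), T,
                    dimnames = list(causal, NULL))
      for (g in causal) {
        tpts <- red$features$time_index[red$features$gene_id == g]
        hit[g, tpts] <- TRUE
      }
      n_per_time <- vapply(seq_len(T), function(t) {
        length(unique(red$features$gene_id[red$features$time_index == t]))
      }, numeric(1))
      list(hit = hit, n_per_time = n_per_time,
           union = length(unique(red$features$gene_id)),
           T = T, terms = sc$design$causal_terms, ck = ck_r)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- failures + 1L
      rlang::warn(sprintf("replicate %d failed: %s", r, conditionMessage(res)))
    } else {
      per_rep[[r]] <- res
      T_global <- res$T
      causal_terms <- res$terms
    }
  }
  per_rep <- per_rep[!vapply(per_rep, is.null, logical(1))]
  R_eff <- length(per_rep)
  if (R_eff == 0L) abort_validation("all replicates failed.")
  causal <- rownames(per_rep[[1]]$hit)
  hit_sum <- Reduce(`+`, lapply(per_rep, function(x) x$hit * 1))
  freq <- tibble::tibble(
    gene_id = rep(causal, times = T_global),
    time_index = rep(seq_len(T_global), each = length(causal)),
    pct = 100 * as.vector(hit_sum) / R_eff
  )
  n_per_time <- colMeans(do.call(rbind, lapply(per_rep, `[[`, "n_per_time")))
  structure(
    list(freq = freq,
         n_per_time = tibble::tibble(time_index = seq_len(T_global),
                                     avg_n_genes = n_per_time),
         avg_union = mean(vapply(per_rep, `[[`, numeric(1), "union")),
         R_effective = R_eff, failures = failures,
         causal_terms = causal_terms,
         params = list(B = B, q_cutoff = q_cutoff, ck = ck, tune = tune,
                       seed = seed)),
    class = "samgsr_replicates"
  )
}

#' @export
print.samgsr_replicates <- function(x, ...) {
  cat(sprintf("<samgsr_replicates> %d replicate(s) (%d failed); avg union size %.2f genes\n",
              x$R_effective, x$failures, x$avg_union))
  wide <- tidyr::pivot_wider(x$freq, names_from = "time_index",
                             values_from = "pct", names_prefix = "t")
  print(wide)
  invisible(x)
}

#' @rdname run_replicates
#' @param x a `samgsr_replicates`.
#' @param ... unused.
#' @export
tidy.samgsr_replicates <- function(x, ...) x$freq

#' @rdname run_replicates
#' @export
glance.samgsr_replicates <- function(x, ...) {
  tibble::tibble(R_effective = x$R_effective, failures = x$failures,
                 avg_union_genes = x$avg_union)
}
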