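# Shared fixture builders. Everything is generated in code; no binary files.

# A tiny deterministic genotype object: n samples, markers with the given
# call columns (list of integer vectors). Optionally phased by splitting
# heterozygotes as 0|1.
toy_geno <- function(call_cols, phased = FALSE, chrom = "chr1") {
  n <- length(call_cols[[1]])
  m <- length(call_cols)
  calls <- do.call(cbind, call_cols)
  rownames(calls) <- sprintf("s%03d", seq_len(n))
  colnames(calls) <- names(call_cols) %||% sprintf("mk%02d", seq_len(m))
  map <- data.frame(marker_id = colnames(calls), chrom = chrom,
                    pos = seq_len(m) * 1000L,
                    ref = "A", alt = "G", stringsAsFactors = FALSE)
  if (!phased) return(ail_geno(calls, map))
  h1 <- pmax(calls - 1L, 0L)
  h2 <- pmin(calls, 1L)
  ail_geno(calls, map, h1, h2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Sample table with a single sex/generation cell (covariates degenerate to
# the intercept) for hand-computable regressions.
flat_samples <- function(n, bw8 = NULL) {
  data.frame(sample_id = sprintf("s%03d", seq_len(n)), sex = "F",
              generation = 2L, line = "CROSS",
              bw8 = bw8 %||% rep(NA_real_, n), stringsAsFactors = FALSE)
}

# Random multi-cell cohort for oracle comparisons.
random_cohort <- function(n, n_markers = 3, seed = 1) {
  set.seed(seed)
  samples <- data.frame(sample_id = sprintf("s%03d", seq_len(n)),
                        sex = sample(c("F", "M"), n, replace = TRUE),
                        generation = sample(2:4, n, replace = TRUE),
                        line = "CROSS",
                        bw8 = rnorm(n, 900, 90), stringsAsFactors = FALSE)
  cols <- lapply(seq_len(n_markers), function(i)
    sample(0:2, n, replace = TRUE, prob = c(0.4, 0.4, 0.2)))
  names(cols) <- sprintf("mk%02d", seq_len(n_markers))
  list(samples = samples, geno = toy_geno(cols))
}

# One moderate AIL simulation cached for the whole test run.
.sim_cache <- new.env()
cached_sim <- function() {
  if (is.null(.sim_cache$sim)) {
    cfg <- sim_config(seed = 42, n_founders_per_line = 15, n_f1 = 30,
                      n_per_generation = stats::setNames(rep(80L, 7), 2:8),
                      n_markers = 120, chrom_length_cm = 80)
    .sim_cache$sim <- simulate_ail(cfg)
  }
  .sim_cache$sim
}

# Independent normal-equations OLS oracle (no shared code with ols_fit).
oracle_ols <- function(X, y) {
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  res <- y - X %*% beta
  df <- length(y) - ncol(X)
  s2 <- sum(res^2) / df
  se <- sqrt(diag(solve(XtX)) * s2)
  list(coef = drop(beta), se = se, df = df, sigma2 = s2)
}
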