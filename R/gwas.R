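#' Normalize phenotypes within sex-generation groups
#'
#' Z-scores body weight within each (sex, generation) cell: value becomes
#' (bw8 - cell mean) / cell SD, with the sample SD (n - 1 denominator). The
#' result has mean 0 and SD 1 within every cell, which removes sex and
#' generation fixed effects before variance-heterogeneity or NOIA analysis.
#'
#' @param samples phenotype-table data.frame with `sex`, `generation`, `bw8`.
#' @return Numeric vector aligned with rows of `samples` (`NA` where `bw8`
#'   is missing).
#' @export
normalize_by_group <- function(samples) {
  out <- rep(NA_real_, nrow(samples))
  cell <- interaction(samples$sex, samples$generation, drop = TRUE)
  for (lv in levels(cell)) {
    i <- which(cell == lv & !is.na(samples$bw8))
    if (length(i) < 2L)
      stop("sex-generation cell ", lv, " has fewer than 2 phenotyped samples")
    s <- stats::sd(samples$bw8[i])
    if (s == 0) stop("sex-generation cell ", lv, " has zero phenotype SD")
    out[i] <- (samples$bw8[i] - mean(samples$bw8[i])) / s
  }
  out
}

# Least squares with explicit rank handling. Returns NA coefficients for
# aliased columns and a degenerate flag when the residual variance vanishes.
ols_fit <- function(X, y) {
  qr_ <- qr(X)
  r <- qr_$rank
  coef <- qr.coef(qr_, y)
  res <- y - qr.fitted(qr_, y)
  df <- length(y) - r
  sigma2 <- if (df > 0) sum(res^2) / df else NA_real_
  se <- rep(NA_real_, ncol(X))
  if (df > 0 && is.finite(sigma2)) {
    piv <- qr_$pivot[seq_len(r)]
    Rinv <- backsolve(qr.R(qr_)[seq_len(r), seq_len(r), drop = FALSE], diag(r))
    se[piv] <- sqrt(sigma2 * rowSums(Rinv^2))
  }
  names(se) <- colnames(X)
  degenerate <- df > 0 && is.finite(sigma2) &&
    sigma2 <= 1e-12 * max(1, stats::var(y))
  list(coef = coef, se = se, df = df, sigma2 = sigma2, rank = r,
       aliased = is.na(coef), degenerate = degenerate)
}

# Design matrix of the fixed-effects association model:
# intercept + sex indicator + generation factor (+ conditioning dosages).
base_design <- function(samples) {
  X <- cbind(`(Intercept)` = rep(1, nrow(samples)))
  if (length(unique(samples$sex)) > 1L)
    X <- cbind(X, sexM = as.numeric(samples$sex == "M"))
  gens <- sort(unique(samples$generation))
  if (length(gens) > 1L)
    for (gg in gens[-1])
      X <- cbind(X, stats::setNames(
        data.frame(as.numeric(samples$generation == gg)),
        paste0("gen", gg))[[1]])
  colnames(X) <- c("(Intercept)",
                   if (length(unique(samples$sex)) > 1L) "sexM",
                   if (length(gens) > 1L) paste0("gen", gens[-1]))
  X
}

#' Fit the single-marker fixed-effects association model
#'
#' Ordinary least squares of the phenotype on an intercept, sex, generation
#' (unordered factor), optional conditioning-marker allele counts, and the
#' tested marker's alternative-allele count. Cases with missing phenotype or
#' any needed genotype are dropped for this marker.
#'
#' @param y numeric phenotype vector aligned with `samples`.
#' @param samples phenotype-table data.frame.
#' @param g an [ail_geno] object containing all samples in `samples`.
#' @param marker marker id to test.
#' @param conditioning optional character vector of marker ids entered as
#'   covariates.
#' @return A list: `marker_id`, `effect` (grams per alternative allele),
#'   `se`, `intercept`, `covariate_effects` (named numeric), `stat` (t),
#'   `pvalue`, `neglog10p`, `n_used`, `residual_variance`, `flag` (one of
#'   `"ok"`, `"monomorphic"`, `"rank_deficient"`, `"degenerate"`).
#' @export
fit_marker_lm <- function(y, samples, g, marker, conditioning = NULL) {
  stopifnot(inherits(g, "ail_geno"))
  A <- g$calls[samples$sample_id, marker]
  cond <- if (length(conditioning))
    g$calls[samples$sample_id, conditioning, drop = FALSE] else NULL
  use <- !is.na(y) & !is.na(A)
  if (!is.null(cond)) use <- use & !apply(is.na(cond), 1L, any)

  empty <- list(marker_id = marker, effect = NA_real_, se = NA_real_,
                intercept = NA_real_, covariate_effects = numeric(0),
                stat = NA_real_, pvalue = NA_real_, neglog10p = NA_real_,
                n_used = sum(use), residual_variance = NA_real_)
  if (length(unique(A[use])) < 2L) {
    empty$flag <- "monomorphic"
    return(empty)
  }

  X <- base_design(samples[use, , drop = FALSE])
  if (!is.null(cond)) {
    Xc <- cond[use, , drop = FALSE]
    colnames(Xc) <- conditioning
    X <- cbind(X, Xc)
  }
  X <- cbind(X, A[use])
  colnames(X)[ncol(X)] <- marker
  fit <- ols_fit(X, y[use])

  k <- ncol(X)
  res <- list(marker_id = marker,
              effect = unname(fit$coef[k]), se = unname(fit$se[k]),
              intercept = unname(fit$coef[1]),
              covariate_effects = fit$coef[-c(1, k)],
              stat = NA_real_, pvalue = NA_real_, neglog10p = NA_real_,
              n_used = sum(use), residual_variance = fit$sigma2,
              flag = "ok")
  if (fit$aliased[k]) {
    res$flag <- "rank_deficient"
    res$effect <- NA_real_; res$se <- NA_real_
    return(res)
  }
  if (fit$degenerate) {
    res$flag <- "degenerate"
    res$stat <- Inf; res$pvalue <- 0; res$neglog10p <- Inf
    res$residual_variance <- 0
    return(res)
  }
  res$stat <- res$effect / res$se
  res$pvalue <- 2 * stats::pt(-abs(res$stat), df = fit$df)
  res$neglog10p <- -log10(res$pvalue)
  res
}

#' Single-marker association scan
#'
#' Applies [fit_marker_lm()] to every requested marker, preserving panel
#' order. When the phenotype and all scanned genotypes are complete, the
#' covariates are projected out once and each marker is tested on the
#' residualized data (Frisch-Waugh-Lovell), which gives numerically
#' identical estimates to the per-marker fit at a fraction of the cost.
#'
#' @inheritParams fit_marker_lm
#' @param markers marker ids to scan; `NULL` scans the whole panel.
#' @return data.frame with columns `marker_id`, `chrom`, `pos`, `n_used`,
#'   `effect`, `se`, `stat`, `pvalue`, `neglog10p`, `flag`.
#' @export
gwas_scan <- function(y, samples, g, markers = NULL, conditioning = NULL) {
  if (is.null(markers)) markers <- g$map$marker_id
  A <- g$calls[samples$sample_id, markers, drop = FALSE]
  if (!anyNA(y) && !anyNA(A)) {
    cond <- if (length(conditioning))
      g$calls[samples$sample_id, conditioning, drop = FALSE] else NULL
    if (is.null(cond) || !anyNA(cond))
      return(gwas_scan_complete(y, samples, g, markers, A, cond))
  }
  rows <- lapply(markers, function(mk)
    fit_marker_lm(y, samples, g, mk, conditioning = conditioning))
  mi <- match(markers, g$map$marker_id)
  data.frame(marker_id = markers,
             chrom = g$map$chrom[mi], pos = g$map$pos[mi],
             n_used = vapply(rows, `[[`, 0L, "n_used"),
             effect = vapply(rows, `[[`, 0, "effect"),
             se = vapply(rows, `[[`, 0, "se"),
             stat = vapply(rows, `[[`, 0, "stat"),
             pvalue = vapply(rows, `[[`, 0, "pvalue"),
             neglog10p = vapply(rows, `[[`, 0, "neglog10p"),
             flag = vapply(rows, `[[`, "", "flag"),
             stringsAsFactors = FALSE)
}

# Complete-data scan path: identical algebra to fit_marker_lm per marker.
gwas_scan_complete <- function(y, samples, g, markers, A, cond) {
  X0 <- base_design(samples)
  if (!is.null(cond)) X0 <- cbind(X0, cond)
  q0 <- qr(X0)
  ry <- qr.resid(q0, y)
  rA <- qr.resid(q0, A)
  saa <- colSums(rA^2)
  n <- length(y)
  df <- n - q0$rank - 1L
  sy2 <- sum(ry^2)

  mono <- vapply(seq_along(markers), function(j)
    length(unique(A[, j])) < 2L, TRUE)
  aliased <- !mono & saa <= 1e-10 * n

  effect <- colSums(rA * ry) / saa
  rss <- pmax(sy2 - effect^2 * saa, 0)
  sigma2 <- rss / df
  degen <- !mono & !aliased & sigma2 <= 1e-12 * max(1, stats::var(y))
  se <- sqrt(sigma2 / saa)
  stat <- effect / se
  pvalue <- 2 * stats::pt(-abs(stat), df)

  flag <- rep("ok", length(markers))
  flag[mono] <- "monomorphic"; flag[aliased] <- "rank_deficient"
  flag[degen] <- "degenerate"
  effect[mono | aliased] <- NA_real_
  se[mono | aliased] <- NA_real_; stat[mono | aliased] <- NA_real_
  pvalue[mono | aliased] <- NA_real_
  stat[degen] <- Inf; pvalue[degen] <- 0

  mi <- match(markers, g$map$marker_id)
  data.frame(marker_id = markers, chrom = g$map$chrom[mi], pos = g$map$pos[mi],
             n_used = n, effect = unname(effect), se = unname(se),
             stat = unname(stat), pvalue = unname(pvalue),
             neglog10p = -log10(unname(pvalue)), flag = flag,
             stringsAsFactors = FALSE)
}

#' Stepwise marker selection with fixed sex/generation covariates
#'
#' Forward selection (add the candidate with the smallest p-value below
#' `alpha_in`) alternated with backward elimination (drop the selected
#' marker with the largest p-value above `alpha_out`) until the model is
#' stable. Sex and generation are always retained. Ties are broken by
#' smaller p-value, then lower map position. With `criterion = "aic"`,
#' additions/removals instead require an AIC decrease.
#'
#' @inheritParams fit_marker_lm
#' @param candidate_markers character vector of candidate marker ids.
#' @param alpha_in,alpha_out p-value thresholds for entry and removal.
#' @param criterion `"pvalue"` (default) or `"aic"`.
#' @return A list: `selected` (marker ids in selection order) and `fit`, an
#'   `lm` object of the final model with terms ordered sex, generation,
#'   selected markers.
#' @export
stepwise_select <- function(y, samples, g, candidate_markers,
                            alpha_in = 0.05, alpha_out = 0.05,
                            criterion = c("pvalue", "aic")) {
  criterion <- match.arg(criterion)
  stopifnot(length(candidate_markers) >= 1L)
  selected <- character(0)
  pos <- g$map$pos[match(candidate_markers, g$map$marker_id)]

  marker_p <- function(mk, current) {
    r <- fit_marker_lm(y, samples, g, mk, conditioning = current)
    if (r$flag %in% c("monomorphic", "rank_deficient")) NA_real_ else r$pvalue
  }
  model_aic <- function(sel) {
    d <- model_frame(y, samples, g, sel)
    stats::AIC(stats::lm(stats::as.formula(model_formula(samples, sel)), data = d))
  }

  repeat {
    changed <- FALSE
    # forward step
    cand <- setdiff(candidate_markers, selected)
    if (length(cand)) {
      ps <- vapply(cand, marker_p, 0, current = selected)
      ok <- !is.na(ps)
      if (criterion == "pvalue") ok <- ok & ps < alpha_in
      if (any(ok)) {
        o <- order(ps, pos[match(cand, candidate_markers)])
        best <- cand[o][ok[o]][1]
        if (criterion == "aic") {
          if (model_aic(c(selected, best)) < model_aic(selected)) {
            selected <- c(selected, best); changed <- TRUE
          }
        } else {
          selected <- c(selected, best); changed <- TRUE
        }
      }
    }
    # backward step
    if (length(selected) > 1L) {
      ps <- vapply(selected, function(mk)
        marker_p(mk, setdiff(selected, mk)), 0)
      if (criterion == "pvalue") {
        worst_p <- max(ps, na.rm = TRUE)
        if (is.finite(worst_p) && worst_p > alpha_out) {
          o <- order(-ps, -pos[match(selected, candidate_markers)])
          selected <- setdiff(selected, selected[o][1]); changed <- TRUE
        }
      } else {
        for (mk in selected[order(-ps)]) {
          if (model_aic(setdiff(selected, mk)) < model_aic(selected)) {
            selected <- setdiff(selected, mk); changed <- TRUE; break
          }
        }
      }
    }
    if (!changed) break
  }

  d <- model_frame(y, samples, g, selected)
  fit <- stats::lm(stats::as.formula(model_formula(samples, selected)), data = d)
  list(selected = selected, fit = fit)
}

model_frame <- function(y, samples, g, markers) {
  d <- data.frame(.y = y, sex = factor(samples$sex),
                  generation = factor(samples$generation))
  for (mk in markers) d[[mk]] <- g$calls[samples$sample_id, mk]
  stats::na.omit(d)
}

model_formula <- function(samples, markers) {
  terms <- c(if (length(unique(samples$sex)) > 1L) "sex",
             if (length(unique(samples$generation)) > 1L) "generation",
             markers)
  if (length(terms) == 0L) terms <- "1"
  paste(".y ~", paste(terms, collapse = " + "))
}

#' Sequential (type-I) ANOVA table of a fitted association model
#'
#' Terms are tested in model order (sex, generation, then markers in
#' selection order); each F statistic is the term mean square divided by the
#' residual mean square of the single fitted model.
#'
#' @param fit an `lm` object, e.g. `stepwise_select(...)$fit`.
#' @return data.frame with columns `term`, `df`, `mean_square`, `f_value`,
#'   `pvalue` (residual row included with `NA` F and p).
#' @export
anova_table <- function(fit) {
  a <- stats::anova(fit)
  if (a["Residuals", "Df"] == 0) stop("zero residual degrees of freedom")
  data.frame(term = rownames(a), df = a$Df, mean_square = a$`Mean Sq`,
             f_value = a$`F value`, pvalue = a$`Pr(>F)`,
             stringsAsFactors = FALSE)
}

#' Check internal consistency of a published sequential ANOVA table
#'
#' Given printed mean squares and F values that share one residual mean
#' square, the implied residual MS is the average of `mean_square / f_value`
#' across rows; each F is then recomputed from its mean square, and p-values
#' from the F distribution.
#'
#' @param mean_square,f_value numeric vectors, one entry per table row.
#' @param df1 numerator degrees of freedom per row (default 1).
#' @param df2 residual degrees of freedom used for p-values.
#' @return A list: `residual_ms`, `f_recomputed`, `p_recomputed`.
#' @export
recompute_anova_f <- function(mean_square, f_value, df1 = 1, df2 = 2900) {
  residual_ms <- mean(mean_square / f_value)
  f2 <- mean_square / residual_ms
  list(residual_ms = residual_ms, f_recomputed = f2,
       p_recomputed = stats::pf(f2, df1, df2, lower.tail = FALSE))
}

#' Per-genotype phenotype summaries at a marker
#'
#' @param y numeric phenotype vector (typically [normalize_by_group()]
#'   output) aligned with `samples`.
#' @param samples phenotype-table data.frame.
#' @param g an [ail_geno] object.
#' @param marker marker id.
#' @return data.frame with one row per observed genotype class: `genotype`
#'   (`RR`, `RA`, `AA`), `mean`, `sd`, `count`.
#' @export
genotype_group_summary <- function(y, samples, g, marker) {
  A <- g$calls[samples$sample_id, marker]
  use <- !is.na(y) & !is.na(A)
  lab <- c("RR", "RA", "AA")
  out <- lapply(0:2, function(gg) {
    yy <- y[use & A == gg]
    if (length(yy) == 0L) return(NULL)
    data.frame(genotype = lab[gg + 1L], mean = mean(yy),
               sd = stats::sd(yy), count = length(yy),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Compact letter display from least-significant-difference tests
#'
#' Pairwise comparisons use the pooled within-group variance
#' `sum((n_i - 1) s_i^2) / sum(n_i - 1)` and t statistics
#' `|m_i - m_j| / sqrt(pooled (1/n_i + 1/n_j))` with `sum(n_i - 1)` degrees
#' of freedom. Groups sharing a letter are not significantly different at
#' `alpha`. Accepts either a [genotype_group_summary()] data.frame or raw
#' summary triples.
#'
#' @param groups data.frame with columns `mean`, `sd`, `count` (e.g. from
#'   [genotype_group_summary()]); alternatively `NULL` if `means`, `sds`,
#'   `ns` are given.
#' @param means,sds,ns numeric vectors of group summaries (used when
#'   `groups` is `NULL`).
#' @param alpha significance level (default 0.05).
#' @return Character vector of letters, one per group, in input order.
#' @export
lsd_letters <- function(groups = NULL, means = NULL, sds = NULL, ns = NULL,
                        alpha = 0.05) {
  if (!is.null(groups)) {
    means <- groups$mean; sds <- groups$sd; ns <- groups$count
  }
  k <- length(means)
  if (k < 2L) stop("need at least 2 groups")
  if (any(ns < 2L)) stop("every group needs n >= 2")
  pooled <- sum((ns - 1) * sds^2) / sum(ns - 1)
  df <- sum(ns - 1)

  sig <- matrix(FALSE, k, k)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    tv <- abs(means[i] - means[j]) / sqrt(pooled * (1 / ns[i] + 1 / ns[j]))
    sig[i, j] <- sig[j, i] <- 2 * stats::pt(-tv, df) < alpha
  }

  # insert-and-absorb compact letter display, computed in mean-descending
  # order so the lettering is invariant to input order
  ord <- order(-means)
  cols <- list(seq_len(k))
  for (a in seq_len(k - 1)) for (b in (a + 1):k) {
    i <- ord[a]; j <- ord[b]
    if (!sig[i, j]) next
    newcols <- list()
    for (cl in cols) {
      if (i %in% cl && j %in% cl) {
        newcols <- c(newcols, list(setdiff(cl, i)), list(setdiff(cl, j)))
      } else newcols <- c(newcols, list(cl))
    }
    # absorb columns that are subsets of another
    keep <- rep(TRUE, length(newcols))
    for (u in seq_along(newcols)) for (v in seq_along(newcols)) {
      if (u != v && keep[u] && keep[v] &&
          all(newcols[[u]] %in% newcols[[v]]) &&
          !(all(newcols[[v]] %in% newcols[[u]]) && u < v)) keep[u] <- FALSE
    }
    cols <- newcols[keep]
  }
  # the partition is order-invariant; letter names follow the input order
  # (first group's class is "a"), matching how such tables are printed
  cols <- cols[order(vapply(cols, min, 0))]
  letters_out <- rep("", k)
  for (ci in seq_along(cols))
    for (i in cols[[ci]])
      letters_out[i] <- paste0(letters_out[i], letters[ci])
  letters_out
}
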