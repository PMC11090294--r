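#' Brown-Forsythe variance-heterogeneity test at one marker
#'
#' Computes, per genotype class, the absolute deviation of each phenotype
#' from the class median, then runs a one-way ANOVA of those deviations on
#' genotype class. A large F indicates that phenotypic variance differs
#' among genotype classes. The median of an even-sized class is the midpoint
#' of the two central order statistics.
#'
#' @param y numeric phenotype vector (normalized within sex-generation
#'   groups; see [normalize_by_group()]).
#' @param geno integer vector of genotypes in \{0, 1, 2\} aligned with `y`.
#' @param min_class_n minimum non-missing observations for a genotype class
#'   to enter the test; smaller classes are dropped and the degrees of
#'   freedom adjusted.
#' @return A list: `group_medians`, `group_mean_absdev` (named by genotype
#'   class), `f_bf`, `df_between`, `df_within`, `pvalue`, `neglog10p`,
#'   `n_used`, `flag` (`"ok"`, `"skipped"`, or `"degenerate"`).
#' @export
brown_forsythe <- function(y, geno, min_class_n = 10L) {
  use <- !is.na(y) & !is.na(geno)
  y <- y[use]; geno <- geno[use]
  counts <- table(geno)
  keep_classes <- names(counts)[counts >= min_class_n]
  keep <- geno %in% as.integer(keep_classes)
  y <- y[keep]; geno <- geno[keep]

  out <- list(group_medians = NULL, group_mean_absdev = NULL,
              f_bf = NA_real_, df_between = NA_integer_,
              df_within = NA_integer_, pvalue = NA_real_,
              neglog10p = NA_real_, n_used = length(y), flag = "ok")
  if (length(unique(geno)) < 2L) {
    out$flag <- "skipped"
    return(out)
  }
  med <- tapply(y, geno, stats::median)
  dev <- abs(y - med[as.character(geno)])
  out$group_medians <- med
  out$group_mean_absdev <- tapply(dev, geno, mean)
  k <- length(med)
  n <- length(y)
  out$df_between <- k - 1L
  out$df_within <- n - k

  grand <- mean(dev)
  ssb <- sum(tapply(dev, geno, length) * (out$group_mean_absdev - grand)^2)
  ssw <- sum((dev - out$group_mean_absdev[as.character(geno)])^2)
  if (ssw == 0) {
    # constant deviations within every class: no dispersion signal to test
    out$flag <- "degenerate"
    if (ssb == 0) {
      out$f_bf <- 0; out$pvalue <- 1; out$neglog10p <- 0
    } else {
      out$f_bf <- Inf; out$pvalue <- 0; out$neglog10p <- Inf
    }
    return(out)
  }
  out$f_bf <- (ssb / out$df_between) / (ssw / out$df_within)
  out$pvalue <- stats::pf(out$f_bf, out$df_between, out$df_within,
                          lower.tail = FALSE)
  out$neglog10p <- -log10(out$pvalue)
  out
}

#' Variance-heterogeneity scan over a marker panel
#'
#' Applies [brown_forsythe()] to every requested marker. Phenotypes should
#' already be normalized once per cohort with [normalize_by_group()].
#'
#' @param y_norm normalized phenotype vector aligned with `samples`.
#' @param samples phenotype-table data.frame.
#' @param g an [ail_geno] object.
#' @param markers marker ids to scan; `NULL` scans the whole panel.
#' @param min_class_n minimum genotype-class size (default 10).
#' @return data.frame with columns `marker_id`, `chrom`, `pos`, `n_used`,
#'   `median_RR`, `median_RA`, `median_AA`, `f_bf`, `df_between`,
#'   `df_within`, `pvalue`, `neglog10p`, `flag`.
#' @export
vgwas_scan <- function(y_norm, samples, g, markers = NULL, min_class_n = 10L) {
  if (is.null(markers)) markers <- g$map$marker_id
  calls <- g$calls[samples$sample_id, , drop = FALSE]
  rows <- lapply(markers, function(mk)
    brown_forsythe(y_norm, calls[, mk], min_class_n = min_class_n))
  med <- function(r, cls) {
    if (is.null(r$group_medians) || !cls %in% names(r$group_medians))
      NA_real_ else unname(r$group_medians[cls])
  }
  mi <- match(markers, g$map$marker_id)
  data.frame(marker_id = markers,
             chrom = g$map$chrom[mi], pos = g$map$pos[mi],
             n_used = vapply(rows, `[[`, 0L, "n_used"),
             median_RR = vapply(rows, med, 0, "0"),
             median_RA = vapply(rows, med, 0, "1"),
             median_AA = vapply(rows, med, 0, "2"),
             f_bf = vapply(rows, `[[`, 0, "f_bf"),
             df_between = vapply(rows, function(r) as.integer(r$df_between), 0L),
             df_within = vapply(rows, function(r) as.integer(r$df_within), 0L),
             pvalue = vapply(rows, `[[`, 0, "pvalue"),
             neglog10p = vapply(rows, `[[`, 0, "neglog10p"),
             flag = vapply(rows, `[[`, "", "flag"),
             stringsAsFactors = FALSE)
}
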