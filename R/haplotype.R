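#' Pairwise D-prime with a likelihood-based confidence interval
#'
#' Computes D' between two markers from phased haplotypes and a confidence
#' interval obtained by profiling the multinomial likelihood over D' (allele
#' frequencies held at their estimates), the construction used by
#' Gabriel-style haplotype-block definitions.
#'
#' @param hA,hB 0/1 vectors of haplotype alleles at the two markers (one
#'   entry per haplotype, i.e. two per sample).
#' @param ci confidence level tail mass (default 0.05 each side, i.e. a 90%
#'   interval as in the standard block definition).
#' @return A list: `dprime`, `ci_low`, `ci_high`, `r2`, `n_hap`,
#'   `informative` (FALSE when either marker is monomorphic).
#' @export
pair_dprime <- function(hA, hB, ci = 0.05) {
  keep <- !is.na(hA) & !is.na(hB)
  hA <- hA[keep]; hB <- hB[keep]
  n <- length(hA)
  pA <- mean(hA); pB <- mean(hB)
  out <- list(dprime = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
              r2 = NA_real_, n_hap = n, informative = FALSE)
  if (n == 0L || pA %in% c(0, 1) || pB %in% c(0, 1)) return(out)

  pAB <- mean(hA == 1 & hB == 1)
  D <- pAB - pA * pB
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB) else
    min(pA * pB, (1 - pA) * (1 - pB))
  out$dprime <- if (dmax > 0) abs(D) / dmax else 0
  out$r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))

  # haplotype-class counts: (A,B) in (1,1), (1,0), (0,1), (0,0)
  cnt <- c(sum(hA == 1 & hB == 1), sum(hA == 1 & hB == 0),
           sum(hA == 0 & hB == 1), sum(hA == 0 & hB == 0))
  sgn <- if (D >= 0) 1 else -1
  grid <- seq(0, 1, by = 0.005)
  ll <- vapply(grid, function(dp) {
    Dg <- sgn * dp * dmax
    p <- c(pA * pB + Dg, pA * (1 - pB) - Dg, (1 - pA) * pB - Dg,
           (1 - pA) * (1 - pB) + Dg)
    p <- pmax(p, 1e-12)
    sum(cnt * log(p))
  }, 0)
  w <- exp(ll - max(ll))
  cdf <- cumsum(w) / sum(w)
  out$ci_low <- grid[which(cdf > ci)[1]]
  out$ci_high <- grid[which(cdf >= 1 - ci)[1]]
  out$informative <- TRUE
  out
}

#' Detect haplotype blocks by the D-prime confidence-interval rule
#'
#' A marker pair is in "strong LD" when the lower bound of its D' confidence
#' interval is at least `ci_strong_low` and the upper bound at least
#' `ci_strong_high`; it shows "strong recombination evidence" when the upper
#' bound is below `ci_recomb`. A candidate interval of contiguous eligible
#' markers is a block when its end-pair is in strong LD and at least
#' `strong_frac` of its informative pairs (strong LD or recombination) are
#' strong. Non-overlapping blocks are chosen greedily from the longest span.
#' Deterministic given the input.
#'
#' @param g a phased [ail_geno] object.
#' @param maf_min minimum minor-allele frequency for a marker to enter block
#'   building (default 0.05).
#' @param ci_strong_low,ci_strong_high,ci_recomb,strong_frac rule thresholds
#'   (defaults 0.70, 0.98, 0.90, 0.95).
#' @param max_block_markers largest number of eligible markers spanned by a
#'   candidate block (computational bound).
#' @return data.frame with one row per block: `chrom`, `start_pos`,
#'   `end_pos`, `first_marker`, `last_marker`, `n_markers`, `marker_ids`
#'   (comma-separated).
#' @export
find_blocks <- function(g, maf_min = 0.05, ci_strong_low = 0.70,
                        ci_strong_high = 0.98, ci_recomb = 0.90,
                        strong_frac = 0.95, max_block_markers = 50L) {
  stopifnot(inherits(g, "ail_geno"))
  if (is.null(g$hap1)) stop("block detection requires phased genotypes")
  af <- colMeans(g$calls, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  elig <- which(maf >= maf_min)
  empty <- data.frame(chrom = character(), start_pos = integer(),
                      end_pos = integer(), first_marker = character(),
                      last_marker = character(), n_markers = integer(),
                      marker_ids = character(), stringsAsFactors = FALSE)
  if (length(elig) < 2L) return(empty)

  H <- rbind(g$hap1[, elig, drop = FALSE], g$hap2[, elig, drop = FALSE])
  m <- length(elig)
  # pair classification cache: 0 = uninformative, 1 = strong, -1 = recomb,
  # 2 = informative-other
  cls <- function(i, j) {
    p <- pair_dprime(H[, i], H[, j])
    if (!p$informative || is.na(p$ci_low)) return(0L)
    if (p$ci_low >= ci_strong_low && p$ci_high >= ci_strong_high) return(1L)
    if (p$ci_high < ci_recomb) return(-1L)
    2L
  }
  cache <- new.env(hash = TRUE)
  cls_c <- function(i, j) {
    key <- paste(i, j)
    if (!is.null(cache[[key]])) return(cache[[key]])
    v <- cls(i, j)
    cache[[key]] <- v
    v
  }

  # candidate intervals, longest first; ties by leftmost start
  cand <- list()
  for (i in seq_len(m - 1L))
    for (j in (i + 1L):min(m, i + max_block_markers - 1L))
      cand[[length(cand) + 1L]] <- c(i, j)
  spans <- vapply(cand, function(x) x[2] - x[1], 0)
  cand <- cand[order(-spans, vapply(cand, `[`, 0, 1))]

  taken <- rep(FALSE, m)
  blocks <- list()
  for (cj in cand) {
    i <- cj[1]; j <- cj[2]
    if (any(taken[i:j])) next
    if (cls_c(i, j) != 1L) next
    n_strong <- 0L; n_inf <- 0L
    for (a in i:(j - 1L)) for (b in (a + 1L):j) {
      v <- cls_c(a, b)
      if (v == 1L) { n_strong <- n_strong + 1L; n_inf <- n_inf + 1L }
      else if (v == -1L) n_inf <- n_inf + 1L
    }
    if (n_inf == 0L || n_strong / n_inf < strong_frac) next
    taken[i:j] <- TRUE
    blocks[[length(blocks) + 1L]] <- c(i, j)
  }
  if (length(blocks) == 0L) return(empty)
  blocks <- blocks[order(vapply(blocks, `[`, 0, 1))]
  rows <- lapply(blocks, function(b) {
    idx <- elig[b[1]:b[2]]
    data.frame(chrom = g$map$chrom[idx[1]],
               start_pos = g$map$pos[idx[1]],
               end_pos = g$map$pos[idx[length(idx)]],
               first_marker = g$map$marker_id[idx[1]],
               last_marker = g$map$marker_id[idx[length(idx)]],
               n_markers = length(idx),
               marker_ids = paste(g$map$marker_id[idx], collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Assign per-sample haplotype labels within a block
#'
#' Each haplotype string over the block markers is mapped to a label (`H1`,
#' `H2`, ... in decreasing frequency); haplotypes rarer than
#' `pool_threshold` are pooled into `OTHER`. Samples with missing phase at
#' any block marker are excluded and counted.
#'
#' @param g a phased [ail_geno] object.
#' @param marker_ids character vector of block marker ids (or one row of
#'   [find_blocks()] output).
#' @param pool_threshold pooling frequency (default 0.01).
#' @return A list: `labels1`, `labels2` (named character vectors per
#'   sample), `frequencies` (named, sums to 1), `haplotype_strings` (label ->
#'   allele string), `n_excluded`.
#' @export
assign_haplotypes <- function(g, marker_ids, pool_threshold = 0.01) {
  stopifnot(inherits(g, "ail_geno"))
  if (is.data.frame(marker_ids))
    marker_ids <- strsplit(marker_ids$marker_ids[1], ",", fixed = TRUE)[[1]]
  if (is.null(g$hap1)) stop("haplotype assignment requires phase")
  h1 <- g$hap1[, marker_ids, drop = FALSE]
  h2 <- g$hap2[, marker_ids, drop = FALSE]
  ok <- !apply(is.na(h1), 1, any) & !apply(is.na(h2), 1, any)
  s1 <- apply(h1[ok, , drop = FALSE], 1, paste, collapse = "")
  s2 <- apply(h2[ok, , drop = FALSE], 1, paste, collapse = "")
  tab <- sort(table(c(s1, s2)), decreasing = TRUE)
  freq <- as.numeric(tab) / sum(tab)
  lab <- ifelse(freq < pool_threshold, "OTHER",
                paste0("H", seq_along(tab)))
  names(lab) <- names(tab)
  freq_out <- tapply(freq, lab, sum)
  # order labels: H1, H2, ... then OTHER
  rank_of <- function(nm) if (nm == "OTHER") Inf else as.numeric(sub("H", "", nm))
  ord <- order(vapply(names(freq_out), rank_of, 0))
  freq_out <- freq_out[ord]
  strings <- stats::setNames(names(lab), lab)[names(freq_out)[names(freq_out) != "OTHER"]]
  list(labels1 = stats::setNames(unname(lab[s1]), names(s1)),
       labels2 = stats::setNames(unname(lab[s2]), names(s2)),
       frequencies = freq_out, haplotype_strings = strings,
       n_excluded = sum(!ok))
}

#' Haplotype association model within one block
#'
#' Ordinary least squares of the phenotype on intercept, sex, generation and
#' haplotype-dosage columns (count 0/1/2 of each non-reference label; the
#' most frequent label is the reference). Reports per-label effects and the
#' joint F test of all haplotype terms.
#'
#' @param y numeric phenotype vector aligned with `samples`.
#' @param samples phenotype-table data.frame.
#' @param assignment result of [assign_haplotypes()].
#' @return A list: `effects`, `se`, `pvalues` (named by label), `joint_f`,
#'   `joint_df`, `pvalue`, `n_used`, `frequencies`, `flag`.
#' @export
fit_haplotype_lm <- function(y, samples, assignment) {
  labs <- names(assignment$frequencies)
  if (length(labs) < 2L) stop("need at least 2 haplotype labels")
  ref <- labs[1]
  others <- labs[-1]
  l1 <- assignment$labels1[samples$sample_id]
  l2 <- assignment$labels2[samples$sample_id]
  use <- !is.na(y) & !is.na(l1) & !is.na(l2)
  dose <- vapply(others, function(h)
    (l1[use] == h) + (l2[use] == h), numeric(sum(use)))
  X0 <- base_design(samples[use, , drop = FALSE])
  X <- cbind(X0, dose)
  colnames(X) <- c(colnames(X0), others)
  fit1 <- ols_fit(X, y[use])
  fit0 <- ols_fit(X0, y[use])
  q <- fit1$rank - fit0$rank
  rss1 <- fit1$sigma2 * fit1$df
  rss0 <- fit0$sigma2 * fit0$df
  flag <- if (any(fit1$aliased)) "collinear_labels" else "ok"
  joint_f <- if (q > 0 && fit1$df > 0 && rss1 > 0)
    ((rss0 - rss1) / q) / (rss1 / fit1$df) else NA_real_
  pv <- if (is.finite(joint_f))
    stats::pf(joint_f, q, fit1$df, lower.tail = FALSE) else
      if (!is.na(rss1) && rss1 == 0) 0 else NA_real_
  hap_idx <- match(others, colnames(X))
  tt <- fit1$coef[hap_idx] / fit1$se[hap_idx]
  list(effects = stats::setNames(fit1$coef[hap_idx], others),
       se = stats::setNames(fit1$se[hap_idx], others),
       pvalues = stats::setNames(2 * stats::pt(-abs(tt), fit1$df), others),
       reference = ref, joint_f = joint_f, joint_df = c(q, fit1$df),
       pvalue = pv, n_used = sum(use),
       frequencies = assignment$frequencies, flag = flag)
}

#' Haplotype-block association scan
#'
#' Assigns haplotypes and fits the haplotype association model for every
#' block.
#'
#' @param y numeric phenotype vector aligned with `samples`.
#' @param samples phenotype-table data.frame.
#' @param g a phased [ail_geno] object.
#' @param blocks data.frame from [find_blocks()].
#' @param pool_threshold passed to [assign_haplotypes()].
#' @return data.frame with one row per block: `first_marker`, `last_marker`,
#'   `n_markers`, `n_haplotypes`, `joint_f`, `pvalue`, `neglog10p`, `n_used`.
#' @export
haplotype_scan <- function(y, samples, g, blocks, pool_threshold = 0.01) {
  rows <- lapply(seq_len(nrow(blocks)), function(i) {
    asg <- assign_haplotypes(g, blocks[i, , drop = FALSE], pool_threshold)
    fit <- fit_haplotype_lm(y, samples, asg)
    data.frame(first_marker = blocks$first_marker[i],
               last_marker = blocks$last_marker[i],
               n_markers = blocks$n_markers[i],
               n_haplotypes = length(asg$frequencies),
               joint_f = fit$joint_f, pvalue = fit$pvalue,
               neglog10p = -log10(fit$pvalue), n_used = fit$n_used,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Ancestry-class (donor-breed) association in a segment
#'
#' Uses externally provided ancestry labels (e.g. from haplotype painting)
#' to build donor-breed dosage columns over a genomic segment and fits the
#' same fixed-effects model as [fit_haplotype_lm()]. The donor of each
#' haplotype is taken from the label segment covering the query segment's
#' midpoint.
#'
#' @param y numeric phenotype vector aligned with `samples`.
#' @param samples phenotype-table data.frame.
#' @param labels ancestry label data.frame (see [read_ancestry()]).
#' @param segment `"chrom:start-end"` string or list with `chrom`, `start`,
#'   `end`.
#' @return As [fit_haplotype_lm()], with donor breeds as labels, or a list
#'   with `flag = "skipped_single_donor"` when only one donor class is
#'   present.
#' @export
ancestry_association <- function(y, samples, labels, segment) {
  if (is.character(segment)) segment <- parse_region(segment)
  midpoint <- (segment$start + segment$end) / 2
  seg <- labels[labels$chrom == segment$chrom & labels$start <= midpoint &
                  labels$end >= midpoint, , drop = FALSE]
  donor_of <- function(hap) {
    s <- seg[seg$haplotype == hap, ]
    stats::setNames(s$donor, s$sample_id)[samples$sample_id]
  }
  d1 <- donor_of(1L); d2 <- donor_of(2L)
  if (any(is.na(d1) | is.na(d2)))
    stop("every analyzed sample must be labeled on both haplotypes in the segment")
  donors <- sort(table(c(d1, d2)), decreasing = TRUE)
  if (length(donors) < 2L)
    return(list(flag = "skipped_single_donor",
                frequencies = as.numeric(donors) / sum(donors)))
  asg <- list(labels1 = stats::setNames(d1, samples$sample_id),
              labels2 = stats::setNames(d2, samples$sample_id),
              frequencies = stats::setNames(as.numeric(donors) / sum(donors),
                                            names(donors)))
  fit_haplotype_lm(y, samples, asg)
}
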