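#' Frequency-adjusted single-locus NOIA design
#'
#' Builds the natural and orthogonal interactions (NOIA) statistical design
#' for one locus from observed genotype-class frequencies. The three
#' genotype rows carry a constant mean column, an additive column
#' `x_a(g) = g - (p12 + 2 p22)` and a dominance column
#' `(-2 p12 p22, 4 p11 p22, -2 p11 p12) / (p11 + p22 - (p11 - p22)^2)`.
#' The columns satisfy the frequency-weighted orthogonality identities
#' `sum(p x_a) = sum(p x_d) = sum(p x_a x_d) = 0`, which makes effect
#' estimates invariant to dropping other terms from the model.
#'
#' @param freq numeric length-3 vector `c(p11, p12, p22)` of genotype-class
#'   frequencies (homozygous reference, heterozygous, homozygous
#'   alternative), summing to 1.
#' @return A list of class `noia_design`: `rows` (3x3 matrix, columns
#'   `mean`, `a`, `d`; the dominance column is dropped when its denominator
#'   vanishes), `freq`, and `flag` (`"ok"` or `"additive_only"`).
#' @export
single_locus_design <- function(freq) {
  freq <- as.numeric(freq)
  if (length(freq) != 3L || any(freq < 0) || abs(sum(freq) - 1) > 1e-12)
    stop("freq must be 3 nonnegative genotype frequencies summing to 1")
  if (sum(freq > 0) < 2L)
    stop("need at least two genotype classes with positive frequency")
  p11 <- freq[1]; p12 <- freq[2]; p22 <- freq[3]
  xa <- (0:2) - (p12 + 2 * p22)
  denom <- p11 + p22 - (p11 - p22)^2
  if (abs(denom) < 1e-12) {
    rows <- cbind(mean = rep(1, 3), a = xa)
    return(structure(list(rows = rows, freq = freq, flag = "additive_only"),
                     class = "noia_design"))
  }
  xd <- c(-2 * p12 * p22, 4 * p11 * p22, -2 * p11 * p12) / denom
  rows <- cbind(mean = rep(1, 3), a = xa, d = xd)
  rownames(rows) <- 0:2
  structure(list(rows = rows, freq = freq, flag = "ok"),
            class = "noia_design")
}

#' Reference point of a set of genotype values
#'
#' The NOIA reference point is the frequency-weighted mean of the genotype
#' values: `R = sum(freq * G)`. For two loci, pass the 9 joint genotype
#' values with the Kronecker product of the marginal frequencies.
#'
#' @param freq genotype-class frequencies (any length, summing to 1).
#' @param G genotype values, same length as `freq`.
#' @return The reference point, a single number.
#' @export
reference_point <- function(freq, G) {
  stopifnot(length(freq) == length(G))
  sum(freq * G)
}

#' Two-locus NOIA design via Kronecker combination
#'
#' Rows are the 9 joint genotypes (locus A genotype varying fastest);
#' columns are ordered (mean, a_A, d_A, a_B, d_B, aa, ad, da, dd), where the
#' interaction columns are elementwise products of the single-locus columns
#' (`ad` = additive at A times dominance at B). When a locus admits no
#' dominance column the affected columns are dropped and the design flagged.
#'
#' @param freqA,freqB length-3 genotype-frequency vectors for the two loci.
#' @return A list of class `noia_design`: `rows` (9 x up-to-9 matrix with
#'   rownames `"gA:gB"`), `freqA`, `freqB`, `flag`.
#' @export
two_locus_design <- function(freqA, freqB) {
  dA <- single_locus_design(freqA)
  dB <- single_locus_design(freqB)
  gA <- rep(0:2, times = 3)
  gB <- rep(0:2, each = 3)
  col_of <- function(d, eff, g) {
    if (!eff %in% colnames(d$rows)) return(NULL)
    d$rows[g + 1L, eff]
  }
  cols <- list(mean = rep(1, 9),
               a_A = col_of(dA, "a", gA), d_A = col_of(dA, "d", gA),
               a_B = col_of(dB, "a", gB), d_B = col_of(dB, "d", gB))
  cols$aa <- if (!is.null(cols$a_A) && !is.null(cols$a_B)) cols$a_A * cols$a_B
  cols$ad <- if (!is.null(cols$a_A) && !is.null(cols$d_B)) cols$a_A * cols$d_B
  cols$da <- if (!is.null(cols$d_A) && !is.null(cols$a_B)) cols$d_A * cols$a_B
  cols$dd <- if (!is.null(cols$d_A) && !is.null(cols$d_B)) cols$d_A * cols$d_B
  cols <- cols[!vapply(cols, is.null, TRUE)]
  rows <- do.call(cbind, cols)
  rownames(rows) <- paste(gA, gB, sep = ":")
  flag <- if (dA$flag == "ok" && dB$flag == "ok") "ok" else "reduced"
  structure(list(rows = rows, freqA = freqA, freqB = freqB, flag = flag),
            class = "noia_design")
}

#' Fit the NOIA model of additive, dominance and pairwise epistatic effects
#'
#' Builds a sample-level design from observed per-locus genotype-class
#' frequencies (main additive/dominance columns per locus plus all pairwise
#' interaction products when `order = 2`) and estimates effects by least
#' squares with per-effect t-tests. The phenotype should be normalized
#' within sex-generation groups beforehand. Empty joint-genotype cells can
#' make interaction columns collinear; affected effects are flagged
#' inestimable.
#'
#' @param y_norm normalized phenotype vector aligned with `samples`.
#' @param samples phenotype-table data.frame.
#' @param g an [ail_geno] object.
#' @param markers 2 or more marker ids entering the model.
#' @param order 1 (main effects only) or 2 (plus all pairwise interactions).
#' @return A list of class `noia_effects`: `effects` data.frame (`effect`,
#'   `estimate`, `se`, `stat`, `pvalue`, `flag`), `reference_point`,
#'   `fitted_genotype_values` (length 3 for one locus, a 3x3 matrix for two
#'   loci, `NULL` otherwise), `n_used`, `markers`, `freqs`.
#' @export
fit_noia <- function(y_norm, samples, g, markers, order = 2) {
  stopifnot(inherits(g, "ail_geno"), order %in% 1:2, length(markers) >= 1L)
  calls <- g$calls[samples$sample_id, markers, drop = FALSE]
  use <- !is.na(y_norm) & !apply(is.na(calls), 1L, any)
  calls <- calls[use, , drop = FALSE]
  y <- y_norm[use]

  designs <- lapply(markers, function(mk)
    single_locus_design(genotype_frequencies(calls[, mk])))
  names(designs) <- markers

  X <- cbind(R = rep(1, length(y)))
  for (mk in markers) {
    d <- designs[[mk]]
    X <- cbind(X, d$rows[calls[, mk] + 1L, setdiff(colnames(d$rows), "mean"),
                         drop = FALSE])
    colnames(X)[(ncol(X) - ncol(d$rows) + 2L):ncol(X)] <-
      paste0(setdiff(colnames(d$rows), "mean"), "_", mk)
  }
  if (order == 2 && length(markers) >= 2L) {
    for (i in seq_len(length(markers) - 1L)) for (j in (i + 1L):length(markers)) {
      mA <- markers[i]; mB <- markers[j]
      for (eA in intersect(c("a", "d"), colnames(designs[[mA]]$rows)))
        for (eB in intersect(c("a", "d"), colnames(designs[[mB]]$rows))) {
          cn <- paste0(eA, eB, "_", mA, "_", mB)
          X <- cbind(X, designs[[mA]]$rows[calls[, mA] + 1L, eA] *
                       designs[[mB]]$rows[calls[, mB] + 1L, eB])
          colnames(X)[ncol(X)] <- cn
        }
    }
  }

  fit <- ols_fit(X, y)
  stat <- fit$coef / fit$se
  pv <- 2 * stats::pt(-abs(stat), df = fit$df)
  effects <- data.frame(effect = colnames(X), estimate = unname(fit$coef),
                        se = unname(fit$se), stat = unname(stat),
                        pvalue = unname(pv),
                        flag = ifelse(is.na(fit$coef), "inestimable", "ok"),
                        stringsAsFactors = FALSE)

  fitted_G <- NULL
  coef0 <- ifelse(is.na(fit$coef), 0, fit$coef)
  if (length(markers) == 1L) {
    d <- designs[[1]]
    rows <- d$rows
    colnames(rows) <- c("R", paste0(setdiff(colnames(rows), "mean"), "_",
                                    markers))[seq_len(ncol(rows))]
    fitted_G <- as.numeric(rows %*% coef0[colnames(rows)])
    names(fitted_G) <- 0:2
  } else if (length(markers) == 2L && order == 2) {
    d2 <- two_locus_design(designs[[1]]$freq, designs[[2]]$freq)
    rn <- colnames(d2$rows)
    map_names <- c(mean = "R",
                   a_A = paste0("a_", markers[1]), d_A = paste0("d_", markers[1]),
                   a_B = paste0("a_", markers[2]), d_B = paste0("d_", markers[2]),
                   aa = paste0("aa_", markers[1], "_", markers[2]),
                   ad = paste0("ad_", markers[1], "_", markers[2]),
                   da = paste0("da_", markers[1], "_", markers[2]),
                   dd = paste0("dd_", markers[1], "_", markers[2]))
    cn <- map_names[rn]
    present <- cn %in% names(coef0)
    G <- as.numeric(d2$rows[, present, drop = FALSE] %*% coef0[cn[present]])
    fitted_G <- matrix(G, 3, 3, dimnames = list(A = 0:2, B = 0:2))
  }

  structure(list(effects = effects, reference_point = unname(fit$coef["R"]),
                 fitted_genotype_values = fitted_G, n_used = length(y),
                 markers = markers,
                 freqs = lapply(designs, `[[`, "freq")),
            class = "noia_effects")
}

#' Pairwise NOIA interaction network over a marker set
#'
#' Fits the two-locus NOIA model for every marker pair and collects the
#' interaction effects (aa, ad, da, dd) with per-coefficient t-test
#' p-values. A Bonferroni-adjusted column over all reported interaction
#' tests is included.
#'
#' @inheritParams fit_noia
#' @param markers 2 or more marker ids.
#' @return data.frame with columns `marker_i`, `marker_j`, `type`,
#'   `estimate`, `se`, `pvalue`, `p_bonferroni`, sorted by p-value.
#' @export
pairwise_interaction_network <- function(y_norm, samples, g, markers) {
  stopifnot(length(markers) >= 2L)
  rows <- list()
  for (i in seq_len(length(markers) - 1L)) for (j in (i + 1L):length(markers)) {
    fit <- fit_noia(y_norm, samples, g, c(markers[i], markers[j]), order = 2)
    eff <- fit$effects
    int <- eff[grepl("^(aa|ad|da|dd)_", eff$effect), , drop = FALSE]
    if (nrow(int) == 0L) next
    rows[[length(rows) + 1L]] <- data.frame(
      marker_i = markers[i], marker_j = markers[j],
      type = sub("_.*$", "", int$effect),
      estimate = int$estimate, se = int$se, pvalue = int$pvalue,
      flag = int$flag, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$pvalue * sum(!is.na(out$pvalue)))
  out[order(out$pvalue), , drop = FALSE]
}

#' Genotype-stratified conditional association scan
#'
#' Stratifies samples by genotype at a conditioning marker and reruns the
#' single-marker scan within each stratum. Because phenotypes are normalized
#' within sex-generation groups beforehand, the default within-stratum model
#' is intercept plus marker; `refit_covariates = TRUE` refits sex and
#' generation inside each stratum instead. Also returns the two-locus 3x3
#' grids of phenotype mean, SD and count against a focal marker, the summary
#' used to visualize masking epistasis.
#'
#' @inheritParams fit_noia
#' @param conditioning_marker marker id whose genotype defines the strata.
#' @param scan_markers marker ids to scan within each stratum (`NULL` scans
#'   the whole panel).
#' @param focal_marker marker id for the 3x3 grid (default: the scan marker
#'   with the smallest p-value in the largest stratum).
#' @param min_class_n strata smaller than this are omitted with a flag.
#' @param refit_covariates logical; see above.
#' @return A list of class `conditional_scan`: `conditioning_marker`,
#'   `strata` (named list over genotypes "0","1","2" of scan data.frames, or
#'   the string `"omitted"`), `stratum_counts`, `focal_marker`, `grid_mean`,
#'   `grid_sd`, `grid_count` (3x3 matrices, conditioning genotype in rows).
#' @export
conditional_scan <- function(y_norm, samples, g, conditioning_marker,
                             scan_markers = NULL, focal_marker = NULL,
                             min_class_n = 10L, refit_covariates = FALSE) {
  if (is.null(scan_markers))
    scan_markers <- setdiff(g$map$marker_id, conditioning_marker)
  cgeno <- g$calls[samples$sample_id, conditioning_marker]
  usable <- !is.na(y_norm) & !is.na(cgeno)
  counts <- vapply(0:2, function(k) sum(usable & cgeno == k), 0L)
  names(counts) <- 0:2
  if (sum(counts >= min_class_n) < 2L)
    stop("conditioning marker has fewer than 2 genotype classes of size >= ",
         min_class_n)

  strata <- list()
  for (k in 0:2) {
    key <- as.character(k)
    if (counts[key] < min_class_n) {
      strata[[key]] <- "omitted"
      next
    }
    idx <- which(usable & cgeno == k)
    s_sub <- samples[idx, , drop = FALSE]
    if (!refit_covariates) {
      # phenotype already normalized: collapse covariates to intercept-only
      s_sub$sex <- "F"
      s_sub$generation <- 0L
    }
    strata[[key]] <- gwas_scan(y_norm[idx], s_sub, g, markers = scan_markers)
  }

  if (is.null(focal_marker)) {
    big <- names(which.max(counts))
    sc <- strata[[big]]
    focal_marker <- sc$marker_id[which.min(sc$pvalue)]
  }
  fgeno <- g$calls[samples$sample_id, focal_marker]
  grid_mean <- grid_sd <- grid_count <- matrix(
    NA_real_, 3, 3, dimnames = list(cond = 0:2, focal = 0:2))
  for (a in 0:2) for (b in 0:2) {
    yy <- y_norm[usable & cgeno == a & !is.na(fgeno) & fgeno == b]
    grid_count[a + 1L, b + 1L] <- length(yy)
    if (length(yy) > 0L) grid_mean[a + 1L, b + 1L] <- mean(yy)
    if (length(yy) > 1L) grid_sd[a + 1L, b + 1L] <- stats::sd(yy)
  }
  structure(list(conditioning_marker = conditioning_marker, strata = strata,
                 stratum_counts = counts, focal_marker = focal_marker,
                 grid_mean = grid_mean, grid_sd = grid_sd,
                 grid_count = grid_count),
            class = "conditional_scan")
}
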