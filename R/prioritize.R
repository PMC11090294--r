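#' Conservation-score percentile threshold (nearest rank)
#'
#' Returns the value such that the fraction of scores greater than or equal
#' to it is `q`: the `ceiling(q * n)`-th largest score.
#'
#' @param scores numeric vector of per-marker conservation scores (non-finite
#'   values dropped).
#' @param q upper-tail fraction (default 0.05, the "top 5%").
#' @return The threshold score.
#' @export
conservation_percentile_threshold <- function(scores, q = 0.05) {
  scores <- scores[is.finite(scores)]
  if (length(scores) == 0L) stop("no finite conservation scores")
  k <- max(1L, ceiling(q * length(scores)))
  sort(scores, decreasing = TRUE)[k]
}

#' Assemble a candidate-variant table
#'
#' Joins an association scan, annotations and conservation scores into one
#' table, one row per marker. Minor allele frequency is computed from
#' analysis-cohort genotypes when `g` is supplied, otherwise from the
#' annotation table's alternative-allele frequency.
#'
#' @param scan data.frame from [gwas_scan()].
#' @param annotations data.frame from [read_vcf()]`$annotations`.
#' @param conservation data.frame with `marker_id`, `phylop`.
#' @param g optional [ail_geno] for cohort-based allele frequencies.
#' @return data.frame with columns `marker_id`, `pos`, `neglog10p`,
#'   `phylop`, `aaf`, `maf`, `effect_category`, `gene_name`,
#'   `transcript_change`, `protein_change`.
#' @export
candidate_table <- function(scan, annotations, conservation, g = NULL) {
  ai <- match(scan$marker_id, annotations$marker_id)
  ci <- match(scan$marker_id, conservation$marker_id)
  aaf <- if (!is.null(g)) {
    vapply(scan$marker_id, function(mk)
      allele_frequencies(g, mk)$alt_freq, 0)
  } else annotations$aaf[ai]
  data.frame(marker_id = scan$marker_id, pos = scan$pos,
             neglog10p = scan$neglog10p,
             phylop = conservation$phylop[ci],
             aaf = aaf, maf = pmin(aaf, 1 - aaf),
             effect_category = annotations$effect_category[ai],
             gene_name = annotations$gene_name[ai],
             transcript_change = annotations$transcript_change[ai],
             protein_change = annotations$protein_change[ai],
             stringsAsFactors = FALSE)
}

#' Filter and rank candidate variants
#'
#' Keeps rows with minor allele frequency above `maf_min` and a conservation
#' score in the top `phylop_q` fraction of the supplied rows (or above an
#' explicit `phylop_threshold`), then sorts by association p-value
#' (descending `neglog10p`), breaking ties by position. Idempotent.
#'
#' @param rows candidate table (see [candidate_table()]).
#' @param maf_min minimum minor allele frequency, exclusive (default 0.1).
#' @param phylop_q top conservation fraction (default 0.05).
#' @param phylop_threshold optional explicit threshold overriding `phylop_q`
#'   (e.g. computed genome-wide rather than over the analyzed region).
#' @return The filtered, sorted subset of `rows`.
#' @export
candidate_filter <- function(rows, maf_min = 0.1, phylop_q = 0.05,
                             phylop_threshold = NULL) {
  if (nrow(rows) == 0L) return(rows)
  if (is.null(phylop_threshold))
    phylop_threshold <- conservation_percentile_threshold(rows$phylop, phylop_q)
  keep <- !is.na(rows$maf) & rows$maf > maf_min &
    !is.na(rows$phylop) & rows$phylop >= phylop_threshold
  out <- rows[keep, , drop = FALSE]
  out[order(-out$neglog10p, out$pos), , drop = FALSE]
}

#' Missense candidate table
#'
#' Subsets candidates annotated `missense_variant`, applies the top-fraction
#' conservation filter (threshold computed over all supplied rows), and
#' sorts by association p-value.
#'
#' @inheritParams candidate_filter
#' @return The filtered, sorted missense subset.
#' @export
missense_table <- function(rows, phylop_q = 0.05, phylop_threshold = NULL) {
  if (nrow(rows) == 0L) return(rows)
  if (is.null(phylop_threshold))
    phylop_threshold <- conservation_percentile_threshold(rows$phylop, phylop_q)
  keep <- rows$effect_category == "missense_variant" &
    !is.na(rows$phylop) & rows$phylop >= phylop_threshold
  out <- rows[keep, , drop = FALSE]
  out[order(-out$neglog10p, out$pos), , drop = FALSE]
}
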