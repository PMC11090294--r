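#' Genotype matrix with marker map and optional phase
#'
#' Container used throughout the package: an integer matrix of
#' alternative-allele counts (samples in rows, markers in columns; `NA` for
#' missing calls), a marker map, and optionally the two phased haplotypes.
#'
#' @param calls integer matrix in \{0, 1, 2, NA\}; rownames are sample ids,
#'   colnames are marker ids.
#' @param map data.frame with columns `marker_id`, `chrom`, `pos` (1-based),
#'   `ref`, `alt`; one row per column of `calls`, positions strictly
#'   increasing within each chromosome.
#' @param hap1,hap2 optional 0/1 matrices of the same dimension as `calls`
#'   giving the two haplotype alleles; `hap1 + hap2` must equal `calls`
#'   wherever calls are non-missing.
#'
#' @return An object of class `ail_geno`: a list with elements `calls`,
#'   `map`, `hap1`, `hap2` (the latter two possibly `NULL`).
#' @export
ail_geno <- function(calls, map, hap1 = NULL, hap2 = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(rownames(calls)) || is.null(colnames(calls)))
    stop("calls must have sample rownames and marker colnames")
  bad <- !is.na(calls) & !(calls %in% 0:2)
  if (any(bad)) stop("genotype calls must be 0, 1, 2 or NA")
  if (anyDuplicated(rownames(calls))) stop("duplicate sample ids")
  if (anyDuplicated(colnames(calls))) stop("duplicate marker ids")
  map <- as.data.frame(map)
  need <- c("marker_id", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(map))) stop("map must have columns: ", paste(need, collapse = ", "))
  if (nrow(map) != ncol(calls) || !identical(as.character(map$marker_id), colnames(calls)))
    stop("map rows must match calls columns (same markers, same order)")
  for (ch in unique(map$chrom)) {
    p <- map$pos[map$chrom == ch]
    if (any(diff(p) <= 0)) stop("positions must be strictly increasing within chromosome ", ch)
  }
  if (any(map$ref == map$alt)) stop("ref and alt alleles must differ")
  if (xor(is.null(hap1), is.null(hap2))) stop("provide both haplotypes or neither")
  if (!is.null(hap1)) {
    hap1 <- as.matrix(hap1); hap2 <- as.matrix(hap2)
    storage.mode(hap1) <- "integer"; storage.mode(hap2) <- "integer"
    if (!all(dim(hap1) == dim(calls)) || !all(dim(hap2) == dim(calls)))
      stop("haplotype matrices must match calls dimensions")
    s <- hap1 + hap2
    ok <- is.na(calls) | (!is.na(s) & s == calls)
    if (!all(ok)) stop("haplotype allele pairs must sum to the unphased call")
    dimnames(hap1) <- dimnames(calls); dimnames(hap2) <- dimnames(calls)
  }
  structure(list(calls = calls, map = map, hap1 = hap1, hap2 = hap2),
            class = "ail_geno")
}

#' @export
print.ail_geno <- function(x, ...) {
  cat(sprintf("ail_geno: %d samples x %d markers (%s, %sphased)\n",
              nrow(x$calls), ncol(x$calls),
              paste(unique(x$map$chrom), collapse = ","),
              if (is.null(x$hap1)) "un" else ""))
  invisible(x)
}

#' @export
dim.ail_geno <- function(x) dim(x$calls)

#' Subset a genotype object by samples and/or markers
#'
#' @param g an `ail_geno` object.
#' @param samples,markers character vectors of ids (or logical/integer
#'   indices); `NULL` keeps all.
#' @return An `ail_geno` restricted to the requested samples and markers.
#' @export
subset_geno <- function(g, samples = NULL, markers = NULL) {
  stopifnot(inherits(g, "ail_geno"))
  si <- if (is.null(samples)) seq_len(nrow(g$calls)) else samples
  mi <- if (is.null(markers)) seq_len(ncol(g$calls)) else markers
  calls <- g$calls[si, mi, drop = FALSE]
  if (is.character(mi)) mi <- match(mi, g$map$marker_id)
  if (is.logical(mi)) mi <- which(mi)
  map <- g$map[mi, , drop = FALSE]
  rownames(map) <- NULL
  h1 <- if (is.null(g$hap1)) NULL else g$hap1[si, colnames(calls), drop = FALSE]
  h2 <- if (is.null(g$hap2)) NULL else g$hap2[si, colnames(calls), drop = FALSE]
  ail_geno(calls, map, h1, h2)
}

#' Allele frequencies and genotype counts at one marker
#'
#' Computes reference and alternative allele frequencies from genotype calls,
#' optionally within a subset of samples. The alternative-allele frequency is
#' `(n_het + 2 * n_altalt) / (2 * n_nonmissing)`.
#'
#' @param g an `ail_geno` object.
#' @param marker a marker id present in `g`.
#' @param subset optional character vector of sample ids (or indices).
#' @return A list with `ref_freq`, `alt_freq` (summing to 1) and
#'   `genotype_counts`, a named vector `c(RR =, RA =, AA =)`.
#' @export
allele_frequencies <- function(g, marker, subset = NULL) {
  stopifnot(inherits(g, "ail_geno"))
  if (!marker %in% colnames(g$calls)) stop("marker not found: ", marker)
  x <- g$calls[, marker]
  if (!is.null(subset)) x <- x[subset]
  x <- x[!is.na(x)]
  if (length(x) == 0L) stop("allele frequency uncomputable: all calls missing at ", marker)
  cnt <- c(RR = sum(x == 0L), RA = sum(x == 1L), AA = sum(x == 2L))
  alt <- (cnt[["RA"]] + 2 * cnt[["AA"]]) / (2 * length(x))
  list(ref_freq = 1 - alt, alt_freq = alt, genotype_counts = cnt)
}

#' Genotype-class frequencies at one marker
#'
#' @param g an `ail_geno` object (or an integer genotype vector).
#' @param marker marker id, ignored when `g` is a vector.
#' @return Numeric vector `c(p11, p12, p22)` of observed genotype-class
#'   frequencies among non-missing calls (homozygous reference,
#'   heterozygous, homozygous alternative).
#' @export
genotype_frequencies <- function(g, marker = NULL) {
  x <- if (inherits(g, "ail_geno")) g$calls[, marker] else g
  x <- x[!is.na(x)]
  if (length(x) == 0L) stop("no non-missing calls")
  c(p11 = mean(x == 0), p12 = mean(x == 1), p22 = mean(x == 2))
}
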