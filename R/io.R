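#' Read genotypes (and optional annotation) from a VCF file
#'
#' Reads a VCF 4.x file, keeps biallelic SNP records only (indels and
#' multi-allelic sites are skipped and counted), and codes genotypes as
#' counts of the alternative allele. REF/ALT are taken from the file and
#' never re-polarized. When every non-missing genotype in the file is phased
#' (`|` separator), the two haplotypes are retained; otherwise calls are
#' unphased. Functional annotation is parsed from the standard `ANN` INFO
#' field when present.
#'
#' @param path path to a VCF file (plain text or gzipped).
#' @param region optional `"chrom:start-end"` string restricting markers by
#'   position (1-based, inclusive).
#' @return A list with elements:
#'   \describe{
#'     \item{geno}{an [ail_geno] object,}
#'     \item{annotations}{data.frame with one row per kept marker:
#'       `marker_id`, `effect_category`, `gene_name`, `transcript_change`,
#'       `protein_change`, `aaf` (empty strings where no ANN field),}
#'     \item{n_skipped}{number of records dropped as non-biallelic-SNP.}
#'   }
#' @export
read_vcf <- function(path, region = NULL) {
  if (!file.exists(path)) stop("cannot read VCF: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix_raw <- vcfR::getFIX(v)
  if (is.null(dim(fix_raw))) fix_raw <- t(fix_raw)
  fix <- as.data.frame(fix_raw, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) stop("VCF contains no variant records")

  is_snp <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T") &
    !grepl(",", fix$ALT, fixed = TRUE)
  is_snp[is.na(is_snp)] <- FALSE
  n_skipped <- sum(!is_snp)
  if (n_skipped > 0)
    message(n_skipped, " non-biallelic-SNP record(s) skipped")

  keep <- which(is_snp)
  if (!is.null(region)) {
    reg <- parse_region(region)
    pos <- as.integer(fix$POS)
    keep <- keep[fix$CHROM[keep] == reg$chrom &
                   pos[keep] >= reg$start & pos[keep] <= reg$end]
  }
  if (length(keep) == 0L) stop("no biallelic SNP records retained")

  fix <- fix[keep, , drop = FALSE]
  marker_id <- ifelse(is.na(fix$ID) | fix$ID == ".",
                      paste(fix$CHROM, fix$POS, sep = "_"), fix$ID)

  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  if (is.null(dim(gt)) || ncol(gt) == 0L) stop("VCF contains no samples")
  samples <- colnames(gt)

  a1 <- substr(gt, 1, 1)
  sep <- substr(gt, 2, 2)
  a2 <- substr(gt, 3, 3)
  a1n <- suppressWarnings(as.integer(a1))
  a2n <- suppressWarnings(as.integer(a2))
  calls <- a1n + a2n
  calls[is.na(gt) | a1 == "." | a2 == "."] <- NA_integer_
  calls <- t(matrix(calls, nrow = nrow(gt), ncol = ncol(gt)))
  rownames(calls) <- samples
  colnames(calls) <- marker_id

  phased <- all(sep[!is.na(gt) & a1 != "."] == "|")
  h1 <- h2 <- NULL
  if (phased && !anyNA(calls)) {
    h1 <- t(matrix(a1n, nrow = nrow(gt), ncol = ncol(gt)))
    h2 <- t(matrix(a2n, nrow = nrow(gt), ncol = ncol(gt)))
    dimnames(h1) <- dimnames(calls); dimnames(h2) <- dimnames(calls)
  }

  map <- data.frame(marker_id = marker_id, chrom = fix$CHROM,
                    pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT,
                    stringsAsFactors = FALSE)
  geno <- ail_geno(calls, map, h1, h2)

  ann <- tryCatch(vcfR::extract.info(v, element = "ANN")[keep],
                  error = function(e) rep(NA_character_, length(keep)))
  annotations <- parse_ann_field(marker_id, ann, calls)

  list(geno = geno, annotations = annotations, n_skipped = n_skipped)
}

parse_region <- function(region) {
  m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
  if (length(m) != 4L) stop("region must be 'chrom:start-end', got: ", region)
  list(chrom = m[2], start = as.integer(m[3]), end = as.integer(m[4]))
}

# ANN subfields follow the snpEff convention:
# Allele|Annotation|Impact|Gene_Name|Gene_ID|Feature_Type|Feature_ID|
# Biotype|Rank|HGVS.c|HGVS.p|...
parse_ann_field <- function(marker_id, ann, calls) {
  get_field <- function(x, i) {
    x <- as.character(x)
    out <- rep("", length(x))
    has <- !is.na(x) & x != ""
    if (!any(has)) return(out)
    first <- vapply(strsplit(x[has], ",", fixed = TRUE), `[`, "", 1L)
    parts <- strsplit(first, "|", fixed = TRUE)
    out[has] <- vapply(parts, function(p) if (length(p) >= i) p[i] else "", "")
    out
  }
  aaf <- colMeans(calls, na.rm = TRUE) / 2
  data.frame(marker_id = marker_id,
             effect_category = get_field(ann, 2L),
             gene_name = get_field(ann, 4L),
             transcript_change = get_field(ann, 10L),
             protein_change = get_field(ann, 11L),
             aaf = as.numeric(aaf),
             stringsAsFactors = FALSE)
}

#' Write a genotype object to a plain-text VCF file
#'
#' Emits a minimal VCF 4.2 file with GT as the only FORMAT field. Haplotypes
#' are written phased (`|`) when phase is stored, otherwise unphased.
#'
#' @param g an [ail_geno] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path) {
  stopifnot(inherits(g, "ail_geno"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(g$calls)), collapse = "\t")),
             con)
  phased <- !is.null(g$hap1)
  sep <- if (phased) "|" else "/"
  for (j in seq_len(ncol(g$calls))) {
    if (phased) {
      gt <- paste0(g$hap1[, j], sep, g$hap2[, j])
      gt[is.na(g$calls[, j])] <- paste0(".", sep, ".")
    } else {
      gt <- c("0/0", "0/1", "1/1")[g$calls[, j] + 1L]
      gt[is.na(g$calls[, j])] <- "./."
    }
    writeLines(paste(c(g$map$chrom[j], g$map$pos[j], g$map$marker_id[j],
                       g$map$ref[j], g$map$alt[j], ".", "PASS", ".", "GT", gt),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a tab-separated phenotype table
#'
#' Expected header: `sample_id`, `sex`, `generation`, `bw8` (a `line` column
#' is optional). Sex codes must be `F` or `M`; `bw8` values that do not parse
#' as numbers become missing.
#'
#' @param path path to the table.
#' @return data.frame with columns `sample_id`, `sex`, `generation`
#'   (integer), `line`, `bw8` (numeric, `NA` where missing).
#' @export
read_phenotypes <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, colClasses = "character")
  need <- c("sample_id", "sex", "generation", "bw8")
  if (!all(need %in% names(d)))
    stop("phenotype table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(d$sample_id))
    stop("duplicate sample_id in phenotype table: ",
         d$sample_id[duplicated(d$sample_id)][1])
  if (!all(d$sex %in% c("F", "M")))
    stop("unknown sex code: ", setdiff(d$sex, c("F", "M"))[1])
  bw8 <- suppressWarnings(as.numeric(d$bw8))
  gen <- as.integer(d$generation)
  if (anyNA(gen) || any(gen < 0)) stop("generation must be a nonnegative integer")
  data.frame(sample_id = d$sample_id, sex = d$sex, generation = gen,
             line = if ("line" %in% names(d)) d$line else NA_character_,
             bw8 = bw8, stringsAsFactors = FALSE)
}

#' Write a phenotype table
#' @param samples data.frame as returned by [read_phenotypes()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(samples, path) {
  out <- samples[, intersect(c("sample_id", "sex", "generation", "line", "bw8"),
                             names(samples))]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated pedigree table
#'
#' Expected header: `sample_id`, `sire_id`, `dam_id`, `generation`. Founders
#' have empty or `NA` parents.
#'
#' @param path path to the table.
#' @return data.frame with those four columns.
#' @export
read_pedigree <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("sample_id", "sire_id", "dam_id", "generation")
  if (!all(need %in% names(d)))
    stop("pedigree table must have columns: ", paste(need, collapse = ", "))
  d$generation <- as.integer(d$generation)
  d
}

#' Write a pedigree table
#' @param ped data.frame with columns `sample_id`, `sire_id`, `dam_id`,
#'   `generation`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  utils::write.table(ped, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-marker conservation score table
#'
#' Expected header: `marker_id`, `phylop`.
#'
#' @param path path to the table.
#' @return data.frame with columns `marker_id` and `phylop` (numeric).
#' @export
read_conservation <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (!all(c("marker_id", "phylop") %in% names(d)))
    stop("conservation table must have columns marker_id, phylop")
  d$phylop <- as.numeric(d$phylop)
  d
}

#' Read an ancestry (donor-breed) label table
#'
#' One row per (sample, haplotype, segment): columns `sample_id`, `chrom`,
#' `start`, `end` (1-based inclusive), `haplotype` (1 or 2) and `donor`
#' (breed label). Labels of this kind are produced by external haplotype
#' painting software and consumed here as-is.
#'
#' @param path path to the table.
#' @return data.frame with the columns above.
#' @export
read_ancestry <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("sample_id", "chrom", "start", "end", "haplotype", "donor")
  if (!all(need %in% names(d)))
    stop("ancestry table must have columns: ", paste(need, collapse = ", "))
  if (!all(d$haplotype %in% 1:2)) stop("haplotype must be 1 or 2")
  d$start <- as.integer(d$start); d$end <- as.integer(d$end)
  d
}

#' Write an association/scan result table
#' @param x data.frame of results.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scan <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
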