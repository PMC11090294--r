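#' Trait architecture for the AIL simulator
#'
#' Specifies the genetic and non-genetic determinants of the simulated
#' phenotype (8-week body weight, grams): fixed effects of sex and
#' generation, additive and dominance marker effects, explicit two-locus
#' epistatic genotype-value grids, variance-heterogeneity loci acting as
#' multipliers on the residual standard deviation, and the baseline residual
#' standard deviation.
#'
#' @param intercept baseline weight in grams.
#' @param sex_effect additional grams for males.
#' @param generation_effects named numeric vector (names are generation
#'   numbers) of grams added per generation; `NULL` gives a mild linear
#'   trend of 2 g per generation so the generation covariate is
#'   non-degenerate.
#' @param additive named numeric vector, grams per alternative allele.
#' @param dominance named numeric vector, grams added to heterozygotes.
#' @param epistatic_pairs list of `list(markers = c(idA, idB), grid = 3x3
#'   matrix)` where `grid[gA + 1, gB + 1]` is the value (grams) added for
#'   joint genotype (gA, gB).
#' @param vqtl named list: marker id -> numeric length-3 vector of positive
#'   residual-SD multipliers for genotypes 0, 1, 2.
#' @param residual_sd baseline residual standard deviation in grams.
#' @return A list of class `trait_architecture`.
#' @export
trait_architecture <- function(intercept = 850, sex_effect = 120,
                               generation_effects = NULL,
                               additive = numeric(0), dominance = numeric(0),
                               epistatic_pairs = list(), vqtl = list(),
                               residual_sd = 90) {
  if (residual_sd < 0) stop("residual_sd must be nonnegative")
  for (v in vqtl) {
    if (length(v) != 3L || any(v <= 0)) stop("vqtl multipliers must be 3 positive values")
  }
  for (ep in epistatic_pairs) {
    if (length(ep$markers) != 2L || !all(dim(as.matrix(ep$grid)) == c(3, 3)))
      stop("epistatic pair needs 2 marker ids and a 3x3 grid")
  }
  structure(list(intercept = intercept, sex_effect = sex_effect,
                 generation_effects = generation_effects,
                 additive = additive, dominance = dominance,
                 epistatic_pairs = epistatic_pairs, vqtl = vqtl,
                 residual_sd = residual_sd),
            class = "trait_architecture")
}

#' Configuration of a synthetic advanced intercross line
#'
#' Defaults emulate the scale of a two-line divergent-selection intercross:
#' 20 founders per line, an F1 of 40 birds, intercross generations F2-F18 of
#' 175 birds each (about 3,000 phenotyped individuals) and 2,000 markers
#' evenly spaced on one 100-cM chromosome.
#'
#' @param seed integer seed; fully determines the simulation.
#' @param n_founders_per_line founders per selected line.
#' @param n_f1 size of the F1.
#' @param n_per_generation named integer vector (names = generation numbers
#'   2, 3, ...) of intercross generation sizes.
#' @param n_markers number of biallelic markers.
#' @param map_positions increasing centimorgan positions; `NULL` gives even
#'   spacing over `chrom_length_cm`.
#' @param chrom_length_cm chromosome length in centimorgans.
#' @param founder_freq_high,founder_freq_low per-marker alternative-allele
#'   frequencies in the two founder lines; `NULL` draws them independently
#'   from Uniform(0.05, 0.95) when founders are simulated.
#' @param architecture a [trait_architecture()].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_founders_per_line = 20L, n_f1 = 40L,
                       n_per_generation = NULL, n_markers = 2000L,
                       map_positions = NULL, chrom_length_cm = 100,
                       founder_freq_high = NULL, founder_freq_low = NULL,
                       architecture = trait_architecture()) {
  if (is.null(n_per_generation))
    n_per_generation <- stats::setNames(rep(175L, 17), 2:18)
  if (is.null(map_positions))
    map_positions <- seq(0, chrom_length_cm, length.out = n_markers)
  if (any(diff(map_positions) < 0)) stop("map positions must be increasing")
  if (length(map_positions) != n_markers) stop("map_positions length must equal n_markers")
  for (f in list(founder_freq_high, founder_freq_low))
    if (!is.null(f) && (any(f < 0) || any(f > 1) || length(f) != n_markers))
      stop("founder frequencies must be length n_markers, in [0,1]")
  if (n_founders_per_line < 1L || n_f1 < 2L || any(n_per_generation < 1L))
    stop("all cohort sizes must be positive (and n_f1 >= 2)")
  structure(list(seed = as.integer(seed),
                 n_founders_per_line = as.integer(n_founders_per_line),
                 n_f1 = as.integer(n_f1),
                 n_per_generation = n_per_generation,
                 n_markers = as.integer(n_markers),
                 map_positions = map_positions,
                 chrom_length_cm = chrom_length_cm,
                 founder_freq_high = founder_freq_high,
                 founder_freq_low = founder_freq_low,
                 architecture = architecture),
            class = "sim_config")
}

default_marker_map <- function(cfg) {
  n <- cfg$n_markers
  # physical positions: 15 kb per marker, arbitrary but fixed scale
  data.frame(marker_id = sprintf("m%04d", seq_len(n)), chrom = "chr1",
             pos = as.integer(seq_len(n)) * 15000L,
             ref = rep_len(c("A", "C", "G", "T"), n),
             alt = rep_len(c("G", "T", "A", "C"), n),
             stringsAsFactors = FALSE)
}

#' Simulate divergent founder lines
#'
#' Each founder haplotype allele is drawn independently per marker from its
#' line's alternative-allele frequency. Lines are labeled HIGH and LOW and
#' sexes are balanced within each line.
#'
#' @param cfg a [sim_config()].
#' @return List with `geno` (phased [ail_geno]), `samples` (phenotype-table
#'   data.frame, `bw8` missing), and the realized `freq_high` / `freq_low`
#'   per-marker frequencies.
#' @export
simulate_founders <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_founders_per_line
  m <- cfg$n_markers
  fh <- cfg$founder_freq_high
  fl <- cfg$founder_freq_low
  if (is.null(fh)) fh <- stats::runif(m, 0.05, 0.95)
  if (is.null(fl)) fl <- stats::runif(m, 0.05, 0.95)

  draw_line <- function(freq, n_ind) {
    h1 <- matrix(stats::rbinom(n_ind * m, 1L, rep(freq, each = n_ind)), n_ind, m)
    h2 <- matrix(stats::rbinom(n_ind * m, 1L, rep(freq, each = n_ind)), n_ind, m)
    list(h1 = h1, h2 = h2)
  }
  hi <- draw_line(fh, n)
  lo <- draw_line(fl, n)
  h1 <- rbind(hi$h1, lo$h1)
  h2 <- rbind(hi$h2, lo$h2)
  ids <- c(sprintf("H%03d", seq_len(n)), sprintf("L%03d", seq_len(n)))
  map <- default_marker_map(cfg)
  dimnames(h1) <- list(ids, map$marker_id)
  dimnames(h2) <- list(ids, map$marker_id)
  geno <- ail_geno(h1 + h2, map, h1, h2)
  sex <- rep(rep_len(c("M", "F"), n), 2)
  samples <- data.frame(sample_id = ids, sex = sex, generation = 0L,
                        line = rep(c("HIGH", "LOW"), each = n),
                        bw8 = NA_real_, stringsAsFactors = FALSE)
  list(geno = geno, samples = samples, freq_high = fh, freq_low = fl)
}

#' Simulate one meiosis (gamete formation) under the Haldane model
#'
#' Crossover counts between chromosome ends follow a Poisson distribution
#' with mean equal to the map length in Morgans; crossover positions are
#' uniform and interference-free. The gamete copies one parental haplotype
#' and switches source at each crossover.
#'
#' @param h1,h2 integer vectors: the parent's two haplotypes.
#' @param map_cm increasing centimorgan positions, one per marker.
#' @return Integer vector: the gamete haplotype.
#' @export
meiosis <- function(h1, h2, map_cm) {
  L <- map_cm[length(map_cm)] - map_cm[1]
  n_xo <- if (L > 0) stats::rpois(1L, L / 100) else 0L
  start <- stats::rbinom(1L, 1L, 0.5)
  if (n_xo == 0L) return(if (start == 0L) h1 else h2)
  xo <- sort(stats::runif(n_xo, map_cm[1], map_cm[length(map_cm)]))
  seg <- findInterval(map_cm, xo)
  use2 <- (seg + start) %% 2L == 1L
  out <- h1
  out[use2] <- h2[use2]
  out
}

#' Simulate the multigenerational intercross pedigree and genotypes
#'
#' The F1 is formed by HIGH x LOW crosses; each later generation is produced
#' by random mating within the previous generation, avoiding full-sib pairs.
#' There is no selection after the founder generation.
#'
#' @param cfg a [sim_config()].
#' @param founders result of [simulate_founders()].
#' @return List with `geno` (phased [ail_geno] over all individuals,
#'   founders first), `samples` and `pedigree` data.frames.
#' @export
simulate_pedigree <- function(cfg, founders) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  map_cm <- cfg$map_positions
  fg <- founders$geno
  n_total <- nrow(fg$calls) + cfg$n_f1 + sum(cfg$n_per_generation)
  m <- cfg$n_markers
  H1 <- matrix(NA_integer_, n_total, m)
  H2 <- matrix(NA_integer_, n_total, m)
  nf <- nrow(fg$calls)
  H1[seq_len(nf), ] <- fg$hap1
  H2[seq_len(nf), ] <- fg$hap2
  ids <- character(n_total)
  ids[seq_len(nf)] <- rownames(fg$calls)
  sex <- character(n_total); sex[seq_len(nf)] <- founders$samples$sex
  gen <- integer(n_total)
  sire <- rep(NA_character_, n_total); dam <- rep(NA_character_, n_total)

  gens <- c(1L, as.integer(names(cfg$n_per_generation)))
  sizes <- c(cfg$n_f1, unname(cfg$n_per_generation))
  prev_idx <- seq_len(nf)
  cursor <- nf
  for (k in seq_along(gens)) {
    g <- gens[k]
    males <- prev_idx[sex[prev_idx] == "M"]
    females <- prev_idx[sex[prev_idx] == "F"]
    if (g == 1L) {
      hi_m <- intersect(males, which(founders$samples$line == "HIGH"))
      hi_f <- intersect(females, which(founders$samples$line == "HIGH"))
      lo_m <- intersect(males, which(founders$samples$line == "LOW"))
      lo_f <- intersect(females, which(founders$samples$line == "LOW"))
      if ((length(hi_m) == 0 || length(lo_f) == 0) &&
          (length(lo_m) == 0 || length(hi_f) == 0))
        stop("cannot form HIGH x LOW F1 pairs: a line lacks a sex")
    } else if (length(males) == 0L || length(females) == 0L) {
      stop("generation ", g, " has fewer than 2 available parents")
    }
    idx <- cursor + seq_len(sizes[k])
    for (i in idx) {
      repeat {
        if (g == 1L) {
          if (stats::runif(1) < 0.5 && length(hi_m) > 0 && length(lo_f) > 0) {
            s <- if (length(hi_m) == 1L) hi_m else sample(hi_m, 1L)
            d <- if (length(lo_f) == 1L) lo_f else sample(lo_f, 1L)
          } else {
            s <- if (length(lo_m) == 1L) lo_m else sample(lo_m, 1L)
            d <- if (length(hi_f) == 1L) hi_f else sample(hi_f, 1L)
          }
          break
        }
        s <- if (length(males) == 1L) males else sample(males, 1L)
        d <- if (length(females) == 1L) females else sample(females, 1L)
        full_sibs <- !is.na(sire[s]) && !is.na(sire[d]) &&
          sire[s] == sire[d] && dam[s] == dam[d]
        if (!full_sibs || (length(males) == 1L && length(females) == 1L)) break
      }
      H1[i, ] <- meiosis(H1[s, ], H2[s, ], map_cm)
      H2[i, ] <- meiosis(H1[d, ], H2[d, ], map_cm)
      ids[i] <- sprintf("F%02d_%04d", g, i - cursor)
      sex[i] <- if (stats::runif(1) < 0.5) "M" else "F"
      gen[i] <- g
      sire[i] <- ids[s]; dam[i] <- ids[d]
    }
    prev_idx <- idx
    cursor <- cursor + sizes[k]
  }

  dimnames(H1) <- list(ids, fg$map$marker_id)
  dimnames(H2) <- list(ids, fg$map$marker_id)
  geno <- ail_geno(H1 + H2, fg$map, H1, H2)
  samples <- data.frame(sample_id = ids, sex = sex, generation = gen,
                        line = c(founders$samples$line,
                                 rep("CROSS", n_total - nf)),
                        bw8 = NA_real_, stringsAsFactors = FALSE)
  pedigree <- data.frame(sample_id = ids, sire_id = sire, dam_id = dam,
                         generation = gen, stringsAsFactors = FALSE)
  list(geno = geno, samples = samples, pedigree = pedigree)
}

#' Simulate phenotypes under a trait architecture
#'
#' Body weight is the sum of an intercept, a male sex effect, a generation
#' effect, additive and dominance marker contributions, epistatic grid
#' contributions, and Gaussian noise whose standard deviation is the
#' baseline residual SD multiplied by the sample's variance-heterogeneity
#' (vQTL) multipliers.
#'
#' @param g an [ail_geno] object.
#' @param samples phenotype-table data.frame (`sample_id`, `sex`,
#'   `generation` used); rows must match samples present in `g`.
#' @param arch a [trait_architecture()].
#' @param seed integer seed for the residual draw.
#' @return `samples` with `bw8` filled in.
#' @export
simulate_phenotypes <- function(g, samples, arch, seed = 1L) {
  stopifnot(inherits(g, "ail_geno"), inherits(arch, "trait_architecture"))
  set.seed(seed)
  calls <- g$calls[samples$sample_id, , drop = FALSE]
  need <- unique(c(names(arch$additive), names(arch$dominance),
                   unlist(lapply(arch$epistatic_pairs, `[[`, "markers")),
                   names(arch$vqtl)))
  if (!all(need %in% colnames(calls)))
    stop("architecture marker absent from panel: ",
         setdiff(need, colnames(calls))[1])
  if (length(need) > 0 && anyNA(calls[, need]))
    stop("missing genotype at an architecture marker")

  n <- nrow(samples)
  y <- rep(arch$intercept, n) + arch$sex_effect * (samples$sex == "M")
  ge <- arch$generation_effects
  if (is.null(ge)) {
    y <- y + 2 * samples$generation
  } else {
    idx <- match(as.character(samples$generation), names(ge))
    y <- y + ifelse(is.na(idx), 0, ge[idx])
  }
  for (mk in names(arch$additive))
    y <- y + arch$additive[[mk]] * calls[, mk]
  for (mk in names(arch$dominance))
    y <- y + arch$dominance[[mk]] * (calls[, mk] == 1L)
  for (ep in arch$epistatic_pairs) {
    grid <- as.matrix(ep$grid)
    y <- y + grid[cbind(calls[, ep$markers[1]] + 1L, calls[, ep$markers[2]] + 1L)]
  }
  sd_i <- rep(arch$residual_sd, n)
  for (mk in names(arch$vqtl))
    sd_i <- sd_i * arch$vqtl[[mk]][calls[, mk] + 1L]
  samples$bw8 <- y + stats::rnorm(n, 0, sd_i)
  samples
}

#' Simulate a complete advanced intercross line cohort
#'
#' Runs founder simulation, pedigree/genotype dropping, and phenotype
#' simulation. Phenotypes are assigned to intercross generations F2 onward
#' only (founders and F1 are not phenotyped, as in a typical AIL study).
#'
#' @param cfg a [sim_config()].
#' @return List with `geno`, `samples`, `pedigree`, `founder_freq`
#'   (list of `high`, `low`) and `config`.
#' @export
simulate_ail <- function(cfg) {
  founders <- simulate_founders(cfg)
  ped <- simulate_pedigree(cfg, founders)
  pheno_rows <- ped$samples$generation >= 2L
  ph <- simulate_phenotypes(ped$geno, ped$samples[pheno_rows, , drop = FALSE],
                            cfg$architecture, seed = cfg$seed + 2L)
  samples <- ped$samples
  samples$bw8[pheno_rows] <- ph$bw8
  list(geno = ped$geno, samples = samples, pedigree = ped$pedigree,
       founder_freq = list(high = founders$freq_high, low = founders$freq_low),
       config = cfg)
}

#' Export a simulated cohort to plain-text files
#'
#' Writes a phased VCF (`genotypes.vcf`), a phenotype table
#' (`phenotypes.tsv`), a pedigree table (`pedigree.tsv`) and a ground-truth
#' architecture table (`architecture.tsv`). Identical configurations produce
#' byte-identical files.
#'
#' @param sim result of [simulate_ail()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_vcf(sim$geno, file.path(dir, "genotypes.vcf"))
  write_phenotypes(sim$samples, file.path(dir, "phenotypes.tsv"))
  write_pedigree(sim$pedigree, file.path(dir, "pedigree.tsv"))
  arch <- sim$config$architecture
  rows <- list()
  for (mk in names(arch$additive))
    rows[[length(rows) + 1L]] <- data.frame(term = "additive", marker_a = mk,
                                            marker_b = "", value = arch$additive[[mk]])
  for (mk in names(arch$dominance))
    rows[[length(rows) + 1L]] <- data.frame(term = "dominance", marker_a = mk,
                                            marker_b = "", value = arch$dominance[[mk]])
  for (ep in arch$epistatic_pairs) {
    grid <- as.matrix(ep$grid)
    for (i in 1:3) for (j in 1:3)
      rows[[length(rows) + 1L]] <- data.frame(
        term = sprintf("epistasis_%d_%d", i - 1L, j - 1L),
        marker_a = ep$markers[1], marker_b = ep$markers[2], value = grid[i, j])
  }
  for (mk in names(arch$vqtl))
    for (gi in 1:3)
      rows[[length(rows) + 1L]] <- data.frame(
        term = sprintf("vqtl_sd_mult_%d", gi - 1L), marker_a = mk,
        marker_b = "", value = arch$vqtl[[mk]][gi])
  truth <- if (length(rows)) do.call(rbind, rows) else
    data.frame(term = character(), marker_a = character(),
               marker_b = character(), value = numeric())
  utils::write.table(truth, file.path(dir, "architecture.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
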