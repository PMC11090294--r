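# Build a phased geno from explicit haplotype matrices.
hap_geno <- function(h1, h2, pos = NULL) {
  m <- ncol(h1)
  rownames(h1) <- rownames(h2) <- sprintf("s%03d", seq_len(nrow(h1)))
  colnames(h1) <- colnames(h2) <- sprintf("mk%02d", seq_len(m))
  map <- data.frame(marker_id = colnames(h1), chrom = "chr1",
                    pos = pos %||% (seq_len(m) * 1000L),
                    ref = "A", alt = "G", stringsAsFactors = FALSE)
  ail_geno(h1 + h2, map, h1, h2)
}

test_that("complete LD forms a block, equilibrium does not", {
  set.seed(31)
  a <- matrix(rbinom(400, 1, 0.5), 200, 2)
  g_ld <- hap_geno(a[, c(1, 1)], a[, c(2, 2)])  # identical columns: D' = 1
  b1 <- find_blocks(g_ld)
  expect_equal(nrow(b1), 1L)
  expect_equal(b1$n_markers, 2L)

  h1 <- matrix(rbinom(2000, 1, 0.5), 1000, 2)
  h2 <- matrix(rbinom(2000, 1, 0.5), 1000, 2)
  g_eq <- hap_geno(h1, h2)
  expect_equal(nrow(find_blocks(g_eq)), 0L)
})

test_that("block finding matches an exhaustive pair-rule oracle", {
  # oracle: enumerate intervals longest-first, apply the same strong-LD /
  # informative-fraction rules from raw pair classifications
  oracle_blocks <- function(g) {
    H <- rbind(g$hap1, g$hap2)
    m <- ncol(H)
    cls <- matrix(0L, m, m)
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      p <- pair_dprime(H[, i], H[, j])
      cls[i, j] <- if (!p$informative || is.na(p$ci_low)) 0L
      else if (p$ci_low >= 0.70 && p$ci_high >= 0.98) 1L
      else if (p$ci_high < 0.90) -1L else 2L
    }
    cand <- expand.grid(i = 1:m, j = 1:m)
    cand <- cand[cand$j > cand$i, ]
    cand <- cand[order(-(cand$j - cand$i), cand$i), ]
    taken <- rep(FALSE, m); out <- list()
    for (r in seq_len(nrow(cand))) {
      i <- cand$i[r]; j <- cand$j[r]
      if (any(taken[i:j]) || cls[i, j] != 1L) next
      sub <- cls[i:j, i:j]
      n_s <- sum(sub == 1L); n_i <- n_s + sum(sub == -1L)
      if (n_i == 0 || n_s / n_i < 0.95) next
      taken[i:j] <- TRUE
      out[[length(out) + 1L]] <- c(i, j)
    }
    out[order(vapply(out, `[`, 0, 1))]
  }

  set.seed(32)
  for (rep in 1:5) {
    # 5-marker panels: two correlated clusters plus noise
    base <- rbinom(300, 1, 0.5)
    flip <- function(x, p) ifelse(runif(length(x)) < p, 1 - x, x)
    H <- cbind(base, flip(base, 0.02), flip(base, 0.5),
               b2 <- rbinom(300, 1, 0.4), flip(b2, 0.03))
    g <- hap_geno(H[1:150, ], H[151:300, ])
    found <- find_blocks(g, maf_min = 0)
    ob <- oracle_blocks(g)
    expect_equal(nrow(found), length(ob))
    if (length(ob)) {
      expect_equal(found$first_marker, sprintf("mk%02d", vapply(ob, `[`, 0, 1)))
      expect_equal(found$last_marker, sprintf("mk%02d", vapply(ob, `[`, 0, 2)))
    }
  }
})

test_that("haplotype assignment labels, pools and excludes correctly", {
  # single-marker block: labels coincide with alleles
  set.seed(33)
  h1 <- matrix(rbinom(100, 1, 0.5), 100, 1)
  h2 <- matrix(rbinom(100, 1, 0.5), 100, 1)
  g <- hap_geno(h1, h2)
  asg <- assign_haplotypes(g, "mk01")
  strings <- asg$haplotype_strings
  expect_setequal(strings, c("0", "1"))

  # two haplotypes at 50/50: two labels, no OTHER
  h <- matrix(rep(c(0L, 1L), each = 50), 100, 3)
  g2 <- hap_geno(h, h)
  asg2 <- assign_haplotypes(g2, c("mk01", "mk02", "mk03"))
  expect_setequal(names(asg2$frequencies), c("H1", "H2"))
  expect_equal(sum(asg2$frequencies), 1)

  # many rare haplotypes pool into OTHER; frequencies still sum to 1
  freqs <- c(0.45, 0.43, rep(0.015, 8))
  idx <- sample(1:10, 2000, TRUE, prob = freqs)
  pats <- t(sapply(1:10, function(i) as.integer(intToBits(i))[1:4]))
  hh <- pats[idx, ]
  g3 <- hap_geno(hh[1:1000, ], hh[1001:2000, ])
  asg3 <- assign_haplotypes(g3, colnames(g3$calls), pool_threshold = 0.05)
  expect_setequal(names(asg3$frequencies), c("H1", "H2", "OTHER"))
  expect_equal(sum(asg3$frequencies), 1)

  # haplotype dosages sum to 2 per fully observed sample
  d <- (asg3$labels1 == "H1") + (asg3$labels2 == "H1") +
    (asg3$labels1 == "H2") + (asg3$labels2 == "H2") +
    (asg3$labels1 == "OTHER") + (asg3$labels2 == "OTHER")
  expect_true(all(d == 2))
})

test_that("haplotype model recovers a noise-free haplotype effect", {
  set.seed(34)
  # 2-marker block, 3 haplotypes: 00 (ref), 11 (+20 g), 10 (0 g)
  pats <- rbind(c(0L, 0L), c(1L, 1L), c(1L, 0L))
  idx1 <- sample(1:3, 300, TRUE, prob = c(0.5, 0.3, 0.2))
  idx2 <- sample(1:3, 300, TRUE, prob = c(0.5, 0.3, 0.2))
  g <- hap_geno(pats[idx1, ], pats[idx2, ])
  s <- flat_samples(300)
  eff <- c(0, 20, 0)
  s$bw8 <- 800 + eff[idx1] + eff[idx2]
  asg <- assign_haplotypes(g, c("mk01", "mk02"))
  fit <- fit_haplotype_lm(s$bw8, s, asg)
  lab11 <- names(which(asg$haplotype_strings == "11"))
  lab10 <- names(which(asg$haplotype_strings == "10"))
  expect_equal(unname(fit$effects[lab11]), 20, tolerance = 1e-8)
  expect_equal(unname(fit$effects[lab10]), 0, tolerance = 1e-8)
})

test_that("a single-marker block reproduces the marker model exactly", {
  set.seed(35)
  calls <- sample(0:2, 150, TRUE)
  h1 <- matrix(pmax(calls - 1L, 0L)); h2 <- matrix(pmin(calls, 1L))
  g <- hap_geno(h1, h2)
  s <- flat_samples(150, bw8 = 700 + 8 * calls + rnorm(150, 0, 15))
  s$sex <- sample(c("F", "M"), 150, TRUE)
  r_marker <- fit_marker_lm(s$bw8, s, g, "mk01")
  asg <- assign_haplotypes(g, "mk01")
  r_hap <- fit_haplotype_lm(s$bw8, s, asg)
  expect_equal(r_hap$pvalue, r_marker$pvalue, tolerance = 1e-8)
  expect_equal(r_hap$joint_f, r_marker$stat^2, tolerance = 1e-8)
})

test_that("blocks partition markers without overlap", {
  sim <- cached_sim()
  bl <- find_blocks(sim$geno, max_block_markers = 10)
  if (nrow(bl) > 0) {
    all_ids <- unlist(strsplit(bl$marker_ids, ","))
    expect_equal(anyDuplicated(all_ids), 0L)
    expect_true(all(all_ids %in% sim$geno$map$marker_id))
  }
  expect_true(all(bl$n_markers >= 2))
})

test_that("ancestry-class association estimates donor contrasts", {
  set.seed(36)
  n <- 600
  s <- flat_samples(n)
  s$sex <- sample(c("F", "M"), n, TRUE)
  donors <- c("Dominique", "Cochin", "Java")
  d1 <- sample(donors, n, TRUE, prob = c(0.6, 0.25, 0.15))
  d2 <- sample(donors, n, TRUE, prob = c(0.6, 0.25, 0.15))
  eff <- c(Dominique = 0, Cochin = 26, Java = -3)
  s$bw8 <- 800 + 40 * (s$sex == "M") + eff[d1] + eff[d2] + rnorm(n, 0, 10)
  labels <- rbind(
    data.frame(sample_id = s$sample_id, chrom = "chr1", start = 1L,
               end = 1000000L, haplotype = 1L, donor = d1),
    data.frame(sample_id = s$sample_id, chrom = "chr1", start = 1L,
               end = 1000000L, haplotype = 2L, donor = d2))
  fit <- ancestry_association(s$bw8, s, labels, "chr1:400000-600000")
  contrast <- fit$effects["Cochin"] - fit$effects["Java"]
  expect_equal(unname(contrast), 29, tolerance = 3 * sqrt(sum(fit$se^2)))

  # labels independent of phenotype: no significant association
  s0 <- s; set.seed(37); s0$bw8 <- rnorm(n, 800, 10)
  fit0 <- ancestry_association(s0$bw8, s0, labels, "chr1:400000-600000")
  expect_gt(fit0$pvalue, 0.001)

  # single donor class: skipped
  lab1 <- labels; lab1$donor <- "Dominique"
  out <- ancestry_association(s$bw8, s, lab1, "chr1:400000-600000")
  expect_equal(out$flag, "skipped_single_donor")
})
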