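test_that("normalization z-scores each sex-generation cell", {
  s <- flat_samples(3, bw8 = c(2, 4, 6))
  expect_equal(normalize_by_group(s), c(-1, 0, 1))

  s2 <- rbind(flat_samples(3, bw8 = c(2, 4, 6)),
              within(flat_samples(3, bw8 = c(102, 104, 109)), {
                sample_id <- paste0(sample_id, "b"); generation <- 3L
              }))
  z <- normalize_by_group(s2)
  expect_equal(mean(z[1:3]), 0)
  expect_equal(mean(z[4:6]), 0)
  expect_equal(sd(z[4:6]), 1)

  s3 <- flat_samples(3, bw8 = c(5, 5, 5))
  expect_error(normalize_by_group(s3), "zero phenotype SD")
})

test_that("single-marker fit matches the hand-computed regression", {
  g <- toy_geno(list(mk = c(0L, 0L, 1L, 1L, 2L, 2L)))
  s <- flat_samples(6, bw8 = c(10, 12, 15, 13, 20, 18))
  r <- fit_marker_lm(s$bw8, s, g, "mk")
  expect_equal(r$effect, 4, tolerance = 1e-10)
  expect_equal(r$intercept, 32 / 3, tolerance = 1e-10)
  expect_equal(r$n_used, 6L)
  expect_equal(r$flag, "ok")
})

test_that("degenerate and rank-deficient fits are flagged", {
  g <- toy_geno(list(mk = c(0L, 0L, 1L, 1L, 2L, 2L),
                     dup = c(0L, 0L, 1L, 1L, 2L, 2L)))
  s <- flat_samples(6, bw8 = 2 * g$calls[, "mk"])
  r <- fit_marker_lm(s$bw8, s, g, "mk")
  expect_equal(r$flag, "degenerate")
  expect_equal(r$effect, 2)
  expect_equal(r$residual_variance, 0)
  expect_equal(r$pvalue, 0)

  r2 <- fit_marker_lm(s$bw8, s, g, "mk", conditioning = "dup")
  expect_equal(r2$flag, "rank_deficient")
  expect_true(is.na(r2$effect))

  g3 <- toy_geno(list(mono = rep(1L, 6)))
  expect_equal(fit_marker_lm(s$bw8, s, g3, "mono")$flag, "monomorphic")
})

test_that("fit_marker_lm agrees with a normal-equations oracle", {
  for (seed in 1:10) {
    rc <- random_cohort(40, n_markers = 2, seed = seed)
    r <- fit_marker_lm(rc$samples$bw8, rc$samples, rc$geno, "mk01",
                       conditioning = "mk02")
    X <- model.matrix(~ sex + factor(generation) + mk02 + mk01,
                      data = cbind(rc$samples,
                                   mk01 = rc$geno$calls[, "mk01"],
                                   mk02 = rc$geno$calls[, "mk02"]))
    o <- oracle_ols(X, rc$samples$bw8)
    k <- ncol(X)
    expect_equal(r$effect, unname(o$coef[k]), tolerance = 1e-8)
    expect_equal(r$se, unname(o$se[k]), tolerance = 1e-8)
    expect_equal(r$residual_variance, o$sigma2, tolerance = 1e-8)
    expect_equal(r$pvalue, 2 * pt(-abs(o$coef[k] / o$se[k]), o$df),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("squared marker t equals the sequential F of the last term", {
  rc <- random_cohort(60, n_markers = 1, seed = 11)
  r <- fit_marker_lm(rc$samples$bw8, rc$samples, rc$geno, "mk01")
  st <- stepwise_select(rc$samples$bw8, rc$samples, rc$geno, "mk01",
                        alpha_in = 1, alpha_out = 1)
  a <- anova_table(st$fit)
  expect_equal(r$stat^2, a$f_value[a$term == "mk01"], tolerance = 1e-10)
  expect_equal(r$pvalue, a$pvalue[a$term == "mk01"], tolerance = 1e-10)
})

test_that("scan localizes a noise-free QTL and conditioning removes it", {
  set.seed(12)
  calls <- lapply(1:5, function(i) sample(0:2, 80, TRUE))
  names(calls) <- sprintf("mk%02d", 1:5)
  calls$mk06 <- calls$mk03  # perfect LD proxy of the causal marker
  g <- toy_geno(calls)
  s <- flat_samples(80, bw8 = 700 + 25 * calls$mk03 + rnorm(80, 0, 1e-6))
  sc <- gwas_scan(s$bw8, s, g)
  expect_true(sc$marker_id[which.max(sc$neglog10p)] %in% c("mk03", "mk06"))

  sc2 <- gwas_scan(s$bw8, s, g, markers = "mk06", conditioning = "mk03")
  expect_equal(sc2$flag, "rank_deficient")
  s2 <- flat_samples(80, bw8 = 700 + 25 * calls$mk03 + rnorm(80, 0, 10))
  sc3 <- gwas_scan(s2$bw8, s2, g, markers = c("mk01", "mk02"),
                   conditioning = "mk03")
  expect_true(all(sc3$neglog10p < 2))
})

test_that("complete-data scan path equals the per-marker fit exactly", {
  sim <- cached_sim()
  ph <- sim$samples[sim$samples$generation >= 2, ]
  mks <- sim$geno$map$marker_id[1:25]
  fast <- gwas_scan(ph$bw8, ph, sim$geno, markers = mks,
                    conditioning = sim$geno$map$marker_id[40])
  slow <- do.call(rbind, lapply(mks, function(mk) {
    r <- fit_marker_lm(ph$bw8, ph, sim$geno, mk,
                       conditioning = sim$geno$map$marker_id[40])
    data.frame(effect = r$effect, se = r$se, pvalue = r$pvalue, flag = r$flag)
  }))
  expect_equal(fast$effect, slow$effect, tolerance = 1e-10)
  expect_equal(fast$se, slow$se, tolerance = 1e-10)
  expect_equal(fast$pvalue, slow$pvalue, tolerance = 1e-10)
  expect_equal(fast$flag, slow$flag)

  # missing data falls back to case-wise deletion per marker
  g2 <- sim$geno
  g2$calls[ph$sample_id[5], mks[1]] <- NA_integer_
  miss <- gwas_scan(ph$bw8, ph, g2, markers = mks[1:2])
  expect_equal(miss$n_used, c(nrow(ph) - 1L, nrow(ph)))
})

test_that("stepwise selection recovers the causal marker among nulls", {
  set.seed(13)
  calls <- lapply(1:6, function(i) sample(0:2, 200, TRUE, prob = c(.3, .5, .2)))
  names(calls) <- sprintf("mk%02d", 1:6)
  g <- toy_geno(calls)
  s <- flat_samples(200, bw8 = 700 + 40 * calls$mk04 + rnorm(200, 0, 20))
  st <- stepwise_select(s$bw8, s, g, names(calls))
  expect_identical(st$selected, "mk04")

  # two markers in perfect LD: exactly one of the pair enters
  calls$mk07 <- calls$mk04
  g2 <- toy_geno(calls)
  st2 <- stepwise_select(s$bw8, s, g2, names(calls))
  expect_equal(length(intersect(st2$selected, c("mk04", "mk07"))), 1L)

  # all-null candidates: selection stays small (false-positive rate)
  s0 <- flat_samples(200, bw8 = rnorm(200, 700, 20))
  st0 <- stepwise_select(s0$bw8, s0, g, sprintf("mk%02d", 1:6))
  expect_lte(length(st0$selected), 1L)
})

test_that("sequential ANOVA preserves orthogonal-term F values", {
  # balanced design: marker orthogonal to sex
  g <- toy_geno(list(mk = rep(c(0L, 1L, 2L), each = 20)))
  s <- flat_samples(60)
  s$sex <- rep(rep(c("F", "M"), 30))
  set.seed(14)
  s$bw8 <- 700 + 30 * (s$sex == "M") + 5 * g$calls[, "mk"] + rnorm(60, 0, 8)
  st <- stepwise_select(s$bw8, s, g, "mk", alpha_in = 1, alpha_out = 1)
  a <- anova_table(st$fit)
  r <- fit_marker_lm(s$bw8, s, g, "mk")
  # orthogonality: fitted first or last, the marker F is the same
  expect_equal(a$f_value[a$term == "mk"], r$stat^2, tolerance = 1e-8)
})

test_that("published-table F recomputation utility is exact on synthetic input", {
  ms <- c(100, 50, 20)
  resid_ms <- 5
  f <- ms / resid_ms
  out <- recompute_anova_f(ms, f, df2 = 100)
  expect_equal(out$residual_ms, resid_ms)
  expect_equal(out$f_recomputed, f)
  expect_equal(out$p_recomputed, pf(f, 1, 100, lower.tail = FALSE))
})

test_that("genotype group summaries track a noise-free negative effect", {
  g <- toy_geno(list(mk = rep(c(0L, 1L, 2L), each = 4)))
  s <- flat_samples(12, bw8 = -0.2 * rep(c(0, 1, 2), each = 4) + 1)
  gs <- genotype_group_summary(s$bw8, s, g, "mk")
  expect_equal(gs$genotype, c("RR", "RA", "AA"))
  expect_equal(diff(gs$mean), c(-0.2, -0.2))
  expect_equal(gs$count, rep(4L, 3))

  g1 <- toy_geno(list(mk = rep(1L, 12)))
  expect_equal(nrow(genotype_group_summary(s$bw8, s, g1, "mk")), 1L)
})

test_that("LSD letters separate groups correctly and ignore input order", {
  # two identical groups share a letter at any alpha
  expect_equal(lsd_letters(means = c(1, 1), sds = c(1, 1), ns = c(10, 10),
                           alpha = 0.5), c("a", "a"))
  # clearly separated groups get distinct letters, named in input order
  lt <- lsd_letters(means = c(0, 10, 20), sds = c(1, 1, 1), ns = c(30, 30, 30))
  expect_equal(lt, c("a", "b", "c"))
  # middle group overlapping both ends shares both letters
  lt2 <- lsd_letters(means = c(0, 1.2, 2.4), sds = c(2, 2, 2), ns = c(12, 12, 12))
  expect_equal(lt2[1] != lt2[3], TRUE)
  expect_true(nchar(lt2[2]) >= 1)
  # invariance to group input order
  m <- c(0.0638, -0.0053, -0.1404); sd_ <- c(1.0719, 0.9631, 0.8803)
  n <- c(1071, 1426, 433)
  l_fwd <- lsd_letters(means = m, sds = sd_, ns = n)
  perm <- c(3, 1, 2)
  l_perm <- lsd_letters(means = m[perm], sds = sd_[perm], ns = n[perm])
  # same partition structure after permuting back (letter names may differ)
  share <- function(l) outer(l, l, Vectorize(function(a, b)
    length(intersect(strsplit(a, "")[[1]], strsplit(b, "")[[1]])) > 0))
  expect_equal(share(l_perm[order(perm)]), share(l_fwd))
  expect_error(lsd_letters(means = c(1, 2), sds = c(1, 1), ns = c(1, 5)),
               "n >= 2")
})
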