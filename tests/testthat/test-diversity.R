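het_pair <- function(n, a = 101L, b = 102L) {
  geno_tbl(id = sprintf("i%02d", seq_len(n)), locus = "L1",
           a1 = rep(a, n), a2 = rep(b, n), population = "P")
}

test_that("allele frequencies come from non-missing copies and sum to 1", {
  g <- het_pair(10)
  fr <- allele_frequencies(g)
  expect_equal(sort(fr$freq), c(0.5, 0.5))
  g1 <- geno_tbl(id = "A", locus = "L1", a1 = 101L, a2 = 101L,
                 population = "P")
  expect_equal(allele_frequencies(g1)$freq, 1)
  # 2 typed + 1 missing: denominators use 4 copies
  gm <- geno_tbl(id = c("A", "B", "C"), locus = "L1",
                 a1 = c(101L, 101L, NA), a2 = c(101L, 102L, NA),
                 population = "P")
  fr2 <- allele_frequencies(gm)
  expect_equal(fr2$n_copies, c(4L, 4L))
  expect_equal(fr2$freq[fr2$allele == 101], 0.75)
  withr::local_seed(1)
  big <- unrelated_geno(30)
  sums <- dplyr::summarise(dplyr::group_by(allele_frequencies(big), locus),
                           s = sum(freq))
  expect_true(all(abs(sums$s - 1) < 1e-12))
})

test_that("expected heterozygosity uses Nei's unbiased correction", {
  h10 <- heterozygosity(het_pair(10))
  expect_equal(h10$h_obs, 1)
  expect_equal(h10$h_exp, (20 / 19) * 0.5, tolerance = 1e-12)
  h5 <- heterozygosity(het_pair(5))
  expect_equal(h5$h_exp, (10 / 9) * 0.5, tolerance = 1e-12)
  hom <- geno_tbl(id = c("A", "B"), locus = "L1", a1 = c(101L, 101L),
                  a2 = c(101L, 101L), population = "P")
  hh <- heterozygosity(hom)
  expect_equal(hh$h_obs, 0)
  expect_equal(hh$h_exp, 0)
})

test_that("the Monte Carlo exact HWE test matches complete enumeration", {
  # monomorphic convention
  mono <- geno_tbl(id = c("A", "B", "C"), locus = "L1", a1 = rep(101L, 3),
                   a2 = rep(101L, 3), population = "P")
  expect_equal(hwe_exact(mono, reps = 10)$hwe_p, 1)
  # all-heterozygote table, n = 5: enumeration oracle
  p_enum <- hwe_enum_biallelic(0, 5, 0)
  res <- hwe_exact(het_pair(5), reps = 20000, seed = 2)
  expect_lt(abs(res$hwe_p - p_enum), 3 * res$hwe_se + 1e-3)
  # a skewed table
  g <- geno_tbl(id = sprintf("i%d", 1:8), locus = "L1",
                a1 = c(rep(101L, 6), 101L, 102L),
                a2 = c(rep(101L, 6), 102L, 102L), population = "P")
  tab <- c(n11 = 6, n12 = 1, n22 = 1)
  res2 <- hwe_exact(g, reps = 20000, seed = 3)
  expect_lt(abs(res2$hwe_p - hwe_enum_biallelic(6, 1, 1)),
            3 * res2$hwe_se + 1e-3)
})

test_that("HWE p-values are roughly uniform under the null", {
  withr::local_seed(4)
  ps <- replicate(60, {
    g <- geno_from_inds(lapply(1:200, function(i) rand_ind(L = 1, A = 4)))
    hwe_exact(g, reps = 400)$hwe_p
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("Weir-Cockerham f matches an indicator-variable ANOVA oracle", {
  withr::local_seed(5)
  g <- family_geno(3, 2, L = 2, A = 4)  # 6 individuals, related -> nonzero f
  f_pkg <- fis_weir_cockerham(g, nperm = 0)
  # oracle: per allele, ANOVA on copy indicators; f = 1 - sum(c)/sum(b + c)
  bc <- c(b = 0, c = 0)
  for (l in unique(g$locus)) {
    ld <- g[g$locus == l & !is.na(g$a1), ]
    n <- nrow(ld)
    for (al in unique(c(ld$a1, ld$a2))) {
      x <- cbind(ld$a1 == al, ld$a2 == al) * 1
      xbar_i <- rowMeans(x)
      msw <- sum((x - xbar_i)^2) / n
      msa <- 2 * sum((xbar_i - mean(x))^2) / (n - 1)
      bc <- bc + c(b = (msa - msw) / 2, c = msw)
    }
  }
  f_oracle <- 1 - bc[["c"]] / (bc[["b"]] + bc[["c"]])
  expect_equal(f_pkg$f_is[f_pkg$locus == "(all)"], f_oracle,
               tolerance = 1e-10)
})

test_that("f is 1 with no heterozygotes and near 0 under HWE", {
  hom <- geno_tbl(id = c("A", "B", "C"), locus = "L1",
                  a1 = c(101L, 102L, 101L), a2 = c(101L, 102L, 101L),
                  population = "P")
  expect_equal(fis_weir_cockerham(hom, nperm = 0)$f_is[1], 1)
  withr::local_seed(6)
  hwe <- geno_from_inds(lapply(1:1000, function(i) rand_ind(L = 10, A = 8)))
  f <- fis_weir_cockerham(hwe, nperm = 0)
  expect_lt(abs(f$f_is[f$locus == "(all)"]), 0.02)
})

test_that("the F_IS permutation test flags homozygote excess one-sidedly", {
  withr::local_seed(7)
  # selfed-like genotypes: strong homozygote excess
  inds <- lapply(1:40, function(i) {
    a <- sample(4, 1) + 100L
    if (runif(1) < 0.8) cbind(a, a) else rand_ind(L = 1, A = 4)
  })
  g <- geno_from_inds(inds)
  res <- fis_weir_cockerham(g, nperm = 199, seed = 8)
  all_row <- res[res$locus == "(all)", ]
  expect_gt(all_row$f_is, 0.3)
  expect_lt(all_row$p, 0.05)
})

test_that("Holm correction reproduces the step-down procedure", {
  out <- holm_correction(c(0.01, 0.04, 0.03), alpha = 0.05)
  expect_equal(out$p_adj, p.adjust(c(0.01, 0.04, 0.03), "holm"))
  expect_equal(out$reject, c(TRUE, FALSE, FALSE))
  expect_false(any(holm_correction(rep(1, 5))$reject))
  expect_equal(holm_correction(0.03)$p_adj, 0.03)
})

test_that("the null-allele EM recovers the simulated null frequency", {
  withr::local_seed(9)
  sim_null <- function(n, r_null, A = 4) {
    p <- c(rep((1 - r_null) / A, A), r_null)
    draws <- t(replicate(n, sample.int(A + 1, 2, replace = TRUE, prob = p)))
    a1 <- draws[, 1]; a2 <- draws[, 2]
    null1 <- a1 == A + 1; null2 <- a2 == A + 1
    vis1 <- ifelse(null1 & null2, NA, ifelse(null1, a2, a1))
    vis2 <- ifelse(null1 & null2, NA, ifelse(null1 | null2,
                                             ifelse(null1, a2, a1), a2))
    geno_tbl(id = sprintf("i%04d", 1:n), locus = "L1",
             a1 = ifelse(is.na(vis1), NA, pmin(vis1, vis2) + 100L),
             a2 = ifelse(is.na(vis1), NA, pmax(vis1, vis2) + 100L),
             population = "P")
  }
  est03 <- null_allele_estimate(sim_null(1000, 0.3))
  expect_lt(abs(est03$null_freq - 0.3), 0.05)
  est00 <- null_allele_estimate(sim_null(500, 0))
  expect_lt(est00$null_freq, 0.05)
  expect_true(all(est03$converged))
})

test_that("locus filtering drops only frequencies strictly above threshold", {
  g <- dplyr::bind_rows(
    geno_tbl(id = "A", locus = "A", a1 = 101L, a2 = 102L, population = "P"),
    geno_tbl(id = "A", locus = "B", a1 = 101L, a2 = 101L, population = "P"),
    geno_tbl(id = "A", locus = "C", a1 = 102L, a2 = 103L, population = "P")
  )
  est <- tibble::tibble(locus = c("A", "B", "C"),
                        null_freq = c(0.48, 0.06, 0.20))
  out <- filter_loci(g, est, threshold = 0.20)
  expect_setequal(geno_loci(out), c("B", "C"))  # 0.20 kept, 0.48 dropped
  expect_equal(attr(out, "dropped_loci"), "A")
  out2 <- filter_loci(g, dplyr::mutate(est, null_freq = 0.1))
  expect_equal(nrow(out2), nrow(g))
})
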