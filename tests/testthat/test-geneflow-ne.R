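test_that("Nm is undefined without private alleles", {
  g <- dplyr::bind_rows(
    het_pair <- geno_tbl(id = sprintf("a%d", 1:5), locus = "L1",
                         a1 = rep(101L, 5), a2 = rep(102L, 5),
                         population = "A"),
    geno_tbl(id = sprintf("b%d", 1:5), locus = "L1", a1 = rep(101L, 5),
             a2 = rep(102L, 5), population = "B")
  )
  expect_message(res <- private_allele_nm(g), "no private alleles")
  expect_true(is.na(res$nm))
})

test_that("Nm solves the private-allele regression at a constructed p(1)", {
  # group A: one private allele at frequency 0.1 among n = 25; group B shares
  # the common allele only
  a_inds <- c(rep(list(matrix(c(101L, 109L), 1, 2)), 5),
              rep(list(matrix(101L, 1, 2)), 20))
  b_inds <- rep(list(matrix(101L, 1, 2)), 25)
  g <- dplyr::bind_rows(
    geno_from_inds(a_inds, ids = sprintf("a%02d", 1:25), population = "A"),
    geno_from_inds(b_inds, ids = sprintf("b%02d", 1:25), population = "B")
  )
  res <- private_allele_nm(g)
  expect_equal(res$mean_private_freq, 0.1)
  expect_equal(res$mean_sample_size, 25)
  # independent evaluation of the published regression at N = 25
  nm_oracle <- exp((log(0.1) - (-2.26)) / (-0.576))
  expect_equal(res$nm, nm_oracle, tolerance = 1e-12)
})

test_that("more gene flow means higher Nm (regression is decreasing)", {
  nm_at <- function(p1) exp((log(p1) - (-2.26)) / (-0.576))
  expect_gt(nm_at(0.05), nm_at(0.2))
})

test_that("the LD method needs locus pairs and hits Inf at huge true size", {
  withr::local_seed(51)
  single <- geno_from_inds(lapply(1:30, function(i) rand_ind(L = 1)))
  expect_error(ne_ld(single), "at least 2 loci")
  infs <- replicate(12, is.infinite(ne_ld(unrelated_geno(50, L = 15))$ne))
  expect_gt(mean(infs), 0.5)
})

test_that("the LD method recovers a finite small Ne", {
  withr::local_seed(53)
  res <- t(replicate(8, {
    e <- ne_ld(wf_cohort_geno(Ne = 50, gens = 8, n = 50, L = 20))
    c(e$ne, e$ci_lo, e$ci_hi)
  }))
  expect_lt(abs(log(median(res[, 1]) / 50)), log(2))  # within factor 2
  expect_gte(mean(res[, 2] <= 50 & res[, 3] >= 50), 0.5)
})

test_that("heterozygote excess returns Inf without excess, Nb with it", {
  hom <- geno_from_inds(lapply(1:20, function(i) {
    a <- sample(4, 1) + 100L
    cbind(a, a)
  }))
  expect_true(is.infinite(ne_het_excess(hom)$ne))
  withr::local_seed(59)
  off <- family_geno(5, 40, L = 15)  # 10 breeders
  est <- ne_het_excess(off)
  expect_true(is.finite(est$ne))
  expect_lt(abs(log(est$ne / 10)), log(2))
})

test_that("coancestry Nb reflects the number of breeding parents", {
  withr::local_seed(61)
  # sample-referenced (field situation): detects a small breeder pool
  est4 <- mean(replicate(5, ne_coancestry(family_geno(2, 20, L = 20))$ne))
  expect_lt(abs(log(est4 / 4)), log(2))  # 4 parents within a factor of 2
  # unrelated sample from a huge pool: coancestry at background
  unrel <- replicate(5, ne_coancestry(unrelated_geno(40, L = 20))$ne)
  expect_gt(min(unrel), 2 * est4)
  # with the breeding pool's frequencies known, the all-pairs mean tracks
  # the parent count monotonically
  uref <- setNames(lapply(1:20, function(l) setNames(rep(1 / 8, 8), 101:108)),
                   sprintf("L%02d", 1:20))
  nb <- vapply(c(2, 4, 8), function(np) {
    mean(replicate(5, ne_coancestry(family_geno(np, 40 / np, L = 20),
                                    ref_freqs = uref)$ne))
  }, numeric(1))
  expect_lt(abs(log(nb[1] / 4)), log(2))
  expect_true(all(diff(nb) > 0))
})

test_that("ne_ld is invariant to locus order and allele relabelling", {
  withr::local_seed(67)
  g <- wf_cohort_geno(Ne = 30, gens = 6, n = 40, L = 8)
  base <- ne_ld(g)$ne
  shuf <- g[order(g$locus, decreasing = TRUE), ]
  expect_equal(ne_ld(shuf)$ne, base)
  relab <- dplyr::mutate(g, a1 = 1000L - a1, a2 = 1000L - a2,
                         tmp = pmin(a1, a2), a2 = pmax(a1, a2), a1 = tmp)
  relab$tmp <- NULL
  expect_equal(ne_ld(relab)$ne, base, tolerance = 1e-10)
})

test_that("raising pcrit never increases the comparisons used", {
  withr::local_seed(71)
  g <- wf_cohort_geno(Ne = 30, gens = 6, n = 40, L = 8)
  n1 <- ne_ld(g, pcrit = 0.02)$n_comparisons
  n2 <- ne_ld(g, pcrit = 0.10)$n_comparisons
  expect_lte(n2, n1)
})

test_that("all three estimators report Inf or NA rather than negatives", {
  withr::local_seed(73)
  g <- unrelated_geno(30, L = 10)
  tab <- ne_estimates(g)
  expect_true(all(tab$ne > 0 | is.na(tab$ne)))
})
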