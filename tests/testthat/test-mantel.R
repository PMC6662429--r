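test_that("Nei distance is 0 for identical frequencies, Inf for disjoint", {
  same <- dplyr::bind_rows(
    geno_tbl(id = sprintf("a%d", 1:5), locus = "L1", a1 = rep(101L, 5),
             a2 = rep(102L, 5), population = "P", nest = "n1"),
    geno_tbl(id = sprintf("b%d", 1:5), locus = "L1", a1 = rep(101L, 5),
             a2 = rep(102L, 5), population = "P", nest = "n2")
  )
  D <- nei_distance(same)
  expect_equal(D["n1", "n2"], 0)
  disjoint <- dplyr::bind_rows(
    geno_tbl(id = "a", locus = "L1", a1 = 101L, a2 = 101L,
             population = "P", nest = "n1"),
    geno_tbl(id = "b", locus = "L1", a1 = 202L, a2 = 202L,
             population = "P", nest = "n2")
  )
  expect_warning(D2 <- nei_distance(disjoint), "no alleles")
  expect_true(is.infinite(D2["n1", "n2"]))
})

test_that("Nei distance matches the closed form on a worked pair", {
  # nest X frequencies (0.5, 0.5); nest Y frequencies (0.9, 0.1)
  x_inds <- rep(list(matrix(c(101L, 102L), 1, 2)), 10)
  y_inds <- c(rep(list(matrix(101L, 1, 2)), 8),
              rep(list(matrix(c(101L, 102L), 1, 2)), 2))
  g <- dplyr::bind_rows(
    geno_from_inds(x_inds, ids = sprintf("x%02d", 1:10), nest = "X"),
    geno_from_inds(y_inds, ids = sprintf("y%02d", 1:10), nest = "Y")
  )
  D <- nei_distance(g)
  I <- (0.5 * 0.9 + 0.5 * 0.1) / sqrt(0.5 * 0.82)
  expect_equal(D["X", "Y"], -log(I), tolerance = 1e-12)
  expect_equal(round(D["X", "Y"], 4), 0.2473)
})

test_that("euclidean distances are straight-line and rigid-motion invariant", {
  co <- tibble::tibble(id = c("a", "b"), x = c(0, 3), y = c(0, 4))
  expect_equal(euclidean_distance(co)["a", "b"], 5)
  th <- 0.7
  rot <- tibble::tibble(id = co$id,
                        x = co$x * cos(th) - co$y * sin(th) + 100,
                        y = co$x * sin(th) + co$y * cos(th) - 50)
  expect_equal(euclidean_distance(rot)["a", "b"], 5, tolerance = 1e-12)
  dup <- tibble::tibble(id = c("a", "b"), x = c(1, 1), y = c(2, 2))
  expect_equal(euclidean_distance(dup)["a", "b"], 0)
})

test_that("Mantel r is 1 with p = 1/(perms+1) for identical matrices", {
  withr::local_seed(79)
  co <- tibble::tibble(id = sprintf("p%d", 1:12), x = runif(12), y = runif(12))
  d <- euclidean_distance(co)
  res <- mantel_test(d, d, nperm = 99, seed = 1)
  expect_equal(res$r, 1)
  expect_equal(res$r2, 1)
  expect_equal(res$p, 1 / 100)
})

test_that("a constant matrix is refused", {
  m <- matrix(1, 5, 5); diag(m) <- 0
  expect_error(mantel_test(m, m, nperm = 9), "undefined")
})

test_that("Mantel r is invariant to monotone-linear rescaling", {
  withr::local_seed(83)
  co <- tibble::tibble(id = sprintf("p%d", 1:15), x = runif(15), y = runif(15))
  co2 <- tibble::tibble(id = co$id, x = runif(15), y = runif(15))
  a <- euclidean_distance(co); b <- euclidean_distance(co2)
  r1 <- mantel_test(a, b, nperm = 0)$r
  r2 <- mantel_test(a * 3.7 + 2, b, nperm = 0)$r
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("the package Mantel test agrees with vegan's", {
  withr::local_seed(89)
  co <- tibble::tibble(id = sprintf("p%d", 1:20),
                       x = runif(20, 0, 100), y = runif(20, 0, 100))
  g <- family_geno(5, 4, L = 10)
  g$nest <- rep(sprintf("p%d", 1:20), each = 10)
  D <- nei_distance(g)
  E <- euclidean_distance(co)[rownames(D), rownames(D)]
  ours <- mantel_test(D, E, nperm = 999, seed = 7)
  veg <- vegan::mantel(as.dist(E), as.dist(D), permutations = 999)
  expect_equal(ours$r, unname(veg$statistic), tolerance = 1e-10)
  expect_lt(abs(ours$p - veg$signif), 0.1)
})

test_that("non-finite entries are excluded pairwise or refused per config", {
  m1 <- matrix(runif(25), 5, 5); m1 <- (m1 + t(m1)) / 2; diag(m1) <- 0
  m2 <- m1 * 2
  m2[1, 2] <- m2[2, 1] <- Inf
  expect_error(mantel_test(m1, m2, nperm = 9, na_action = "error"),
               "non-finite")
  res <- mantel_test(m1, m2, nperm = 9, seed = 1)
  expect_true(is.finite(res$r))
})

test_that("ibd_test ties nests to their coordinates in both modes", {
  withr::local_seed(97)
  s <- simulate_study(sim_config(missing_rate = 0), seed = 8)
  sub <- s$panel[s$panel$site == "TIE", ]
  res_nest <- ibd_test(sub, s$patterns$TIE, nperm = 49, seed = 2)
  expect_true(res_nest$r >= -1 && res_nest$r <= 1)
  expect_equal(res_nest$n, length(unique(sub$nest)))
  res_ind <- ibd_test(sub, s$patterns$TIE, mode = "individual", nperm = 19,
                      seed = 2)
  expect_equal(res_ind$n, length(unique(sub$id)))
})
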