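test_that("theta is 1 under complete fixation and ~0 under label splitting", {
  fixed <- dplyr::bind_rows(
    geno_from_inds(lapply(1:10, function(i) matrix(101L, 5, 2)),
                   ids = sprintf("a%d", 1:10), population = "A"),
    geno_from_inds(lapply(1:10, function(i) matrix(202L, 5, 2)),
                   ids = sprintf("b%d", 1:10), population = "B")
  )
  expect_equal(pairwise_fst(fixed, nperm = 0)$fst, 1)
  withr::local_seed(23)
  one_pop <- unrelated_geno(80, L = 15)
  split <- dplyr::mutate(one_pop,
    population = ifelse(id %in% unique(id)[1:40], "X", "Y"))
  res <- pairwise_fst(split, nperm = 99, seed = 1)
  expect_lt(abs(res$fst), 0.01)
  expect_gt(res$p, 0.05)
})

test_that("Weir-Cockerham theta recovers Balding-Nichols divergence", {
  withr::local_seed(29)
  th <- replicate(10, {
    pairwise_fst(bn_two_demes(0.15, n_per = 100, L = 20), nperm = 0)$fst
  })
  expect_lt(abs(mean(th) - 0.15), 0.03)
})

test_that("variance components equal the brute-force distance oracle", {
  withr::local_seed(31)
  for (i in 1:8) {
    n_cl <- sample(2:3, 1)
    nests <- paste0("c", rep(1:n_cl, each = 2), "_n", rep(1:2, n_cl))
    inds <- list(); nest_lab <- character(); cl_lab <- character()
    for (nst in nests) {
      for (k in 1:sample(2:3, 1)) {
        inds[[length(inds) + 1L]] <- rand_ind(L = 2, A = 3)
        nest_lab <- c(nest_lab, nst)
        cl_lab <- c(cl_lab, sub("_n.*", "", nst))
      }
    }
    if (length(inds) > 16) next
    g <- geno_from_inds(inds, nest = nest_lab, cluster = cl_lab)
    fit <- hierarchical_amova(g, nperm = 0)
    oracle <- amova_bruteforce(g)
    expect_equal(fit$components$sigma, oracle, tolerance = 1e-10)
  }
})

test_that("the F identity holds on non-degenerate fits", {
  withr::local_seed(37)
  s <- simulate_study(sim_config(), seed = 101)
  sub <- set_clusters(s$panel[s$panel$site == "TIE", ],
                      assign_clusters(s$patterns$TIE, 40))
  fit <- hierarchical_amova(sub, nperm = 0)
  st <- setNames(fit$statistics$estimate, fit$statistics$statistic)
  expect_equal((1 - st[["F_IT"]]),
               (1 - st[["F_IS"]]) * (1 - st[["F_SC"]]) * (1 - st[["F_CT"]]),
               tolerance = 1e-10)
  # variance components sum to the total derived from the sums of squares
  expect_equal(sum(fit$components$pct_total), 100, tolerance = 1e-8)
})

test_that("duplicating every individual barely moves the estimates", {
  withr::local_seed(41)
  s <- simulate_study(sim_config(missing_rate = 0), seed = 55)
  sub <- set_clusters(s$panel[s$panel$site == "TIE", ],
                      assign_clusters(s$patterns$TIE, 40))
  fit1 <- hierarchical_amova(sub, nperm = 0)
  doubled <- dplyr::bind_rows(sub, dplyr::mutate(sub, id = paste0(id, "_dup")))
  fit2 <- hierarchical_amova(doubled, nperm = 0)
  st1 <- setNames(fit1$statistics$estimate, fit1$statistics$statistic)
  st2 <- setNames(fit2$statistics$estimate, fit2$statistics$statistic)
  # the between-nest/cluster statistics are insensitive to duplication; the
  # within-nest ones carry an O(nests/individuals) degrees-of-freedom drift
  expect_lt(abs(st1[["F_CT"]] - st2[["F_CT"]]), 0.005)
  expect_lt(abs(st1[["F_IT"]] - st2[["F_IT"]]), 0.005)
  expect_lt(abs(st1[["F_SC"]] - st2[["F_SC"]]), 0.02)
  expect_lt(abs(st1[["F_IS"]] - st2[["F_IS"]]), 0.02)
  # theta is duplication-stable too
  two <- dplyr::mutate(sub, population = ifelse(nest %in% unique(nest)[1:10],
                                                "A", "B"))
  th1 <- pairwise_fst(two, nperm = 0)$fst
  th2 <- pairwise_fst(dplyr::bind_rows(two, dplyr::mutate(two, id = paste0(id, "_d"))),
                      nperm = 0)$fst
  expect_lt(abs(th1 - th2), 0.005)
})

test_that("identical individuals give a degenerate all-zero fit", {
  g <- geno_from_inds(lapply(1:8, function(i) matrix(101L, 3, 2)),
                      nest = rep(c("n1", "n2", "n3", "n4"), each = 2),
                      cluster = rep(c("c1", "c2"), each = 4))
  fit <- hierarchical_amova(g, nperm = 10, seed = 1)
  expect_true(fit$degenerate)
  expect_equal(fit$statistics$estimate, rep(0, 4))
  rep_tab <- amova_report(fit)
  expect_true(attr(rep_tab, "degenerate"))
})

test_that("a single cluster leaves F_CT undefined but the rest computed", {
  withr::local_seed(43)
  g <- family_geno(4, 3, L = 5)
  g$cluster <- "only"
  fit <- hierarchical_amova(g, nperm = 0)
  st <- setNames(fit$statistics$estimate, fit$statistics$statistic)
  expect_true(is.na(st[["F_CT"]]))
  expect_false(is.na(st[["F_SC"]]))
  expect_false(is.na(st[["F_IS"]]))
})

test_that("tidy and glance expose the fit as tibbles", {
  withr::local_seed(47)
  g <- family_geno(4, 3, L = 5)
  g$cluster <- rep(c("c1", "c2"), each = nrow(g) / 2)
  fit <- hierarchical_amova(g, nperm = 19, seed = 2)
  td <- generics::tidy(fit)
  expect_named(td, c("statistic", "estimate", "p", "se"))
  gl <- generics::glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$permutations, 19)
  expect_equal(nrow(amova_report(fit)), 4)
})
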