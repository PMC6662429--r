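# Analysis of molecular variance on allele identity (F-statistics, not
# allele-size based).  Two-level comparisons use the Weir-Cockerham (1984)
# theta estimator; the four-level design (clusters / nests / individuals /
# within individuals) uses the nested sums-of-squares decomposition over
# allele copies with unequal-size coefficients, negative components retained.

# ---- Weir-Cockerham theta ---------------------------------------------------

# Variance components a (among groups), b (among individuals within groups),
# c (within individuals) for one locus across r groups, summed over alleles.
wc_abc_one <- function(a1, a2, grp) {
  grp <- factor(grp)
  r <- nlevels(grp)
  if (r < 2) return(c(a = NA_real_, b = NA_real_, c = NA_real_))
  n_i <- as.vector(table(grp))
  if (any(n_i == 0)) return(c(a = 0, b = 0, c = 0))
  nbar <- mean(n_i)
  if (nbar <= 1) return(c(a = NA_real_, b = NA_real_, c = NA_real_))
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  alleles <- unique(c(a1, a2))
  het <- a1 != a2
  out <- c(a = 0, b = 0, c = 0)
  for (al in alleles) {
    cnt <- tapply((a1 == al) + (a2 == al), grp, sum)
    p_i <- cnt / (2 * n_i)
    h_i <- tapply(het & (a1 == al | a2 == al), grp, mean)
    pbar <- sum(n_i * p_i) / (r * nbar)
    s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n_i * h_i) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    out <- out + c(a = a, b = b, c = hbar / 2)
  }
  out
}

# Multilocus theta: components summed over loci (ratio of sums, not mean of
# ratios), on the long genotype tibble restricted to the groups of interest.
wc_theta <- function(geno, by = "population") {
  dat <- typed(geno)
  comp <- dat |>
    group_by(.data$locus) |>
    group_map(~ wc_abc_one(.x$a1, .x$a2, .x[[by]]))
  comp <- do.call(rbind, comp)
  sums <- colSums(comp, na.rm = TRUE)
  den <- sums[["a"]] + sums[["b"]] + sums[["c"]]
  if (!is.finite(den) || den == 0) return(NA_real_)
  sums[["a"]] / den
}

#' Pairwise F_ST (Weir-Cockerham theta) with permutation tests
#'
#' Computes multilocus theta for every pair of groups, with significance by
#' permuting individuals between the two groups (labels permuted at the
#' individual level, so both allele copies move together).
#'
#' @inheritParams allele_frequencies
#' @param nperm Number of permutations (the study convention is 16,000).
#' @param seed RNG seed.
#' @return A tibble `group1, group2, fst, p, permutations`.
#' @export
pairwise_fst <- function(geno, by = "population", nperm = 999, seed = NULL) {
  dat <- typed(geno)
  groups <- sort(unique(dat[[by]]))
  assert_that(length(groups) >= 2, "need at least 2 groups")
  pairs <- combn(groups, 2, simplify = FALSE)
  with_seed(seed, {
    res <- lapply(pairs, function(pr) {
      sub <- dat[dat[[by]] %in% pr, , drop = FALSE]
      obs <- wc_theta(sub, by)
      p <- NA_real_
      if (nperm > 0 && is.finite(obs)) {
        ids <- unique(sub$id)
        labs <- sub[[by]][match(ids, sub$id)]
        exceed <- 0L
        for (i in seq_len(nperm)) {
          perm <- setNames(sample(labs), ids)
          sub2 <- sub
          sub2[[by]] <- unname(perm[sub2$id])
          stat <- wc_theta(sub2, by)
          if (is.finite(stat) && stat >= obs - 1e-12) exceed <- exceed + 1L
        }
        p <- perm_p(exceed, nperm)
      }
      tibble(group1 = pr[1], group2 = pr[2], fst = obs, p = p,
             permutations = nperm)
    })
    bind_rows(res)
  })
}

# ---- hierarchical AMOVA -----------------------------------------------------

# allele-count matrix: rows = groups 1..G, cols = alleles 1..K, counting both
# copies of every typed individual.
count_mat <- function(gidx, aidx1, aidx2, G, K) {
  m <- tabulate((aidx1 - 1L) * G + gidx, G * K) +
    tabulate((aidx2 - 1L) * G + gidx, G * K)
  matrix(m, nrow = G, ncol = K)
}

# sum over groups of SS among the copies in each group, identity distance:
# SS(group with counts c_1..c_K, m copies) = (m - sum(c^2)/m) / 2.
ss_within <- function(M) {
  m <- rowSums(M)
  ok <- m > 0
  sum((m[ok] - rowSums(M[ok, , drop = FALSE]^2) / m[ok]) / 2)
}

# Variance components (sigma1 = among clusters, sigma2 = among nests within
# clusters, sigma3 = among individuals within nests, sigma4 = within
# individuals) for one locus.  `nest` is an integer nest index per typed
# individual, `cl_of_nest` an integer cluster index per nest.
amova_sigma_one <- function(a1, a2, nest, cl_of_nest, n_nest, n_cl) {
  K <- max(c(a1, a2))
  N <- length(a1)
  Mn <- count_mat(nest, a1, a2, n_nest, K)
  Mc <- rowsum(Mn, cl_of_nest)
  # rowsum keeps only present groups; rebuild full matrix
  Mc_full <- matrix(0, n_cl, K)
  Mc_full[as.integer(rownames(Mc)), ] <- Mc
  tot <- colSums(Mn)
  n_p <- rowSums(Mn)
  N_g <- rowSums(Mc_full)
  Ncop <- 2 * N
  P <- sum(n_p > 0)
  G <- sum(N_g > 0)
  ss_tot <- (Ncop - sum(tot^2) / Ncop) / 2
  ss_wc <- ss_within(Mc_full)
  ss_wn <- ss_within(Mn)
  ss_wi <- sum(a1 != a2) / 2
  sigma4 <- ss_wi / N
  sigma3 <- if (N > P) ((ss_wn - ss_wi) / (N - P) - sigma4) / 2 else NA_real_
  s34 <- sigma4 + 2 * ifelse(is.na(sigma3), 0, sigma3)
  # unequal-size coefficients
  Ng_of_nest <- N_g[cl_of_nest]
  ok <- n_p > 0
  A <- sum(n_p[ok]^2 / Ng_of_nest[ok])
  B <- sum(n_p^2) / Ncop
  C <- sum(N_g^2) / Ncop
  sigma2 <- if (P > G) {
    k3 <- (Ncop - A) / (P - G)
    ((ss_wc - ss_wn) / (P - G) - s34) / k3
  } else NA_real_
  sigma1 <- if (G > 1) {
    k4 <- (A - B) / (G - 1)
    k5 <- (Ncop - C) / (G - 1)
    ((ss_tot - ss_wc) / (G - 1) - s34 - k4 * ifelse(is.na(sigma2), 0, sigma2)) / k5
  } else NA_real_
  list(sigma = c(sigma1, sigma2, sigma3, sigma4),
       ss = c(ss_tot - ss_wc, ss_wc - ss_wn, ss_wn - ss_wi, ss_wi),
       df = c(G - 1, P - G, N - P, N))
}

# internal: encode a genotype tibble into per-locus integer structures for
# fast recomputation under permutation.
amova_encode <- function(geno) {
  dat <- typed(geno) |> filter(!is.na(.data$nest), !is.na(.data$cluster))
  assert_that(nrow(dat) > 0, "no typed individuals with nest and cluster labels")
  inds <- dat |> distinct(.data$id, .data$nest, .data$cluster)
  assert_that(!anyDuplicated(inds$id),
              "an individual maps to more than one nest/cluster")
  nests <- inds |> distinct(.data$nest, .data$cluster)
  nest_levels <- nests$nest
  cl_levels <- unique(nests$cluster)
  cl_of_nest <- match(nests$cluster, cl_levels)
  nest_of_ind <- match(inds$nest, nest_levels)
  loci <- lapply(split(dat, dat$locus), function(ld) {
    alleles <- sort(unique(c(ld$a1, ld$a2)))
    list(ind = match(ld$id, inds$id),
         a1 = match(ld$a1, alleles), a2 = match(ld$a2, alleles))
  })
  list(inds = inds, nest_of_ind = nest_of_ind, cl_of_nest = cl_of_nest,
       n_nest = length(nest_levels), n_cl = length(cl_levels), loci = loci)
}

amova_sigmas <- function(enc, nest_of_ind = NULL, cl_of_nest = NULL,
                         repair = NULL) {
  nest_of_ind <- nest_of_ind %||% enc$nest_of_ind
  cl_of_nest <- cl_of_nest %||% enc$cl_of_nest
  sig <- matrix(0, length(enc$loci), 4)
  ssm <- matrix(0, length(enc$loci), 4)
  dfm <- matrix(0, length(enc$loci), 4)
  for (i in seq_along(enc$loci)) {
    lc <- enc$loci[[i]]
    a1 <- lc$a1; a2 <- lc$a2
    if (!is.null(repair)) {
      pr <- repair(a1, a2, nest_of_ind[lc$ind])
      a1 <- pr[[1]]; a2 <- pr[[2]]
    }
    s <- amova_sigma_one(a1, a2, nest_of_ind[lc$ind], cl_of_nest,
                         enc$n_nest, enc$n_cl)
    sig[i, ] <- s$sigma
    ssm[i, ] <- s$ss
    dfm[i, ] <- s$df
  }
  sums <- colSums(sig, na.rm = TRUE)
  all_na <- apply(sig, 2, function(v) all(is.na(v)))
  sums[all_na] <- NA_real_
  list(sigma = sums, per_locus = sig, ss = colSums(ssm), df = dfm[1, ])
}

amova_f <- function(sigma) {
  s1 <- sigma[1]; s2 <- sigma[2]; s3 <- sigma[3]; s4 <- sigma[4]
  tot <- s1 + s2 + s3 + s4
  c(f_ct = s1 / tot,
    f_sc = s2 / (s2 + s3 + s4),
    f_is = s3 / (s3 + s4),
    f_it = (s1 + s2 + s3) / tot)
}

# re-pair allele copies among individuals within each stratum (vector of
# stratum indices, one per typed individual at this locus).
repair_within <- function(a1, a2, strata) {
  for (s in unique(strata)) {
    w <- which(strata == s)
    copies <- sample(c(a1[w], a2[w]))
    m <- length(w)
    a1[w] <- copies[seq_len(m)]
    a2[w] <- copies[m + seq_len(m)]
  }
  list(a1, a2)
}

#' Four-level hierarchical AMOVA over clusters, nests and individuals
#'
#' Partitions allele-identity variance among clusters (F_CT), among nests
#' within clusters (F_SC), among individuals within nests (F_IS), and within
#' individuals (F_IT), with unequal sample sizes and missing genotypes
#' handled per locus. Negative variance components are retained, so slightly
#' negative F_CT values are representable. Each statistic has its own
#' permutation null: whole nests among clusters for F_CT; individuals among
#' nests within clusters for F_SC; allele copies among individuals within
#' nests for F_IS; allele copies among all individuals for F_IT.
#'
#' @inheritParams geno_loci
#' @param nperm Permutations per statistic (the study convention is 10,000).
#' @param seed RNG seed.
#' @param statistics Which F-statistics to test by permutation (all four by
#'   default); estimates are always reported for all levels.
#' @return An object of class `amova_fit`: a list with `components` (tibble
#'   `level, df, ss, sigma, pct_total`), `statistics` (tibble
#'   `statistic, estimate, p, se`), `permutations`, and `degenerate` (TRUE
#'   when there is no variation at all, in which case all statistics are
#'   reported as 0). The genotype tibble must carry `nest` and `cluster`
#'   labels (see [set_clusters()]).
#' @export
hierarchical_amova <- function(geno, nperm = 999, seed = NULL,
                               statistics = c("F_CT", "F_SC", "F_IS",
                                              "F_IT")) {
  enc <- amova_encode(geno)
  obs <- amova_sigmas(enc)
  tot <- sum(obs$sigma)
  degenerate <- isTRUE(all(abs(obs$ss) < 1e-12))
  f_obs <- if (degenerate) c(f_ct = 0, f_sc = 0, f_is = 0, f_it = 0)
    else amova_f(obs$sigma)
  pvals <- c(f_ct = NA_real_, f_sc = NA_real_, f_is = NA_real_,
             f_it = NA_real_)
  ses <- pvals
  if (!degenerate && nperm > 0) {
    with_seed(seed, {
      n_ind <- nrow(enc$inds)
      cl_of_ind <- enc$cl_of_nest[enc$nest_of_ind]
      stats_perm <- matrix(NA_real_, nperm, 4)
      do_stat <- c("F_CT", "F_SC", "F_IS", "F_IT") %in% statistics
      for (i in seq_len(nperm)) {
        if (do_stat[1]) {
          # F_CT: whole nests permuted among clusters
          s_ct <- amova_sigmas(enc, cl_of_nest = sample(enc$cl_of_nest))
          stats_perm[i, 1] <- amova_f(s_ct$sigma)[["f_ct"]]
        }
        if (do_stat[2]) {
          # F_SC: individuals permuted among nests within clusters
          nest_perm <- enc$nest_of_ind
          for (g in seq_len(enc$n_cl)) {
            w <- which(cl_of_ind == g)
            nest_perm[w] <- sample(nest_perm[w])
          }
          s_sc <- amova_sigmas(enc, nest_of_ind = nest_perm)
          stats_perm[i, 2] <- amova_f(s_sc$sigma)[["f_sc"]]
        }
        if (do_stat[3]) {
          # F_IS: allele copies re-paired among individuals within nests
          s_is <- amova_sigmas(enc, repair = function(a1, a2, nest)
            repair_within(a1, a2, nest))
          stats_perm[i, 3] <- amova_f(s_is$sigma)[["f_is"]]
        }
        if (do_stat[4]) {
          # F_IT: allele copies re-paired among all individuals
          s_it <- amova_sigmas(enc, repair = function(a1, a2, nest)
            repair_within(a1, a2, rep(1L, length(nest))))
          stats_perm[i, 4] <- amova_f(s_it$sigma)[["f_it"]]
        }
      }
      for (j in 1:4) {
        if (!is.finite(f_obs[j])) next
        ok <- is.finite(stats_perm[, j])
        exceed <- sum(stats_perm[ok, j] >= f_obs[j] - 1e-12)
        pvals[j] <- perm_p(exceed, sum(ok))
        ses[j] <- sqrt(pvals[j] * (1 - pvals[j]) / max(1, sum(ok)))
      }
    })
  }
  tot_fin <- sum(obs$sigma, na.rm = TRUE)
  components <- tibble(
    level = c("among_clusters", "among_nests_within_clusters",
              "among_individuals_within_nests", "within_individuals"),
    df = obs$df, ss = obs$ss, sigma = obs$sigma,
    pct_total = if (is.finite(tot_fin) && tot_fin != 0) {
      100 * obs$sigma / tot_fin
    } else {
      rep(0, 4)
    }
  )
  statistics <- tibble(
    statistic = c("F_CT", "F_SC", "F_IS", "F_IT"),
    estimate = unname(f_obs), p = unname(pvals), se = unname(ses)
  )
  structure(list(components = components, statistics = statistics,
                 permutations = nperm, degenerate = degenerate,
                 n_individuals = nrow(enc$inds), n_nests = enc$n_nest,
                 n_clusters = enc$n_cl),
            class = "amova_fit")
}

#' @export
print.amova_fit <- function(x, ...) {
  cat(sprintf("Hierarchical AMOVA: %d individuals, %d nests, %d clusters\n",
              x$n_individuals, x$n_nests, x$n_clusters))
  if (x$degenerate) cat("(degenerate: no molecular variation)\n")
  print(as.data.frame(x$statistics), row.names = FALSE)
  invisible(x)
}

#' Tidy an AMOVA fit into one row per F-statistic
#' @param x An `amova_fit` from [hierarchical_amova()].
#' @param ... Unused.
#' @method tidy amova_fit
#' @export
tidy.amova_fit <- function(x, ...) x$statistics

#' One-row summary of an AMOVA fit
#' @inheritParams tidy.amova_fit
#' @method glance amova_fit
#' @export
glance.amova_fit <- function(x, ...) {
  est <- setNames(x$statistics$estimate, tolower(x$statistics$statistic))
  tibble(n_individuals = x$n_individuals, n_nests = x$n_nests,
         n_clusters = x$n_clusters, f_ct = est[["f_ct"]],
         f_sc = est[["f_sc"]], f_is = est[["f_is"]], f_it = est[["f_it"]],
         permutations = x$permutations, degenerate = x$degenerate)
}

#' Report table for AMOVA results
#'
#' @param result An `amova_fit`, or a pairwise F_ST tibble from
#'   [pairwise_fst()].
#' @return A tibble `statistic, estimate, p, se` (the two-level case has one
#'   F_ST row per pair); the degenerate flag propagates as an attribute.
#' @export
amova_report <- function(result) {
  if (inherits(result, "amova_fit")) {
    out <- result$statistics
    attr(out, "degenerate") <- result$degenerate
    return(out)
  }
  tibble(statistic = paste0("F_ST(", result$group1, " vs ", result$group2, ")"),
         estimate = result$fst, p = result$p, se = NA_real_)
}
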