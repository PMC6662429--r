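# Per-locus descriptive genetics on the long genotype tibble.  All functions
# exclude missing genotypes pairwise per locus (never listwise) and take the
# grouping label as a column name, defaulting to the population label.

typed <- function(geno) geno |> filter(!is.na(.data$a1))

#' Allele frequencies per group and locus
#'
#' @inheritParams geno_loci
#' @param by Name of the label column defining groups (default
#'   `"population"`).
#' @return A tibble with the grouping column, `locus`, `allele`, `count`
#'   (allele copies observed), `n_copies` (total copies typed at the locus in
#'   the group) and `freq`. Frequencies sum to 1 per locus and group. Loci
#'   with no typed individuals in a group simply have no rows for it.
#' @export
allele_frequencies <- function(geno, by = "population") {
  long <- typed(geno) |>
    select(dplyr::all_of(by), "locus", "a1", "a2") |>
    pivot_longer(c("a1", "a2"), values_to = "allele") |>
    count(.data[[by]], .data$locus, .data$allele, name = "count")
  long |>
    group_by(.data[[by]], .data$locus) |>
    mutate(n_copies = sum(.data$count), freq = .data$count / .data$n_copies) |>
    ungroup()
}

#' Observed and expected heterozygosity per group and locus
#'
#' Expected heterozygosity uses Nei's unbiased small-sample correction
#' \eqn{H_E = \frac{2n}{2n-1}(1 - \sum_k p_k^2)}.
#'
#' @inheritParams allele_frequencies
#' @return A tibble with the grouping column, `locus`, `n` (typed
#'   individuals), `n_alleles`, `h_obs`, `h_exp`.
#' @export
heterozygosity <- function(geno, by = "population") {
  dat <- typed(geno)
  assert_that(nrow(dat) > 0, "no typed genotypes")
  obs <- dat |>
    group_by(.data[[by]], .data$locus) |>
    summarise(n = dplyr::n(), h_obs = mean(.data$a1 != .data$a2),
              .groups = "drop")
  exp <- allele_frequencies(geno, by) |>
    group_by(.data[[by]], .data$locus) |>
    summarise(n_alleles = dplyr::n(),
              h_exp = (.data$n_copies[1] / (.data$n_copies[1] - 1)) *
                (1 - sum(.data$freq^2)),
              .groups = "drop")
  res <- obs |> left_join(exp, by = c(by, "locus"))
  if (any(res$n < 2)) {
    abort("heterozygosity needs at least 2 typed individuals per group/locus")
  }
  res |> select(dplyr::all_of(by), "locus", "n", "n_alleles", "h_obs", "h_exp")
}

# Monte Carlo exact HWE test for one locus: probability, under the
# fixed-allele-count (Levene) null, of genotype tables no more probable than
# the observed one.  Only the table-dependent part of the conditional
# probability matters: log T = h log 2 - sum(log n_jk!).
hwe_mc_one <- function(a1, a2, reps) {
  n <- length(a1)
  if (length(unique(c(a1, a2))) < 2) return(c(p = 1, se = 0))
  tab_stat <- function(x1, x2) {
    key <- paste(pmin(x1, x2), pmax(x1, x2))
    njk <- tabulate(factor(key))
    sum(x1 != x2) * log(2) - sum(lfactorial(njk))
  }
  t_obs <- tab_stat(a1, a2)
  copies <- c(a1, a2)
  exceed <- 0L
  for (i in seq_len(reps)) {
    s <- sample(copies)
    if (tab_stat(s[1:n], s[(n + 1):(2 * n)]) <= t_obs + 1e-9) exceed <- exceed + 1L
  }
  p <- perm_p(exceed, reps)
  c(p = p, se = sqrt(p * (1 - p) / reps))
}

#' Exact test of Hardy-Weinberg equilibrium (Monte Carlo)
#'
#' For each group and locus, estimates the exact-test p-value of Guo &
#' Thompson's conditional null (all genotype tables with the observed allele
#' counts) by direct Monte Carlo sampling of random pairings of the allele
#' copies, together with its Monte Carlo standard error. Monomorphic loci
#' have p = 1 by convention.
#'
#' @inheritParams allele_frequencies
#' @param reps Number of random tables (default 2000).
#' @param seed RNG seed.
#' @return A tibble with the grouping column, `locus`, `n`, `hwe_p`, `hwe_se`.
#' @export
hwe_exact <- function(geno, by = "population", reps = 2000, seed = NULL) {
  dat <- typed(geno)
  with_seed(seed, {
    dat |>
      group_by(.data[[by]], .data$locus) |>
      summarise(n = dplyr::n(), {
        if (dplyr::n() < 3) {
          tibble(hwe_p = NA_real_, hwe_se = NA_real_)
        } else {
          ps <- hwe_mc_one(.data$a1, .data$a2, reps)
          tibble(hwe_p = ps[["p"]], hwe_se = ps[["se"]])
        }
      }, .groups = "drop")
  })
}

# Weir-Cockerham within-population components for one locus in one group:
# b (among individuals) and c (within individuals) summed over alleles.
wc_bc_one <- function(a1, a2) {
  n <- length(a1)
  alleles <- unique(c(a1, a2))
  p <- (tabulate(match(a1, alleles), length(alleles)) +
          tabulate(match(a2, alleles), length(alleles))) / (2 * n)
  het <- a1 != a2
  h <- vapply(seq_along(alleles), function(k) {
    mean(het & (a1 == alleles[k] | a2 == alleles[k]))
  }, numeric(1))
  b <- (n / (n - 1)) * (p * (1 - p) - (2 * n - 1) / (4 * n) * h)
  c_ <- h / 2
  c(b = sum(b), c = sum(c_))
}

#' Weir-Cockerham F_IS with permutation significance
#'
#' Estimates the within-group inbreeding coefficient f per locus and across
#' loci (summing the among- and within-individual variance components over
#' loci), for each group. Significance of the multilocus f is assessed by
#' permuting allele copies among individuals within the group; the one-sided
#' p-value is `P(rand f >= obs f)` with the `(exceed + 1)/(nperm + 1)`
#' convention.
#'
#' @inheritParams allele_frequencies
#' @param nperm Number of permutations (the study convention is 16,000).
#' @param seed RNG seed.
#' @return A tibble with the grouping column, `locus` (`"(all)"` for the
#'   multilocus row), `n`, `f_is`, and for multilocus rows `p` (NA for
#'   per-locus rows). Groups where every locus is monomorphic get `f_is` NA.
#' @export
fis_weir_cockerham <- function(geno, by = "population", nperm = 999,
                               seed = NULL) {
  dat <- typed(geno)
  groups <- unique(dat[[by]])
  with_seed(seed, {
    res <- lapply(groups, function(g) {
      gd <- dat[dat[[by]] == g, , drop = FALSE]
      loci <- unique(gd$locus)
      per <- lapply(loci, function(l) {
        ld <- gd[gd$locus == l, ]
        if (nrow(ld) < 2) return(tibble(locus = l, n = nrow(ld),
                                        b = NA_real_, c = NA_real_))
        bc <- wc_bc_one(ld$a1, ld$a2)
        tibble(locus = l, n = nrow(ld), b = bc[["b"]], c = bc[["c"]])
      }) |> bind_rows()
      fis <- function(b, c_) {
        den <- sum(b + c_, na.rm = TRUE)
        if (!is.finite(den) || den <= 0) return(NA_real_)
        1 - sum(c_, na.rm = TRUE) / den
      }
      f_locus <- ifelse(per$b + per$c > 0, 1 - per$c / (per$b + per$c), NA_real_)
      f_all <- fis(per$b, per$c)
      p_all <- NA_real_
      if (is.finite(f_all) && nperm > 0) {
        exceed <- 0L
        split_loci <- split(gd, gd$locus)
        for (i in seq_len(nperm)) {
          stat <- {
            bc <- vapply(split_loci, function(ld) {
              if (nrow(ld) < 2) return(c(b = NA_real_, c = NA_real_))
              copies <- sample(c(ld$a1, ld$a2))
              m <- nrow(ld)
              wc_bc_one(copies[1:m], copies[(m + 1):(2 * m)])
            }, numeric(2))
            fis(bc["b", ], bc["c", ])
          }
          if (is.finite(stat) && stat >= f_all - 1e-12) exceed <- exceed + 1L
        }
        p_all <- perm_p(exceed, nperm)
      }
      bind_rows(
        tibble(group = g, locus = per$locus, n = per$n, f_is = f_locus,
               p = NA_real_),
        tibble(group = g, locus = "(all)", n = max(per$n), f_is = f_all,
               p = p_all)
      )
    }) |> bind_rows()
    names(res)[names(res) == "group"] <- by
    res
  })
}

#' Holm step-down multiple-testing correction
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @param alpha Family-wise error rate (default 0.05).
#' @return A tibble `p, p_adj, reject` in the input order; `p_adj` are the
#'   monotone Holm-adjusted p-values.
#' @export
holm_correction <- function(pvals, alpha = 0.05) {
  assert_that(all(pvals >= 0 & pvals <= 1, na.rm = TRUE),
              "p-values must lie in [0, 1]")
  adj <- p.adjust(pvals, method = "holm")
  tibble(p = pvals, p_adj = adj, reject = !is.na(adj) & adj <= alpha)
}

# Dempster EM for a single non-amplifying (null) allele at one locus.
# Classes: observed heterozygotes j/k, apparent homozygotes k/k (true k/k or
# k/null), and blanks (null/null; amplification failures are absorbed here,
# which is the convention of the classic EM treatment).
null_em_one <- function(a1, a2, n_blank, max_iter = 10000, tol = 1e-9) {
  n_vis <- length(a1)
  n <- n_vis + n_blank
  alleles <- sort(unique(c(a1, a2)))
  K <- length(alleles)
  i1 <- match(a1, alleles); i2 <- match(a2, alleles)
  het <- i1 != i2
  het_copies <- tabulate(c(i1[het], i2[het]), K)
  hom_counts <- tabulate(i1[!het], K)
  # init from apparent copy counts, reserving a little mass for the null
  r <- max(0.05, sqrt(n_blank / max(1, n)))
  p <- tabulate(c(i1, i2), K)
  p <- (1 - r) * p / sum(p)
  for (it in seq_len(max_iter)) {
    w <- ifelse(p > 0, p^2 / (p^2 + 2 * p * r), 1)  # P(true hom | apparent hom)
    cnt <- het_copies + hom_counts * (1 + w)
    null_cnt <- sum(hom_counts * (1 - w)) + 2 * n_blank
    tot <- 2 * n
    p_new <- cnt / tot
    r_new <- null_cnt / tot
    delta <- max(abs(c(p_new - p, r_new - r)))
    p <- p_new; r <- r_new
    if (delta < tol) return(list(freq = r, converged = TRUE, iters = it))
  }
  list(freq = r, converged = FALSE, iters = max_iter)
}

#' Null-allele frequency by EM
#'
#' Estimates, per locus, the frequency of a single non-amplifying allele by
#' the Dempster EM algorithm, from the deficit of observed heterozygotes
#' (apparent homozygotes are a mixture of true homozygotes and
#' visible/null heterozygotes; blank genotypes are treated as null
#' homozygotes).
#'
#' @inheritParams geno_loci
#' @param loci Loci to estimate (default: all).
#' @param max_iter,tol EM stopping rule.
#' @return A tibble `locus, null_freq, converged, n` (individuals, including
#'   blanks). Monomorphic loci return `NA` with a note that the model needs
#'   at least two visible alleles.
#' @export
null_allele_estimate <- function(geno, loci = NULL, max_iter = 10000,
                                 tol = 1e-9) {
  loci <- loci %||% geno_loci(geno)
  res <- lapply(loci, function(l) {
    ld <- geno[geno$locus == l, ]
    vis <- ld[!is.na(ld$a1), ]
    n_blank <- sum(is.na(ld$a1))
    if (length(unique(c(vis$a1, vis$a2))) < 2) {
      return(tibble(locus = l, null_freq = NA_real_, converged = NA,
                    n = nrow(ld)))
    }
    em <- null_em_one(vis$a1, vis$a2, n_blank, max_iter, tol)
    tibble(locus = l, null_freq = em$freq, converged = em$converged,
           n = nrow(ld))
  })
  bind_rows(res)
}

#' Drop loci whose estimated null-allele frequency exceeds a threshold
#'
#' @inheritParams geno_loci
#' @param estimates A tibble `locus, null_freq` from
#'   [null_allele_estimate()].
#' @param threshold Loci with `null_freq` strictly greater than this are
#'   removed (default 0.20; a locus at exactly the threshold is kept).
#' @return The genotype tibble without the flagged loci; the dropped locus
#'   names are stored in the `"dropped_loci"` attribute.
#' @export
filter_loci <- function(geno, estimates, threshold = 0.20) {
  assert_that(all(geno_loci(geno) %in% estimates$locus),
              "estimates must cover every locus in the panel")
  drop <- estimates$locus[!is.na(estimates$null_freq) &
                            estimates$null_freq > threshold]
  out <- geno |> filter(!.data$locus %in% drop)
  attr(out, "dropped_loci") <- drop
  out
}
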