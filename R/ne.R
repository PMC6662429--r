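# Effective population size from a single sample, by three classical
# single-cohort estimators: linkage disequilibrium (Burrows' composite delta
# with the Waples (2006) sampling-bias correction, after Waples & Do's LDNe),
# heterozygote excess (Zhdanova & Pudovkin 2008), and molecular coancestry
# (Nomura 2008).  All report Inf rather than negative estimates when the
# signal is at or below its pure-sampling expectation.

# Genotypes of one group as a list of per-locus integer matrices (n x 2,
# NA = missing), individuals aligned across loci.
geno_matrices <- function(geno) {
  ids <- geno_inds(geno)
  loci <- geno_loci(geno)
  lapply(loci, function(l) {
    ld <- geno[geno$locus == l, ]
    m <- matrix(NA_integer_, length(ids), 2)
    ix <- match(ld$id, ids)
    m[ix, 1] <- ld$a1
    m[ix, 2] <- ld$a2
    m
  }) |> setNames(loci)
}

# mean Burrows r^2 over all allele pairs of one locus pair, restricted to
# alleles with sample frequency in [pcrit, 1 - pcrit]; returns the
# comparisons as rows (r2, S) or NULL.
burrows_r2_pair <- function(mA, mB, pcrit) {
  ok <- !is.na(mA[, 1]) & !is.na(mB[, 1])
  S <- sum(ok)
  if (S < 3) return(NULL)
  mA <- mA[ok, , drop = FALSE]
  mB <- mB[ok, , drop = FALSE]
  usable <- function(m) {
    al <- sort(unique(as.vector(m)))
    f <- vapply(al, function(a) mean(m == a), numeric(1))
    keep <- al[f >= pcrit & f <= 1 - pcrit]
    # with two alleles the second is perfectly (negatively) correlated with
    # the first; drop it
    if (length(al) == 2 && length(keep) == 2) keep <- keep[1]
    keep
  }
  aA <- usable(mA)
  aB <- usable(mB)
  if (length(aA) == 0 || length(aB) == 0) return(NULL)
  out <- vector("list", length(aA) * length(aB))
  k <- 0
  for (ai in aA) {
    X <- rowSums(mA == ai)
    p <- mean(X) / 2
    for (bj in aB) {
      Y <- rowSums(mB == bj)
      q <- mean(Y) / 2
      delta <- (sum(X * Y) / S) / 2 - 2 * p * q
      delta <- delta * S / (S - 1)
      r2 <- delta^2 / (p * (1 - p) * q * (1 - q))
      k <- k + 1
      out[[k]] <- c(r2 = r2, S = S)
    }
  }
  do.call(rbind, out[seq_len(k)])
}

# expected r^2 under pure sampling (random mating), Waples (2006)
r2_sample_expect <- function(S) {
  ifelse(S >= 30, 1 / S + 3.19 / S^2, 0.0018 + 0.907 / S + 4.44 / S^2)
}

ld_ne_from_r2 <- function(r2bar, S) {
  r2p <- r2bar - r2_sample_expect(S)
  if (!is.finite(r2p) || r2p <= 0) return(Inf)
  if (S >= 30) {
    disc <- 1 / 9 - 2.76 * r2p
    (1 / 3 + sqrt(max(0, disc))) / (2 * r2p)
  } else {
    disc <- 0.308^2 - 2.08 * r2p
    (0.308 + sqrt(max(0, disc))) / (2 * r2p)
  }
}

#' Effective population size by the linkage-disequilibrium method
#'
#' Computes Burrows' composite disequilibrium between every pair of loci,
#' averages the squared correlation over allele-pair comparisons, subtracts
#' the expected pure-sampling component at the harmonic-mean sample size,
#' and inverts the drift relationship for Ne under random mating. The
#' confidence interval comes from a leave-one-locus-out jackknife (locus
#' pairs share loci, so a pairwise jackknife would be too confident).
#'
#' @inheritParams geno_loci
#' @param pcrit Alleles with sample frequency below this are excluded
#'   (default 0.05, the usual guard against rare-allele bias).
#' @param jackknife Compute a 95% CI by locus jackknife (default TRUE).
#' @return A one-row tibble `method, ne, ci_lo, ci_hi, r2, r2_expected, n,
#'   n_comparisons`; `ne` is `Inf` when mean r2 does not exceed its sampling
#'   expectation.
#' @export
ne_ld <- function(geno, pcrit = 0.05, jackknife = TRUE) {
  mats <- geno_matrices(geno)
  assert_that(length(mats) >= 2,
              "the LD method needs at least 2 loci (no locus pairs otherwise)")
  pairs <- combn(length(mats), 2, simplify = FALSE)
  comp <- lapply(pairs, function(pr) burrows_r2_pair(mats[[pr[1]]],
                                                     mats[[pr[2]]], pcrit))
  keep <- !vapply(comp, is.null, logical(1))
  assert_that(any(keep), "no polymorphic locus pairs after pcrit screening")
  comp <- comp[keep]
  pairs <- pairs[keep]
  all_rows <- do.call(rbind, comp)
  r2bar <- mean(all_rows[, "r2"])
  S_h <- 1 / mean(1 / all_rows[, "S"])
  ne <- ld_ne_from_r2(r2bar, S_h)
  ci <- c(NA_real_, NA_real_)
  # jackknife leaves out one locus at a time (locus pairs sharing a locus
  # are dependent, so a pairwise jackknife would understate the variance)
  drop_units <- unique(unlist(pairs))
  if (jackknife && length(drop_units) > 2) {
    m <- length(drop_units)
    jack <- vapply(drop_units, function(l) {
      keep_p <- !vapply(pairs, function(pr) l %in% pr, logical(1))
      rows <- do.call(rbind, comp[keep_p])
      mean(rows[, "r2"])
    }, numeric(1))
    jbar <- mean(jack)
    se <- sqrt((m - 1) / m * sum((jack - jbar)^2))
    r2_ci <- r2bar + c(1, -1) * 1.96 * se  # low r2 -> high Ne
    ci <- vapply(r2_ci, ld_ne_from_r2, numeric(1), S = S_h)
    ci <- sort(ci)
  }
  tibble(method = "ld", ne = ne, ci_lo = ci[1], ci_hi = ci[2], r2 = r2bar,
         r2_expected = r2_sample_expect(S_h), n = S_h,
         n_comparisons = nrow(all_rows))
}

#' Effective number of breeders by the heterozygote-excess method
#'
#' In the progeny of few breeders, allele frequencies differ between parents
#' by chance and offspring show an excess of heterozygotes relative to
#' Hardy-Weinberg expectation. The per-allele relative excess
#' `D = (H_obs - H_exp) / H_exp` is averaged over alleles and loci and
#' inverted as `Nb = 1/(2 D) + 1/(2 (D + 1))`.
#'
#' @inheritParams ne_ld
#' @return A one-row tibble `method, ne, ci_lo, ci_hi, d_bar, n`; `ne` is
#'   `Inf` when the mean excess is zero or negative (the usual outcome at
#'   moderate true size and modest sample size).
#' @export
ne_het_excess <- function(geno, pcrit = 0.05) {
  mats <- geno_matrices(geno)
  ds <- unlist(lapply(mats, function(m) {
    m <- m[!is.na(m[, 1]), , drop = FALSE]
    n <- nrow(m)
    if (n < 2) return(NULL)
    al <- sort(unique(as.vector(m)))
    if (length(al) < 2) return(NULL)
    vapply(al, function(a) {
      p <- mean(m == a)
      if (p < pcrit || p > 1 - pcrit) return(NA_real_)
      h_obs <- mean(xor(m[, 1] == a, m[, 2] == a))
      h_exp <- 2 * p * (1 - p) * (2 * n) / (2 * n - 1)
      (h_obs - h_exp) / h_exp
    }, numeric(1))
  }))
  ds <- ds[is.finite(ds)]
  assert_that(length(ds) > 0, "no alleles pass the pcrit screen")
  dbar <- mean(ds)
  n <- max(vapply(mats, function(m) sum(!is.na(m[, 1])), numeric(1)))
  ne <- if (dbar <= 0) Inf else 1 / (2 * dbar) + 1 / (2 * (dbar + 1))
  tibble(method = "het_excess", ne = ne, ci_lo = NA_real_, ci_hi = NA_real_,
         d_bar = dbar, n = n)
}

#' Effective number of breeders by molecular coancestry
#'
#' Estimates molecular coancestry for every pair of sampled individuals --
#' allele-sharing similarity corrected for the background probability that
#' two random copies match (`sum p_k^2`) -- and inverts the mean coancestry
#' as `f = 1/(2 Nb)`. Family-structured samples (few parents) have high
#' pairwise coancestry and a small Nb. The CI comes from a jackknife over
#' individuals.
#'
#' The reference frequencies matter. When they must be estimated from the
#' sample itself (the field situation, and the default), the mean pairwise
#' coancestry is close to zero by construction -- the sample frequencies
#' absorb the mean kinship -- so the estimator falls back on the mean of the
#' *positive* pairwise values. That convention detects small breeder pools
#' but saturates as the true number of parents grows. If the allele
#' frequencies of the breeding pool are known independently (`ref_freqs`,
#' e.g. the generating frequencies of a synthetic study), the plain
#' all-pairs mean is used and the breeder count is recovered without that
#' saturation.
#'
#' @inheritParams ne_ld
#' @param ref_freqs Optional external reference frequencies: a named list
#'   `locus -> named numeric vector` of allele frequencies (names are allele
#'   codes). Default `NULL` uses sample frequencies.
#' @return A one-row tibble `method, ne, ci_lo, ci_hi, f_bar, n`; `ne` is
#'   `Inf` when coancestry is at or below background.
#' @export
ne_coancestry <- function(geno, ref_freqs = NULL) {
  mats <- geno_matrices(geno)
  n_ind <- nrow(mats[[1]])
  assert_that(n_ind >= 2, "need at least 2 individuals")
  external_ref <- !is.null(ref_freqs)
  # per-locus similarity numerators and background
  per_locus <- lapply(names(mats), function(lname) {
    m <- mats[[lname]]
    ok <- !is.na(m[, 1])
    al <- sort(unique(as.vector(m[ok, ])))
    if (length(al) < 2) return(NULL)
    if (external_ref) {
      rf <- ref_freqs[[lname]]
      assert_that(!is.null(rf), paste0("ref_freqs missing locus ", lname))
      s0 <- sum(rf^2)
    } else {
      f <- vapply(al, function(a) mean(m[ok, ] == a), numeric(1))
      s0 <- sum(f^2)
    }
    # similarity s_ij = mean over the 4 copy comparisons
    A1 <- outer(m[, 1], m[, 1], "==") + outer(m[, 1], m[, 2], "==") +
      outer(m[, 2], m[, 1], "==") + outer(m[, 2], m[, 2], "==")
    s <- A1 / 4
    s[!ok, ] <- NA
    s[, !ok] <- NA
    list(num = s - s0, den = 1 - s0)
  })
  per_locus <- per_locus[!vapply(per_locus, is.null, logical(1))]
  assert_that(length(per_locus) > 0, "no polymorphic loci")
  num <- Reduce(`+`, lapply(per_locus, function(x) {
    y <- x$num
    y[is.na(y)] <- 0
    y
  }))
  cnt <- Reduce(`+`, lapply(per_locus, function(x) (!is.na(x$num)) * x$den))
  fmat <- num / cnt
  pos_mean <- if (external_ref) {
    function(v) mean(v[is.finite(v)])
  } else {
    function(v) {
      v <- v[is.finite(v) & v > 0]
      if (length(v) == 0) return(NA_real_)
      mean(v)
    }
  }
  ut <- upper.tri(fmat)
  fbar <- pos_mean(fmat[ut])
  ne_of <- function(f) if (!is.finite(f) || f <= 0) Inf else 1 / (2 * f)
  ne <- ne_of(fbar)
  ci <- c(NA_real_, NA_real_)
  if (n_ind > 3) {
    jack <- vapply(seq_len(n_ind), function(i) {
      sub <- fmat[-i, -i]
      pos_mean(sub[upper.tri(sub)])
    }, numeric(1))
    jbar <- mean(jack)
    se <- sqrt((n_ind - 1) / n_ind * sum((jack - jbar)^2))
    f_ci <- fbar + c(1, -1) * 1.96 * se
    ci <- sort(vapply(f_ci, ne_of, numeric(1)))
  }
  tibble(method = "coancestry", ne = ne, ci_lo = ci[1], ci_hi = ci[2],
         f_bar = fbar, n = n_ind)
}

#' Table of all three Ne estimates for one group
#'
#' @inheritParams ne_ld
#' @return A tibble with one row per method, `Inf` serialised as `Inf` in R
#'   and `"inf"` when written to CSV by [run_pipeline()].
#' @export
ne_estimates <- function(geno, pcrit = 0.05) {
  bind_rows(
    ne_ld(geno, pcrit = pcrit) |> select("method", "ne", "ci_lo", "ci_hi", "n"),
    ne_het_excess(geno, pcrit = pcrit) |>
      select("method", "ne", "ci_lo", "ci_hi", "n"),
    ne_coancestry(geno) |> select("method", "ne", "ci_lo", "ci_hi", "n")
  )
}
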