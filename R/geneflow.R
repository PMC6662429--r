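# Gene flow from private alleles, after Barton & Slatkin's (1986) log-log
# regression of the mean private-allele frequency p(1) on Nm:
#   ln p(1) = a + b ln(Nm)
# with coefficients tabulated for per-deme sample sizes of 10, 25 and 50
# (the sizes used in the original simulations).  The sample-size correction
# interpolates the estimate linearly between the two bracketing regressions
# at the harmonic-mean sample size, the convention popularised by Genepop.

bs_coefs <- data.frame(
  n = c(10, 25, 50),
  a = c(-2.44, -2.26, -1.83),
  b = c(-0.505, -0.576, -0.574)
)

bs_nm_at <- function(log_p1, nref) {
  i <- match(nref, bs_coefs$n)
  exp((log_p1 - bs_coefs$a[i]) / bs_coefs$b[i])
}

#' Gene flow (Nm) by the private-allele method
#'
#' Computes the mean frequency of private alleles (alleles observed in
#' exactly one group), then solves the Barton-Slatkin regression for the
#' number of migrants per generation, interpolating between the tabulated
#' reference sample sizes (10, 25, 50) at the harmonic-mean number of
#' individuals per group.
#'
#' @inheritParams allele_frequencies
#' @return A one-row tibble `nm, mean_private_freq, n_private,
#'   mean_sample_size`. When no private alleles exist `nm` is `NA` with a
#'   message: the regression is unbounded, i.e. gene flow is too high to
#'   measure this way.
#' @export
private_allele_nm <- function(geno, by = "population") {
  freqs <- allele_frequencies(geno, by)
  groups <- unique(freqs[[by]])
  assert_that(length(groups) >= 2, "need at least 2 groups")
  priv <- freqs |>
    group_by(.data$locus, .data$allele) |>
    filter(dplyr::n() == 1) |>
    ungroup()
  # harmonic mean individuals per group (copies / 2, averaged over loci)
  nsz <- typed(geno) |>
    count(.data[[by]], .data$locus) |>
    group_by(.data[[by]]) |>
    summarise(n = mean(.data$n), .groups = "drop")
  n_harm <- 1 / mean(1 / nsz$n)
  if (nrow(priv) == 0) {
    message("no private alleles: Nm undefined (unbounded gene flow)")
    return(tibble(nm = NA_real_, mean_private_freq = NA_real_,
                  n_private = 0L, mean_sample_size = n_harm))
  }
  p1 <- mean(priv$freq)
  lg <- log(p1)
  nc <- pmin(50, pmax(10, n_harm))
  lo <- max(bs_coefs$n[bs_coefs$n <= nc])
  hi <- min(bs_coefs$n[bs_coefs$n >= nc])
  nm <- if (lo == hi) {
    bs_nm_at(lg, lo)
  } else {
    wt <- (nc - lo) / (hi - lo)
    (1 - wt) * bs_nm_at(lg, lo) + wt * bs_nm_at(lg, hi)
  }
  tibble(nm = nm, mean_private_freq = p1, n_private = nrow(priv),
         mean_sample_size = n_harm)
}
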