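# Isolation by distance: Nei's standard genetic distance between frequency
# units (nests by default), straight-line geographic distance, and the
# Mantel permutation test of their correlation.

#' Nei's standard genetic distance between groups
#'
#' \eqn{D = -\ln I}, where the normalised identity
#' \eqn{I = \sum_l \sum_k x_k y_k / \sqrt{\sum_l \sum_k x_k^2 \cdot \sum_l \sum_k y_k^2}}
#' aggregates over loci before normalising. Groups sharing no alleles at any
#' locus have \eqn{I = 0} and infinite distance (flagged, left as `Inf`).
#'
#' @inheritParams allele_frequencies
#' @param by Frequency unit (default `"nest"`; use `"id"` for an
#'   individual-by-individual matrix where each individual is a 2-copy
#'   frequency vector).
#' @return A symmetric matrix of class `dist`-convertible (plain matrix with
#'   dimnames); zero diagonal.
#' @export
nei_distance <- function(geno, by = "nest") {
  freqs <- allele_frequencies(geno, by)
  groups <- unique(freqs[[by]])
  assert_that(length(groups) >= 2, "need at least 2 groups")
  # frequency vectors per group: named list locus -> allele -> freq
  key <- paste(freqs$locus, freqs$allele, sep = "\r")
  all_keys <- unique(key)
  fm <- matrix(0, length(groups), length(all_keys),
               dimnames = list(groups, all_keys))
  fm[cbind(match(freqs[[by]], groups), match(key, all_keys))] <- freqs$freq
  locus_of_key <- sub("\r.*$", "", all_keys)
  # which loci each group was typed at
  typed_loci <- freqs |> distinct(.data[[by]], .data$locus)
  n <- length(groups)
  D <- matrix(0, n, n, dimnames = list(groups, groups))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      li <- typed_loci$locus[typed_loci[[by]] == groups[i]]
      lj <- typed_loci$locus[typed_loci[[by]] == groups[j]]
      shared <- locus_of_key %in% intersect(li, lj)
      x <- fm[i, shared]; y <- fm[j, shared]
      jxy <- sum(x * y); jx <- sum(x^2); jy <- sum(y^2)
      I <- jxy / sqrt(jx * jy)
      D[i, j] <- D[j, i] <- if (I <= 0) Inf else -log(min(1, I))
    }
  }
  if (any(is.infinite(D))) {
    warn(sprintf("%d pair(s) share no alleles: distance set to Inf",
                 sum(is.infinite(D[upper.tri(D)]))))
  }
  D
}

#' Euclidean (straight-line) distance matrix
#'
#' @param coords A `ppattern` or any data frame with columns `id, x, y`
#'   (metres, planar).
#' @return A symmetric matrix of pairwise distances with ids as dimnames.
#' @export
euclidean_distance <- function(coords) {
  m <- as.matrix(dist(cbind(coords$x, coords$y)))
  dimnames(m) <- list(coords$id, coords$id)
  m
}

#' Mantel test between two distance matrices
#'
#' The statistic is the Pearson correlation of the off-diagonal
#' upper-triangle entries; the null is generated by simultaneous row/column
#' permutation of the second matrix. One-sided for positive association (the
#' isolation-by-distance alternative), with
#' `p = (exceedances + 1) / (permutations + 1)`.
#'
#' @param a,b Symmetric distance matrices with identical ids in identical
#'   order (dimnames, if present, are checked).
#' @param nperm Number of permutations (the study convention is 10,000).
#' @param seed RNG seed.
#' @param na_action `"pairwise"` (default) drops non-finite entries (e.g.
#'   infinite Nei distances) from the correlation, pairwise under every
#'   permutation; `"error"` refuses them.
#' @return A one-row tibble of class `mantel_result`:
#'   `r, r2, p, permutations, n`.
#' @export
mantel_test <- function(a, b, nperm = 999, seed = NULL,
                        na_action = c("pairwise", "error")) {
  na_action <- match.arg(na_action)
  a <- as.matrix(a); b <- as.matrix(b)
  assert_that(all(dim(a) == dim(b)), "matrices differ in size")
  if (!is.null(dimnames(a)[[1]]) && !is.null(dimnames(b)[[1]])) {
    assert_that(identical(dimnames(a)[[1]], dimnames(b)[[1]]),
                "matrices must share ids in the same order")
  }
  n <- nrow(a)
  ut <- upper.tri(a)
  if (na_action == "error" && (any(!is.finite(a[ut])) || any(!is.finite(b[ut])))) {
    abort("non-finite distances present (na_action = 'error')")
  }
  cor_ut <- function(bm) {
    av <- a[ut]; bv <- bm[ut]
    ok <- is.finite(av) & is.finite(bv)
    if (sd(av[ok]) == 0 || sd(bv[ok]) == 0) {
      abort("constant distance matrix: Mantel r undefined")
    }
    cor(av[ok], bv[ok])
  }
  r_obs <- cor_ut(b)
  p <- with_seed(seed, {
    exceed <- 0L
    for (i in seq_len(nperm)) {
      ord <- sample.int(n)
      if (cor_ut(b[ord, ord]) >= r_obs - 1e-12) exceed <- exceed + 1L
    }
    perm_p(exceed, nperm)
  })
  out <- tibble(r = r_obs, r2 = r_obs^2, p = p, permutations = nperm, n = n)
  class(out) <- c("mantel_result", class(out))
  out
}

#' Tidy a Mantel result
#' @param x A `mantel_result`.
#' @param ... Unused.
#' @method tidy mantel_result
#' @export
tidy.mantel_result <- function(x, ...) as_tibble(unclass(x))

#' @method glance mantel_result
#' @export
glance.mantel_result <- function(x, ...) as_tibble(unclass(x))

#' Isolation-by-distance test for a study
#'
#' Convenience wrapper pairing Nei genetic distances with geographic
#' distances. In `mode = "nest"` (default) each nest is the frequency unit
#' and geographic distances are between nest coordinates; in `mode =
#' "individual"` each individual is a 2-copy frequency vector located at its
#' natal nest.
#'
#' @inheritParams geno_loci
#' @param pattern A `ppattern` of nest coordinates (ids = nest labels).
#' @param mode `"nest"` or `"individual"`.
#' @param nperm,seed Passed to [mantel_test()].
#' @return A `mantel_result` tibble.
#' @export
ibd_test <- function(geno, pattern, mode = c("nest", "individual"),
                     nperm = 999, seed = NULL) {
  mode <- match.arg(mode)
  dat <- geno |> filter(!is.na(.data$nest))
  if (mode == "nest") {
    gd <- nei_distance(dat, by = "nest")
    ids <- rownames(gd)
    coords <- pp_coords(pattern)
    assert_that(all(ids %in% coords$id),
                "every genotyped nest needs a coordinate")
    coords <- coords[match(ids, coords$id), ]
    mantel_test(gd, euclidean_distance(coords), nperm = nperm, seed = seed)
  } else {
    gd <- nei_distance(dat, by = "id")
    ids <- rownames(gd)
    nest_of <- dat$nest[match(ids, dat$id)]
    coords <- pp_coords(pattern)
    assert_that(all(nest_of %in% coords$id),
                "every natal nest needs a coordinate")
    xy <- coords[match(nest_of, coords$id), ]
    xy$id <- ids
    mantel_test(gd, euclidean_distance(xy), nperm = nperm, seed = seed)
  }
}
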