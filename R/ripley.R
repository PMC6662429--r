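# Ripley's K for rectangular windows.  K(r) = lambda^-1 E[extra events within
# r of a typical event]; under complete spatial randomness K(r) = pi r^2 and
# the variance-stabilised L(r) - r = sqrt(K/pi) - r is zero.

# Fraction of the circle of radius d centred at (x, y) lying inside the
# rectangular window; valid for d <= half the shorter side (at most two
# adjacent edges can be crossed).  Vectorised over points/distances.
iso_fraction <- function(x, y, d, window) {
  dl <- x - window[1]; dr <- window[2] - x
  db <- y - window[3]; dt <- window[4] - y
  ang <- function(e) {
    th <- numeric(length(d))
    cross <- e < d
    th[cross] <- acos(pmin(1, e[cross] / d[cross]))
    th
  }
  tl <- ang(dl); tr <- ang(dr); tb <- ang(db); tt <- ang(dt)
  corner <- function(t1, t2) pmax(0, t1 + t2 - pi / 2)
  outside <- 2 * (tl + tr + tb + tt) -
    corner(tl, tb) - corner(tb, tr) - corner(tr, tt) - corner(tt, tl)
  1 - outside / (2 * pi)
}

# Translation-correction weight for an ordered pair displaced by (dx, dy).
translate_weight <- function(dx, dy, window) {
  a <- window[2] - window[1]; b <- window[4] - window[3]
  (a * b) / ((a - abs(dx)) * (b - abs(dy)))
}

# K at each r in `r_grid` for coordinate matrix xy (n x 2).
k_curve <- function(xy, window, r_grid, correction) {
  n <- nrow(xy)
  area <- (window[2] - window[1]) * (window[4] - window[3])
  dmat <- as.matrix(dist(xy))
  ut <- upper.tri(dmat)
  sel <- ut & dmat <= max(r_grid)
  d <- dmat[sel]
  if (length(d) == 0) return(numeric(length(r_grid)))
  idx <- which(sel, arr.ind = TRUE)
  wsum <- switch(correction,
    none = rep(2, length(d)),
    isotropic = {
      wi <- 1 / iso_fraction(xy[idx[, 1], 1], xy[idx[, 1], 2], d, window)
      wj <- 1 / iso_fraction(xy[idx[, 2], 1], xy[idx[, 2], 2], d, window)
      wi + wj
    },
    translate = {
      dx <- xy[idx[, 1], 1] - xy[idx[, 2], 1]
      dy <- xy[idx[, 1], 2] - xy[idx[, 2], 2]
      2 * translate_weight(dx, dy, window)
    },
    abort(sprintf("unknown edge correction '%s'", correction))
  )
  ord <- order(d)
  d <- d[ord]
  cw <- cumsum(wsum[ord])
  fi <- findInterval(r_grid, d)
  k <- ifelse(fi == 0, 0, cw[pmax(fi, 1)])
  area * k / (n * (n - 1))
}

default_r_grid <- function(pattern, r_max = NULL, length_out = 512) {
  w <- pp_window(pattern)
  short <- min(w[2] - w[1], w[4] - w[3])
  if (is.null(r_max)) r_max <- short / 4
  seq(0, r_max, length.out = length_out)
}

check_r_grid <- function(pattern, r_grid, correction) {
  w <- pp_window(pattern)
  short <- min(w[2] - w[1], w[4] - w[3])
  if (correction %in% c("isotropic", "translate") && max(r_grid) > short / 2) {
    abort(sprintf(
      "max(r) = %g exceeds the %s-correction validity bound of %g m (half the shorter window side)",
      max(r_grid), correction, short / 2))
  }
}

#' Ripley's K and the L(r) - r transform for a nest point pattern
#'
#' Estimates \eqn{\hat K(r) = A / (n(n-1)) \sum_{i \ne j} w_{ij} 1[d_{ij} \le r]}
#' with the chosen edge-correction weight, and the variance-stabilised
#' \eqn{L(r) - r = \sqrt{\hat K(r)/\pi} - r}, positive under clustering and
#' negative under overdispersion.
#'
#' @param pattern A `ppattern` from [pp()] with at least 2 points.
#' @param r Distance grid in metres; default 512 equal steps from 0 to a
#'   quarter of the shorter window side.
#' @param correction Edge correction: `"isotropic"` (Ripley's weight, the
#'   default for rectangular windows), `"translate"`, or `"none"`.
#' @param r_max Convenience cap used when `r` is not given (e.g. the 250 m /
#'   100 m / 40 m scales of a multi-site analysis).
#' @return A tibble of class `k_estimate` with columns `r`, `k_obs`,
#'   `k_theo` (\eqn{\pi r^2}), `l_minus_r`; attributes `lambda` (intensity),
#'   `correction`, `n`.
#' @export
ripley_k <- function(pattern, r = NULL, correction = c("isotropic", "translate", "none"),
                     r_max = NULL) {
  correction <- match.arg(correction)
  assert_that(nrow(pattern) >= 2, "Ripley's K needs at least 2 points")
  if (is.null(r)) r <- default_r_grid(pattern, r_max)
  check_r_grid(pattern, r, correction)
  xy <- cbind(pattern$x, pattern$y)
  k <- k_curve(xy, pp_window(pattern), r, correction)
  out <- tibble(r = r, k_obs = k, k_theo = pi * r^2,
                l_minus_r = sqrt(k / pi) - r)
  structure(out, lambda = nrow(pattern) / pp_area(pattern),
            correction = correction, n = nrow(pattern),
            window = pp_window(pattern),
            class = c("k_estimate", class(out)))
}

#' Monte Carlo envelope of Ripley's K under complete spatial randomness
#'
#' Simulates `nsim` patterns of the observed number of points placed uniformly
#' in the observation window, computes K for each, and takes the pointwise
#' minimum/maximum as the rank-1 envelope. The attained two-sided significance
#' of the resulting test is exactly `2 / (nsim + 1)` at each r (0.0208 for the
#' conventional 95 simulations).
#'
#' @inheritParams ripley_k
#' @param nsim Number of CSR simulations (default 95).
#' @param seed RNG seed for the simulations.
#' @return A tibble of class `k_envelope` with columns `r, k_obs, k_theo,
#'   k_lo, k_hi, l_minus_r, l_lo, l_hi, exceed_lo, exceed_hi`; attributes
#'   `alpha`, `nsim`, `correction`, `n`.
#' @export
csr_envelope <- function(pattern, r = NULL, nsim = 95,
                         correction = c("isotropic", "translate", "none"),
                         seed = NULL, r_max = NULL) {
  correction <- match.arg(correction)
  assert_that(nsim >= 1, "nsim must be at least 1")
  est <- ripley_k(pattern, r = r, correction = correction, r_max = r_max)
  r <- est$r
  w <- pp_window(pattern)
  n <- nrow(pattern)
  sims <- with_seed(seed, {
    vapply(seq_len(nsim), function(s) {
      xy <- cbind(runif(n, w[1], w[2]), runif(n, w[3], w[4]))
      k_curve(xy, w, r, correction)
    }, numeric(length(r)))
  })
  sims <- matrix(sims, nrow = length(r))
  k_lo <- apply(sims, 1, min)
  k_hi <- apply(sims, 1, max)
  out <- tibble(
    r = r, k_obs = est$k_obs, k_theo = est$k_theo,
    k_lo = k_lo, k_hi = k_hi,
    l_minus_r = est$l_minus_r,
    l_lo = sqrt(k_lo / pi) - r, l_hi = sqrt(k_hi / pi) - r,
    exceed_lo = est$k_obs < k_lo, exceed_hi = est$k_obs > k_hi
  )
  structure(out, alpha = 2 / (nsim + 1), nsim = nsim, correction = correction,
            n = n, window = w, class = c("k_envelope", class(out)))
}

#' Classify dispersion at each distance from a CSR envelope
#'
#' @param envelope A `k_envelope` from [csr_envelope()].
#' @param estimate Optional `k_estimate` whose `k_obs` should be classified
#'   instead of the envelope's own; its r grid must match the envelope's.
#' @return The envelope tibble with a `dispersion` column:
#'   `"clustered"` where the observed K exceeds the upper bound,
#'   `"overdispersed"` below the lower bound, `"random"` otherwise.
#' @export
classify_dispersion <- function(envelope, estimate = NULL) {
  k_obs <- envelope$k_obs
  if (!is.null(estimate)) {
    if (length(estimate$r) != length(envelope$r) ||
        any(abs(estimate$r - envelope$r) > 1e-9)) {
      abort("estimate and envelope were computed on different r grids")
    }
    k_obs <- estimate$k_obs
  }
  envelope |>
    mutate(k_obs = k_obs,
           dispersion = dplyr::case_when(
             k_obs > .data$k_hi ~ "clustered",
             k_obs < .data$k_lo ~ "overdispersed",
             TRUE ~ "random"
           ))
}
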