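# Edge thinning: link nests whose distance is <= r, track the number of
# connected components as r grows, and read off "threshold distances" (TD)
# where the component count plateaus.  Connectivity is single linkage, so the
# whole profile falls out of the single-linkage dendrogram: the components of
# the threshold graph at radius r are exactly the clusters obtained by
# cutting the single-linkage tree at height r (ties at d == r are linked).

single_linkage <- function(pattern) {
  xy <- cbind(pattern$x, pattern$y)
  hclust(dist(xy), method = "single")
}

#' Edge-thinning profile of a nest point pattern
#'
#' For each link radius r in `0, step, 2*step, ..., r_max`, counts the
#' connected components of the graph joining all pairs of nests at distance
#' `<= r`, together with the mean number of nests per component.
#'
#' @inheritParams ripley_k
#' @param step Radius increment in metres (default 5 m).
#' @param r_max Largest radius; defaults to the maximum pairwise distance
#'   rounded up to a multiple of `step`, by which point everything is one
#'   cluster.
#' @return A tibble of class `thinning_profile` with columns `r`,
#'   `n_clusters`, `mean_size`.
#' @export
edge_thinning <- function(pattern, step = 5, r_max = NULL) {
  assert_that(step > 0, "step must be positive")
  n <- nrow(pattern)
  assert_that(n >= 1, "need at least one point")
  if (n == 1) {
    r <- seq(0, r_max %||% step, by = step)
    out <- tibble(r = r, n_clusters = 1L, mean_size = 1)
    return(structure(out, class = c("thinning_profile", class(out))))
  }
  hc <- single_linkage(pattern)
  if (is.null(r_max)) r_max <- step * ceiling(max(hc$height) / step)
  r <- seq(0, r_max, by = step)
  # component count at radius r = n - (number of merges at height <= r)
  nc <- n - findInterval(r, sort(hc$height))
  out <- tibble(r = r, n_clusters = as.integer(nc), mean_size = n / nc)
  structure(out, n = n, step = step,
            class = c("thinning_profile", class(out)))
}

#' Detect plateaus (threshold distances) in a thinning profile
#'
#' A plateau is a maximal run of constant cluster count over consecutive
#' radii, of length at least `min_run` steps; its onset radius is the
#' threshold distance at which the spatial structure is minimally connected
#' at that cluster count. The leading all-singletons run (no links formed
#' yet) is not a plateau.
#'
#' @param profile A `thinning_profile` from [edge_thinning()].
#' @param min_run Minimum run length, in steps, to count as a plateau
#'   (default 2; runs of 1 step are reported only if `min_run = 1`).
#' @return A tibble with columns `td` (onset radius, metres), `n_clusters`,
#'   `mean_size`, `length` (run length in steps).
#' @export
detect_plateaus <- function(profile, min_run = 2) {
  assert_that(nrow(profile) > 0, "empty thinning profile")
  assert_that(min_run >= 1, "min_run must be at least 1")
  n <- profile$n_clusters[1]
  rl <- rle(profile$n_clusters)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  keep <- rl$lengths >= min_run
  # exclude the degenerate prefix where every point is still a singleton
  if (length(keep) > 0 && rl$values[1] == max(profile$n_clusters) &&
      profile$r[1] == 0) {
    keep[1] <- FALSE
  }
  tibble(
    td = profile$r[starts[keep]],
    n_clusters = rl$values[keep],
    mean_size = profile$mean_size[starts[keep]],
    length = rl$lengths[keep]
  )
}

#' Assign nests to clusters at a link radius
#'
#' Labels are the connected components of the graph joining nests at distance
#' `<= radius`; chains connect transitively.
#'
#' @inheritParams ripley_k
#' @param radius Link radius in metres (a threshold distance from
#'   [detect_plateaus()], or a study-chosen value).
#' @return A tibble `id, cluster` with cluster labels `"C1"`, `"C2"`, ...
#'   numbered by first appearance in the input order.
#' @export
assign_clusters <- function(pattern, radius) {
  assert_that(radius >= 0, "radius must be nonnegative")
  n <- nrow(pattern)
  if (n == 1) return(tibble(id = pattern$id, cluster = "C1"))
  hc <- single_linkage(pattern)
  grp <- cutree(hc, h = radius)
  lab <- match(grp, unique(grp))
  tibble(id = pattern$id, cluster = paste0("C", lab))
}
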