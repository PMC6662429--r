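# Nest coordinates are projected planar metres (e.g. UTM).  A point pattern is
# a tibble (id, x, y, [year]) carrying its rectangular observation window as
# an attribute; all spatial statistics assume that window.

#' Construct a planar point pattern
#'
#' @param xy A data frame with columns `id`, `x`, `y` and optionally `year`;
#'   coordinates in metres on a projected plane.
#' @param window Observation rectangle `c(xmin, xmax, ymin, ymax)`; defaults
#'   to the bounding box of the points.
#' @return A tibble of class `ppattern` with the window stored as an
#'   attribute (see [pp_window()]).
#' @export
#' @examples
#' pp(data.frame(id = c("n1", "n2"), x = c(0, 10), y = c(0, 10)))
pp <- function(xy, window = NULL) {
  xy <- as_tibble(xy)
  assert_that(all(c("id", "x", "y") %in% names(xy)),
              "point pattern needs columns id, x, y")
  xy$id <- as.character(xy$id)
  if (!"year" %in% names(xy)) xy$year <- NA_integer_
  assert_that(all(is.finite(xy$x)) && all(is.finite(xy$y)),
              "coordinates must be finite")
  dup <- xy$id[duplicated(xy$id)]
  if (length(dup) > 0) {
    abort(paste0("duplicated point id(s): ", paste(unique(dup), collapse = ", ")))
  }
  if (is.null(window)) {
    window <- c(min(xy$x), max(xy$x), min(xy$y), max(xy$y))
  }
  window <- as.numeric(window)
  assert_that(length(window) == 4 && window[2] > window[1] && window[4] > window[3],
              "window must be c(xmin, xmax, ymin, ymax) with positive area")
  inside <- xy$x >= window[1] & xy$x <= window[2] &
    xy$y >= window[3] & xy$y <= window[4]
  if (!all(inside)) {
    abort(paste0("point(s) outside the window: ",
                 paste(xy$id[!inside], collapse = ", ")))
  }
  structure(xy[c("id", "x", "y", "year")], window = window,
            class = c("ppattern", class(xy)))
}

#' Observation window of a point pattern
#' @param pattern A `ppattern` from [pp()].
#' @return Numeric `c(xmin, xmax, ymin, ymax)`.
#' @export
pp_window <- function(pattern) attr(pattern, "window")

#' Area of the observation window, in square metres
#' @inheritParams pp_window
#' @export
pp_area <- function(pattern) {
  w <- pp_window(pattern)
  (w[2] - w[1]) * (w[4] - w[3])
}

#' Read nest coordinates from CSV
#'
#' Expects columns `id, x, y` and optionally `year`, in projected planar
#' metres. Values that look like geographic longitude/latitude are rejected:
#' every distance in the downstream analyses is straight-line metres, and
#' silently treating degrees as metres would corrupt all of them.
#'
#' @param path CSV path.
#' @param window Optional explicit window `c(xmin, xmax, ymin, ymax)`.
#' @return A `ppattern` tibble.
#' @export
read_coordinates <- function(path, window = NULL) {
  df <- as_tibble(read.csv(path, stringsAsFactors = FALSE,
                           colClasses = c(id = "character")))
  assert_that(all(c("id", "x", "y") %in% names(df)),
              "coordinates CSV needs columns id, x, y")
  if (nrow(df) > 0 && all(abs(df$x) <= 180) && all(abs(df$y) <= 90)) {
    abort(paste0(
      "coordinates look like geographic lon/lat (|x| <= 180, |y| <= 90); ",
      "project them to planar metres (e.g. UTM) before use"
    ))
  }
  pp(df, window = window)
}

#' @export
print.ppattern <- function(x, ...) {
  w <- pp_window(x)
  cat(sprintf("Planar point pattern: %d points in [%g, %g] x [%g, %g] m\n",
              nrow(x), w[1], w[2], w[3], w[4]))
  NextMethod()
}

#' Nest-centroid coordinates from per-individual records
#'
#' @inheritParams pp_window
#' @return A tibble `id, x, y` (one row per point) without the window.
#' @export
pp_coords <- function(pattern) as_tibble(pattern)[c("id", "x", "y")]
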