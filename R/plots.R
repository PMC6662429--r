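# ggplot2 displays for the spatial results.  Each returns a ggplot object.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_ribbon
#'   geom_step geom_hline labs theme_minimal coord_equal
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Plot a nest point pattern
#' @param object A `ppattern`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ppattern
#' @export
autoplot.ppattern <- function(object, ...) {
  w <- pp_window(object)
  ggplot(as_tibble(object), aes(x = .data$x, y = .data$y)) +
    geom_point(shape = 17) +
    coord_equal(xlim = w[1:2], ylim = w[3:4]) +
    labs(x = "x (m)", y = "y (m)") +
    theme_minimal()
}

#' Plot Ripley's K with its CSR envelope
#'
#' Panel mirroring the conventional K-function display: observed K with the
#' theoretical CSR curve and the simulation envelope band.
#'
#' @param object A `k_envelope` from [csr_envelope()].
#' @param which `"K"` or `"L"` (the variance-stabilised L(r) - r).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot k_envelope
#' @export
autoplot.k_envelope <- function(object, which = c("K", "L"), ...) {
  which <- match.arg(which)
  if (which == "K") {
    ggplot(object, aes(x = .data$r)) +
      geom_ribbon(aes(ymin = .data$k_lo, ymax = .data$k_hi), fill = "grey80") +
      geom_line(aes(y = .data$k_theo), linetype = 2) +
      geom_line(aes(y = .data$k_obs)) +
      labs(x = "r (m)", y = "K(r)") +
      theme_minimal()
  } else {
    ggplot(object, aes(x = .data$r)) +
      geom_ribbon(aes(ymin = .data$l_lo, ymax = .data$l_hi), fill = "grey80") +
      geom_hline(yintercept = 0, linetype = 2) +
      geom_line(aes(y = .data$l_minus_r)) +
      labs(x = "r (m)", y = "L(r) - r") +
      theme_minimal()
  }
}

#' Plot an edge-thinning profile
#'
#' Step plot of the connected-cluster count against link radius; plateaus
#' are the flat runs.
#'
#' @param object A `thinning_profile` from [edge_thinning()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot thinning_profile
#' @export
autoplot.thinning_profile <- function(object, ...) {
  ggplot(object, aes(x = .data$r, y = .data$n_clusters)) +
    geom_step() +
    labs(x = "link radius r (m)", y = "number of clusters") +
    theme_minimal()
}
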