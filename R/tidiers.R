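#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' @export
tidy.hull_set <- function(x, ...) {
  as_tibble(x)[, c("root", "area", "n_enclosed")]
}

#' @export
tidy.isopleth_set <- function(x, ...) {
  as_tibble(x)[, c("level", "area_km2", "fraction_enclosed", "n_hulls",
                   "centroid_x", "centroid_y")]
}

#' @export
glance.isopleth_set <- function(x, ...) {
  hulls <- attr(x, "hulls")
  tibble(n_points = nrow(attr(hulls, "points")),
         n_hulls = nrow(hulls),
         n_levels = nrow(x),
         outer_area_km2 = max(x$area_km2))
}

#' @export
tidy.a_selection <- function(x, ...) as_tibble(x)

#' @export
glance.a_selection <- function(x, ...) {
  tibble(chosen_a = attr(x, "chosen"),
         n_candidates = nrow(x),
         n_acceptable = sum(x$acceptable))
}

#' @export
tidy.ks_uniform <- function(x, ...) glance.ks_uniform(x)

#' @export
tidy.collinearity_screen <- function(x, ...) x$vif

#' @export
glance.collinearity_screen <- function(x, ...) {
  off <- x$correlations[upper.tri(x$correlations)]
  tibble(max_abs_correlation = max(abs(off)),
         max_vif = max(x$vif$vif),
         any_singular = any(x$vif$singular))
}
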