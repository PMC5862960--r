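#' Local convex hull neighbour sets
#'
#' Three neighbour rules, shared by the hull constructors:
#' * `k`: the root plus its k-1 nearest neighbours;
#' * `r`: the root plus every point within fixed radius r;
#' * `a` (adaptive): the root plus nearest neighbours added in increasing
#'   distance while the running sum of their distances to the root stays
#'   at or below a.
#'
#' @param points Tibble or matrix with planar coordinates `x`, `y` (metres).
#' @param method One of "k", "r", "a".
#' @param value The k, r (m) or a (m) value; must be > 0.
#' @param s Time-weighting exponent hook; only `s = 0` (no time weighting)
#'   is supported.
#' @return List (one element per root point) of integer index vectors, root
#'   first, neighbours in increasing distance.
#' @export
locoh_neighbors <- function(points, method = c("a", "k", "r"), value,
                            s = 0) {
  method <- match.arg(method)
  if (s != 0) abort("locoh_neighbors: only s = 0 (no time weighting) is supported")
  if (value <= 0) abort("locoh_neighbors: value must be > 0")
  pts <- as.matrix(as_tibble(points)[, c("x", "y")])
  n <- nrow(pts)
  if (method == "k" && value > n) abort("locoh_neighbors: k exceeds number of points")
  dmat <- as.matrix(stats::dist(pts))
  lapply(seq_len(n), function(i) {
    d <- dmat[i, ]
    ord <- order(d, seq_len(n)) # root itself sorts first (distance 0)
    ord <- c(i, setdiff(ord, i))
    ds <- d[ord]
    sel <- switch(method,
      k = seq_len(value),
      r = which(ds <= value),
      a = which(cumsum(ds) <= value))
    ord[sel]
  })
}

#' Build local convex hulls
#'
#' One convex hull per root point over the root and its neighbours, with the
#' enclosed-point count (all points inside or on the hull) used downstream
#' as the density ordering. Degenerate neighbour sets (collinear or
#' duplicated points) yield zero-area hulls and are kept, not dropped.
#'
#' @inheritParams locoh_neighbors
#' @param neighbors Optional precomputed neighbour sets.
#' @return A `hull_set`: tibble with `root`, `hull` (list of vertex
#'   matrices), `area` (m^2), `n_enclosed`; the point set is carried as an
#'   attribute.
#' @export
locoh_hulls <- function(points, method = c("a", "k", "r"), value,
                        neighbors = NULL, s = 0) {
  pts <- as.matrix(as_tibble(points)[, c("x", "y")])
  if (is.null(neighbors))
    neighbors <- locoh_neighbors(points, method, value, s = s)
  hulls <- lapply(neighbors, function(idx) {
    convex_hull(pts[idx, , drop = FALSE])
  })
  out <- tibble(
    root = seq_len(nrow(pts)),
    hull = hulls,
    area = purrr::map_dbl(hulls, polygon_area),
    n_enclosed = purrr::map_int(hulls, function(h) {
      sum(points_in_convex(pts[, 1], pts[, 2], h))
    }))
  class(out) <- c("hull_set", class(out))
  attr(out, "points") <- pts
  out
}

#' Density isopleths from a hull set
#'
#' Hulls are sorted by enclosed-point count (descending; ties by area
#' ascending, smaller-denser first) and unioned cumulatively until the
#' fraction of all points enclosed reaches each requested level. Lower
#' levels are therefore always spatially nested inside higher ones, and
#' areas are non-decreasing with level.
#'
#' @param hulls A `hull_set` from [locoh_hulls].
#' @param levels Coverage fractions in (0, 1]; default
#'   `c(0.10, 0.25, 0.50, 0.95)`. The 0.10-0.25 isopleths delimit core use.
#' @return An `isopleth_set`: tibble with `level`, `area_km2`,
#'   `fraction_enclosed`, `n_hulls`, `centroid_x`, `centroid_y`, `members`
#'   (list of hull indices in union order).
#' @export
build_isopleths <- function(hulls, levels = c(0.10, 0.25, 0.50, 0.95)) {
  stopifnot(inherits(hulls, "hull_set"), nrow(hulls) >= 1)
  if (any(levels <= 0 | levels > 1))
    abort("build_isopleths: levels must lie in (0, 1]")
  levels <- sort(levels)
  pts <- attr(hulls, "points")
  n <- nrow(pts)
  ord <- order(-hulls$n_enclosed, hulls$area)
  enclosed <- rep(FALSE, n)
  frac <- numeric(length(ord))
  for (m in seq_along(ord)) {
    h <- hulls$hull[[ord[m]]]
    enclosed <- enclosed | points_in_convex(pts[, 1], pts[, 2], h)
    frac[m] <- sum(enclosed) / n
  }
  rows <- purrr::map_dfr(levels, function(lv) {
    m <- which(frac >= lv - 1e-12)[1]
    if (is.na(m)) m <- length(ord) # safety: all hulls
    members <- ord[seq_len(m)]
    u <- polygon_union_area(hulls$hull[members])
    tibble(level = lv, area_km2 = u$area / 1e6,
           fraction_enclosed = frac[m], n_hulls = m,
           centroid_x = u$centroid[1], centroid_y = u$centroid[2],
           members = list(members))
  })
  class(rows) <- c("isopleth_set", class(rows))
  attr(rows, "hulls") <- hulls
  rows
}

#' Select the adaptive-a value
#'
#' Applies the published selection rule: choose the smallest candidate a
#' whose outer isopleth has no interior gaps while overlapping terrestrial
#' habitat by at most a small tolerance. Gap and land diagnostics are
#' evaluated on a raster overlay of the isopleth region (resolution
#' `raster_n`); the isopleth area itself is exact.
#'
#' @param points Planar point tibble (`x`, `y` in UTM metres).
#' @param candidates Numeric vector (>= 2) of candidate a values (m).
#' @param grid [bathy_grid] supplying the land mask.
#' @param level Isopleth level to diagnose (default 0.95).
#' @param land_tol Maximum tolerated land-overlap fraction of the isopleth
#'   area (default 0.01).
#' @param zone UTM zone used to map raster cells back to the grid.
#' @param raster_n Raster resolution per axis for the diagnostics.
#' @return An `a_selection` tibble: `a`, `area_km2`, `n_holes`, `n_parts`,
#'   `land_fraction`, `acceptable`; a candidate is acceptable when the
#'   isopleth surface has no gaps -- neither interior holes nor
#'   fragmentation into disjoint parts -- and its land overlap is within
#'   tolerance. The chosen a (smallest acceptable) is attached as attribute
#'   `chosen` (NA, with a warning, if none qualify).
#' @export
select_a_value <- function(points, candidates, grid, level = 0.95,
                           land_tol = 0.01, zone = 4, raster_n = 120) {
  if (length(candidates) < 2) abort("select_a_value: need >= 2 candidate a values")
  candidates <- sort(candidates)
  rows <- purrr::map_dfr(candidates, function(a) {
    hs <- locoh_hulls(points, method = "a", value = a)
    iso <- build_isopleths(hs, levels = level)
    polys <- hs$hull[iso$members[[1]]]
    ras <- union_raster(polys, n = raster_n)
    holes <- count_holes(ras$covered)
    parts <- count_parts(ras$covered)
    cov_idx <- which(as.vector(ras$covered))
    land_frac <- if (length(cov_idx) == 0) 0 else {
      ll <- utm_to_latlon(ras$px[cov_idx], ras$py[cov_idx], zone = zone)
      ok <- grid_covers(grid, ll$lat, ll$lon)
      land <- rep(FALSE, length(cov_idx))
      if (any(ok)) land[ok] <- depth_at(grid, ll$lat[ok], ll$lon[ok]) <= 0
      mean(land)
    }
    tibble(a = a, area_km2 = iso$area_km2, n_holes = holes,
           n_parts = parts, land_fraction = land_frac,
           acceptable = holes == 0 & parts == 1 & land_frac <= land_tol)
  })
  chosen <- rows$a[rows$acceptable][1]
  if (is.na(chosen) || length(chosen) == 0) {
    warn("select_a_value: no candidate eliminates gaps within the land tolerance")
    chosen <- NA_real_
  }
  class(rows) <- c("a_selection", class(rows))
  attr(rows, "chosen") <- chosen
  rows
}

#' Exclude offshore loops from a coastal track
#'
#' Offshore migrations bias coastal utilisation estimates; maximal runs of
#' consecutive fixes whose harvested seafloor depth exceeds the isobath
#' (default 4,000 m) are removed in full, leaving coastal fixes untouched.
#' The rule is purely depth-thresholded, with no manual judgement.
#'
#' @param track Tibble with `lat`, `lon` (retained fixes).
#' @param grid [bathy_grid] covering the track.
#' @param isobath_m Exclusion isobath (default 4000).
#' @return The coastal subset of `track`.
#' @export
exclude_offshore_loops <- function(track, grid, isobath_m = 4000) {
  if (nrow(track) == 0) return(track)
  depth <- depth_at(grid, track$lat, track$lon)
  track[depth <= isobath_m, , drop = FALSE]
}

#' Export isopleths as GeoJSON
#'
#' One Feature per level (MultiPolygon of the member hulls, in WGS84 via the
#' inverse UTM projection) with properties `level`, `area_km2`,
#' `fraction_enclosed`.
#'
#' @param iso An `isopleth_set`.
#' @param path Output path.
#' @param zone UTM zone of the planar coordinates.
#' @export
write_isopleths_geojson <- function(iso, path, zone = 4) {
  hulls <- attr(iso, "hulls")
  features <- purrr::map(seq_len(nrow(iso)), function(i) {
    polys <- hulls$hull[iso$members[[i]]]
    coords <- purrr::map(polys, function(p) {
      if (nrow(p) < 3) return(NULL)
      ll <- utm_to_latlon(p[, 1], p[, 2], zone = zone)
      ring <- purrr::map2(c(ll$lon, ll$lon[1]), c(ll$lat, ll$lat[1]), c)
      list(ring)
    })
    coords <- purrr::compact(coords)
    list(type = "Feature",
         properties = list(level = iso$level[i],
                           area_km2 = iso$area_km2[i],
                           fraction_enclosed = iso$fraction_enclosed[i]),
         geometry = list(type = "MultiPolygon", coordinates = coords))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
autoplot.isopleth_set <- function(object, ...) {
  hulls <- attr(object, "hulls")
  df <- purrr::map_dfr(rev(seq_len(nrow(object))), function(i) {
    purrr::map_dfr(object$members[[i]], function(m) {
      h <- hulls$hull[[m]]
      if (nrow(h) < 3) return(NULL)
      tibble(level = object$level[i], hull_id = m,
             x = h[, 1], y = h[, 2])
    })
  })
  pts <- attr(hulls, "points")
  ggplot2::ggplot(df) +
    ggplot2::geom_polygon(ggplot2::aes(.data$x, .data$y,
                                       group = interaction(.data$level,
                                                           .data$hull_id),
                                       fill = factor(.data$level)),
                          alpha = 0.8, colour = NA) +
    ggplot2::geom_point(data = tibble(x = pts[, 1], y = pts[, 2]),
                        ggplot2::aes(.data$x, .data$y),
                        size = 0.3, alpha = 0.4) +
    ggplot2::scale_fill_viridis_d(direction = -1, name = "Isopleth") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Easting (m)", y = "Northing (m)")
}

#' @export
print.isopleth_set <- function(x, ...) {
  cat("<isopleth_set>\n")
  print(as_tibble(x)[, c("level", "area_km2", "fraction_enclosed",
                         "n_hulls")])
  invisible(x)
}
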