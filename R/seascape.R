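#' Bathymetry grid
#'
#' A regular latitude/longitude grid of seafloor depth. Depth is metres below
#' sea level (positive at sea); negative values are land elevation. `origin`
#' is the centre of the south-west cell; row `i`, column `j` is centred at
#' `origin + (i-1, j-1) * cell_size` in (lat, lon).
#'
#' @param depth Numeric matrix, `n_rows x n_cols`, rows south to north.
#' @param origin_lat,origin_lon Centre of the south-west cell (degrees).
#' @param cell_size Cell size in degrees (> 0).
#' @return An object of class `bathy_grid`.
#' @export
bathy_grid <- function(depth, origin_lat, origin_lon, cell_size) {
  stopifnot(is.matrix(depth), cell_size > 0)
  if (!all(is.finite(depth) | is.na(depth)))
    abort("bathy_grid: depth values must be finite or NA (nodata)")
  structure(
    list(depth = depth, origin_lat = origin_lat, origin_lon = origin_lon,
         cell_size = cell_size, n_rows = nrow(depth), n_cols = ncol(depth)),
    class = "bathy_grid")
}

#' @export
print.bathy_grid <- function(x, ...) {
  cat(sprintf("<bathy_grid> %d x %d cells, %.6g deg resolution\n",
              x$n_rows, x$n_cols, x$cell_size))
  cat(sprintf("  lat [%.4f, %.4f], lon [%.4f, %.4f]\n",
              x$origin_lat, x$origin_lat + (x$n_rows - 1) * x$cell_size,
              x$origin_lon, x$origin_lon + (x$n_cols - 1) * x$cell_size))
  d <- x$depth[is.finite(x$depth)]
  cat(sprintf("  depth range: %.1f to %.1f m (%.1f%% land)\n",
              min(d), max(d), 100 * mean(d < 0)))
  invisible(x)
}

grid_lat <- function(grid, i) grid$origin_lat + (i - 1) * grid$cell_size
grid_lon <- function(grid, j) grid$origin_lon + (j - 1) * grid$cell_size

grid_covers <- function(grid, lat, lon) {
  half <- grid$cell_size / 2
  lat >= grid$origin_lat - half &
    lat <= grid_lat(grid, grid$n_rows) + half &
    lon >= grid$origin_lon - half &
    lon <= grid_lon(grid, grid$n_cols) + half
}

#' Generate a synthetic island seascape
#'
#' Builds a bathymetry grid containing one or more oceanic islands, each with
#' a land core, an insular shelf ramping from the shore down to the shelf
#' break, and a steep slope descending to abyssal depth beyond it. Oceanic
#' high islands are surrounded by exactly this structure: a shelf sloping
#' gradually from shore to a break at 100-200 m, then a rapid descent past
#' 1000 m. The construction is deterministic for a given configuration.
#'
#' @param islands Data frame with columns `name`, `lat`, `lon`,
#'   `land_radius_km`, `shelf_width_km` (one row per island).
#' @param resolution Cell size in degrees (default 0.005, about 550 m).
#' @param margin_km Open-water margin added around the islands' footprint.
#' @param shelf_break_m Depth at the outer edge of the shelf (default 200).
#' @param abyss_m Deep-ocean floor depth (default 4500).
#' @param descent_width_km Horizontal width of the slope from shelf break to
#'   abyssal depth (default 25).
#' @param land_height_m Peak island elevation (default 600).
#' @return A [bathy_grid].
#' @export
generate_seascape <- function(islands, resolution = 0.005, margin_km = 60,
                              shelf_break_m = 200, abyss_m = 4500,
                              descent_width_km = 25, land_height_m = 600) {
  islands <- as_tibble(islands)
  need <- c("lat", "lon", "land_radius_km", "shelf_width_km")
  if (nrow(islands) < 1 || !all(need %in% names(islands)))
    abort("generate_seascape: need >= 1 island with lat, lon, land_radius_km, shelf_width_km")
  if (resolution <= 0) abort("generate_seascape: resolution must be > 0")
  # land cores may not overlap (distinct islands); shared shelves are fine
  if (nrow(islands) > 1) {
    for (i in seq_len(nrow(islands) - 1)) {
      for (j in seq(i + 1, nrow(islands))) {
        d <- gc_distance_km(islands$lon[i], islands$lat[i],
                            islands$lon[j], islands$lat[j])
        if (d < islands$land_radius_km[i] + islands$land_radius_km[j])
          abort("generate_seascape: island land cores overlap")
      }
    }
  }
  reach_km <- islands$land_radius_km + islands$shelf_width_km +
    descent_width_km + margin_km
  lat_half <- reach_km / km_per_deg_lat()
  lat0 <- min(islands$lat - lat_half); lat1 <- max(islands$lat + lat_half)
  lon_half <- reach_km / km_per_deg_lon(islands$lat)
  lon0 <- min(islands$lon - lon_half); lon1 <- max(islands$lon + lon_half)
  lats <- seq(lat0, lat1, by = resolution)
  lons <- seq(lon0, lon1, by = resolution)
  lonm <- matrix(lons, nrow = length(lats), ncol = length(lons), byrow = TRUE)
  latm <- matrix(lats, nrow = length(lats), ncol = length(lons))
  depth <- matrix(abyss_m, nrow = length(lats), ncol = length(lons))
  for (i in seq_len(nrow(islands))) {
    d_km <- matrix(gc_distance_km(as.vector(lonm), as.vector(latm),
                                  islands$lon[i], islands$lat[i]),
                   nrow = length(lats))
    r_land <- islands$land_radius_km[i]
    r_shelf <- r_land + islands$shelf_width_km[i]
    di <- ifelse(d_km < r_land,
                 -land_height_m * (1 - d_km / r_land),
                 ifelse(d_km <= r_shelf,
                        shelf_break_m * (d_km - r_land) / (r_shelf - r_land),
                        pmin(abyss_m, shelf_break_m +
                               (abyss_m - shelf_break_m) *
                               (d_km - r_shelf) / descent_width_km)))
    depth <- pmin(depth, di)
  }
  bathy_grid(depth, lat0, lon0, resolution)
}

#' Read / write a bathymetry grid as an ESRI ASCII grid
#'
#' Plain-text raster exchange format (`ncols`/`nrows`/`xllcorner`/
#' `yllcorner`/`cellsize`/`NODATA_value` header followed by rows north to
#' south), readable by standard GIS software.
#'
#' @param grid A [bathy_grid].
#' @param path File path.
#' @param nodata Value written for missing cells.
#' @return `write_bathy_asc` returns `path` invisibly; `read_bathy_asc`
#'   returns a [bathy_grid].
#' @export
write_bathy_asc <- function(grid, path, nodata = -9999) {
  stopifnot(inherits(grid, "bathy_grid"))
  hdr <- c(
    sprintf("ncols %d", grid$n_cols),
    sprintf("nrows %d", grid$n_rows),
    sprintf("xllcorner %.10g", grid$origin_lon - grid$cell_size / 2),
    sprintf("yllcorner %.10g", grid$origin_lat - grid$cell_size / 2),
    sprintf("cellsize %.10g", grid$cell_size),
    sprintf("NODATA_value %g", nodata))
  m <- grid$depth
  m[is.na(m)] <- nodata
  rows <- apply(m[rev(seq_len(nrow(m))), , drop = FALSE], 1,
                function(r) paste(format(r, trim = TRUE, digits = 10),
                                  collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_bathy_asc
#' @export
read_bathy_asc <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  vals <- lapply(lines[seq(i, length(lines))],
                 function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  m <- do.call(rbind, vals)
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  bathy_grid(m,
             origin_lat = hdr$yllcorner + hdr$cellsize / 2,
             origin_lon = hdr$xllcorner + hdr$cellsize / 2,
             cell_size = hdr$cellsize)
}

#' @export
autoplot.bathy_grid <- function(object, ...) {
  df <- tibble(
    lat = rep(grid_lat(object, seq_len(object$n_rows)), object$n_cols),
    lon = rep(grid_lon(object, seq_len(object$n_cols)),
              each = object$n_rows),
    depth = as.vector(object$depth))
  ggplot2::ggplot(df, ggplot2::aes(.data$lon, .data$lat)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$depth)) +
    ggplot2::scale_fill_gradient2(low = "darkgreen", mid = "lightblue",
                                  high = "navy", midpoint = 200,
                                  name = "Depth (m)") +
    ggplot2::coord_fixed(1 / cos(mean(df$lat) * pi / 180)) +
    ggplot2::labs(x = "Longitude", y = "Latitude")
}
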