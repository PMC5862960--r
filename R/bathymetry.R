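#' Harvest seafloor depth under a position
#'
#' Bilinear interpolation of the four surrounding cell centres; a query at a
#' cell centre returns that cell's value exactly. Queries within the half-cell
#' rim of the grid edge are clamped to the centre lattice. The harvested value
#' is seafloor depth below the animal's surface position, never the animal's
#' swimming depth.
#'
#' @param grid A [bathy_grid].
#' @param lat,lon Query position(s), degrees. Vectorised.
#' @return Numeric vector of depths (m; negative = land).
#' @export
depth_at <- function(grid, lat, lon) {
  stopifnot(inherits(grid, "bathy_grid"))
  if (any(!grid_covers(grid, lat, lon)))
    abort("depth_at: position outside grid bounds")
  # fractional row/col on the cell-centre lattice, clamped at the rim
  fi <- pmin(pmax((lat - grid$origin_lat) / grid$cell_size, 0), grid$n_rows - 1)
  fj <- pmin(pmax((lon - grid$origin_lon) / grid$cell_size, 0), grid$n_cols - 1)
  i0 <- pmin(floor(fi) + 1, grid$n_rows - 1L); i0 <- pmax(i0, 1L)
  j0 <- pmin(floor(fj) + 1, grid$n_cols - 1L); j0 <- pmax(j0, 1L)
  if (grid$n_rows == 1L) i0 <- rep(1L, length(fi))
  if (grid$n_cols == 1L) j0 <- rep(1L, length(fj))
  i1 <- pmin(i0 + 1L, grid$n_rows); j1 <- pmin(j0 + 1L, grid$n_cols)
  u <- fi - (i0 - 1); v <- fj - (j0 - 1)
  m <- grid$depth
  q00 <- m[cbind(i0, j0)]; q01 <- m[cbind(i0, j1)]
  q10 <- m[cbind(i1, j0)]; q11 <- m[cbind(i1, j1)]
  out <- (1 - u) * (1 - v) * q00 + (1 - u) * v * q01 +
    u * (1 - v) * q10 + u * v * q11
  bad <- is.na(out)
  if (any(bad)) {
    warn("depth_at: nodata neighbour(s); using nearest valid cell")
    ok <- which(!is.na(m), arr.ind = TRUE)
    if (nrow(ok) == 0) abort("depth_at: grid has no valid cells")
    for (b in which(bad)) {
      d2 <- (ok[, 1] - (fi[b] + 1))^2 + (ok[, 2] - (fj[b] + 1))^2
      nearest <- ok[which.min(d2), , drop = FALSE]
      out[b] <- m[nearest]
    }
  }
  out
}

#' Depth lookup across nested grids
#'
#' Prefers the fine coastal grid wherever it covers the query, falling back
#' to the coarse offshore grid, matching the standard practice of pairing a
#' high-resolution coastal matrix with a coarser open-ocean one.
#'
#' @param fine,coarse [bathy_grid] objects; `fine` is preferred.
#' @param lat,lon Query position(s).
#' @return Numeric vector of depths (m).
#' @export
multi_resolution_depth <- function(fine, coarse, lat, lon) {
  in_fine <- grid_covers(fine, lat, lon)
  in_coarse <- grid_covers(coarse, lat, lon)
  if (any(!in_fine & !in_coarse))
    abort("multi_resolution_depth: position covered by neither grid")
  out <- numeric(length(lat))
  if (any(in_fine))
    out[in_fine] <- depth_at(fine, lat[in_fine], lon[in_fine])
  rest <- !in_fine
  if (any(rest))
    out[rest] <- depth_at(coarse, lat[rest], lon[rest])
  out
}

#' Per-sex seafloor depth-frequency profile
#'
#' Harvests seafloor depth under each retained fix, normalises the histogram
#' per shark, then averages across sharks within each sex: the mean and
#' standard error are between-individual (computed over sharks, not over
#' pooled fixes), so heavily tracked animals do not dominate.
#'
#' @param fixes Tibble of surface fixes with columns `shark_id`, `sex`,
#'   `lat`, `lon` (retained fixes only).
#' @param grid A [bathy_grid] (or use `depth` to supply harvested depths).
#' @param breaks Bin edges in metres; depths beyond the last edge fall into
#'   an overflow bin. Default 0 to 1000 by 50 m.
#' @param depth Optional pre-harvested depths (overrides `grid`).
#' @return A `depth_profile` tibble: `bin_low`, `bin_high`, `sex`, `mean`,
#'   `se`, `n` (sharks), with `se` 0 and `single_shark` flag when n = 1.
#' @export
depth_profile <- function(fixes, grid = NULL, breaks = seq(0, 1000, by = 50),
                          depth = NULL) {
  fixes <- as_tibble(fixes)
  if (is.null(depth)) {
    stopifnot(inherits(grid, "bathy_grid"))
    depth <- depth_at(grid, fixes$lat, fixes$lon)
  }
  fixes$.depth <- depth
  zero <- fixes |> group_by(.data$shark_id) |> summarise(n = n()) |>
    filter(.data$n == 0)
  if (nrow(zero) > 0)
    warn("depth_profile: sharks with zero fixes excluded")
  edges <- c(breaks, Inf)
  labs_low <- edges[-length(edges)]
  labs_high <- edges[-1]
  per_shark <- fixes |>
    group_by(.data$shark_id, .data$sex) |>
    summarise(frac = list(as.vector(
      table(cut(pmax(.data$.depth, min(breaks)), edges, right = FALSE,
                include.lowest = TRUE)) / length(.data$.depth))),
      .groups = "drop")
  out <- per_shark |>
    tidyr::unnest_longer("frac", indices_to = "bin") |>
    group_by(.data$sex, .data$bin) |>
    summarise(mean = mean(.data$frac),
              se = if (n() > 1) sd(.data$frac) / sqrt(n()) else 0,
              n = n(), .groups = "drop") |>
    mutate(bin_low = labs_low[.data$bin], bin_high = labs_high[.data$bin],
           single_shark = .data$n == 1) |>
    select("bin_low", "bin_high", "sex", "mean", "se", "n", "single_shark") |>
    arrange(.data$sex, .data$bin_low)
  class(out) <- c("depth_profile", class(out))
  out
}

#' Write a depth profile as CSV
#' @param profile A [depth_profile] result.
#' @param path File path.
#' @export
write_depth_profile_csv <- function(profile, path) {
  readr::write_csv(as_tibble(profile), path)
  invisible(path)
}

#' @export
autoplot.depth_profile <- function(object, ...) {
  df <- as_tibble(object) |>
    mutate(bin = sprintf("%g-%g", .data$bin_low,
                         ifelse(is.finite(.data$bin_high), .data$bin_high, Inf)),
           bin = factor(.data$bin, levels = unique(.data$bin)))
  ggplot2::ggplot(df, ggplot2::aes(.data$bin, .data$mean)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$se,
                                        ymax = .data$mean + .data$se),
                           width = 0.3) +
    ggplot2::facet_wrap(~sex, ncol = 1) +
    ggplot2::labs(x = "Seafloor depth bin (m)",
                  y = "Mean fraction of fixes (± SE)") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
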