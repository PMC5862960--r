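#' Prepare a raw Argos fix table for filtering
#'
#' Normalises a fix table to the column set used by the filtering pipeline
#' and adds provenance columns: every fix stays in the table for the whole
#' pipeline, with `retained` flipped to `FALSE` and a `reason` recorded when
#' a rule removes it. Reasons are one of `class_z`, `distant_outlier`,
#' `speed`, `land`, `cluster_thinned`.
#'
#' @param fixes Tibble with `time` (POSIXct, UTC), `lat`, `lon`, `lc`, and
#'   optionally `shark_id`.
#' @return An `argos_track` tibble sorted by time with `retained`/`reason`.
#' @export
as_argos_track <- function(fixes) {
  fixes <- as_tibble(fixes)
  stopifnot(all(c("time", "lat", "lon", "lc") %in% names(fixes)))
  bad <- !is.na(fixes$lat) & (abs(fixes$lat) > 90 | abs(fixes$lon) > 180)
  if (any(bad)) abort("as_argos_track: coordinates out of range")
  if (!all(as.character(fixes$lc) %in% LC_LEVELS))
    abort("as_argos_track: unknown location class")
  out <- fixes |>
    mutate(lc = as.character(.data$lc)) |>
    arrange(.data$time)
  if (!"retained" %in% names(out)) out$retained <- TRUE
  if (!"reason" %in% names(out)) out$reason <- NA_character_
  if (!"argos_track" %in% class(out))
    class(out) <- c("argos_track", class(out))
  out
}

#' Retained fixes of a track
#' @param track An `argos_track`.
#' @return The subset of rows with `retained == TRUE`.
#' @export
argos_retained <- function(track) filter(track, .data$retained)

mark_removed <- function(track, idx, reason) {
  track$retained[idx] <- FALSE
  track$reason[idx] <- reason
  track
}

#' Drop class-Z fixes
#'
#' Accurate positions are possible with every Argos location quality except
#' Z, which is therefore removed outright.
#'
#' @param track An `argos_track`.
#' @return The track with Z fixes flagged removed (reason `class_z`).
#' @export
drop_class_z <- function(track) {
  track <- as_argos_track(track)
  mark_removed(track, which(track$retained & track$lc == "Z"), "class_z")
}

#' Remove spurious distant locations
#'
#' Automates the manual removal of obviously spurious distant fixes as a
#' radius rule around a reference position (normally the tagging site). The
#' default radius of 2,500 km comfortably exceeds the longest genuine
#' offshore excursion documented for the species in the region (1,460 km).
#'
#' @param track An `argos_track`.
#' @param reference Numeric `c(lat, lon)` reference position.
#' @param max_km Removal radius in km (default 2500).
#' @return Track with distant fixes flagged removed (reason
#'   `distant_outlier`).
#' @export
remove_distant_outliers <- function(track, reference, max_km = 2500) {
  stopifnot(max_km > 0, length(reference) == 2)
  track <- as_argos_track(track)
  live <- which(track$retained & !is.na(track$lat))
  d <- gc_distance_km(track$lon[live], track$lat[live],
                      reference[2], reference[1])
  mark_removed(track, live[d > max_km], "distant_outlier")
}

#' Location-class anchored swim-speed filter
#'
#' Higher-quality fixes (LC 1, 2, 3 and GPS-quality G) anchor the filter and
#' are never removed by the speed rule. Each class 0/A/B fix is retained only
#' if it lies within a `vmax_kmh` buffer of its anchor -- great-circle
#' distance to the most recent anchor divided by elapsed time -- and, when a
#' bathymetry grid is supplied, falls at sea (depth > 0). Fixes preceding the
#' first anchor are judged against the first subsequent anchor. Retained
#' 0/A/B fixes never become anchors themselves. The default 4.2 km/h
#' threshold is the empirical sustained swimming speed of large tiger sharks.
#'
#' @param track An `argos_track` (Z fixes should be dropped first).
#' @param vmax_kmh Speed threshold in km/h (default 4.2).
#' @param grid Optional [bathy_grid] for the at-sea check.
#' @return Track with out-of-buffer fixes flagged `speed` and on-land fixes
#'   flagged `land`.
#' @export
speed_filter <- function(track, vmax_kmh = 4.2, grid = NULL) {
  track <- as_argos_track(track)
  live <- which(track$retained)
  lc <- track$lc[live]
  is_anchor <- lc %in% LC_ANCHOR
  is_low <- lc %in% c("0", "A", "B")
  if (!any(is_anchor) && any(is_low)) {
    warn("speed_filter: no anchor-class fixes; removing all 0/A/B fixes")
    return(mark_removed(track, live[is_low], "speed"))
  }
  anchor_pos <- which(is_anchor)
  t_num <- as.numeric(track$time[live])
  removed_speed <- logical(length(live))
  removed_land <- logical(length(live))
  for (i in which(is_low)) {
    prev <- anchor_pos[anchor_pos < i]
    ref <- if (length(prev) > 0) max(prev) else min(anchor_pos[anchor_pos > i])
    d_km <- gc_distance_km(track$lon[live[i]], track$lat[live[i]],
                           track$lon[live[ref]], track$lat[live[ref]])
    dt_h <- abs(t_num[i] - t_num[ref]) / 3600
    if (d_km > vmax_kmh * dt_h) {
      removed_speed[i] <- TRUE
    } else if (!is.null(grid) &&
               depth_at(grid, track$lat[live[i]], track$lon[live[i]]) <= 0) {
      removed_land[i] <- TRUE
    }
  }
  track <- mark_removed(track, live[removed_speed], "speed")
  mark_removed(track, live[removed_land], "land")
}

#' Thin temporally clustered fixes
#'
#' Oversampling during long surface bouts produces temporal clusters that
#' bias hull construction. Maximal runs of consecutive retained fixes whose
#' successive gaps are all strictly below the threshold (default: the median
#' inter-fix interval of the retained track) are reduced to a single
#' representative: the highest location class in the run, earliest on ties.
#'
#' @param track An `argos_track`.
#' @param threshold_s Re-sampling threshold in seconds; `NULL` (default)
#'   uses the median retained inter-fix interval.
#' @return Track with cluster members flagged `cluster_thinned`.
#' @export
thin_temporal_clusters <- function(track, threshold_s = NULL) {
  track <- as_argos_track(track)
  live <- which(track$retained)
  if (length(live) < 2) return(track)
  gaps <- diff(as.numeric(track$time[live]))
  if (is.null(threshold_s)) threshold_s <- stats::median(gaps)
  # run ids: a new run starts wherever the preceding gap is >= threshold
  run_id <- cumsum(c(TRUE, gaps >= threshold_s))
  drop <- integer(0)
  for (r in unique(run_id)) {
    members <- live[run_id == r]
    if (length(members) == 1) next
    best <- members[order(lc_rank(track$lc[members]),
                          as.numeric(track$time[members]))][1]
    drop <- c(drop, setdiff(members, best))
  }
  mark_removed(track, drop, "cluster_thinned")
}

#' Full Argos filtering pipeline
#'
#' Convenience wrapper running, in order: class-Z removal, distant-outlier
#' removal, the anchored speed filter, and temporal-cluster thinning.
#'
#' @inheritParams speed_filter
#' @inheritParams remove_distant_outliers
#' @param thin Apply temporal-cluster thinning (default TRUE).
#' @return The fully flagged `argos_track`.
#' @export
filter_argos <- function(track, reference, max_km = 2500, vmax_kmh = 4.2,
                         grid = NULL, thin = TRUE) {
  track <- as_argos_track(track) |>
    drop_class_z() |>
    remove_distant_outliers(reference, max_km) |>
    speed_filter(vmax_kmh = vmax_kmh, grid = grid)
  if (thin) track <- thin_temporal_clusters(track)
  track
}

#' Read / write Argos fix tables as CSV
#'
#' Column layout: `time` (ISO-8601 UTC), `lat`, `lon`, `lc`, plus
#' `retained`/`reason` provenance when present.
#'
#' @param track An `argos_track` (for writing).
#' @param path File path.
#' @return `read_argos_csv` returns an `argos_track`.
#' @export
write_argos_csv <- function(track, path) {
  readr::write_csv(as_tibble(track), path)
  invisible(path)
}

#' @rdname write_argos_csv
#' @export
read_argos_csv <- function(path) {
  as_argos_track(readr::read_csv(path, show_col_types = FALSE,
                                 col_types = readr::cols(
                                   lc = readr::col_character())))
}

#' Export a filtered track as GeoJSON
#'
#' Retained fixes as a MultiPoint feature plus a LineString in time order.
#'
#' @param track An `argos_track`.
#' @param path Output path.
#' @export
write_track_geojson <- function(track, path) {
  kept <- argos_retained(as_argos_track(track))
  coords <- purrr::map2(kept$lon, kept$lat, c)
  gj <- list(
    type = "FeatureCollection",
    features = list(
      list(type = "Feature",
           properties = list(n_fixes = nrow(kept)),
           geometry = list(type = "MultiPoint", coordinates = coords)),
      list(type = "Feature",
           properties = list(role = "track"),
           geometry = list(type = "LineString", coordinates = coords))))
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
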