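#' @importFrom rlang .data abort warn %||%
#' @importFrom dplyr mutate filter arrange group_by ungroup summarise select
#'   bind_rows left_join n row_number lag lead distinct across
#' @importFrom tibble tibble as_tibble
#' @importFrom stats sd runif rnorm rbinom quantile median cor lm
#' @importFrom utils head tail
NULL

# Earth radius used for all great-circle work (m); keep a single constant so
# the speed filter threshold (km/h) and simulator steps agree.
EARTH_RADIUS_M <- 6371000

# Argos location classes from best to worst. "G" marks GPS-quality fixes.
LC_LEVELS <- c("G", "3", "2", "1", "0", "A", "B", "Z")
LC_ANCHOR <- c("G", "3", "2", "1")

lc_rank <- function(lc) match(as.character(lc), LC_LEVELS)

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371 km, the convention used
#' throughout the package (movement simulation, speed filtering, predictor
#' assembly).
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees (WGS84).
#' @return Numeric vector of distances in km.
#' @export
gc_distance_km <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = EARTH_RADIUS_M) / 1000
}

# Deterministic per-component sub-seed derived from one user seed, so the
# movement, duty-cycle and Argos streams are isolated but jointly reproducible.
derive_seed <- function(seed, component) {
  offs <- c(seascape = 11L, movement = 23L, duty = 37L, argos = 41L,
            schedule = 53L, misc = 67L)
  if (!component %in% names(offs)) offs <- c(offs, stats::setNames(97L, component))
  as.integer((as.numeric(seed) * 7919 + offs[[component]]) %% 2147483629)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  force(code)
}

#' Local calendar day of a timestamp
#'
#' Detection-day metrics are day-boundary sensitive; the study region sits at
#' UTC-10, the package default. The offset is configurable everywhere it is
#' used.
#'
#' @param time POSIXct timestamps (UTC).
#' @param utc_offset Hours to add to UTC to obtain local time (default -10).
#' @return `Date` vector of local calendar days.
#' @export
local_day <- function(time, utc_offset = -10) {
  as.Date(time + utc_offset * 3600, tz = "UTC")
}

# Degrees of longitude per km at a given latitude (small-area local scaling
# used by the simulator; analysis-grade work goes through the UTM projection).
km_per_deg_lat <- function() pi * EARTH_RADIUS_M / 180 / 1000
km_per_deg_lon <- function(lat) km_per_deg_lat() * cos(lat * pi / 180)
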