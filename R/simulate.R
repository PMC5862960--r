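#' Movement parameters for the shark simulator
#'
#' The simulator is a biased correlated random walk attracted to a core
#' location, the structure the home-range analysis is designed to recover:
#' a dense core with use decaying outward across the insular shelf.
#'
#' @param center_lat,center_lon Attraction centre (degrees); must be at sea.
#' @param attraction_per_h Strength of the pull toward the centre (1/h); the
#'   expected step moves this fraction of the distance to the centre per hour.
#' @param noise_km Standard deviation of the random displacement per step
#'   (km per step, per axis).
#' @param max_speed_kmh Hard cap on realised speed; steps are truncated so
#'   consecutive positions never imply a faster speed. Defaults to 4.2 km/h,
#'   the empirical sustained-swimming threshold for large tiger sharks.
#' @param surface_prob Probability a step is flagged at-surface. Large tiger
#'   sharks spend roughly 10-20% of their time within 2 m of the surface;
#'   the default 0.15 sits mid-range.
#' @param excursion_rate_per_h Poisson rate of offshore excursions (default 0).
#' @param excursion_duration_h Mean excursion duration (h, exponential).
#' @param excursion_speed_kmh Outward drift speed while on excursion.
#' @return A list of class `movement_params`.
#' @export
movement_params <- function(center_lat, center_lon, attraction_per_h = 0.5,
                            noise_km = 0.5, max_speed_kmh = 4.2,
                            surface_prob = 0.15, excursion_rate_per_h = 0,
                            excursion_duration_h = 24,
                            excursion_speed_kmh = 3) {
  stopifnot(attraction_per_h >= 0, noise_km >= 0, max_speed_kmh > 0,
            surface_prob >= 0, surface_prob <= 1, excursion_rate_per_h >= 0)
  structure(list(center_lat = center_lat, center_lon = center_lon,
                 attraction_per_h = attraction_per_h, noise_km = noise_km,
                 max_speed_kmh = max_speed_kmh, surface_prob = surface_prob,
                 excursion_rate_per_h = excursion_rate_per_h,
                 excursion_duration_h = excursion_duration_h,
                 excursion_speed_kmh = excursion_speed_kmh),
            class = "movement_params")
}

#' Simulate a shark track on a seascape
#'
#' Biased correlated random walk on a regular time grid. Each step pulls the
#' animal toward the attraction centre, adds Gaussian noise, truncates the
#' displacement to the configured maximum speed, and redraws any step that
#' would land on shore (land reflection: sharks do not beach). At-surface
#' flags are drawn independently per step. Optional offshore excursions
#' switch the walk to an outward drift for an exponential duration.
#'
#' @param shark_id Identifier carried through to downstream tables.
#' @param params A [movement_params].
#' @param grid A [bathy_grid]; positions are constrained to depth > 0.
#' @param start_time POSIXct start of the track (UTC).
#' @param duration_days Track length in days.
#' @param step_min Time step in minutes (default 1).
#' @param seed Integer seed; identical seeds give identical tracks.
#' @return Tibble of class `true_path`: `shark_id`, `time`, `lat`, `lon`,
#'   `at_surface`.
#' @export
simulate_shark_track <- function(shark_id, params, grid,
                                 start_time = as.POSIXct("2014-01-01",
                                                         tz = "UTC"),
                                 duration_days, step_min = 1, seed = 1) {
  stopifnot(inherits(params, "movement_params"), duration_days > 0)
  if (depth_at(grid, params$center_lat, params$center_lon) <= 0)
    abort("simulate_shark_track: attraction centre is on land")
  n <- floor(duration_days * 24 * 60 / step_min) + 1
  dt_h <- step_min / 60
  pull <- min(params$attraction_per_h * dt_h, 1)
  max_step <- params$max_speed_kmh * dt_h
  lat <- numeric(n); lon <- numeric(n)
  lat[1] <- params$center_lat; lon[1] <- params$center_lon
  with_seed(derive_seed(seed, "movement"), {
    at_surface <- runif(n) < params$surface_prob
    # excursion state machine
    exc_until <- 0
    p_exc <- 1 - exp(-params$excursion_rate_per_h * dt_h)
    exc_draw <- runif(n)
    for (t in seq_len(n - 1)) {
      on_exc <- t < exc_until
      if (!on_exc && exc_draw[t] < p_exc) {
        exc_until <- t + stats::rexp(1, 1 / params$excursion_duration_h) / dt_h
        on_exc <- TRUE
      }
      for (try in 1:50) {
        if (on_exc) {
          # drift directly away from the attraction centre
          dy <- (lat[t] - params$center_lat) * km_per_deg_lat()
          dx <- (lon[t] - params$center_lon) * km_per_deg_lon(lat[t])
          nrm <- sqrt(dx^2 + dy^2)
          dir <- if (nrm < 1e-9) c(1, 0) else c(dx, dy) / nrm
          step_x <- dir[1] * params$excursion_speed_kmh * dt_h +
            rnorm(1, 0, params$noise_km)
          step_y <- dir[2] * params$excursion_speed_kmh * dt_h +
            rnorm(1, 0, params$noise_km)
        } else {
          step_y <- pull * (params$center_lat - lat[t]) * km_per_deg_lat() +
            rnorm(1, 0, params$noise_km)
          step_x <- pull * (params$center_lon - lon[t]) *
            km_per_deg_lon(lat[t]) + rnorm(1, 0, params$noise_km)
        }
        len <- sqrt(step_x^2 + step_y^2)
        if (len > max_step) {
          step_x <- step_x * max_step / len
          step_y <- step_y * max_step / len
        }
        new_lat <- lat[t] + step_y / km_per_deg_lat()
        new_lon <- lon[t] + step_x / km_per_deg_lon(lat[t])
        ok <- grid_covers(grid, new_lat, new_lon) &&
          depth_at(grid, new_lat, new_lon) > 0
        if (ok) break
        if (try == 50) { new_lat <- lat[t]; new_lon <- lon[t] }
      }
      lat[t + 1] <- new_lat; lon[t + 1] <- new_lon
    }
  })
  out <- tibble(shark_id = shark_id,
                time = start_time + (seq_len(n) - 1) * step_min * 60,
                lat = lat, lon = lon, at_surface = at_surface)
  class(out) <- c("true_path", class(out))
  attr(out, "params") <- params
  attr(out, "step_min") <- step_min
  out
}

#' Simulate duty-cycled acoustic detections
#'
#' Transmission times follow the coded-transmitter duty cycle: a pulse train
#' of uniform duration in `train_range_s`, then a randomised silent interval
#' uniform in `off_range_s` (default 20-230 s). Every receiver that is
#' deployed, within `range_m` of the shark at the instant of transmission,
#' and listening before the transmitter battery expires logs one detection.
#'
#' @param path A `true_path` from [simulate_shark_track].
#' @param transmitter_id Transmitter code.
#' @param receivers Tibble with `receiver_id`, `lat`, `lon`, `deploy_start`,
#'   `deploy_end` (POSIXct).
#' @param activation POSIXct transmitter activation (default: track start).
#' @param battery_days Nominal battery life in days (default 730).
#' @param train_range_s Pulse-train duration range (default c(3, 5)).
#' @param off_range_s Random off-time range (default c(20, 230)).
#' @param range_m Maximum detection range (default 900 m).
#' @param seed Integer seed.
#' @return Tibble of detections: `time`, `receiver_id`, `transmitter_id`.
#' @export
simulate_acoustic_detections <- function(path, transmitter_id, receivers,
                                         activation = NULL,
                                         battery_days = 730,
                                         train_range_s = c(3, 5),
                                         off_range_s = c(20, 230),
                                         range_m = 900, seed = 1) {
  receivers <- as_tibble(receivers)
  stopifnot(all(c("receiver_id", "lat", "lon", "deploy_start", "deploy_end")
                %in% names(receivers)))
  if (is.null(activation)) activation <- min(path$time)
  battery_end <- activation + battery_days * 86400
  t0 <- as.numeric(min(path$time)); t1 <- as.numeric(max(path$time))
  t1 <- min(t1, as.numeric(battery_end))
  if (t1 <= t0) return(tibble(time = as.POSIXct(character(), tz = "UTC"),
                              receiver_id = character(),
                              transmitter_id = character()))
  mean_cycle <- mean(train_range_s) + mean(off_range_s)
  n_max <- ceiling((t1 - t0) / (min(train_range_s) + min(off_range_s))) + 10
  tx_times <- with_seed(derive_seed(seed, "duty"), {
    trains <- runif(n_max, train_range_s[1], train_range_s[2])
    offs <- runif(n_max, off_range_s[1], off_range_s[2])
    t0 + cumsum(trains + offs)
  })
  tx_times <- tx_times[tx_times <= t1]
  if (length(tx_times) == 0) return(tibble(
    time = as.POSIXct(character(), tz = "UTC"),
    receiver_id = character(), transmitter_id = character()))
  # linear interpolation of the regular-grid path at transmission instants
  pt <- as.numeric(path$time)
  sh_lat <- stats::approx(pt, path$lat, xout = tx_times)$y
  sh_lon <- stats::approx(pt, path$lon, xout = tx_times)$y
  out <- purrr::map_dfr(seq_len(nrow(receivers)), function(i) {
    r <- receivers[i, ]
    d_m <- gc_distance_km(sh_lon, sh_lat, r$lon, r$lat) * 1000
    keep <- d_m <= range_m &
      tx_times >= as.numeric(r$deploy_start) &
      tx_times <= as.numeric(r$deploy_end)
    tibble(time = as.POSIXct(tx_times[keep], origin = "1970-01-01",
                             tz = "UTC"),
           receiver_id = r$receiver_id,
           transmitter_id = transmitter_id)
  })
  arrange(out, .data$time, .data$receiver_id)
}

#' Simulate Argos fixes from a surfacing track
#'
#' Argos satellite coverage in the study region averages only 6-12 minutes
#' per hour; a fix can be generated only when the shark is at the surface
#' during a coverage window. Each hour gets one contiguous coverage window of
#' uniform length in `coverage_min_per_h` at a random offset. Each surfaced
#' step falling in coverage yields a fix with probability `fix_prob`; the fix
#' is assigned a location class from `lc_probs` and displaced by isotropic
#' Gaussian error with the class RMS from `lc_error_rms_m`. Class Z fixes
#' carry no usable position (NA coordinates, flagged).
#'
#' @param path A `true_path` with at-surface flags.
#' @param coverage_min_per_h Range of coverage minutes per hour (default
#'   c(6, 12)).
#' @param lc_probs Named probabilities over location classes. Default
#'   `c("3" = .1, "2" = .15, "1" = .15, "0" = .2, A = .2, B = .2)`.
#' @param lc_error_rms_m Named RMS positional error (m) per class. Defaults:
#'   LC3 150, LC2 300, LC1 1000, LC0 3000, A 5000, B 10000, G 30, Z NA.
#' @param fix_prob Per surfaced-covered step probability of a fix (0.25).
#' @param seed Integer seed.
#' @return Tibble of class `argos_track`: `shark_id`, `time`, `lat`, `lon`,
#'   `lc`, plus `true_lat`, `true_lon` for validation work.
#' @export
simulate_argos_fixes <- function(path,
                                 coverage_min_per_h = c(6, 12),
                                 lc_probs = c("3" = 0.1, "2" = 0.15,
                                              "1" = 0.15, "0" = 0.2,
                                              "A" = 0.2, "B" = 0.2),
                                 lc_error_rms_m = c(G = 30, "3" = 150,
                                                    "2" = 300, "1" = 1000,
                                                    "0" = 3000, A = 5000,
                                                    B = 10000, Z = NA),
                                 fix_prob = 0.25, seed = 1) {
  stopifnot("at_surface" %in% names(path))
  missing_cls <- setdiff(setdiff(names(lc_probs), "Z"), names(lc_error_rms_m))
  if (length(missing_cls) > 0)
    abort(paste0("simulate_argos_fixes: no error RMS for class ",
                 paste(missing_cls, collapse = ", ")))
  step_min <- attr(path, "step_min") %||% 1
  empty <- tibble(shark_id = character(), time = path$time[0],
                  lat = numeric(), lon = numeric(), lc = character(),
                  true_lat = numeric(), true_lon = numeric())
  class(empty) <- c("argos_track", class(empty))
  if (!any(path$at_surface)) return(empty)
  res <- with_seed(derive_seed(seed, "argos"), {
    hrs <- floor(as.numeric(path$time) / 3600)
    uh <- unique(hrs)
    cov_len <- runif(length(uh), coverage_min_per_h[1],
                     coverage_min_per_h[2]) * 60
    cov_start <- uh * 3600 + runif(length(uh)) * (3600 - cov_len)
    idx <- match(hrs, uh)
    tsec <- as.numeric(path$time)
    in_cov <- tsec >= cov_start[idx] & tsec <= cov_start[idx] + cov_len[idx]
    cand <- which(path$at_surface & in_cov)
    cand <- cand[runif(length(cand)) < fix_prob]
    if (length(cand) == 0) {
      empty
    } else {
      lc <- sample(names(lc_probs), length(cand), replace = TRUE,
                   prob = lc_probs)
      rms <- lc_error_rms_m[lc]
      sd_axis <- rms / sqrt(2) / 1000
      err_x <- rnorm(length(cand), 0, ifelse(is.na(sd_axis), 0, sd_axis))
      err_y <- rnorm(length(cand), 0, ifelse(is.na(sd_axis), 0, sd_axis))
      tl <- path$lat[cand]; tn <- path$lon[cand]
      out <- tibble(shark_id = path$shark_id[cand], time = path$time[cand],
                    lat = tl + err_y / km_per_deg_lat(),
                    lon = tn + err_x / km_per_deg_lon(tl),
                    lc = lc, true_lat = tl, true_lon = tn)
      out$lat[out$lc == "Z"] <- NA_real_
      out$lon[out$lc == "Z"] <- NA_real_
      class(out) <- c("argos_track", class(out))
      out
    }
  })
  res
}

#' Simulate a daily visit schedule at a receiver
#'
#' Residency null model used to validate the Site Fidelity Index: each
#' monitored local day the shark visits the receiver independently with
#' probability `p_daily`; a visit places a short burst of detections at a
#' uniform time of day. The SFI recovered from these detections converges on
#' `100 * p_daily` with binomial error.
#'
#' @param transmitter_id,receiver_id Identifiers.
#' @param start Date of first monitored day.
#' @param n_days Number of monitored days.
#' @param p_daily Independent daily visiting probability.
#' @param detections_per_visit Number of detections per visit (default 3).
#' @param utc_offset Local-day offset (default -10).
#' @param seed Integer seed.
#' @return Tibble of detections: `time`, `receiver_id`, `transmitter_id`.
#' @export
simulate_visit_schedule <- function(transmitter_id, receiver_id, start,
                                    n_days, p_daily,
                                    detections_per_visit = 3,
                                    utc_offset = -10, seed = 1) {
  stopifnot(p_daily >= 0, p_daily <= 1, n_days > 0)
  with_seed(derive_seed(seed, "schedule"), {
    visit <- runif(n_days) < p_daily
    days <- which(visit)
    if (length(days) == 0)
      return(tibble(time = as.POSIXct(character(), tz = "UTC"),
                    receiver_id = character(), transmitter_id = character()))
    # place the burst mid-day local time so it cannot straddle a day boundary
    day0 <- as.POSIXct(paste(as.Date(start) - 1, "00:00:00"), tz = "UTC") -
      utc_offset * 3600
    t0 <- as.numeric(day0) + days * 86400 +
      runif(length(days), 6 * 3600, 18 * 3600)
    ts <- rep(t0, each = detections_per_visit) +
      seq(0, by = 120, length.out = detections_per_visit)
    tibble(time = as.POSIXct(sort(ts), origin = "1970-01-01", tz = "UTC"),
           receiver_id = receiver_id, transmitter_id = transmitter_id)
  })
}

#' Track speed check
#'
#' Realised speeds between consecutive positions of a simulated track.
#' @param path A `true_path`.
#' @return Numeric vector of speeds (km/h), length `nrow(path) - 1`.
#' @export
track_speeds_kmh <- function(path) {
  n <- nrow(path)
  d_km <- gc_distance_km(path$lon[-n], path$lat[-n],
                         path$lon[-1], path$lat[-1])
  dt_h <- diff(as.numeric(path$time)) / 3600
  d_km / dt_h
}
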