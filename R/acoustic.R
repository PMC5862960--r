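#' Monitoring windows per transmitter-receiver pair
#'
#' The Site Fidelity Index denominator. For every pair the monitored
#' interval set is the intersection of the receiver's deployment intervals,
#' the transmitter's active life (activation to nominal battery end -- the
#' zero-battery-failure assumption), and the analysis period; monitored days
#' are the distinct local calendar days those intervals touch.
#'
#' @param receivers Tibble with `receiver_id`, `deploy_start`, `deploy_end`
#'   (POSIXct; several rows per receiver allowed for redeployments).
#' @param transmitters Tibble with `transmitter_id`, `activation` (POSIXct),
#'   `battery_days` (numeric, required).
#' @param period Optional POSIXct `c(start, end)` analysis period.
#' @param utc_offset Local-day offset in hours (default -10).
#' @return Tibble: `transmitter_id`, `receiver_id`, `monitored_days`,
#'   `days` (list of Date vectors of monitored local days).
#' @export
monitoring_windows <- function(receivers, transmitters, period = NULL,
                               utc_offset = -10) {
  receivers <- as_tibble(receivers)
  transmitters <- as_tibble(transmitters)
  if (!"battery_days" %in% names(transmitters) ||
      any(is.na(transmitters$battery_days)))
    abort("monitoring_windows: every transmitter needs a battery life")
  tidyr::crossing(transmitter_id = unique(transmitters$transmitter_id),
                  receiver_id = unique(receivers$receiver_id)) |>
    purrr::pmap_dfr(function(transmitter_id, receiver_id) {
      tx <- transmitters[transmitters$transmitter_id == transmitter_id, ][1, ]
      rx <- receivers[receivers$receiver_id == receiver_id, ]
      tx_start <- tx$activation
      tx_end <- tx$activation + tx$battery_days * 86400
      days <- as.Date(character())
      for (k in seq_len(nrow(rx))) {
        s <- max(as.numeric(rx$deploy_start[k]), as.numeric(tx_start))
        e <- min(as.numeric(rx$deploy_end[k]), as.numeric(tx_end))
        if (!is.null(period)) {
          s <- max(s, as.numeric(period[1]))
          e <- min(e, as.numeric(period[2]))
        }
        if (s <= e) {
          d0 <- local_day(as.POSIXct(s, origin = "1970-01-01", tz = "UTC"),
                          utc_offset)
          d1 <- local_day(as.POSIXct(e, origin = "1970-01-01", tz = "UTC"),
                          utc_offset)
          days <- c(days, seq(d0, d1, by = "day"))
        }
      }
      days <- sort(unique(days))
      tibble(transmitter_id = transmitter_id, receiver_id = receiver_id,
             monitored_days = length(days), days = list(days))
    })
}

#' Segment detections into visits
#'
#' A visit is a contiguous presence bout of one shark at one receiver. The
#' chronological scan closes the open visit when the next detection occurs
#' at a different receiver (the visit ends at the last detection at the old
#' receiver and a new one opens immediately) or arrives `gap_min` minutes or
#' more after the previous one. Visit duration is last minus first detection
#' in minutes; a single-detection visit is assigned `single_detection_min`
#' (see [single_detection_minutes]).
#'
#' @param detections Tibble with `time`, `transmitter_id`, `receiver_id`.
#' @param gap_min Gap closing a visit (default 30 minutes).
#' @param single_detection_min Duration assigned to one-detection visits
#'   (default 7.7 min), applied to all transmitters regardless of duty cycle
#'   to avoid duty-cycle bias.
#' @return Tibble of visits: `transmitter_id`, `receiver_id`, `start`,
#'   `end`, `duration_min`, `n_detections`.
#' @export
segment_visits <- function(detections, gap_min = 30,
                           single_detection_min = single_detection_minutes()) {
  detections <- as_tibble(detections) |>
    arrange(.data$transmitter_id, .data$time, .data$receiver_id)
  if (nrow(detections) == 0)
    return(tibble(transmitter_id = character(), receiver_id = character(),
                  start = as.POSIXct(character(), tz = "UTC"),
                  end = as.POSIXct(character(), tz = "UTC"),
                  duration_min = numeric(), n_detections = integer()))
  detections |>
    group_by(.data$transmitter_id) |>
    mutate(.new = row_number() == 1 |
             .data$receiver_id != lag(.data$receiver_id) |
             as.numeric(.data$time) - as.numeric(lag(.data$time)) >=
             gap_min * 60,
           .visit = cumsum(.new)) |>
    group_by(.data$transmitter_id, .data$.visit, .data$receiver_id) |>
    summarise(start = min(.data$time), end = max(.data$time),
              n_detections = n(), .groups = "drop") |>
    mutate(duration_min = ifelse(
      .data$n_detections == 1, single_detection_min,
      (as.numeric(.data$end) - as.numeric(.data$start)) / 60)) |>
    select("transmitter_id", "receiver_id", "start", "end",
           "duration_min", "n_detections") |>
    arrange(.data$transmitter_id, .data$start)
}

#' Duration convention for single-detection visits
#'
#' The longest coded pulse train (3.6 s) preceded and followed by listening
#' periods equal to the maximum random off time (230 s), rounded to one
#' decimal: (3.6 + 2 x 230) / 60 = 7.7 min. Based on the slowest duty cycle
#' and applied to all transmitters.
#'
#' @param train_s Longest pulse-train duration (s).
#' @param max_off_s Maximum random off time (s).
#' @return Duration in minutes, rounded to one decimal.
#' @export
single_detection_minutes <- function(train_s = 3.6, max_off_s = 230) {
  round((train_s + 2 * max_off_s) / 60, 1)
}

#' Site Fidelity Index
#'
#' Days detected divided by monitored days, expressed as a percentage.
#' Days detected are the distinct local calendar days with at least one
#' detection of that transmitter at that receiver.
#'
#' @param detections Detection tibble (`time`, `transmitter_id`,
#'   `receiver_id`).
#' @param windows Output of [monitoring_windows].
#' @param utc_offset Local-day offset (default -10).
#' @return Tibble: `transmitter_id`, `receiver_id`, `days_detected`,
#'   `monitored_days`, `sfi` (percent).
#' @export
compute_sfi <- function(detections, windows, utc_offset = -10) {
  detections <- as_tibble(detections)
  det_days <- detections |>
    mutate(day = local_day(.data$time, utc_offset)) |>
    distinct(.data$transmitter_id, .data$receiver_id, .data$day)
  out <- windows |>
    mutate(days_detected = purrr::pmap_int(
      list(.data$transmitter_id, .data$receiver_id, .data$days),
      function(tx, rx, wd) {
        dd <- det_days$day[det_days$transmitter_id == tx &
                             det_days$receiver_id == rx]
        length(intersect(dd, wd))
      })) |>
    select("transmitter_id", "receiver_id", "days_detected",
           "monitored_days")
  any_det <- det_days |>
    dplyr::count(.data$transmitter_id, .data$receiver_id, name = "n_days")
  zero_win <- out |>
    left_join(any_det, by = c("transmitter_id", "receiver_id")) |>
    filter(.data$monitored_days == 0 & !is.na(.data$n_days) & .data$n_days > 0)
  if (nrow(zero_win) > 0)
    abort("compute_sfi: detections present for a pair with zero monitored days")
  outside <- dplyr::anti_join(
    det_days |>
      dplyr::semi_join(windows, by = c("transmitter_id", "receiver_id")),
    windows |> tidyr::unnest(cols = "days") |>
      select("transmitter_id", "receiver_id", day = "days"),
    by = c("transmitter_id", "receiver_id", "day"))
  if (nrow(outside) > 0)
    warn(sprintf("compute_sfi: %d detection day(s) outside monitoring windows",
                 nrow(outside)))
  mutate(out, sfi = ifelse(.data$monitored_days > 0,
                           100 * .data$days_detected / .data$monitored_days,
                           0))
}

#' Revisit interval equivalent of an SFI value
#'
#' Under uniform spacing, an SFI of p percent means one detection day every
#' 100/p days: SFI 20 is a visit at least every 5 days, SFI 10 every 10.
#'
#' @param sfi_percent SFI value(s) in (0, 100].
#' @return Mean days between detection days.
#' @export
sfi_equivalent_revisit_interval <- function(sfi_percent) {
  if (any(sfi_percent <= 0)) abort("sfi_equivalent_revisit_interval: SFI must be > 0")
  100 / sfi_percent
}

#' Detection-day frequency at a receiver
#'
#' Percentage of a receiver's monitored days on which at least one tagged
#' shark (any transmitter) was detected.
#'
#' @param detections Detection tibble.
#' @param receiver_id Receiver to summarise.
#' @param monitored_days Either an integer count or a Date vector of
#'   monitored local days (detection days outside it are ignored).
#' @param utc_offset Local-day offset (default -10).
#' @return Percentage in [0, 100].
#' @export
detection_day_frequency <- function(detections, receiver_id, monitored_days,
                                    utc_offset = -10) {
  det <- filter(as_tibble(detections), .data$receiver_id == !!receiver_id)
  days <- unique(local_day(det$time, utc_offset))
  if (inherits(monitored_days, "Date")) {
    100 * length(intersect(days, monitored_days)) / length(monitored_days)
  } else {
    if (monitored_days <= 0) return(0)
    100 * length(days) / monitored_days
  }
}

#' Daily co-detection summary at a receiver
#'
#' Distinct sharks detected per local day, the percentage of monitored days
#' with two or more sharks, and the single-day maximum.
#'
#' @inheritParams detection_day_frequency
#' @return List with `per_day` (tibble `day`, `n_sharks`),
#'   `pct_multi_shark_days`, `max_sharks_per_day`.
#' @export
codetection_summary <- function(detections, receiver_id,
                                monitored_days = NULL, utc_offset = -10) {
  det <- filter(as_tibble(detections), .data$receiver_id == !!receiver_id)
  per_day <- det |>
    mutate(day = local_day(.data$time, utc_offset)) |>
    group_by(.data$day) |>
    summarise(n_sharks = dplyr::n_distinct(.data$transmitter_id),
              .groups = "drop")
  denom <- if (is.null(monitored_days)) nrow(per_day)
  else if (inherits(monitored_days, "Date")) length(monitored_days)
  else monitored_days
  list(per_day = per_day,
       pct_multi_shark_days = if (denom > 0)
         100 * sum(per_day$n_sharks >= 2) / denom else 0,
       max_sharks_per_day = if (nrow(per_day) > 0)
         max(per_day$n_sharks) else 0L)
}

#' Per-shark residency summaries
#'
#' One row per shark: mean (excluding zeros) and maximum SFI; mean and
#' maximum visit duration (all visits included); mean (excluding zero days)
#' and maximum visits per day; inter-visit intervals and absence durations
#' from the most-visited receiver (most visits, ties broken by higher SFI).
#'
#' @param visits Output of [segment_visits].
#' @param sfi Output of [compute_sfi].
#' @param utc_offset Local-day offset (default -10).
#' @return Tibble with one row per transmitter; interval columns are
#'   list-columns of hours, `single_visit` flags sharks whose interval set
#'   is empty.
#' @export
shark_summaries <- function(visits, sfi, utc_offset = -10) {
  visits <- as_tibble(visits)
  sfi <- as_tibble(sfi)
  purrr::map_dfr(unique(visits$transmitter_id), function(tx) {
    v <- filter(visits, .data$transmitter_id == tx)
    s <- filter(sfi, .data$transmitter_id == tx)
    nz <- s$sfi[s$sfi > 0]
    per_day <- v |>
      mutate(day = local_day(.data$start, utc_offset)) |>
      group_by(.data$day) |> summarise(n = n(), .groups = "drop")
    by_rx <- v |> group_by(.data$receiver_id) |>
      summarise(n_visits = n(), .groups = "drop") |>
      left_join(s, by = "receiver_id") |>
      arrange(-.data$n_visits, -.data$sfi)
    home <- by_rx$receiver_id[1]
    vh <- filter(v, .data$receiver_id == home) |> arrange(.data$start)
    absent_h <- if (nrow(vh) > 1)
      (as.numeric(vh$start[-1]) - as.numeric(vh$end[-nrow(vh)])) / 3600
    else numeric(0)
    tibble(transmitter_id = tx,
           mean_sfi_excl_zero = if (length(nz) > 0) mean(nz) else NA_real_,
           max_sfi = if (nrow(s) > 0) max(s$sfi) else NA_real_,
           mean_visit_min = mean(v$duration_min),
           max_visit_min = max(v$duration_min),
           mean_visits_per_day = mean(per_day$n),
           max_visits_per_day = max(per_day$n),
           most_visited = home,
           absence_from_home_h = list(absent_h),
           single_visit = nrow(vh) <= 1)
  })
}

#' Plot an SFI matrix
#'
#' Shark-by-receiver tile plot of SFI values, the standard way to spot
#' spatially clustered fidelity across an array.
#'
#' @param sfi Output of [compute_sfi].
#' @return A ggplot object.
#' @export
plot_sfi_matrix <- function(sfi) {
  ggplot2::ggplot(as_tibble(sfi),
                  ggplot2::aes(.data$receiver_id, .data$transmitter_id,
                               fill = .data$sfi)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "SFI (%)") +
    ggplot2::labs(x = "Receiver", y = "Shark") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
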