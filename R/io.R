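# CSV interchange for the acoustic tables. Layouts mirror common receiver
# export conventions: detections as (time, receiver_id, transmitter_id) with
# ISO-8601 UTC timestamps.

#' Read and write detection logs
#' @param detections Detection tibble.
#' @param path File path.
#' @export
write_detections_csv <- function(detections, path) {
  readr::write_csv(as_tibble(detections)[, c("time", "receiver_id",
                                             "transmitter_id")], path)
  invisible(path)
}

#' @rdname write_detections_csv
#' @export
read_detections_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    time = readr::col_datetime(),
                    receiver_id = readr::col_character(),
                    transmitter_id = readr::col_character()))
}

#' Write visit and SFI tables
#' @param x Tibble from [segment_visits], [compute_sfi] or
#'   [shark_summaries].
#' @param path File path.
#' @export
write_residency_csv <- function(x, path) {
  x <- as_tibble(x)
  listcols <- vapply(x, is.list, logical(1))
  x[listcols] <- lapply(x[listcols], function(col)
    vapply(col, function(v) paste(signif(as.numeric(v), 6), collapse = ";"),
           character(1)))
  readr::write_csv(x, path)
  invisible(path)
}
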