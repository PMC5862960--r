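# Independent oracles used across the suite. Each deliberately reimplements
# the checked computation with a different algorithm (or an external
# library) so implementation and check never share code paths.

# Brute-force visit splitter: explicit chronological loop with open-visit
# state, closing on receiver change or a gap >= gap_min.
oracle_split_visits <- function(detections, gap_min = 30,
                                single_min = 7.7) {
  detections <- detections[order(detections$transmitter_id,
                                 detections$time,
                                 detections$receiver_id), ]
  out <- list()
  for (tx in unique(detections$transmitter_id)) {
    d <- detections[detections$transmitter_id == tx, ]
    open_start <- d$time[1]; open_end <- d$time[1]
    open_rx <- d$receiver_id[1]; open_n <- 1L
    close_visit <- function() {
      dur <- as.numeric(open_end - open_start, units = "mins")
      out[[length(out) + 1]] <<- data.frame(
        transmitter_id = tx, receiver_id = open_rx,
        start = open_start, end = open_end,
        duration_min = if (open_n == 1L) single_min else dur,
        n_detections = open_n)
    }
    if (nrow(d) > 1) {
      for (i in 2:nrow(d)) {
        gap <- as.numeric(d$time[i] - d$time[i - 1], units = "mins")
        if (d$receiver_id[i] != open_rx || gap >= gap_min) {
          close_visit()
          open_start <- d$time[i]; open_rx <- d$receiver_id[i]; open_n <- 0L
        }
        open_end <- d$time[i]; open_n <- open_n + 1L
      }
    }
    close_visit()
  }
  res <- do.call(rbind, out)
  res[order(res$transmitter_id, res$start), ]
}

# Ray-casting point-in-polygon with an explicit on-boundary test, O(n * m).
oracle_point_in_poly <- function(px, py, poly, eps = 1e-9) {
  n <- nrow(poly)
  scale <- max(abs(poly)) + 1
  vapply(seq_along(px), function(q) {
    x <- px[q]; y <- py[q]
    crossings <- 0L
    for (k in seq_len(n)) {
      a <- poly[k, ]; b <- poly[if (k == n) 1 else k + 1, ]
      # on-segment check
      ab2 <- sum((b - a)^2)
      t <- if (ab2 == 0) 0 else
        min(1, max(0, ((x - a[1]) * (b[1] - a[1]) +
                         (y - a[2]) * (b[2] - a[2])) / ab2))
      if ((x - (a[1] + t * (b[1] - a[1])))^2 +
          (y - (a[2] + t * (b[2] - a[2])))^2 <= (eps * scale)^2)
        return(TRUE)
      if ((a[2] > y) != (b[2] > y)) {
        xint <- a[1] + (y - a[2]) / (b[2] - a[2]) * (b[1] - a[1])
        if (x < xint) crossings <- crossings + 1L
      }
    }
    crossings %% 2L == 1L
  }, logical(1))
}

# ECDF-based KS D oracle built on stats::ecdf step functions.
oracle_ks_d <- function(x, y) {
  v <- sort(unique(c(x, y)))
  max(abs(stats::ecdf(x)(v) - stats::ecdf(y)(v)))
}

# Shapely union-area oracle: one python call for a whole batch of polygon
# sets. `batches` is a list; each element is a list of vertex matrices.
shapely_union_areas <- function(batches) {
  stopifnot(nzchar(Sys.which("python")))
  enc <- lapply(batches, function(polys)
    lapply(polys, function(p) unname(apply(p, 1, c, simplify = FALSE))))
  inp <- tempfile(fileext = ".json")
  outp <- tempfile(fileext = ".json")
  jsonlite::write_json(enc, inp, auto_unbox = FALSE, digits = NA)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import json, sys",
    "from shapely.geometry import Polygon",
    "from shapely.ops import unary_union",
    sprintf("batches = json.load(open(%s))", deparse(inp)),
    "areas = []",
    "for polys in batches:",
    "    geoms = [Polygon(p) for p in polys if len(p) >= 3]",
    "    areas.append(unary_union(geoms).area if geoms else 0.0)",
    sprintf("json.dump(areas, open(%s, 'w'))", deparse(outp))), script)
  status <- system2("python", script, stdout = TRUE, stderr = TRUE)
  if (!file.exists(outp))
    stop("shapely oracle failed: ", paste(status, collapse = "\n"))
  as.numeric(jsonlite::read_json(outp, simplifyVector = TRUE))
}

# Direct bilinear interpolation oracle (scalar loop over queries).
oracle_bilinear <- function(grid, lat, lon) {
  vapply(seq_along(lat), function(q) {
    fi <- (lat[q] - grid$origin_lat) / grid$cell_size
    fj <- (lon[q] - grid$origin_lon) / grid$cell_size
    i0 <- max(0, min(floor(fi), grid$n_rows - 2))
    j0 <- max(0, min(floor(fj), grid$n_cols - 2))
    u <- fi - i0; v <- fj - j0
    m <- grid$depth
    (1 - u) * (1 - v) * m[i0 + 1, j0 + 1] +
      (1 - u) * v * m[i0 + 1, j0 + 2] +
      u * (1 - v) * m[i0 + 2, j0 + 1] +
      u * v * m[i0 + 2, j0 + 2]
  }, numeric(1))
}

# Shared small-island fixture, built once per test run.
.fixture_env <- new.env()
test_seascape <- function() {
  if (is.null(.fixture_env$grid)) {
    isl <- tibble::tibble(name = "Moku", lat = 20.8, lon = -156.6,
                          land_radius_km = 15, shelf_width_km = 12)
    .fixture_env$grid <- generate_seascape(isl, resolution = 0.01)
  }
  .fixture_env$grid
}

# Random detection log generator for the segmentation oracle suites.
random_detection_log <- function(seed, n = 25, n_sharks = 2,
                                 n_receivers = 3) {
  set.seed(seed)
  t0 <- as.POSIXct("2014-06-01", tz = "UTC")
  tibble::tibble(
    time = t0 + sort(sample.int(36 * 3600, n)),
    transmitter_id = sample(paste0("T", seq_len(n_sharks)), n,
                            replace = TRUE),
    receiver_id = sample(paste0("R", seq_len(n_receivers)), n,
                         replace = TRUE))
}

expect_same_partition <- function(got, want) {
  expect_equal(nrow(got), nrow(want))
  expect_equal(got$transmitter_id, want$transmitter_id)
  expect_equal(got$receiver_id, want$receiver_id)
  expect_equal(as.numeric(got$start), as.numeric(want$start))
  expect_equal(as.numeric(got$end), as.numeric(want$end))
  expect_equal(got$duration_min, want$duration_min)
  expect_equal(as.integer(got$n_detections), as.integer(want$n_detections))
}
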