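pts_tbl <- function(x, y) tibble::tibble(x = x, y = y)

test_that("neighbour rules match their definitions on a collinear set", {
  # root at origin; points at distances 1, 2, 3 along the x axis
  pts <- pts_tbl(c(0, 1, 2, 3), rep(0, 4))
  nb_a <- locoh_neighbors(pts, "a", value = 4)
  expect_setequal(nb_a[[1]], c(1, 2, 3)) # 1 + 2 = 3 <= 4; +3 would exceed
  nb_r <- locoh_neighbors(pts, "r", value = 2.5)
  expect_setequal(nb_r[[1]], c(1, 2, 3)) # all points within radius 2.5
  set.seed(1)
  pts10 <- pts_tbl(runif(10), runif(10))
  nb_k <- locoh_neighbors(pts10, "k", value = 3)
  expect_true(all(lengths(nb_k) == 3)) # root + 2 nearest
  d <- as.matrix(dist(pts10))
  for (i in 1:10)
    expect_setequal(nb_k[[i]], c(i, order(d[i, ])[2:3]))
  expect_error(locoh_neighbors(pts10, "k", value = 11), "exceeds")
  expect_error(locoh_neighbors(pts10, "a", value = -1))
  expect_error(locoh_neighbors(pts10, "a", value = 1, s = 1),
               "time weighting")
})

test_that("a-method neighbour sets grow monotonically with a", {
  set.seed(8)
  pts <- pts_tbl(rnorm(40), rnorm(40))
  avals <- c(0.5, 1, 2, 4, 8)
  sets <- lapply(avals, function(a) locoh_neighbors(pts, "a", a))
  for (k in seq_along(avals)[-1]) {
    for (i in seq_len(40)) {
      expect_true(all(sets[[k - 1]][[i]] %in% sets[[k]][[i]]))
    }
  }
})

test_that("hulls carry exact areas and oracle-validated enclosed counts", {
  sq <- pts_tbl(c(0, 1, 1, 0), c(0, 0, 1, 1))
  hs <- locoh_hulls(sq, "k", value = 4)
  expect_equal(hs$area, rep(1, 4)) # every hull is the unit square
  expect_equal(hs$n_enclosed, rep(4L, 4))
  # collinear points: zero-area hull, counted not errored
  col3 <- pts_tbl(c(0, 1, 2), c(0, 0, 0))
  hc <- locoh_hulls(col3, "k", value = 3)
  expect_equal(hc$area, rep(0, 3))
  expect_equal(hc$n_enclosed, rep(3L, 3))
  # random cloud vs brute-force ray-casting oracle
  set.seed(12)
  cloud <- pts_tbl(rnorm(30), rnorm(30))
  hr <- locoh_hulls(cloud, "k", value = 6)
  for (i in seq_len(30)) {
    oracle <- sum(oracle_point_in_poly(cloud$x, cloud$y, hr$hull[[i]]))
    expect_equal(hr$n_enclosed[i], oracle)
  }
})

test_that("isopleths nest, satisfy coverage, and union areas match shapely", {
  set.seed(3)
  pts <- pts_tbl(c(rnorm(10, sd = 0.5), rnorm(10, 8, sd = 0.5)),
                 c(rnorm(10, sd = 0.5), rnorm(10, 8, sd = 0.5)))
  hs <- locoh_hulls(pts, "k", value = 10)
  iso <- build_isopleths(hs, levels = c(0.25, 0.5, 0.95, 1.0))
  expect_true(all(diff(iso$area_km2) >= -1e-12))
  expect_true(all(iso$fraction_enclosed >= iso$level))
  expect_equal(iso$fraction_enclosed[4], 1.0)
  # two separated clusters of 10: the 0.5 region needs only one cluster
  expect_gte(iso$fraction_enclosed[2], 0.5)
  m <- iso$members[[2]]
  roots <- hs$root[m]
  expect_true(all(roots <= 10) || all(roots > 10))
  # containment: members at lower levels are prefixes of higher levels
  for (k in 2:4)
    expect_identical(iso$members[[k - 1]],
                     iso$members[[k]][seq_along(iso$members[[k - 1]])])
  # exact union areas against shapely
  areas <- shapely_union_areas(
    lapply(iso$members, function(mm) hs$hull[mm]))
  expect_equal(iso$area_km2 * 1e6, areas, tolerance = 1e-9)
  expect_error(build_isopleths(hs, levels = c(0, 0.5)), "levels")
})

test_that("union area and centroid agree with shapely on random hull sets", {
  set.seed(21)
  batches <- lapply(1:10, function(i) {
    polys <- lapply(seq_len(sample(3:10, 1)), function(j) {
      convex_hull(matrix(rnorm(14, mean = runif(1, 0, 6)), ncol = 2))
    })
    polys
  })
  got <- vapply(batches, function(b) polygon_union_area(b)$area, numeric(1))
  want <- shapely_union_areas(batches)
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("core isopleth recovers the programmed attraction centre", {
  g <- test_seascape()
  p <- movement_params(center_lat = 20.95, center_lon = -156.45,
                       attraction_per_h = 0.5, noise_km = 0.5,
                       max_speed_kmh = 4.2)
  tr <- simulate_shark_track("S", p, g, duration_days = 5000 * 30 / 1440,
                             step_min = 30, seed = 11)
  pl <- project_to_planar(tr)
  sub <- pl[seq(1, nrow(pl), by = 5), ]
  hs <- locoh_hulls(sub, "k", value = 15)
  iso <- build_isopleths(hs, levels = 0.25)
  ctr <- latlon_to_utm(20.95, -156.45)
  err_km <- sqrt((iso$centroid_x - ctr$x)^2 +
                   (iso$centroid_y - ctr$y)^2) / 1000
  expect_lt(err_km, 2)
})

test_that("two sharks with centres >= 20 km apart have disjoint cores", {
  g <- test_seascape()
  mk <- function(lat, lon, seed) {
    p <- movement_params(center_lat = lat, center_lon = lon,
                         attraction_per_h = 0.5, noise_km = 0.4)
    tr <- simulate_shark_track("S", p, g, duration_days = 25,
                               step_min = 30, seed = seed)
    pl <- project_to_planar(tr)
    hs <- locoh_hulls(pl, "k", value = 12)
    list(hs = hs, iso = build_isopleths(hs, levels = c(0.25, 0.95)))
  }
  a <- mk(20.95, -156.45, 101)
  b <- mk(20.68, -156.38, 102) # ~30 km away on the southern shelf
  pa <- a$hs$hull[a$iso$members[[1]]]
  pb <- b$hs$hull[b$iso$members[[1]]]
  ua <- polygon_union_area(pa)$area
  ub <- polygon_union_area(pb)$area
  uab <- polygon_union_area(c(pa, pb))$area
  expect_lt(ua + ub - uab, 1e-6 * (ua + ub)) # no overlap
  expect_gte(a$iso$fraction_enclosed[2], 0.95)
  expect_lte(a$iso$fraction_enclosed[2], 1.0)
})

test_that("a-value selection applies the gap and land criteria", {
  g <- test_seascape()
  # shark working the outer shelf annulus all around the island
  set.seed(5)
  n <- 150
  th <- runif(n, 0, 2 * pi)
  rad <- sqrt(runif(n, 20^2, 30^2)) # km from island centre
  lat <- 20.8 + rad * sin(th) / sharkmove:::km_per_deg_lat()
  lon <- -156.6 + rad * cos(th) / sharkmove:::km_per_deg_lon(20.8)
  pl <- project_to_planar(tibble::tibble(lat = lat, lon = lon))
  sel <- select_a_value(pl, candidates = c(5000, 40000, 120000, 3000000),
                        grid = g, raster_n = 150)
  expect_true(all(diff(sel$area_km2) >= -1e-9)) # outer area grows with a
  expect_gt(sel$n_holes[1] + sel$n_parts[1], 1) # tiny a leaves gaps
  expect_false(sel$acceptable[1])
  # huge a drapes the hulls across the island: land overlap rejected
  expect_gt(sel$land_fraction[4], 0.01)
  expect_false(sel$acceptable[4])
  chosen <- attr(sel, "chosen")
  expect_false(is.na(chosen))
  row <- sel[sel$a == chosen, ]
  expect_equal(row$n_holes, 0L)
  expect_equal(row$n_parts, 1L)
  expect_lte(row$land_fraction, 0.01)
  expect_true(all(!sel$acceptable[sel$a < chosen]))
  # no candidate satisfying both criteria: diagnostics returned, signalled
  expect_warning(
    none <- select_a_value(pl, candidates = c(5000, 3000000), grid = g,
                           raster_n = 100),
    "no candidate")
  expect_true(is.na(attr(none, "chosen")))
  expect_equal(nrow(none), 2)
})

test_that("a-value selection picks the smallest gap-free offshore a", {
  g <- test_seascape()
  # two clusters of fixes on the eastern shelf, far from land
  set.seed(6)
  east <- function(d_km, n, spread)
    tibble::tibble(
      lat = 20.8 + rnorm(n, 0, spread) / sharkmove:::km_per_deg_lat(),
      lon = -156.6 + (d_km + rnorm(n, 0, spread)) /
        sharkmove:::km_per_deg_lon(20.8))
  pts <- dplyr::bind_rows(east(19, 25, 1), east(25, 25, 1))
  pl <- project_to_planar(pts)
  sel <- select_a_value(pl, candidates = c(1000, 4000, 20000, 80000),
                        grid = g, raster_n = 60)
  chosen <- attr(sel, "chosen")
  expect_false(is.na(chosen))
  row <- sel[sel$a == chosen, ]
  expect_equal(row$n_holes, 0L)
  expect_equal(row$n_parts, 1L)
  expect_lte(row$land_fraction, 0.01)
  expect_true(all(!sel$acceptable[sel$a < chosen]))
})

test_that("offshore loops beyond the 4000 m isobath are excised in full", {
  g <- test_seascape()
  shelf_lat <- rep(20.95, 10); shelf_lon <- rep(-156.45, 10)
  # excursion: 20 fixes far east over abyssal water
  exc_lat <- rep(20.8, 20)
  exc_lon <- -156.6 + (15 + 12 + 30) / sharkmove:::km_per_deg_lon(20.8) +
    seq(0, 0.05, length.out = 20)
  tr <- tibble::tibble(lat = c(shelf_lat, exc_lat, shelf_lat),
                       lon = c(shelf_lon, exc_lon, shelf_lon))
  expect_true(all(depth_at(g, exc_lat, exc_lon) > 4000))
  out <- exclude_offshore_loops(tr, g)
  expect_equal(nrow(out), 20)
  expect_true(all(out$lon == -156.45))
  # all-shelf track: identity
  shelf <- tibble::tibble(lat = shelf_lat, lon = shelf_lon)
  expect_equal(nrow(exclude_offshore_loops(shelf, g)), 10)
})

test_that("isopleth GeoJSON export carries level properties", {
  set.seed(4)
  pts <- project_to_planar(tibble::tibble(
    lat = 20.95 + rnorm(25, 0, 0.02), lon = -156.45 + rnorm(25, 0, 0.02)))
  hs <- locoh_hulls(pts, "k", value = 5)
  iso <- build_isopleths(hs, levels = c(0.5, 0.95))
  path <- withr::local_tempfile(fileext = ".geojson")
  write_isopleths_geojson(iso, path)
  gj <- jsonlite::read_json(path)
  expect_equal(length(gj$features), 2)
  expect_equal(gj$features[[1]]$properties$level, 0.5)
  expect_equal(gj$features[[2]]$properties$area_km2, iso$area_km2[2])
})
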