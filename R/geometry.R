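# Planar geometry primitives for the local-convex-hull machinery. All
# polygons are numeric matrices with columns x, y, vertices in order, not
# closed (first vertex not repeated).

#' Convex hull of a point set
#' @param pts Two-column matrix of planar coordinates.
#' @return Matrix of hull vertices in counter-clockwise order.
#' @export
convex_hull <- function(pts) {
  pts <- unique(pts[stats::complete.cases(pts), , drop = FALSE])
  if (nrow(pts) == 1) return(pts)
  idx <- grDevices::chull(pts[, 1], pts[, 2])
  pts[rev(idx), , drop = FALSE] # chull is clockwise; reverse to CCW
}

#' Polygon area (shoelace)
#' @param poly Vertex matrix.
#' @return Non-negative area; 0 for degenerate (point/segment) polygons.
#' @export
polygon_area <- function(poly) {
  n <- nrow(poly)
  if (is.null(n) || n < 3) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# Membership in a convex polygon (inside or on boundary, tolerance eps).
# Degenerate polygons (point/segment) use distance-to-segment.
points_in_convex <- function(px, py, poly, eps = 1e-9) {
  n <- nrow(poly)
  if (n == 1) {
    return(sqrt((px - poly[1, 1])^2 + (py - poly[1, 2])^2) <= eps)
  }
  if (n == 2 || polygon_area(poly) == 0) {
    # distance to each edge segment of the degenerate chain
    inside <- rep(FALSE, length(px))
    for (k in seq_len(n)) {
      a <- poly[k, ]; b <- poly[if (k == n) 1 else k + 1, ]
      ab2 <- sum((b - a)^2)
      t <- if (ab2 == 0) rep(0, length(px)) else
        pmin(1, pmax(0, ((px - a[1]) * (b[1] - a[1]) +
                           (py - a[2]) * (b[2] - a[2])) / ab2))
      d2 <- (px - (a[1] + t * (b[1] - a[1])))^2 +
        (py - (a[2] + t * (b[2] - a[2])))^2
      inside <- inside | d2 <= eps^2
    }
    return(inside)
  }
  scale <- max(abs(poly)) + 1
  inside <- rep(TRUE, length(px))
  j <- c(2:n, 1)
  for (k in seq_len(n)) {
    cross <- (poly[j[k], 1] - poly[k, 1]) * (py - poly[k, 2]) -
      (poly[j[k], 2] - poly[k, 2]) * (px - poly[k, 1])
    inside <- inside & cross >= -eps * scale
  }
  inside
}

# --- union area / centroid of a set of convex polygons -----------------
#
# Boundary-fragment method (Green's theorem): every polygon edge is split at
# its intersections with the edges of the other polygons; a sub-segment lies
# on the union boundary iff its midpoint is not strictly interior to any
# other polygon. Traversing each surviving fragment with its own polygon's
# counter-clockwise orientation orients the whole union boundary with the
# interior on the left (outer rings CCW, hole rings CW), so the line
# integrals for area and first moments apply directly. Coincident edges --
# frequent when neighbour sets repeat -- are kept once (lowest polygon
# index) when the interiors agree, and dropped entirely when two polygons
# merely touch along a seam.

edge_table <- function(polys) {
  purrr::map_dfr(seq_along(polys), function(i) {
    p <- polys[[i]]
    n <- nrow(p)
    if (n < 2) return(NULL)
    j <- c(2:n, 1)
    tibble(poly = i, x1 = p[, 1], y1 = p[, 2], x2 = p[j, 1], y2 = p[j, 2])
  })
}

# force counter-clockwise orientation
ccw <- function(poly) {
  n <- nrow(poly)
  j <- c(2:n, 1)
  s <- sum(poly[, 1] * poly[j, 2] - poly[j, 1] * poly[, 2]) / 2
  if (s < 0) poly[rev(seq_len(n)), , drop = FALSE] else poly
}

poly_signature <- function(poly, digits = 9) {
  v <- round(poly, digits)
  k <- order(v[, 1], v[, 2])[1]
  n <- nrow(v)
  idx <- ((k - 1 + seq_len(n) - 1) %% n) + 1
  paste(v[idx, 1], v[idx, 2], sep = ",", collapse = ";")
}

# Split-point parameters along each edge from pairwise edge intersections
# (blocked generation with bbox prefilter to bound memory).
edge_split_params <- function(ed, block = 400L) {
  m <- nrow(ed)
  ts <- vector("list", m)
  if (m < 2) return(ts)
  exmin <- pmin(ed$x1, ed$x2); exmax <- pmax(ed$x1, ed$x2)
  eymin <- pmin(ed$y1, ed$y2); eymax <- pmax(ed$y1, ed$y2)
  acc_edge <- list(); acc_t <- list()
  for (s in seq(1L, m - 1L, by = block)) {
    ib <- s:min(s + block - 1L, m - 1L)
    a <- rep(ib, times = m - ib)
    b <- unlist(lapply(ib, function(i) seq(i + 1L, m)), use.names = FALSE)
    keep <- ed$poly[a] != ed$poly[b] &
      exmin[a] <= exmax[b] & exmin[b] <= exmax[a] &
      eymin[a] <= eymax[b] & eymin[b] <= eymax[a]
    a <- a[keep]; b <- b[keep]
    if (length(a) == 0) next
    d1x <- ed$x2[a] - ed$x1[a]; d1y <- ed$y2[a] - ed$y1[a]
    d2x <- ed$x2[b] - ed$x1[b]; d2y <- ed$y2[b] - ed$y1[b]
    den <- d1x * d2y - d1y * d2x
    ok <- abs(den) > 0
    qx <- ed$x1[b] - ed$x1[a]; qy <- ed$y1[b] - ed$y1[a]
    t <- ifelse(ok, (qx * d2y - qy * d2x) / den, NA_real_)
    u <- ifelse(ok, (qx * d1y - qy * d1x) / den, NA_real_)
    hit <- which(ok & t > 0 & t < 1 & u >= 0 & u <= 1)
    hit2 <- which(ok & u > 0 & u < 1 & t >= 0 & t <= 1)
    acc_edge[[length(acc_edge) + 1L]] <- c(a[hit], b[hit2])
    acc_t[[length(acc_t) + 1L]] <- c(t[hit], u[hit2])
  }
  all_edge <- unlist(acc_edge, use.names = FALSE)
  all_t <- unlist(acc_t, use.names = FALSE)
  if (length(all_edge) > 0) {
    grp <- split(all_t, all_edge)
    ts[as.integer(names(grp))] <- grp
  }
  ts
}

#' Area and centroid of a union of convex polygons
#'
#' Exact (to floating point) union area by the boundary-fragment method:
#' edges are split at their crossings with other polygons, fragments whose
#' midpoint lies strictly inside another polygon are dropped (coincident
#' fragments are kept once; seams where two polygons touch from opposite
#' sides are interior and dropped), and Green's-theorem line integrals over
#' the surviving fragments give the union area and its first moments. Holes
#' in the union are handled naturally: their boundary fragments are
#' traversed with the interior on the left.
#'
#' @param polys List of convex-polygon vertex matrices.
#' @return List with `area`, `centroid` (c(x, y); NA for empty unions).
#' @export
polygon_union_area <- function(polys) {
  polys <- purrr::keep(polys, ~ !is.null(.x) && nrow(.x) >= 3 &&
                         polygon_area(.x) > 0)
  if (length(polys) == 0) return(list(area = 0, centroid = c(NA, NA)))
  polys <- lapply(polys, ccw)
  polys <- polys[!duplicated(vapply(polys, poly_signature, character(1)))]
  ed <- edge_table(polys)
  tol <- 1e-9 * (max(abs(c(ed$x1, ed$y1))) + 1)
  ts <- edge_split_params(ed)
  # fragment arrays; unsplit edges pass through as a single fragment
  tt_all <- lapply(seq_len(nrow(ed)), function(e) {
    if (length(ts[[e]]) == 0) c(0, 1) else sort(unique(c(0, ts[[e]], 1)))
  })
  n_frag <- lengths(tt_all) - 1L
  e_id <- rep.int(seq_len(nrow(ed)), n_frag)
  t0 <- unlist(lapply(tt_all, function(v) v[-length(v)]), use.names = FALSE)
  t1 <- unlist(lapply(tt_all, function(v) v[-1]), use.names = FALSE)
  f_poly <- ed$poly[e_id]
  f_ax <- ed$x1[e_id] + t0 * (ed$x2[e_id] - ed$x1[e_id])
  f_ay <- ed$y1[e_id] + t0 * (ed$y2[e_id] - ed$y1[e_id])
  f_bx <- ed$x1[e_id] + t1 * (ed$x2[e_id] - ed$x1[e_id])
  f_by <- ed$y1[e_id] + t1 * (ed$y2[e_id] - ed$y1[e_id])
  long <- (f_ax - f_bx)^2 + (f_ay - f_by)^2 > (2 * tol)^2
  frags <- list(poly = f_poly[long], ax = f_ax[long], ay = f_ay[long],
                bx = f_bx[long], by = f_by[long])
  mx <- (frags$ax + frags$bx) / 2
  my <- (frags$ay + frags$by) / 2
  fdx <- frags$bx - frags$ax; fdy <- frags$by - frags$ay
  keep <- rep(TRUE, length(mx))
  ord_mx <- order(mx)
  mx_sorted <- mx[ord_mx]
  for (j in seq_along(polys)) {
    p <- polys[[j]]
    # sorted-x window, then exact bbox filter, on the shortlist only
    lo <- findInterval(min(p[, 1]) - tol, mx_sorted) + 1L
    hi <- findInterval(max(p[, 1]) + tol, mx_sorted)
    if (hi < lo) next
    shortlist <- ord_mx[lo:hi]
    cand <- shortlist[keep[shortlist] & frags$poly[shortlist] != j &
                        my[shortlist] >= min(p[, 2]) - tol &
                        my[shortlist] <= max(p[, 2]) + tol]
    if (length(cand) == 0) next
    n <- nrow(p)
    nx <- c(2:n, 1)
    mincr <- rep(Inf, length(cand))
    coinc_dot <- rep(NA_real_, length(cand)) # edge-direction dot on the touched edge
    for (k in seq_len(n)) {
      ex <- p[nx[k], 1] - p[k, 1]; ey <- p[nx[k], 2] - p[k, 2]
      el <- sqrt(ex^2 + ey^2)
      if (el == 0) next
      cr <- (ex * (my[cand] - p[k, 2]) - ey * (mx[cand] - p[k, 1])) / el
      on_edge <- abs(cr) <= tol &
        (mx[cand] - p[k, 1]) * ex + (my[cand] - p[k, 2]) * ey >= -tol * el &
        (mx[cand] - p[nx[k], 1]) * ex + (my[cand] - p[nx[k], 2]) * ey <=
        tol * el
      coinc_dot[on_edge] <- (fdx[cand][on_edge] * ex +
                               fdy[cand][on_edge] * ey)
      mincr <- pmin(mincr, cr)
    }
    strictly_in <- mincr > tol
    on_bnd <- !strictly_in & mincr >= -tol & !is.na(coinc_dot)
    drop <- strictly_in |
      (on_bnd & coinc_dot < 0) |                       # opposite seam
      (on_bnd & coinc_dot > 0 & j < frags$poly[cand])  # duplicate: keep lowest
    keep[cand[drop]] <- FALSE
  }
  fa <- frags$ax[keep]; fb <- frags$bx[keep]
  ga <- frags$ay[keep]; gb <- frags$by[keep]
  area <- sum(fa * gb - fb * ga) / 2
  if (abs(area) < tol^2)
    return(list(area = 0, centroid = c(NA, NA)))
  momx <- sum((gb - ga) * (fa^2 + fa * fb + fb^2)) / 6
  momy <- -sum((fb - fa) * (ga^2 + ga * gb + gb^2)) / 6
  list(area = area, centroid = c(momx / area, momy / area))
}

# Rasterised view of a polygon union over its bounding box; used for the
# hole-count and land-overlap diagnostics where exact topology is overkill.
union_raster <- function(polys, n = 120, pad = 0.02) {
  allv <- do.call(rbind, polys)
  xr <- range(allv[, 1]); yr <- range(allv[, 2])
  dx <- diff(xr); dy <- diff(yr)
  xr <- xr + c(-1, 1) * pad * max(dx, dy, 1e-9)
  yr <- yr + c(-1, 1) * pad * max(dx, dy, 1e-9)
  gx <- seq(xr[1], xr[2], length.out = n)
  gy <- seq(yr[1], yr[2], length.out = n)
  px <- rep(gx, times = n); py <- rep(gy, each = n)
  covered <- rep(FALSE, n * n)
  for (p in polys) {
    if (nrow(p) < 3) next
    covered <- covered | points_in_convex(px, py, p)
    # hulls smaller than a cell still occupy their centroid cell
    ci <- findInterval(mean(p[, 1]), gx, all.inside = TRUE)
    cj <- findInterval(mean(p[, 2]), gy, all.inside = TRUE)
    covered[(cj - 1L) * n + ci] <- TRUE
  }
  list(x = gx, y = gy, covered = matrix(covered, nrow = n),
       px = px, py = py)
}

# Connected components of covered cells (8-neighbour, the topological dual
# of 4-neighbour hole connectivity).
count_parts <- function(covered) {
  n <- nrow(covered); m <- ncol(covered)
  seen <- !covered
  parts <- 0L
  stack <- integer(n * m)
  for (start in which(!seen)) {
    if (seen[start]) next
    parts <- parts + 1L
    top <- 1L
    stack[1L] <- start
    seen[start] <- TRUE
    while (top > 0L) {
      cell <- stack[top]; top <- top - 1L
      i <- ((cell - 1L) %% n) + 1L
      j <- ((cell - 1L) %/% n) + 1L
      for (dj in -1L:1L) {
        jj <- j + dj
        if (jj < 1L || jj > m) next
        for (di in -1L:1L) {
          ii <- i + di
          if (ii < 1L || ii > n) next
          nb <- (jj - 1L) * n + ii
          if (!seen[nb]) {
            seen[nb] <- TRUE; top <- top + 1L; stack[top] <- nb
          }
        }
      }
    }
  }
  parts
}

# Count interior holes: connected components (4-neighbour) of uncovered
# cells that do not touch the raster border.
count_holes <- function(covered) {
  n <- nrow(covered); m <- ncol(covered)
  seen <- covered # treat covered cells as visited
  holes <- 0L
  stack <- integer(n * m)
  for (start in which(!seen)) {
    if (seen[start]) next
    top <- 1L
    stack[1L] <- start
    seen[start] <- TRUE
    touches <- FALSE
    while (top > 0L) {
      cell <- stack[top]; top <- top - 1L
      i <- ((cell - 1L) %% n) + 1L
      j <- ((cell - 1L) %/% n) + 1L
      if (i == 1L || i == n || j == 1L || j == m) touches <- TRUE
      if (i > 1L && !seen[cell - 1L]) {
        seen[cell - 1L] <- TRUE; top <- top + 1L; stack[top] <- cell - 1L
      }
      if (i < n && !seen[cell + 1L]) {
        seen[cell + 1L] <- TRUE; top <- top + 1L; stack[top] <- cell + 1L
      }
      if (j > 1L && !seen[cell - n]) {
        seen[cell - n] <- TRUE; top <- top + 1L; stack[top] <- cell - n
      }
      if (j < m && !seen[cell + n]) {
        seen[cell + n] <- TRUE; top <- top + 1L; stack[top] <- cell + n
      }
    }
    if (!touches) holes <- holes + 1L
  }
  holes
}
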