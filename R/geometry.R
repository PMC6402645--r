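#' Planar polygon area (shoelace formula)
#'
#' Area of a simple polygon given its ring vertices in projected metric
#' coordinates. The ring is implicitly closed; orientation (clockwise or
#' counter-clockwise) does not matter.
#'
#' @param geom two-column matrix or data.frame of (x, y) vertices in meters.
#' @return area in m^2 (strictly positive).
#' @export
polygon_flat_area <- function(geom) {
  geom <- validate_polygon(geom)
  x <- geom[, 1]; y <- geom[, 2]
  n <- nrow(geom)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# Coerce + validate a polygon ring: >= 3 distinct non-collinear vertices,
# finite coordinates, simple (no self-intersection). Drops a duplicated
# closing vertex if present. Returns the vertex matrix.
validate_polygon <- function(geom) {
  geom <- as.matrix(geom)
  if (ncol(geom) < 2) stop("polygon must have two coordinate columns")
  geom <- geom[, 1:2, drop = FALSE]
  storage.mode(geom) <- "double"
  if (!all(is.finite(geom))) stop("polygon coordinates must be finite")
  n <- nrow(geom)
  if (n >= 2 && all(geom[1, ] == geom[n, ])) geom <- geom[-n, , drop = FALSE]
  if (nrow(unique(geom)) < 3)
    stop("invalid geometry: fewer than 3 distinct vertices")
  x <- geom[, 1]; y <- geom[, 2]
  n <- nrow(geom)
  j <- c(2:n, 1)
  ar2 <- abs(sum(x * y[j] - x[j] * y))
  scale2 <- max(diff(range(x)), diff(range(y)))^2
  if (ar2 <= 1e-12 * max(scale2, 1))
    stop("invalid geometry: vertices are collinear")
  if (ring_self_intersects(geom))
    stop("invalid geometry: self-intersecting ring")
  geom
}

# O(n^2) simplicity check on the closed ring, skipping adjacent edges.
ring_self_intersects <- function(geom) {
  n <- nrow(geom)
  idx <- cbind(seq_len(n), c(2:n, 1))
  for (i in seq_len(n - 1)) {
    for (k in (i + 1):n) {
      # skip edges sharing a vertex (consecutive, incl. wrap-around)
      if (k == i + 1 || (i == 1 && k == n)) next
      if (segments_intersect(geom[idx[i, 1], ], geom[idx[i, 2], ],
                             geom[idx[k, 1], ], geom[idx[k, 2], ]))
        return(TRUE)
    }
  }
  FALSE
}

# Proper or touching intersection of segments p1-p2 and p3-p4.
segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  on_seg <- function(a, b, c) {
    min(a[1], b[1]) <= c[1] && c[1] <= max(a[1], b[1]) &&
      min(a[2], b[2]) <= c[2] && c[2] <= max(a[2], b[2])
  }
  if (d1 == 0 && on_seg(p3, p4, p1)) return(TRUE)
  if (d2 == 0 && on_seg(p3, p4, p2)) return(TRUE)
  if (d3 == 0 && on_seg(p1, p2, p3)) return(TRUE)
  if (d4 == 0 && on_seg(p1, p2, p4)) return(TRUE)
  FALSE
}

#' Slope-corrected surface area
#'
#' Inflates a map-plane polygon area to true surface area,
#' \code{corrected = flat / cos(slope)}, using the mean slope of the patch.
#' At slope 0 the area is unchanged; the correction grows without bound as
#' the slope approaches vertical.
#'
#' @param flat_area planar area in m^2 (non-negative).
#' @param mean_slope_deg mean slope in degrees, in \code{[0, 90)}.
#' @return corrected area in m^2.
#' @export
slope_corrected_area <- function(flat_area, mean_slope_deg) {
  if (any(!is.finite(flat_area)) || any(flat_area < 0))
    stop("flat_area must be finite and non-negative")
  if (any(!is.finite(mean_slope_deg)) || any(mean_slope_deg < 0) ||
      any(mean_slope_deg >= 90))
    stop("mean_slope_deg must lie in [0, 90)")
  flat_area / cos(mean_slope_deg * pi / 180)
}

#' Distance to the nearest target point
#'
#' Planar Euclidean distance (projected coordinates in meters) from a point
#' to the closest of a set of target points, reported in kilometers. Used for
#' colony-to-foraging-hotspot distances.
#'
#' @param point numeric length-2 (x, y) in meters.
#' @param targets two-column matrix of target coordinates in meters.
#' @return distance in km.
#' @export
distance_to_nearest <- function(point, targets) {
  targets <- as.matrix(targets)
  if (nrow(targets) == 0) stop("empty target set")
  d2 <- (targets[, 1] - point[1])^2 + (targets[, 2] - point[2])^2
  sqrt(min(d2)) / 1000
}

# Vectorized even-odd (ray casting) point-in-polygon test.
# px, py: query coordinates; poly: vertex matrix (open ring).
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses & !is.na(crosses))
    j <- i
  }
  inside
}

# Minimum distance (m) from point p to a polyline given as a vertex matrix.
dist_to_polyline <- function(p, line) {
  line <- as.matrix(line)
  if (nrow(line) == 0) stop("empty polyline")
  if (nrow(line) == 1)
    return(sqrt((line[1, 1] - p[1])^2 + (line[1, 2] - p[2])^2))
  ax <- line[-nrow(line), 1]; ay <- line[-nrow(line), 2]
  bx <- line[-1, 1]; by <- line[-1, 2]
  dx <- bx - ax; dy <- by - ay
  len2 <- dx^2 + dy^2
  t <- ((p[1] - ax) * dx + (p[2] - ay) * dy) / pmax(len2, .Machine$double.eps)
  t <- pmin(pmax(t, 0), 1)
  qx <- ax + t * dx; qy <- ay + t * dy
  sqrt(min((qx - p[1])^2 + (qy - p[2])^2))
}

# TRUE if two convex-or-not simple polygons overlap (vertex containment or
# edge crossing). Used for the absence-polygon exclusion mask.
polygons_overlap <- function(a, b) {
  if (any(points_in_polygon(a[, 1], a[, 2], b))) return(TRUE)
  if (any(points_in_polygon(b[, 1], b[, 2], a))) return(TRUE)
  na <- nrow(a); nb <- nrow(b)
  ja <- c(2:na, 1); jb <- c(2:nb, 1)
  for (i in seq_len(na)) {
    for (k in seq_len(nb)) {
      if (segments_intersect(a[i, ], a[ja[i], ], b[k, ], b[jb[k], ]))
        return(TRUE)
    }
  }
  FALSE
}

#' Pseudo-absence sampling design
#'
#' Parameters of the constrained random-polygon generator used to build the
#' zero class for occurrence modelling: fixed-size polygons placed near the
#' coast and within foraging range of the at-sea hotspots, avoiding an
#' exclusion mask (glaciers, islets, known colonies).
#'
#' @param n_polygons number of absence polygons to generate.
#' @param polygon_area_m2 area of every polygon in m^2 (study value 2900,
#'   the mean surveyed colony-patch size).
#' @param coast_buffer_km maximum centroid distance to the coastline (study
#'   value 7 km).
#' @param hotspot_buffer_km maximum centroid distance to the nearest foraging
#'   hotspot (study value 55 km).
#' @param exclusion list of polygon vertex matrices that generated polygons
#'   must not intersect (may be empty).
#' @param seed integer seed; the output is a deterministic function of it.
#' @return an object of class \code{absence_design}.
#' @export
absence_design <- function(n_polygons, polygon_area_m2 = 2900,
                           coast_buffer_km = 7, hotspot_buffer_km = 55,
                           exclusion = list(), seed = 1L) {
  stopifnot(n_polygons >= 1, polygon_area_m2 > 0,
            coast_buffer_km > 0, hotspot_buffer_km > 0)
  structure(list(n_polygons = as.integer(n_polygons),
                 polygon_area_m2 = polygon_area_m2,
                 coast_buffer_km = coast_buffer_km,
                 hotspot_buffer_km = hotspot_buffer_km,
                 exclusion = exclusion,
                 seed = as.integer(seed)),
            class = "absence_design")
}

#' Generate constrained pseudo-absence polygons
#'
#' Rejection-samples square polygons of fixed area with random orientation.
#' Every polygon's centroid lies within \code{coast_buffer_km} of the
#' coastline and within \code{hotspot_buffer_km} of the nearest foraging
#' hotspot, and no polygon intersects the exclusion mask. Sampling stops
#' with an error after \code{1000 * n_polygons} attempts if the feasible
#' region is too small.
#'
#' @param design an \code{\link{absence_design}}.
#' @param coastline polyline vertex matrix (meters).
#' @param hotspots two-column matrix of hotspot coordinates (meters).
#' @return list of polygon vertex matrices (4 x 2 each).
#' @export
generate_absence_polygons <- function(design, coastline, hotspots) {
  stopifnot(inherits(design, "absence_design"))
  coastline <- as.matrix(coastline)
  hotspots <- as.matrix(hotspots)
  if (nrow(coastline) == 0) stop("empty coastline")
  if (nrow(hotspots) == 0) stop("empty hotspot set")
  set.seed(design$seed)
  buf <- design$coast_buffer_km * 1000
  xr <- range(coastline[, 1]) + c(-buf, buf)
  yr <- range(coastline[, 2]) + c(-buf, buf)
  half <- sqrt(design$polygon_area_m2) / 2
  out <- vector("list", design$n_polygons)
  got <- 0L
  attempts <- 0L
  cap <- 1000L * design$n_polygons
  while (got < design$n_polygons) {
    if (attempts >= cap)
      stop(sprintf(
        "absence sampling exhausted after %d attempts (%d/%d placed): feasible region too small",
        attempts, got, design$n_polygons))
    attempts <- attempts + 1L
    cx <- stats::runif(1, xr[1], xr[2])
    cy <- stats::runif(1, yr[1], yr[2])
    theta <- stats::runif(1, 0, pi / 2)
    if (dist_to_polyline(c(cx, cy), coastline) > buf) next
    if (distance_to_nearest(c(cx, cy), hotspots) > design$hotspot_buffer_km) next
    rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
    corners <- matrix(c(-half, -half, half, -half, half, half, -half, half),
                      ncol = 2, byrow = TRUE) %*% t(rot)
    poly <- sweep(corners, 2, c(cx, cy), "+")
    bad <- FALSE
    for (ex in design$exclusion) {
      if (polygons_overlap(poly, as.matrix(ex))) { bad <- TRUE; break }
    }
    if (bad) next
    got <- got + 1L
    out[[got]] <- poly
  }
  out
}
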