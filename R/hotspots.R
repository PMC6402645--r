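#' Strip-transect bird density
#'
#' Birds per km^2 from a strip transect: the count divided by the surveyed
#' area, \code{length_km * strip_width_m / 1000}. The study counted all
#' little auks (sitting and flying) within 300 m of the vessel.
#'
#' @param bird_count birds counted (>= 0); vectorized.
#' @param length_km transect length in km (> 0).
#' @param strip_width_m strip width in m (study value 300).
#' @return density in birds/km^2.
#' @export
transect_density <- function(bird_count, length_km, strip_width_m = 300) {
  if (any(length_km <= 0)) stop("transect length must be positive")
  if (any(strip_width_m <= 0)) stop("strip width must be positive")
  if (any(bird_count < 0)) stop("bird count must be non-negative")
  bird_count / (length_km * strip_width_m / 1000)
}

# Deterministic sub-meter jitter used only inside the triangulation to break
# cocircular/collinear degeneracies; queries at exact data sites bypass it.
.det_jitter <- function(i, salt, scale) {
  ((sin(i * 12.9898 + salt) * 43758.5453) %% 1 - 0.5) * 1e-8 * scale
}

# Circumcenter and squared circumradius of triangle (i, j, k).
.circum <- function(px, py, i, j, k) {
  ax <- px[i]; ay <- py[i]; bx <- px[j]; by <- py[j]; cx <- px[k]; cy <- py[k]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(d) < .Machine$double.eps) return(c(Inf, Inf, Inf))
  a2 <- ax^2 + ay^2; b2 <- bx^2 + by^2; c2 <- cx^2 + cy^2
  ux <- (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d
  uy <- (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d
  c(ux, uy, (ax - ux)^2 + (ay - uy)^2)
}

# Bowyer-Watson Delaunay triangulation. Returns an integer matrix of
# triangle vertex indices into the input points.
delaunay_triangulate <- function(x, y) {
  n <- length(x)
  if (n < 3) stop("interpolation undefined: need at least 3 points")
  scale <- max(diff(range(x)), diff(range(y)))
  if (scale <= 0) stop("degenerate point set")
  px <- x + .det_jitter(seq_len(n), 0, scale)
  py <- y + .det_jitter(seq_len(n), 1, scale)
  cx <- mean(range(px)); cy <- mean(range(py))
  m <- 20 * scale
  px <- c(px, cx - 2 * m, cx + 2 * m, cx)
  py <- c(py, cy - m, cy - m, cy + 2 * m)
  tris <- matrix(c(n + 1L, n + 2L, n + 3L), nrow = 1)
  cc <- matrix(.circum(px, py, n + 1L, n + 2L, n + 3L), nrow = 1)
  for (p in seq_len(n)) {
    bad <- which((px[p] - cc[, 1])^2 + (py[p] - cc[, 2])^2 <= cc[, 3])
    if (length(bad) == 0) next  # degenerate: should not happen inside super-tri
    bt <- tris[bad, , drop = FALSE]
    edges <- rbind(bt[, c(1, 2)], bt[, c(2, 3)], bt[, c(3, 1)])
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    keep <- key %in% names(which(table(key) == 1))
    boundary <- edges[keep, , drop = FALSE]
    tris <- tris[-bad, , drop = FALSE]
    cc <- cc[-bad, , drop = FALSE]
    if (nrow(boundary) > 0) {
      newt <- cbind(boundary, p)
      newcc <- t(apply(newt, 1, function(tr) .circum(px, py, tr[1], tr[2], tr[3])))
      tris <- rbind(tris, newt)
      cc <- rbind(cc, newcc)
    }
  }
  keep <- rowSums(tris > n) == 0
  tris <- tris[keep, , drop = FALSE]
  if (nrow(tris) == 0)
    stop("interpolation undefined: points are collinear")
  dimnames(tris) <- NULL
  tris
}

#' Interpolate an at-sea density surface
#'
#' Builds a continuous bird-density surface from scattered transect
#' densities by piecewise-linear (barycentric) interpolation on a Delaunay
#' triangulation. The surface honors the data exactly at the data sites,
#' never exceeds the input range, and is undefined (NA) outside the convex
#' hull of the transects.
#'
#' @param points two-column matrix of transect centroids (meters).
#' @param densities bird densities (birds/km^2) at the points.
#' @param cell_size grid cell size in meters for the rasterized surface.
#' @param extent optional \code{c(xmin, xmax, ymin, ymax)}; defaults to the
#'   bounding box of the points.
#' @return object of class \code{density_surface}: list with \code{grid}
#'   (a \code{\link{dem_grid}} of birds/km^2), the input points/values, the
#'   triangulation and a \code{method} provenance tag.
#' @export
interpolate_surface <- function(points, densities, cell_size,
                                extent = NULL) {
  points <- as.matrix(points)
  if (nrow(points) != length(densities))
    stop("points and densities lengths differ")
  if (any(!is.finite(points)) || any(!is.finite(densities)))
    stop("non-finite inputs")
  tris <- delaunay_triangulate(points[, 1], points[, 2])
  if (is.null(extent))
    extent <- c(range(points[, 1]), range(points[, 2]))
  xs <- seq(extent[1] + cell_size / 2, extent[2], by = cell_size)
  ys <- seq(extent[3] + cell_size / 2, extent[4], by = cell_size)
  nr <- length(ys); ncl <- length(xs)
  vals <- matrix(NA_real_, nr, ncl)
  # row 1 = north: ys descending
  ys_desc <- rev(ys)
  for (t in seq_len(nrow(tris))) {
    tp <- points[tris[t, ], , drop = FALSE]
    tv <- densities[tris[t, ]]
    cols <- which(xs >= min(tp[, 1]) - cell_size & xs <= max(tp[, 1]) + cell_size)
    rows <- which(ys_desc >= min(tp[, 2]) - cell_size & ys_desc <= max(tp[, 2]) + cell_size)
    if (!length(cols) || !length(rows)) next
    qx <- rep(xs[cols], each = length(rows))
    qy <- rep(ys_desc[rows], times = length(cols))
    l <- .barycentric(tp, qx, qy)
    inside <- l[, 1] >= -1e-9 & l[, 2] >= -1e-9 & l[, 3] >= -1e-9
    if (!any(inside)) next
    v <- l[, 1] * tv[1] + l[, 2] * tv[2] + l[, 3] * tv[3]
    sub <- vals[rows, cols, drop = FALSE]
    sel <- matrix(inside, nrow = length(rows))
    sub[sel] <- v[inside]
    vals[rows, cols] <- sub
  }
  grid <- dem_grid(vals, cell_size = cell_size,
                   origin = c(extent[1], extent[3]))
  structure(list(grid = grid, points = points, values = densities,
                 tris = tris, method = "delaunay-barycentric-linear"),
            class = "density_surface")
}

# Barycentric coordinates of queries (qx, qy) wrt triangle tp (3 x 2).
.barycentric <- function(tp, qx, qy) {
  x1 <- tp[1, 1]; y1 <- tp[1, 2]; x2 <- tp[2, 1]; y2 <- tp[2, 2]
  x3 <- tp[3, 1]; y3 <- tp[3, 2]
  det <- (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3)
  l1 <- ((y2 - y3) * (qx - x3) + (x3 - x2) * (qy - y3)) / det
  l2 <- ((y3 - y1) * (qx - x3) + (x1 - x3) * (qy - y3)) / det
  cbind(l1, l2, 1 - l1 - l2)
}

#' Evaluate a density surface at arbitrary points
#'
#' Exact at the data sites (the defining property of an interpolating, as
#' opposed to smoothing, surface); barycentric-linear inside the convex
#' hull; NA outside.
#'
#' @param object a \code{\link{interpolate_surface}} result.
#' @param newxy two-column matrix of query coordinates (meters).
#' @param ... unused.
#' @return numeric vector of densities.
#' @export
predict.density_surface <- function(object, newxy, ...) {
  newxy <- as.matrix(newxy)
  scale <- max(diff(range(object$points[, 1])),
               diff(range(object$points[, 2])))
  out <- rep(NA_real_, nrow(newxy))
  for (q in seq_len(nrow(newxy))) {
    d2 <- (object$points[, 1] - newxy[q, 1])^2 +
      (object$points[, 2] - newxy[q, 2])^2
    hit <- which.min(d2)
    if (d2[hit] <= (1e-9 * scale)^2) { out[q] <- object$values[hit]; next }
    for (t in seq_len(nrow(object$tris))) {
      tp <- object$points[object$tris[t, ], , drop = FALSE]
      l <- .barycentric(tp, newxy[q, 1], newxy[q, 2])
      if (all(l >= -1e-9)) {
        out[q] <- sum(l * object$values[object$tris[t, ]])
        break
      }
    }
  }
  out
}

#' Detect foraging hotspots on a density surface
#'
#' Hotspots are the highest local concentrations of birds at sea: strict
#' local maxima of the rasterized surface over a 3x3 neighborhood, ranked
#' by density and greedily thinned so that no two retained hotspots lie
#' closer than \code{min_separation_km}. A flat surface has no strict local
#' maximum and yields an empty result.
#'
#' @param surface a \code{\link{interpolate_surface}} result or a
#'   \code{\link{dem_grid}}.
#' @param min_separation_km minimum distance between retained hotspots.
#' @param top_k maximum number of hotspots returned.
#' @return data.frame with \code{x, y, peak_density}, ordered by density.
#' @export
detect_hotspots <- function(surface, min_separation_km = 10, top_k = 10) {
  grid <- if (inherits(surface, "density_surface")) surface$grid else surface
  stopifnot(inherits(grid, "dem_grid"))
  v <- grid$values
  nr <- nrow(v); ncl <- ncol(v)
  if (nr < 1 || ncl < 1) stop("empty surface")
  vp <- matrix(-Inf, nr + 2, ncl + 2)
  vp[2:(nr + 1), 2:(ncl + 1)] <- ifelse(is.na(v), -Inf, v)
  ismax <- matrix(TRUE, nr, ncl)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- vp[2:(nr + 1) + dr, 2:(ncl + 1) + dc]
    ismax <- ismax & (vp[2:(nr + 1), 2:(ncl + 1)] > nb)
  }
  ismax[is.na(v)] <- FALSE
  idx <- which(ismax, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(data.frame(x = numeric(0), y = numeric(0),
                      peak_density = numeric(0)))
  cc <- grid_cell_centers(grid)
  cand <- data.frame(x = cc$x[idx[, 2]], y = cc$y[idx[, 1]],
                     peak_density = v[idx])
  cand <- cand[order(-cand$peak_density), , drop = FALSE]
  kept <- cand[0, ]
  for (r in seq_len(nrow(cand))) {
    if (nrow(kept) == 0 ||
        distance_to_nearest(c(cand$x[r], cand$y[r]),
                            as.matrix(kept[, c("x", "y")])) >= min_separation_km) {
      kept <- rbind(kept, cand[r, ])
      if (nrow(kept) >= top_k) break
    }
  }
  rownames(kept) <- NULL
  kept
}
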