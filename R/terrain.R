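#' Gridded raster container
#'
#' A minimal single-band raster: a matrix of values whose first row is the
#' northern edge (as in Esri ASCII grids), a square cell size in meters, the
#' (x, y) of the lower-left corner, and a nodata sentinel. All aukcensus
#' raster operations (slope/aspect, zonal statistics, density surfaces) use
#' this container.
#'
#' @param values numeric matrix; row 1 is the northernmost row.
#' @param cell_size cell edge length in meters (study DEMs use 20 m).
#' @param origin numeric length-2, (x, y) of the lower-left grid corner.
#' @param nodata sentinel marking missing cells (stored as NA internally).
#' @return an object of class \code{dem_grid}.
#' @export
dem_grid <- function(values, cell_size = 20, origin = c(0, 0),
                     nodata = -9999) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (cell_size <= 0) stop("cell_size must be positive")
  values[values == nodata] <- NA_real_
  structure(list(values = values, cell_size = cell_size,
                 origin = as.numeric(origin), nodata = nodata),
            class = "dem_grid")
}

#' @export
print.dem_grid <- function(x, ...) {
  cat(sprintf("dem_grid: %d x %d cells of %g m, origin (%g, %g), %d nodata\n",
              nrow(x$values), ncol(x$values), x$cell_size,
              x$origin[1], x$origin[2], sum(is.na(x$values))))
  invisible(x)
}

# Cell-center coordinates of a dem_grid. Row 1 = north (largest y).
grid_cell_centers <- function(grid) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  xs <- grid$origin[1] + (seq_len(nc) - 0.5) * grid$cell_size
  ys <- grid$origin[2] + (nr - seq_len(nr) + 0.5) * grid$cell_size
  list(x = xs, y = ys)
}

#' Read an Esri ASCII grid
#'
#' @param path path to a \code{.asc} file.
#' @return a \code{\link{dem_grid}}.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  origin_x <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else
    hdr$xllcenter - hdr$cellsize / 2
  origin_y <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else
    hdr$yllcenter - hdr$cellsize / 2
  dem_grid(m, cell_size = hdr$cellsize, origin = c(origin_x, origin_y),
           nodata = nodata)
}

#' Write an Esri ASCII grid
#'
#' @param grid a \code{\link{dem_grid}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_ascii_grid <- function(grid, path) {
  stopifnot(inherits(grid, "dem_grid"))
  v <- grid$values
  v[is.na(v)] <- grid$nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", grid$origin[1]),
    sprintf("yllcorner %.10g", grid$origin[2]),
    sprintf("cellsize %.10g", grid$cell_size),
    sprintf("NODATA_value %.10g", grid$nodata)), con)
  utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Slope and aspect from a DEM (Horn's method)
#'
#' Per-cell slope (degrees, \code{[0, 90)}) and aspect (degrees clockwise
#' from north, \code{[0, 360)}) by Horn's 8-neighbor finite differences, the
#' de-facto GIS standard. Border cells use edge replication. Flat cells
#' (zero gradient) receive the flat-aspect sentinel \code{-1}. Cells whose
#' 3x3 neighborhood is all nodata propagate NA.
#'
#' @param dem a \code{\link{dem_grid}} of elevations, at least 3x3.
#' @return list with \code{slope} and \code{aspect} \code{dem_grid}s.
#' @export
slope_aspect_from_dem <- function(dem) {
  stopifnot(inherits(dem, "dem_grid"))
  z <- dem$values
  if (nrow(z) < 3 || ncol(z) < 3) stop("DEM must be at least 3 x 3 cells")
  nr <- nrow(z); nc <- ncol(z)
  # edge-replicated padding
  zp <- z[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]
  sh <- function(dr, dc) zp[seq_len(nr) + 1 + dr, seq_len(nc) + 1 + dc]
  a <- sh(-1, -1); b <- sh(-1, 0); cc <- sh(-1, 1)
  d <- sh(0, -1);                  f <- sh(0, 1)
  g <- sh(1, -1);  h <- sh(1, 0);  i <- sh(1, 1)
  # fill nodata neighbors with the center value so they drop out of the
  # finite differences; all-nodata neighborhoods stay NA via the center
  fill <- function(m) ifelse(is.na(m), z, m)
  a <- fill(a); b <- fill(b); cc <- fill(cc); d <- fill(d)
  f <- fill(f); g <- fill(g); h <- fill(h); i <- fill(i)
  cs <- dem$cell_size
  dzdx <- ((cc + 2 * f + i) - (a + 2 * d + g)) / (8 * cs)
  dzdy <- ((g + 2 * h + i) - (a + 2 * b + cc)) / (8 * cs)
  slope <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  asp <- atan2(dzdy, -dzdx) * 180 / pi
  aspect <- ifelse(asp < 0, 90 - asp,
                   ifelse(asp > 90, 360 - asp + 90, 90 - asp))
  aspect[aspect >= 360] <- aspect[aspect >= 360] - 360
  flat <- !is.na(dzdx) & dzdx == 0 & dzdy == 0
  aspect[flat] <- -1
  slope[is.na(z)] <- NA_real_
  aspect[is.na(z)] <- NA_real_
  list(slope = dem_grid(slope, dem$cell_size, dem$origin, dem$nodata),
       aspect = dem_grid(aspect, dem$cell_size, dem$origin, dem$nodata))
}

#' Zonal mean of a raster over a polygon
#'
#' Arithmetic mean of the grid cells whose centers fall inside the polygon;
#' nodata cells are excluded. If no cell center falls inside (sliver
#' polygons smaller than a cell), the cell nearest the polygon centroid is
#' used and a warning is issued.
#'
#' @param grid a \code{\link{dem_grid}}.
#' @param geom polygon vertex matrix (meters).
#' @param exclude values to drop before averaging (e.g. the flat-aspect
#'   sentinel \code{-1} when averaging aspect); default none.
#' @return mean cell value.
#' @export
zonal_mean <- function(grid, geom, exclude = NULL) {
  stopifnot(inherits(grid, "dem_grid"))
  geom <- validate_polygon(geom)
  cc <- grid_cell_centers(grid)
  xr <- range(geom[, 1]); yr <- range(geom[, 2])
  ci <- which(cc$x >= xr[1] - grid$cell_size & cc$x <= xr[2] + grid$cell_size)
  ri <- which(cc$y >= yr[1] - grid$cell_size & cc$y <= yr[2] + grid$cell_size)
  vals <- numeric(0)
  if (length(ci) && length(ri)) {
    gx <- rep(cc$x[ci], each = length(ri))
    gy <- rep(cc$y[ri], times = length(ci))
    inside <- points_in_polygon(gx, gy, geom)
    vals <- grid$values[ri, ci, drop = FALSE][matrix(inside,
                                                     nrow = length(ri))]
  }
  if (!is.null(exclude)) vals <- vals[!(vals %in% exclude)]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) {
    warning("no valid cell center inside polygon; using cell nearest the centroid")
    ctr <- colMeans(geom)
    col <- which.min(abs(cc$x - ctr[1]))
    row <- which.min(abs(cc$y - ctr[2]))
    v <- grid$values[row, col]
    if (is.na(v)) stop("empty zone: nearest cell is nodata")
    return(v)
  }
  mean(vals)
}

#' Terrain summary for a colony patch
#'
#' Computes the patch-level quantities the census and the occurrence models
#' consume: planar (shoelace) area, zonal mean slope, aspect, elevation and
#' solar radiation, and the slope-corrected surface area
#' \code{flat / cos(mean slope)}.
#'
#' @param geom polygon vertex matrix (meters).
#' @param dem elevation \code{\link{dem_grid}} (m a.s.l.).
#' @param radiation solar radiation \code{\link{dem_grid}} (kWh), or NULL.
#' @return data.frame with one row: \code{flat_area_m2, mean_slope_deg,
#'   mean_aspect_deg, mean_elevation_m, radiation_sum, corrected_area_m2}.
#' @export
terrain_summary <- function(geom, dem, radiation = NULL) {
  sa <- slope_aspect_from_dem(dem)
  flat <- polygon_flat_area(geom)
  slope <- zonal_mean(sa$slope, geom)
  aspect <- zonal_mean(sa$aspect, geom, exclude = -1)
  elev <- zonal_mean(dem, geom)
  rad <- if (is.null(radiation)) NA_real_ else zonal_mean(radiation, geom)
  data.frame(flat_area_m2 = flat,
             mean_slope_deg = slope,
             mean_aspect_deg = aspect,
             mean_elevation_m = elev,
             radiation_sum = rad,
             corrected_area_m2 = slope_corrected_area(flat, slope))
}
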