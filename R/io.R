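#' Write features to GeoJSON
#'
#' Minimal GeoJSON FeatureCollection writer for the vector data the
#' pipeline exchanges: polygons (colony patches, pseudo-absences, geology),
#' polylines (coastline) and points (hotspots). Coordinates are meters of
#' the declared projected plane.
#'
#' @param features list of features; each a list with \code{type} (one of
#'   \code{"Polygon"}, \code{"LineString"}, \code{"Point"}), \code{coords}
#'   (vertex matrix, or length-2 vector for points) and optional
#'   \code{properties} (named list).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_geojson <- function(features, path) {
  fjson <- lapply(features, function(f) {
    geom <- switch(f$type,
      Point = list(type = "Point", coordinates = as.numeric(f$coords)),
      LineString = list(type = "LineString",
                        coordinates = unname(as.matrix(f$coords))),
      Polygon = {
        ring <- unname(as.matrix(f$coords))
        if (!all(ring[1, ] == ring[nrow(ring), ]))
          ring <- rbind(ring, ring[1, ])
        list(type = "Polygon", coordinates = list(ring))
      },
      stop("unsupported geometry type: ", f$type))
    props <- if (is.null(f$properties)) stats::setNames(list(), character(0))
    else f$properties
    list(type = "Feature", geometry = geom, properties = props)
  })
  obj <- list(type = "FeatureCollection", features = fjson)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a GeoJSON FeatureCollection
#'
#' Counterpart of \code{\link{write_geojson}}; supports Point, LineString
#' and Polygon (outer ring only) features.
#'
#' @param path path to a GeoJSON file.
#' @return list of features (\code{type}, \code{coords}, \code{properties}).
#' @export
read_geojson <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$type, "FeatureCollection"))
    stop("not a FeatureCollection")
  lapply(obj$features, function(f) {
    g <- f$geometry
    coords <- switch(g$type,
      Point = as.numeric(unlist(g$coordinates)),
      LineString = do.call(rbind, lapply(g$coordinates,
                                         function(p) as.numeric(unlist(p)))),
      Polygon = {
        ring <- do.call(rbind, lapply(g$coordinates[[1]],
                                      function(p) as.numeric(unlist(p))))
        ring[-nrow(ring), , drop = FALSE]  # drop closing vertex
      },
      stop("unsupported geometry type: ", g$type))
    props <- lapply(f$properties, function(p) p)
    list(type = g$type, coords = coords, properties = props)
  })
}

#' Read a transect table
#'
#' Delimited text with columns \code{x, y, length_km, count} and optional
#' \code{year}; coordinates in meters.
#'
#' @param path path to a CSV file.
#' @return data.frame.
#' @export
read_transects <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x", "y", "length_km", "count")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  tab
}

#' Read a rock-size / nest-density observation table
#'
#' Delimited text with columns \code{rock_diameter_m, nest_density} and
#' optional \code{source}.
#'
#' @param path path to a CSV file.
#' @return data.frame.
#' @export
read_density_obs <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("rock_diameter_m", "nest_density")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  tab
}
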