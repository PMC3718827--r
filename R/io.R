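# File I/O: ESRI ASCII grids, occurrence CSVs, region GeoJSON.
#
# The ASCII grid dialect is implemented here directly: no raster/GDAL package
# is available in the runtime, and the format is a six-line header plus a
# whitespace-separated matrix. The GeoTIFF dialect is declared but rejected.

#' Read a raster file into a [grid_layer()]
#'
#' Only the `ascii_grid` dialect (ESRI ASCII: ncols / nrows / xllcorner /
#' yllcorner / cellsize / NODATA_value header) is supported in this build;
#' `geotiff` errors because no GDAL binding is available offline.
#'
#' @param path file path.
#' @param dialect `"ascii_grid"` or `"geotiff"`.
#' @param name layer name; defaults to the file stem.
#' @param categorical read as a [categorical_grid_layer()]?
#' @return a `GridLayer`.
#' @export
read_raster <- function(path, dialect = c("ascii_grid", "geotiff"),
                        name = NULL, categorical = FALSE) {
  dialect <- match.arg(dialect)
  if (dialect == "geotiff")
    stop("geotiff dialect requires GDAL support, which is not available; ",
         "use ascii_grid")
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 6) stop("malformed ASCII grid: fewer than 6 lines")
  hdr <- list()
  for (i in 1:6) {
    tok <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (length(tok) != 2)
      stop("malformed ASCII grid header line ", i, ": '", lines[i], "'")
    hdr[[tolower(tok[1])]] <- tok[2]
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  for (k in need) if (is.null(hdr[[k]]))
    stop("ASCII grid header missing field: ", k)
  ncols <- as.integer(hdr$ncols); nrows <- as.integer(hdr$nrows)
  nodata <- as.numeric(hdr$nodata_value)
  body <- lines[-(1:6)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != nrows)
    stop("ASCII grid body has ", length(body), " rows, header says nrows=",
         nrows)
  vals <- matrix(NA_real_, nrows, ncols)
  for (i in seq_len(nrows)) {
    row <- as.numeric(strsplit(trimws(body[i]), "[[:space:]]+")[[1]])
    if (length(row) != ncols)
      stop("ASCII grid row ", i, " has ", length(row),
           " values, header says ncols=", ncols)
    vals[i, ] <- row
  }
  mask <- vals == nodata
  vals[mask] <- NA_real_
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  if (categorical) {
    categorical_grid_layer(name, vals, as.numeric(hdr$xllcorner),
                           as.numeric(hdr$yllcorner),
                           as.numeric(hdr$cellsize), mask)
  } else {
    grid_layer(name, vals, as.numeric(hdr$xllcorner),
               as.numeric(hdr$yllcorner), as.numeric(hdr$cellsize), mask)
  }
}

#' Write a layer as an ESRI ASCII grid
#'
#' Output is deterministic (fixed number formatting), so
#' `write_raster(read_raster(p))` reproduces a file written by this function
#' byte for byte.
#'
#' @param layer a `GridLayer`.
#' @param path output path.
#' @param nodata nodata sentinel written for masked cells.
#' @return `path`, invisibly.
#' @export
write_raster <- function(layer, path, nodata = -9999) {
  v <- layer$values
  v[layer$nodata_mask] <- nodata
  fmt <- function(x) formatC(x, format = "g", digits = 15)
  hdr <- c(paste("ncols", ncol(v)),
           paste("nrows", nrow(v)),
           paste("xllcorner", fmt(layer$origin_lon)),
           paste("yllcorner", fmt(layer$origin_lat)),
           paste("cellsize", fmt(layer$cell_size)),
           paste("NODATA_value", fmt(nodata)))
  rows <- apply(v, 1, function(r) paste(fmt(r), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read presence-only occurrence records from CSV
#'
#' Requires `lon` and `lat` columns (decimal degrees WGS84); an optional `id`
#' column is kept, otherwise ids `occ_1`, ... are assigned. Rows with
#' coordinates outside valid ranges are dropped with a warning reporting the
#' count.
#'
#' @param path CSV path with header `lon,lat[,id]`.
#' @return data.frame of class `OccurrenceSet` with columns `lon`, `lat`,
#'   `id`.
#' @export
read_occurrences <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("lon", "lat") %in% names(df)))
    stop("occurrence CSV must have columns lon, lat")
  occurrence_set(df$lon, df$lat, if ("id" %in% names(df)) df$id else NULL)
}

#' Construct an occurrence set
#'
#' @param lon,lat numeric vectors, decimal degrees.
#' @param id optional unique record ids.
#' @return data.frame of class `OccurrenceSet`.
#' @export
occurrence_set <- function(lon, lat, id = NULL) {
  lon <- as.numeric(lon); lat <- as.numeric(lat)
  if (is.null(id)) id <- sprintf("occ_%d", seq_along(lon))
  id <- as.character(id)
  if (anyDuplicated(id)) stop("occurrence ids must be unique")
  bad <- !is.finite(lon) | !is.finite(lat) |
    lon < -180 | lon > 180 | lat < -90 | lat > 90
  if (any(bad)) {
    warning(sum(bad), " occurrence record(s) outside valid lon/lat ranges ",
            "dropped")
    lon <- lon[!bad]; lat <- lat[!bad]; id <- id[!bad]
  }
  structure(data.frame(lon = lon, lat = lat, id = id,
                       stringsAsFactors = FALSE),
            class = c("OccurrenceSet", "data.frame"))
}

#' Write occurrences to CSV
#' @param occ an `OccurrenceSet`.
#' @param path output path.
#' @export
write_occurrences <- function(occ, path) {
  utils::write.csv(as.data.frame(occ)[, c("lon", "lat", "id")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Drop occurrences not covered by the environmental layers
#'
#' Retains only records whose containing cell is valid (non-nodata in every
#' layer and not land). The number excluded is reported via a message.
#'
#' @param occ an `OccurrenceSet`.
#' @param stack a `LayerStack`.
#' @return the filtered `OccurrenceSet`, with attribute `n_excluded`.
#' @export
filter_to_coverage <- function(occ, stack) {
  ref <- first_layer(stack)
  idx <- cell_index(ref, occ$lon, occ$lat)
  ok <- valid_mask(stack)
  keep <- !is.na(idx$row) & ok[cbind(idx$row, idx$col)]
  keep[is.na(keep)] <- FALSE
  n_excl <- sum(!keep)
  if (n_excl > 0)
    message(n_excl, " record(s) excluded: not covered by the environmental ",
            "layers")
  out <- occurrence_set(occ$lon[keep], occ$lat[keep], occ$id[keep])
  attr(out, "n_excluded") <- n_excl
  out
}

#' Extract per-point environmental values from a stack
#'
#' Containing-cell lookup (flooring convention); categorical layers yield
#' integer codes.
#'
#' @param stack a `LayerStack`.
#' @param points an `OccurrenceSet` (or data.frame with lon/lat).
#' @return data.frame, one column per layer plus `id`.
#' @export
extract_values <- function(stack, points) {
  ref <- first_layer(stack)
  idx <- cell_index(ref, points$lon, points$lat)
  if (anyNA(idx$row)) {
    ids <- if (!is.null(points$id)) points$id[is.na(idx$row)]
           else which(is.na(idx$row))
    stop("point(s) outside grid extent: ", paste(ids, collapse = ", "))
  }
  out <- data.frame(id = if (!is.null(points$id)) points$id
                         else paste0("pt_", seq_len(nrow(idx))),
                    stringsAsFactors = FALSE)
  for (nm in names(stack$layers)) {
    v <- stack$layers[[nm]]$values[cbind(idx$row, idx$col)]
    if (inherits(stack$layers[[nm]], "CategoricalGridLayer"))
      v <- as.integer(v)
    out[[nm]] <- v
  }
  out
}

# regions --------------------------------------------------------------------

#' Construct a set of named regions
#'
#' @param regions list of `list(name=, lon=, lat=)` simple polygons
#'   (vertices in order, ring closed implicitly).
#' @return object of class `RegionSet`.
#' @export
region_set <- function(regions) {
  nm <- vapply(regions, function(r) r$name, "")
  if (anyDuplicated(nm)) stop("region names must be unique")
  for (r in regions) {
    if (length(r$lon) != length(r$lat) || length(r$lon) < 3)
      stop("region '", r$name, "' is not a valid polygon")
  }
  structure(list(regions = regions), class = "RegionSet")
}

#' Read regions from a GeoJSON FeatureCollection
#'
#' Each feature must be a Polygon (outer ring used) with a `name` property.
#'
#' @param path GeoJSON path.
#' @return a `RegionSet`.
#' @export
read_regions <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection")
    stop("expected a GeoJSON FeatureCollection")
  regs <- lapply(gj$features, function(f) {
    if (f$geometry$type != "Polygon")
      stop("only Polygon features supported")
    ring <- f$geometry$coordinates[[1]]
    lon <- vapply(ring, function(p) as.numeric(p[[1]]), 0)
    lat <- vapply(ring, function(p) as.numeric(p[[2]]), 0)
    # drop the closing vertex if the ring repeats it
    n <- length(lon)
    if (n > 3 && lon[1] == lon[n] && lat[1] == lat[n]) {
      lon <- lon[-n]; lat <- lat[-n]
    }
    list(name = f$properties$name, lon = lon, lat = lat)
  })
  region_set(regs)
}

#' Write regions as GeoJSON
#' @param regions a `RegionSet`.
#' @param path output path.
#' @export
write_regions <- function(regions, path) {
  feats <- lapply(regions$regions, function(r) {
    ring <- lapply(c(seq_along(r$lon), 1),
                   function(i) c(r$lon[i], r$lat[i]))
    list(type = "Feature",
         properties = list(name = r$name),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Even-odd point-in-polygon test
#'
#' Ray-casting in lon/lat coordinates; adequate for the simple, small
#' polygons handled here (management regions, synthetic tiles).
#'
#' @param lon,lat point coordinate vectors.
#' @param poly_lon,poly_lat polygon vertices (unclosed ring).
#' @return logical vector.
#' @export
point_in_polygon <- function(lon, lat, poly_lon, poly_lat) {
  n <- length(poly_lon)
  inside <- rep(FALSE, length(lon))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly_lon[i]; yi <- poly_lat[i]
    xj <- poly_lon[j]; yj <- poly_lat[j]
    cross <- ((yi > lat) != (yj > lat)) &
      (lon < (xj - xi) * (lat - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross & is.finite(cross))
    j <- i
  }
  inside
}
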