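# ---------------------------------------------------------------------------
# Grid data model
#
# Conventions (fixed, documented, and relied on throughout the package):
#   * values is a numeric matrix in row-major north-to-south order: row 1 is
#     the northernmost row, column 1 the westernmost column.
#   * origin_lon / origin_lat are the coordinates of the outer SW cell edges
#     (the ESRI xllcorner / yllcorner).
#   * cells are half-open [edge, edge + cell_size) in both axes; a point is
#     assigned to a cell by flooring.
#   * nodata_mask is TRUE where the cell carries no data.
# ---------------------------------------------------------------------------

#' Construct an environmental grid layer
#'
#' A `GridLayer` is one environmental variable on a regular lon/lat grid.
#' Row 1 of `values` is the northernmost row; `origin_lon`/`origin_lat` are
#' the south-west corner edges; cells are half-open `[edge, edge + cell_size)`.
#'
#' @param name variable identifier, e.g. `"temperature"`.
#' @param values numeric matrix, rows ordered north to south.
#' @param origin_lon,origin_lat degrees, outer SW cell edges.
#' @param cell_size cell edge length in degrees (> 0).
#' @param nodata_mask logical matrix, `TRUE` = no data. Defaults to
#'   `is.na(values)`.
#' @param units free-text units label.
#' @return an object of class `GridLayer`.
#' @export
grid_layer <- function(name, values, origin_lon, origin_lat,
                       cell_size = 0.005, nodata_mask = NULL, units = "") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(nodata_mask)) nodata_mask <- is.na(values)
  nodata_mask <- as.matrix(nodata_mask)
  if (!is.logical(nodata_mask)) stop("nodata_mask must be logical")
  if (!identical(dim(values), dim(nodata_mask)))
    stop("values and nodata_mask must have identical shape")
  if (!is.finite(cell_size) || cell_size <= 0) stop("cell_size must be > 0")
  nodata_mask <- nodata_mask | is.na(values)
  values[nodata_mask] <- NA_real_
  structure(list(name = name, values = values, nodata_mask = nodata_mask,
                 origin_lon = as.numeric(origin_lon),
                 origin_lat = as.numeric(origin_lat),
                 cell_size = as.numeric(cell_size), units = units),
            class = "GridLayer")
}

#' Construct a categorical grid layer
#'
#' Like [grid_layer()] but values are non-negative integer class codes and a
#' `legend` maps every code appearing in the data to a class name.
#'
#' @inheritParams grid_layer
#' @param legend named character vector; names are codes as strings.
#' @return an object of class `c("CategoricalGridLayer", "GridLayer")`.
#' @export
categorical_grid_layer <- function(name, values, origin_lon, origin_lat,
                                   cell_size = 0.005, nodata_mask = NULL,
                                   legend = NULL, units = "class") {
  g <- grid_layer(name, values, origin_lon, origin_lat, cell_size,
                  nodata_mask, units)
  codes <- sort(unique(g$values[!g$nodata_mask]))
  if (length(codes) && any(codes < 0 | codes != floor(codes)))
    stop("categorical codes must be non-negative integers")
  if (is.null(legend))
    legend <- stats::setNames(paste0("class_", codes), as.character(codes))
  missing <- setdiff(as.character(codes), names(legend))
  if (length(missing))
    stop("legend missing codes: ", paste(missing, collapse = ", "))
  g$legend <- legend
  class(g) <- c("CategoricalGridLayer", "GridLayer")
  g
}

#' Bundle layers sharing one geometry into a stack
#'
#' @param layers named list of [grid_layer()] / [categorical_grid_layer()]
#'   objects on identical geometry.
#' @param land_mask logical matrix (`TRUE` = land / excluded) with the shared
#'   shape; defaults to all-sea.
#' @return an object of class `LayerStack`.
#' @export
layer_stack <- function(layers, land_mask = NULL) {
  if (!length(layers) || is.null(names(layers)) || any(names(layers) == ""))
    stop("layers must be a non-empty named list")
  ref <- layers[[1]]
  for (nm in names(layers)) {
    l <- layers[[nm]]
    if (!inherits(l, "GridLayer")) stop("layer '", nm, "' is not a GridLayer")
    same <- identical(dim(l$values), dim(ref$values)) &&
      isTRUE(all.equal(l$origin_lon, ref$origin_lon)) &&
      isTRUE(all.equal(l$origin_lat, ref$origin_lat)) &&
      isTRUE(all.equal(l$cell_size, ref$cell_size))
    if (!same) stop("layer '", nm, "' does not share the stack geometry")
  }
  if (is.null(land_mask)) {
    land_mask <- matrix(FALSE, nrow(ref$values), ncol(ref$values))
  }
  land_mask <- as.matrix(land_mask)
  if (!is.logical(land_mask) || !identical(dim(land_mask), dim(ref$values)))
    stop("land_mask must be a logical matrix with the shared shape")
  structure(list(layers = layers, land_mask = land_mask),
            class = "LayerStack")
}

#' @export
print.GridLayer <- function(x, ...) {
  cat(sprintf("<%s> '%s' %dx%d cells of %g deg, origin (%g, %g), %d nodata\n",
              class(x)[1], x$name, nrow(x$values), ncol(x$values),
              x$cell_size, x$origin_lon, x$origin_lat, sum(x$nodata_mask)))
  invisible(x)
}

#' @export
print.LayerStack <- function(x, ...) {
  cat(sprintf("<LayerStack> %d layers (%s), %d land cells\n",
              length(x$layers), paste(names(x$layers), collapse = ", "),
              sum(x$land_mask)))
  invisible(x)
}

# grid helpers ---------------------------------------------------------------

#' Latitude / longitude of cell centres
#'
#' @param layer a `GridLayer`.
#' @return `cell_centre_lats`: vector of centre latitudes per row (north to
#'   south); `cell_centre_lons`: per column (west to east).
#' @export
cell_centre_lats <- function(layer) {
  nr <- nrow(layer$values)
  layer$origin_lat + (nr - seq_len(nr) + 0.5) * layer$cell_size
}

#' @rdname cell_centre_lats
#' @export
cell_centre_lons <- function(layer) {
  layer$origin_lon + (seq_len(ncol(layer$values)) - 0.5) * layer$cell_size
}

#' Locate the grid cell containing each point
#'
#' Points are assigned by flooring against the half-open cell convention.
#'
#' @param layer a `GridLayer` (geometry reference).
#' @param lon,lat coordinate vectors in degrees.
#' @return data.frame with columns `row`, `col` (NA where outside the extent).
#' @export
cell_index <- function(layer, lon, lat) {
  nr <- nrow(layer$values); nc <- ncol(layer$values)
  col <- floor((lon - layer$origin_lon) / layer$cell_size) + 1
  # row counted from the north: lat edge flooring against the south origin
  row <- nr - floor((lat - layer$origin_lat) / layer$cell_size)
  bad <- !is.finite(col) | !is.finite(row) | col < 1 | col > nc |
    row < 1 | row > nr
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

valid_mask <- function(stack) {
  ok <- !stack$land_mask
  for (l in stack$layers) ok <- ok & !l$nodata_mask
  ok
}

first_layer <- function(stack) stack$layers[[1]]
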