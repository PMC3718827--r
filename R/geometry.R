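# Spherical geometry: distances, per-cell areas, terrain slope.
# Earth is modelled as a sphere of radius 6371.0 km throughout; one degree
# of a great circle is 2*pi*R/360 = 111.1949 km.

EARTH_RADIUS_KM <- 6371.0
KM_PER_DEGREE <- 2 * pi * EARTH_RADIUS_KM / 360   # 111.19493...

#' Great-circle distance in km
#'
#' Haversine formula on a sphere of radius 6371.0 km. Vectorised over both
#' endpoints.
#'
#' @param lon1,lat1,lon2,lat2 coordinates in degrees.
#' @return distance(s) in km.
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  a <- pmin(pmax(a, 0), 1)
  2 * EARTH_RADIUS_KM * asin(sqrt(a))
}

#' Pairwise haversine distance matrix
#' @param lon,lat coordinate vectors.
#' @return symmetric matrix of km distances.
#' @export
haversine_matrix <- function(lon, lat) {
  n <- length(lon)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    m[i, ] <- haversine_km(lon[i], lat[i], lon, lat)
  }
  (m + t(m)) / 2
}

#' Per-cell area in km^2
#'
#' Small-cell spherical approximation: area = (cell_size * K)^2 * cos(centre
#' latitude) with K = 111.1949 km/degree; constant along rows.
#'
#' @param layer a `GridLayer` supplying the geometry.
#' @return a `GridLayer` named `"cell_area_km2"` of areas (no cells masked).
#' @export
cell_area_km2 <- function(layer) {
  lats <- cell_centre_lats(layer)
  a <- (layer$cell_size * KM_PER_DEGREE)^2 * cos(lats * pi / 180)
  vals <- matrix(a, nrow(layer$values), ncol(layer$values))
  grid_layer("cell_area_km2", vals, layer$origin_lon, layer$origin_lat,
             layer$cell_size, units = "km^2")
}

#' Seafloor slope in percent (Horn 3x3 method)
#'
#' Maximum gradient magnitude from the Horn eight-neighbour kernel, as a
#' percentage (100 * rise/run). Cell spacing is converted to metres with the
#' spherical degree convention: dy = cell_size * 111.1949 km, dx scaled by
#' cos(latitude). Cells with any nodata neighbour (including the border) are
#' nodata.
#'
#' @param bathy `GridLayer` of bathymetry in metres.
#' @return `GridLayer` named `"slope"`, units percent.
#' @export
slope_percent <- function(bathy) {
  z <- bathy$values
  nr <- nrow(z); nc <- ncol(z)
  if (nr < 3 || nc < 3) stop("slope_percent needs a grid of at least 3x3")
  lats <- cell_centre_lats(bathy)
  dy_m <- bathy$cell_size * KM_PER_DEGREE * 1000
  dx_m <- dy_m * cos(lats * pi / 180)            # per row
  out <- matrix(NA_real_, nr, nc)
  ir <- 2:(nr - 1); ic <- 2:(nc - 1)
  # shifted sub-matrices of the 3x3 neighbourhood; row 1 is north
  nw <- z[ir - 1, ic - 1]; n_ <- z[ir - 1, ic]; ne <- z[ir - 1, ic + 1]
  w_ <- z[ir, ic - 1];                          e_ <- z[ir, ic + 1]
  sw <- z[ir + 1, ic - 1]; s_ <- z[ir + 1, ic]; se <- z[ir + 1, ic + 1]
  gx <- ((ne + 2 * e_ + se) - (nw + 2 * w_ + sw)) / (8 * dx_m[ir])
  gy <- ((nw + 2 * n_ + ne) - (sw + 2 * s_ + se)) / (8 * dy_m)
  out[ir, ic] <- 100 * sqrt(gx^2 + gy^2)
  out[is.na(z)] <- NA_real_   # slope undefined where depth itself is nodata
  grid_layer("slope", out, bathy$origin_lon, bathy$origin_lat,
             bathy$cell_size, units = "%")
}
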