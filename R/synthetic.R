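# Synthetic environmental worlds with known ground truth.
#
# Continuous fields are Gaussian-filtered white noise (a cheap stand-in for
# oceanographic texture); temperature additionally carries a linear
# latitudinal gradient. The land mask and the categorical landscape layer
# are carved from further smooth fields so patches are spatially contiguous.
# Occurrences are rejection-sampled from the known "true" envelope, grouped
# into well-separated populations.

#' Run code under a temporary RNG seed
#'
#' Restores the caller's `.Random.seed` afterwards so generators are
#' deterministic without clobbering global RNG state.
#' @param seed integer seed.
#' @param code expression.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive a per-stage seed from a global seed
#'
#' Deterministic string hash folded with the global seed, kept below 2^31.
#' @param seed global integer seed.
#' @param stage stage name.
#' @return integer seed.
#' @export
derive_seed <- function(seed, stage) {
  h <- 0
  for (c in utf8ToInt(stage)) h <- (h * 31 + c) %% 1000003
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

#' Synthetic world configuration
#'
#' Defaults give a desk-scale 200x200-cell, 1 degree x 1 degree mid-latitude
#' domain that runs the full pipeline in seconds.
#'
#' @param extent `c(lon_min, lon_max, lat_min, lat_max)` in degrees.
#' @param cell_size degrees (0.005 matches the field resolution; coarser is
#'   fine for tests).
#' @param seed integer RNG seed.
#' @param smoothness Gaussian filter sigma, in cells, per smooth field.
#' @param n_landscape_classes number of landscape classes (>= 2).
#' @param n_populations number of occurrence populations (>= 1).
#' @param pop_spread_km within-population scatter radius (km).
#' @param pts_per_pop records per population.
#' @param contamination fraction of records placed ignoring the truth
#'   (0 <= eps < 0.5).
#' @param land_fraction fraction of the domain masked as land.
#' @param linkage_km population-grouping threshold the generator respects
#'   (centres are placed >= 3x this apart).
#' @return list of class `SyntheticConfig`.
#' @export
synthetic_config <- function(extent = c(-6, -5, 54, 55), cell_size = 0.005,
                             seed = 1, smoothness = 12,
                             n_landscape_classes = 4, n_populations = 3,
                             pop_spread_km = 5, pts_per_pop = 50,
                             contamination = 0, land_fraction = 0.1,
                             linkage_km = 10) {
  stopifnot(length(extent) == 4, extent[2] > extent[1], extent[4] > extent[3],
            contamination >= 0, contamination < 0.5, n_populations >= 1,
            n_landscape_classes >= 2, cell_size > 0)
  structure(list(extent = extent, cell_size = cell_size, seed = seed,
                 smoothness = smoothness,
                 n_landscape_classes = n_landscape_classes,
                 n_populations = n_populations,
                 pop_spread_km = pop_spread_km, pts_per_pop = pts_per_pop,
                 contamination = contamination,
                 land_fraction = land_fraction, linkage_km = linkage_km),
            class = "SyntheticConfig")
}

#' Ground-truth envelope specification for the generator
#'
#' One generating interval per continuous variable, a preferred landscape
#' code set, and the latitudinal temperature gradient (degC per degree of
#' latitude; negative means cooler northwards).
#'
#' @param temperature,bathymetry,slope,salinity,current_speed `c(lo, hi)`
#'   generating intervals in the variable's units (degC, m elevation,
#'   percent, PSS, m/s).
#' @param preferred_landscape integer codes the species prefers.
#' @param temperature_gradient degC per degree latitude.
#' @param domain_warm_bias degC added to the domain's mean temperature
#'   relative to the niche centre. 0 places the species mid-range; a
#'   positive value emulates a population at its warm range edge (the
#'   domain runs warmer than the thermal optimum, so habitat is
#'   temperature-limited at the warm edge and uniform warming can only
#'   erode it).
#' @return list of class `TruthSpec`.
#' @export
truth_spec <- function(temperature = c(8, 11),
                       bathymetry = c(-110, -50),
                       slope = c(0, 6),
                       salinity = c(33.6, 34.6),
                       current_speed = c(0.2, 0.9),
                       preferred_landscape = c(0L, 1L),
                       temperature_gradient = -2,
                       domain_warm_bias = 0) {
  iv <- list(temperature = temperature, bathymetry = bathymetry,
             slope = slope, salinity = salinity,
             current_speed = current_speed)
  for (nm in names(iv))
    if (iv[[nm]][1] >= iv[[nm]][2]) stop("interval for ", nm, " degenerate")
  if (!length(preferred_landscape)) stop("preferred set must be non-empty")
  structure(list(intervals = iv,
                 preferred_landscape = as.integer(preferred_landscape),
                 temperature_gradient = temperature_gradient,
                 domain_warm_bias = domain_warm_bias),
            class = "TruthSpec")
}

# separable Gaussian smoothing with edge renormalisation
gaussian_smooth <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  smoother <- function(n) {
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    k <- exp(-d^2 / (2 * sigma^2))
    k[d > 3 * sigma] <- 0
    k / rowSums(k)
  }
  smoother(nrow(mat)) %*% mat %*% t(smoother(ncol(mat)))
}

# smooth standard-normal-ish field on the grid
smooth_field <- function(nr, nc, sigma) {
  f <- gaussian_smooth(matrix(stats::rnorm(nr * nc), nr, nc), sigma)
  (f - mean(f)) / stats::sd(f)
}

#' Generate a synthetic environmental layer stack
#'
#' Returns five continuous layers (temperature with the configured
#' latitudinal gradient plus smooth noise; bathymetry; slope derived from
#' bathymetry via [slope_percent()]; salinity; current speed) and one
#' categorical landscape layer of contiguous patches, plus a contiguous land
#' mask. Deterministic given `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @param truth a [truth_spec()].
#' @return a `LayerStack`.
#' @export
generate_environment <- function(config, truth = truth_spec()) {
  with_seed(derive_seed(config$seed, "environment"), {
    ext <- config$extent
    nc <- round((ext[2] - ext[1]) / config$cell_size)
    nr <- round((ext[4] - ext[3]) / config$cell_size)
    mk <- function(name, vals, units)
      grid_layer(name, vals, ext[1], ext[3], config$cell_size, units = units)
    lat_mid <- (ext[3] + ext[4]) / 2
    lats <- ext[3] + (nr - seq_len(nr) + 0.5) * config$cell_size
    # temperature: niche centre (plus any warm bias) at mid-latitude,
    # linear gradient plus smooth noise wide enough to exceed the warm
    # edge in the south
    t_mid <- mean(truth$intervals$temperature) +
      (if (is.null(truth$domain_warm_bias)) 0 else truth$domain_warm_bias)
    temp <- matrix(t_mid + truth$temperature_gradient * (lats - lat_mid),
                   nr, nc) +
      1.2 * smooth_field(nr, nc, config$smoothness)
    bathy <- -80 + 35 * smooth_field(nr, nc, config$smoothness)
    sal <- 34.1 + 0.5 * smooth_field(nr, nc, config$smoothness)
    cur <- pmax(0.55 + 0.35 * smooth_field(nr, nc, config$smoothness), 0)
    land_f <- smooth_field(nr, nc, config$smoothness * 1.5)
    land <- land_f > stats::quantile(land_f, 1 - config$land_fraction)
    ls_f <- smooth_field(nr, nc, config$smoothness)
    brks <- stats::quantile(ls_f, seq(0, 1,
                                      length.out = config$n_landscape_classes
                                      + 1))
    brks[1] <- -Inf; brks[length(brks)] <- Inf
    ls <- matrix(as.integer(cut(ls_f, brks, labels = FALSE)) - 1L, nr, nc)
    bathy_l <- mk("bathymetry", bathy, "m")
    slope_l <- slope_percent(bathy_l)
    landscape <- categorical_grid_layer(
      "landscape", ls, ext[1], ext[3], config$cell_size,
      legend = stats::setNames(
        paste0("landscape_", seq_len(config$n_landscape_classes) - 1),
        as.character(seq_len(config$n_landscape_classes) - 1)))
    layer_stack(list(temperature = mk("temperature", temp, "degC"),
                     bathymetry = bathy_l,
                     slope = slope_l,
                     salinity = mk("salinity", sal, "PSS"),
                     current_speed = mk("current_speed", cur, "m/s"),
                     landscape = landscape),
                land_mask = land)
  })
}

# logical grid of cells satisfying the generating envelope
truth_mask <- function(stack, truth) {
  ok <- valid_mask(stack)
  for (nm in names(truth$intervals)) {
    v <- stack$layers[[nm]]$values
    iv <- truth$intervals[[nm]]
    ok <- ok & !is.na(v) & v >= iv[1] & v <= iv[2]
  }
  ls <- stack$layers$landscape$values
  ok & !is.na(ls) & ls %in% truth$preferred_landscape
}

#' Generate occurrence records from the known truth
#'
#' Population centres are placed on truth-satisfying cells at least
#' `3 * linkage_km` apart; members scatter within `pop_spread_km` of their
#' centre and are resampled until they land on truth-satisfying cells.
#' A `contamination` fraction is instead placed uniformly at random on sea
#' cells, ignoring the truth. Deterministic given `config$seed`.
#'
#' @param stack stack from [generate_environment()].
#' @param truth the [truth_spec()] used to build it.
#' @param config the [synthetic_config()].
#' @return an `OccurrenceSet`.
#' @export
generate_occurrences <- function(stack, truth, config) {
  with_seed(derive_seed(config$seed, "occurrences"), {
    ref <- first_layer(stack)
    tm <- truth_mask(stack, truth)
    if (!any(tm))
      stop("the truth envelope matches no cell of this stack; ",
           "widen the generating intervals")
    sea <- valid_mask(stack)
    lats <- cell_centre_lats(ref); lons <- cell_centre_lons(ref)
    cells <- which(tm, arr.ind = TRUE)
    cell_lon <- lons[cells[, 2]]; cell_lat <- lats[cells[, 1]]
    # population centres: greedy acceptance with full restarts, so a badly
    # placed first centre cannot wedge the sampler
    min_sep <- 3 * config$linkage_km
    centres <- matrix(NA_real_, 0, 2)
    for (restart in 1:50) {
      centres <- matrix(NA_real_, 0, 2)
      tries <- 0
      while (nrow(centres) < config$n_populations && tries < 500) {
        tries <- tries + 1
        k <- sample.int(length(cell_lon), 1)
        if (nrow(centres) == 0 ||
            all(haversine_km(centres[, 1], centres[, 2],
                             cell_lon[k], cell_lat[k]) > min_sep)) {
          centres <- rbind(centres, c(cell_lon[k], cell_lat[k]))
        }
      }
      if (nrow(centres) == config$n_populations) break
    }
    if (nrow(centres) < config$n_populations)
      stop("could not place ", config$n_populations, " population centres ",
           min_sep, " km apart; enlarge the extent or widen the truth")
    n_total <- config$n_populations * config$pts_per_pop
    n_cont <- floor(config$contamination * n_total)
    lon <- numeric(0); lat <- numeric(0)
    for (p in seq_len(config$n_populations)) {
      got <- 0
      while (got < config$pts_per_pop) {
        # uniform in a disk around the centre (planar small-distance approx)
        r <- config$pop_spread_km * sqrt(stats::runif(1))
        th <- stats::runif(1, 0, 2 * pi)
        plat <- centres[p, 2] + (r * sin(th)) / KM_PER_DEGREE
        plon <- centres[p, 1] + (r * cos(th)) /
          (KM_PER_DEGREE * cos(centres[p, 2] * pi / 180))
        ix <- cell_index(ref, plon, plat)
        if (!is.na(ix$row) && tm[ix$row, ix$col]) {
          lon <- c(lon, plon); lat <- c(lat, plat); got <- got + 1
        }
      }
    }
    if (n_cont > 0) {
      sea_cells <- which(sea, arr.ind = TRUE)
      k <- sample.int(nrow(sea_cells), n_cont, replace = TRUE)
      repl <- sample.int(n_total, n_cont)
      lon[repl] <- lons[sea_cells[k, 2]]
      lat[repl] <- lats[sea_cells[k, 1]]
    }
    occurrence_set(lon, lat, sprintf("occ_%03d", seq_len(n_total)))
  })
}

#' Tile the extent into rectangular named regions
#'
#' Splits the configured extent into a near-square grid of `n_regions`
#' rectangles named `"R1"`, `"R2"`, ... jointly covering the domain without
#' overlap.
#'
#' @param config a [synthetic_config()].
#' @param n_regions number of tiles (>= 1).
#' @return a `RegionSet`.
#' @export
generate_regions <- function(config, n_regions = 4) {
  stopifnot(n_regions >= 1)
  ext <- config$extent
  nc <- ceiling(sqrt(n_regions))
  nr <- ceiling(n_regions / nc)
  xs <- seq(ext[1], ext[2], length.out = nc + 1)
  ys <- seq(ext[3], ext[4], length.out = nr + 1)
  regs <- list(); k <- 0
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (k >= n_regions) break
    k <- k + 1
    x0 <- xs[j]; y0 <- ys[i]
    x1 <- if (j == nc || k == n_regions && j < nc) ext[2] else xs[j + 1]
    y1 <- if (i == nr) ext[4] else ys[i + 1]
    regs[[k]] <- list(name = paste0("R", k),
                      lon = c(x0, x1, x1, x0), lat = c(y0, y0, y1, y1))
  }
  region_set(regs)
}
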