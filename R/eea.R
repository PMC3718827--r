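# Environmental Envelope Analysis: occurrence records are grouped into
# populations by single-linkage proximity (default 10 km), each record gets
# a 1 km buffer standing for bed extent, the "preferred range" of each
# continuous variable is its interquartile range over occurrence locations,
# and preferred landscape classes are those inhabited by at least the median
# (over inhabited classes) fraction of populations. The envelope is the set
# of sea cells satisfying every preferred range simultaneously.

#' Group occurrences into populations by single-linkage proximity
#'
#' Connected components under "haversine distance <= linkage_km": two records
#' belong to the same population iff a chain of records connects them with
#' every hop within the threshold. Population ids are ordered by their
#' southernmost member (ties by westernmost). Optionally, pairs whose
#' connecting chord crosses land are treated as unconnected, a reproducible
#' proxy for excluding groupings across obvious land barriers.
#'
#' @param occ an `OccurrenceSet`.
#' @param linkage_km linkage threshold in km (default 10).
#' @param stack optional `LayerStack` supplying the land mask for the
#'   barrier rule; ignored if `land_barrier = FALSE`.
#' @param land_barrier apply the land-crossing exclusion? Default `FALSE`.
#' @return object of class `PopulationSet`: list with `populations` (each
#'   `list(id, member_ids, footprint)`) and `occ` (records with a
#'   `population` column).
#' @export
group_populations <- function(occ, linkage_km = 10, stack = NULL,
                              land_barrier = FALSE) {
  n <- nrow(occ)
  if (n < 1) stop("at least one occurrence required")
  if (n == 1) {
    member <- 1L
  } else {
    d <- haversine_matrix(occ$lon, occ$lat)
    if (land_barrier) {
      if (is.null(stack)) stop("land_barrier = TRUE needs a stack")
      for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        if (d[i, j] <= linkage_km &&
            chord_crosses_land(stack, occ$lon[i], occ$lat[i],
                               occ$lon[j], occ$lat[j]))
          d[i, j] <- d[j, i] <- Inf
      }
    }
    hc <- stats::hclust(stats::as.dist(d), method = "single")
    member <- stats::cutree(hc, h = linkage_km)
  }
  # relabel so population 1 holds the southernmost member
  south <- vapply(split(seq_len(n), member), function(ix) {
    s <- ix[order(occ$lat[ix], occ$lon[ix])][1]
    c(occ$lat[s], occ$lon[s])
  }, numeric(2))
  ord <- order(south[1, ], south[2, ])
  relabel <- match(member, as.integer(colnames(south))[ord])
  pops <- lapply(seq_along(ord), function(p)
    list(id = p, member_ids = occ$id[relabel == p], footprint = NULL))
  occ2 <- as.data.frame(occ)
  occ2$population <- relabel
  structure(list(populations = pops, occ = occ2), class = "PopulationSet")
}

# does the straight lon/lat chord between two nearby points cross land?
chord_crosses_land <- function(stack, lon1, lat1, lon2, lat2, n_steps = 25) {
  ref <- first_layer(stack)
  t <- seq(0, 1, length.out = n_steps)
  ix <- cell_index(ref, lon1 + t * (lon2 - lon1), lat1 + t * (lat2 - lat1))
  inb <- !is.na(ix$row)
  any(stack$land_mask[cbind(ix$row[inb], ix$col[inb])])
}

#' Buffer each population to a bed-extent footprint
#'
#' The footprint is the union of disks of `radius_km` around every member
#' record (planar small-distance approximation), rasterised onto the stack
#' grid and clipped to valid sea cells. A population whose footprint is
#' entirely on land/nodata keeps an empty footprint with a warning.
#'
#' @param pops a `PopulationSet` from [group_populations()].
#' @param stack a `LayerStack`.
#' @param radius_km buffer radius in km (default 1).
#' @return the `PopulationSet` with logical footprint grids filled in.
#' @export
buffer_population <- function(pops, stack, radius_km = 1) {
  ref <- first_layer(stack)
  sea <- valid_mask(stack)
  lats <- cell_centre_lats(ref); lons <- cell_centre_lons(ref)
  nr <- nrow(ref$values); nc <- ncol(ref$values)
  occ <- pops$occ
  for (p in seq_along(pops$populations)) {
    fp <- matrix(FALSE, nr, nc)
    mem <- occ[occ$population == p, , drop = FALSE]
    for (k in seq_len(nrow(mem))) {
      dlat <- radius_km / KM_PER_DEGREE
      dlon <- radius_km / (KM_PER_DEGREE * cos(mem$lat[k] * pi / 180))
      rows <- which(lats >= mem$lat[k] - dlat - ref$cell_size &
                    lats <= mem$lat[k] + dlat + ref$cell_size)
      cols <- which(lons >= mem$lon[k] - dlon - ref$cell_size &
                    lons <= mem$lon[k] + dlon + ref$cell_size)
      if (!length(rows) || !length(cols)) next
      dd <- outer(lats[rows], lons[cols], function(la, lo)
        haversine_km(mem$lon[k], mem$lat[k], lo, la))
      fp[rows, cols] <- fp[rows, cols] | (dd <= radius_km)
    }
    clipped <- fp & sea
    if (any(fp) && !any(clipped))
      warning("population ", p, " footprint falls entirely on land/nodata")
    pops$populations[[p]]$footprint <- clipped
  }
  pops
}

#' Interquartile preferred range
#'
#' `[Q1, Q3]` with quartiles by linear interpolation of order statistics
#' (quantile type 7). Degenerate inputs give zero-width intervals.
#'
#' @param values numeric vector with at least one finite value.
#' @return `c(lo, hi)`.
#' @export
preferred_range <- function(values) {
  values <- values[is.finite(values)]
  if (!length(values)) stop("preferred_range needs at least one finite value")
  unname(stats::quantile(values, c(0.25, 0.75), type = 7))
}

#' Preferred landscape classes from population footprints
#'
#' For each class code t the inhabitation fraction f_t is the share of
#' populations whose footprint overlaps at least one cell of t. Preferred
#' classes are those with f_t > 0 and f_t >= the median of the positive
#' fractions. The maximum positive fraction is reported alongside but plays
#' no role in selection.
#'
#' @param pops a buffered `PopulationSet`.
#' @param landscape the stack's `CategoricalGridLayer`.
#' @return integer vector of preferred codes, with attributes `fractions`
#'   (named, per inhabited code), `median` and `max`.
#' @export
landscape_preference <- function(pops, landscape) {
  fp1 <- pops$populations[[1]]$footprint
  if (is.null(fp1)) stop("populations must be buffered first")
  if (!identical(dim(fp1), dim(landscape$values)))
    stop("landscape layer geometry does not match the footprints")
  codes <- sort(unique(landscape$values[!landscape$nodata_mask]))
  npop <- length(pops$populations)
  f <- vapply(codes, function(t) {
    hit <- vapply(pops$populations, function(p) {
      any(p$footprint & landscape$values == t, na.rm = TRUE)
    }, TRUE)
    mean(hit)
  }, 0)
  names(f) <- as.character(as.integer(codes))
  pos <- f[f > 0]
  med <- stats::median(pos)
  preferred <- as.integer(names(pos)[pos >= med])
  structure(preferred, fractions = f, median = med, max = max(pos))
}

#' Build the environmental envelope from occurrences
#'
#' Continuous preferred ranges are interquartile ranges of the values
#' extracted at occurrence cells (pooled over populations); the landscape
#' preference uses the buffered population footprints.
#'
#' @param stack a `LayerStack` (continuous layers + one categorical
#'   landscape layer).
#' @param occ occurrences already passing [filter_to_coverage()].
#' @param linkage_km population linkage threshold (km).
#' @param buffer_km bed-extent buffer radius (km).
#' @return object of class `EnvelopeSpec`: `continuous_ranges` (named list
#'   of `c(lo, hi)`), `preferred_landscape` (codes), `provenance`.
#' @export
build_envelope <- function(stack, occ, linkage_km = 10, buffer_km = 1) {
  vals <- extract_values(stack, occ)
  cont <- names(stack$layers)[!vapply(stack$layers,
                                      inherits, TRUE,
                                      what = "CategoricalGridLayer")]
  ranges <- lapply(cont, function(nm) preferred_range(vals[[nm]]))
  names(ranges) <- cont
  cat_nm <- setdiff(names(stack$layers), cont)
  pops <- buffer_population(group_populations(occ, linkage_km), stack,
                            buffer_km)
  pref <- if (length(cat_nm))
    landscape_preference(pops, stack$layers[[cat_nm[1]]])
  else integer(0)
  structure(list(continuous_ranges = ranges,
                 preferred_landscape = as.integer(pref),
                 landscape_fractions = attr(pref, "fractions"),
                 provenance = list(n_occurrences = nrow(occ),
                                   n_populations = length(pops$populations),
                                   linkage_km = linkage_km,
                                   buffer_km = buffer_km)),
            class = "EnvelopeSpec")
}

#' @export
print.EnvelopeSpec <- function(x, ...) {
  cat("Environmental envelope (preferred ranges)\n")
  cat(sprintf("  built from %d occurrences in %d populations\n",
              x$provenance$n_occurrences, x$provenance$n_populations))
  for (nm in names(x$continuous_ranges)) {
    r <- x$continuous_ranges[[nm]]
    cat(sprintf("  %-14s [%.4g, %.4g]\n", nm, r[1], r[2]))
  }
  cat("  preferred landscape codes:",
      paste(x$preferred_landscape, collapse = ", "), "\n")
  invisible(x)
}

#' Rasterise the envelope onto the stack grid
#'
#' A cell is in the envelope iff every continuous value lies in its closed
#' preferred interval, the landscape code is preferred, and the cell is
#' valid sea. The enclosed area (sum of [cell_area_km2()] over envelope
#' cells) is attached as attribute `area_km2`.
#'
#' @param stack a `LayerStack` containing every enveloped variable.
#' @param env an `EnvelopeSpec`.
#' @return `GridLayer` of 0/1 values (nodata where the stack is invalid),
#'   attribute `area_km2`.
#' @export
envelope_mask <- function(stack, env) {
  missing <- setdiff(names(env$continuous_ranges), names(stack$layers))
  if (length(missing))
    stop("stack is missing enveloped variable(s): ",
         paste(missing, collapse = ", "))
  ok <- valid_mask(stack)
  inside <- ok
  for (nm in names(env$continuous_ranges)) {
    v <- stack$layers[[nm]]$values
    r <- env$continuous_ranges[[nm]]
    inside <- inside & !is.na(v) & v >= r[1] & v <= r[2]
  }
  cat_nm <- names(stack$layers)[vapply(stack$layers, inherits, TRUE,
                                       what = "CategoricalGridLayer")]
  if (length(cat_nm) && length(env$preferred_landscape)) {
    ls <- stack$layers[[cat_nm[1]]]$values
    inside <- inside & !is.na(ls) & ls %in% env$preferred_landscape
  }
  ref <- first_layer(stack)
  vals <- ifelse(ok, as.numeric(inside), NA_real_)
  out <- grid_layer("envelope", vals, ref$origin_lon, ref$origin_lat,
                    ref$cell_size, nodata_mask = !ok, units = "0/1")
  attr(out, "area_km2") <- mask_area_km2(out)
  out
}

#' Area covered by the TRUE/1 cells of a mask layer
#' @param mask_layer `GridLayer` of 0/1 (or logical) values.
#' @return area in km^2.
#' @export
mask_area_km2 <- function(mask_layer) {
  a <- cell_area_km2(mask_layer)$values
  sum(a[which(mask_layer$values > 0)])
}
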