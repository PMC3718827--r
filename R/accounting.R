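# Suitability accounting: probability bands, habitat categories, area
# tables per management region and epoch, percent-loss tables, and
# envelope-versus-model comparison statistics.
#
# Bands are the ten half-open decimal intervals [k/10, (k+1)/10) with 1.0
# closed into the top band. Categories: "most suitable" (MS) = [0.5, 1.0],
# "less suitable" (LS) = [0.1, 0.5), "unsuitable" (US) = [0.0, 0.1) — the
# half-open reading of the printed "0.5-1.0 / 0.1-0.49 / 0.0-0.09" labels,
# so every probability has exactly one band and one category.

#' Band and category of a suitability probability
#'
#' @param p probabilities in [0, 1] (vectorised).
#' @return data.frame with `band` (0-9) and `category` (`"MS"`, `"LS"`,
#'   `"US"`).
#' @export
categorize <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("probabilities must lie in [0, 1]")
  band <- pmin(floor(p * 10), 9)
  category <- ifelse(p >= 0.5, "MS", ifelse(p >= 0.1, "LS", "US"))
  data.frame(band = as.integer(band), category = category,
             stringsAsFactors = FALSE)
}

#' Band, category and total areas of a suitability map
#'
#' Sums per-cell areas ([cell_area_km2()]) over each probability band and
#' habitat category, overall and (when `regions` is given) per region.
#' Cells are assigned to the first region whose polygon contains their
#' centre; a region containing no cell yields zero-area rows with a
#' warning.
#'
#' @param map a `SuitabilityMap` (`GridLayer` of probabilities).
#' @param regions optional `RegionSet`.
#' @param epoch optional label recorded in the `epoch` column.
#' @return data.frame of class `AreaTable` with columns `epoch`, `region`,
#'   `level` (`"band"`, `"category"`, `"total"`), `key`, `area_km2`.
#' @export
band_areas <- function(map, regions = NULL, epoch = NA) {
  areas <- cell_area_km2(map)$values
  ok <- !map$nodata_mask
  p <- map$values[ok]
  a <- areas[ok]
  cc <- categorize(p)
  region_of <- rep("ALL", length(p))
  tables <- list(one_region_table("ALL", cc, a, epoch))
  if (!is.null(regions)) {
    lats <- cell_centre_lats(map); lons <- cell_centre_lons(map)
    cells <- which(ok, arr.ind = TRUE)
    clon <- lons[cells[, 2]]; clat <- lats[cells[, 1]]
    assigned <- rep(NA_character_, length(p))
    for (r in regions$regions) {
      hit <- is.na(assigned) & point_in_polygon(clon, clat, r$lon, r$lat)
      assigned[hit] <- r$name
      if (!any(assigned == r$name, na.rm = TRUE))
        warning("region '", r$name, "' contains no grid cell")
      tables[[length(tables) + 1]] <-
        one_region_table(r$name, cc[which(assigned == r$name), , drop = FALSE],
                         a[which(assigned == r$name)], epoch)
    }
  }
  out <- do.call(rbind, tables)
  class(out) <- c("AreaTable", "data.frame")
  out
}

one_region_table <- function(region, cc, a, epoch) {
  band_area <- vapply(0:9, function(b) sum(a[cc$band == b]), 0)
  cat_area <- vapply(c("MS", "LS", "US"),
                     function(k) sum(a[cc$category == k]), 0)
  data.frame(epoch = epoch, region = region,
             level = c(rep("band", 10), rep("category", 3), "total"),
             key = c(as.character(0:9), "MS", "LS", "US", "total"),
             area_km2 = c(band_area, cat_area, sum(a)),
             stringsAsFactors = FALSE)
}

#' Integer percent loss between two areas
#'
#' `round((a0 - at) / a0 * 100)`; a zero baseline yields `NA`, rendered as
#' `"n/a"` in formatted tables. A growth in area comes back as a negative
#' loss.
#'
#' @param a0 baseline area (km^2, >= 0).
#' @param at later-epoch area (km^2, >= 0).
#' @return integer percent, or `NA` where the baseline is zero.
#' @export
percent_loss <- function(a0, at) {
  stopifnot(all(a0 >= 0), all(at >= 0))
  out <- round((a0 - at) / a0 * 100)
  out[a0 == 0] <- NA
  out
}

#' Format a percent loss for reporting
#' @param x value from [percent_loss()].
#' @return character, `"n/a"` where `NA`.
#' @export
format_percent_loss <- function(x) ifelse(is.na(x), "n/a", as.character(x))

#' Envelope-versus-model comparison statistics from areas
#'
#' The arithmetic core behind the comparison table: given the envelope area
#' and the MS/LS areas with their envelope-overlap percentages, computes
#' the combined overlap (excluding unsuitable habitat) and the
#' over-prediction percentage
#' `(area(MS u LS) - area(envelope)) / area(MS u LS) * 100`, both rounded
#' to integer percents.
#'
#' @param envelope_km2 envelope area.
#' @param ms_km2,ls_km2 category areas.
#' @param ms_overlap_pct,ls_overlap_pct percent of each category overlapped
#'   by the envelope.
#' @return list with `combined_overlap_pct` and `over_prediction_pct`.
#' @export
overlap_stats_from_areas <- function(envelope_km2, ms_km2, ms_overlap_pct,
                                     ls_km2, ls_overlap_pct) {
  suitable <- ms_km2 + ls_km2
  overlap <- ms_km2 * ms_overlap_pct / 100 + ls_km2 * ls_overlap_pct / 100
  list(combined_overlap_pct = round(overlap / suitable * 100),
       over_prediction_pct = round((suitable - envelope_km2) /
                                     suitable * 100))
}

#' Envelope-versus-model comparison statistics from grids
#'
#' Measures, per habitat category, the model area and the percentage of it
#' overlapped by the envelope, then the combined (MS u LS) overlap and the
#' over-prediction percentage.
#'
#' @param envelope `GridLayer` 0/1 envelope mask.
#' @param map `SuitabilityMap` on the same geometry.
#' @return object of class `ComparisonStats`.
#' @export
overlap_stats <- function(envelope, map) {
  if (!identical(dim(envelope$values), dim(map$values)) ||
      !isTRUE(all.equal(envelope$cell_size, map$cell_size)))
    stop("envelope and suitability map geometry mismatch")
  areas <- cell_area_km2(map)$values
  ok <- !map$nodata_mask & !envelope$nodata_mask
  env <- envelope$values > 0 & ok
  p <- map$values
  ms <- ok & !is.na(p) & p >= 0.5
  ls <- ok & !is.na(p) & p >= 0.1 & p < 0.5
  area_of <- function(m) sum(areas[m])
  env_a <- area_of(env); ms_a <- area_of(ms); ls_a <- area_of(ls)
  ms_ov <- area_of(env & ms); ls_ov <- area_of(env & ls)
  suitable <- ms_a + ls_a
  pct <- function(num, den) if (den > 0) round(num / den * 100) else NA
  structure(list(envelope_km2 = env_a,
                 ms_km2 = ms_a, ms_overlap_pct = pct(ms_ov, ms_a),
                 ls_km2 = ls_a, ls_overlap_pct = pct(ls_ov, ls_a),
                 combined_overlap_pct = pct(ms_ov + ls_ov, suitable),
                 over_prediction_pct = pct(suitable - env_a, suitable)),
            class = "ComparisonStats")
}

#' @export
print.ComparisonStats <- function(x, ...) {
  cat("Envelope vs model comparison\n")
  cat(sprintf("  envelope %.2f km2 | MS %.2f km2 (%s%% overlapped) | ",
              x$envelope_km2, x$ms_km2, x$ms_overlap_pct))
  cat(sprintf("LS %.2f km2 (%s%% overlapped)\n", x$ls_km2,
              x$ls_overlap_pct))
  cat(sprintf("  combined overlap %s%%, over-prediction %s%%\n",
              x$combined_overlap_pct, x$over_prediction_pct))
  invisible(x)
}

#' Most-suitable area loss per region and epoch
#'
#' From a list of [band_areas()] tables (one per epoch), extracts the MS
#' area per region and the integer percent loss relative to the baseline
#' epoch.
#'
#' @param tables named list of `AreaTable`s; names are epoch labels.
#' @param baseline name of the baseline epoch (must be present).
#' @return data.frame with `region`, `epoch`, `ms_km2`, `loss_pct`
#'   (NA where the baseline area is zero) and `loss` (formatted, `"n/a"`).
#' @export
loss_table <- function(tables, baseline) {
  if (!baseline %in% names(tables))
    stop("baseline epoch '", baseline, "' missing from tables")
  ms_of <- function(tab) {
    d <- tab[tab$level == "category" & tab$key == "MS", ]
    stats::setNames(d$area_km2, d$region)
  }
  base <- ms_of(tables[[baseline]])
  rows <- list()
  for (ep in names(tables)) {
    ms <- ms_of(tables[[ep]])
    if (!setequal(names(ms), names(base)))
      stop("epoch '", ep, "' covers different regions than the baseline")
    for (rg in names(base)) {
      lp <- percent_loss(base[[rg]], ms[[rg]])
      rows[[length(rows) + 1]] <- data.frame(
        region = rg, epoch = ep, ms_km2 = ms[[rg]], loss_pct = lp,
        loss = format_percent_loss(lp), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
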