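# Linear ocean-warming scenarios: a uniform temperature increase
# interpolated linearly between the baseline year and the horizon. Under
# the assumed A1B trajectory (4 degC surface warming by 2100 from a 2009
# baseline) the increments are 0.92, 1.80, 3.12 and 4.00 degC for 2030,
# 2050, 2080 and 2100. Only temperature is perturbed; depth, salinity,
# currents and landscape are held fixed.

#' Warming scenario specification
#'
#' @param baseline_year baseline epoch (default 2009).
#' @param horizon_year year by which the full increase is reached (2100).
#' @param total_increase_C total uniform warming in degC (default 4.0).
#' @param epochs projection years, within `[baseline, horizon]`.
#' @return list of class `ScenarioSpec`.
#' @export
scenario_spec <- function(baseline_year = 2009, horizon_year = 2100,
                          total_increase_C = 4.0,
                          epochs = c(2030, 2050, 2080, 2100)) {
  if (horizon_year <= baseline_year)
    stop("horizon_year must exceed baseline_year")
  if (total_increase_C < 0) stop("total_increase_C must be >= 0")
  if (any(epochs < baseline_year | epochs > horizon_year))
    stop("epochs must lie within [baseline_year, horizon_year]")
  structure(list(baseline_year = baseline_year, horizon_year = horizon_year,
                 total_increase_C = total_increase_C, epochs = epochs),
            class = "ScenarioSpec")
}

#' Temperature increment for a given year
#'
#' Linear interpolation between baseline and horizon, reported to 2
#' decimals: `dT = total * (year - baseline) / (horizon - baseline)`.
#'
#' @param spec a [scenario_spec()].
#' @param year epoch year within the spec's range.
#' @return warming increment in degC, rounded to 2 decimals.
#' @export
temperature_increment <- function(spec, year) {
  if (any(year < spec$baseline_year | year > spec$horizon_year))
    stop("year out of scenario range [", spec$baseline_year, ", ",
         spec$horizon_year, "]")
  round(spec$total_increase_C * (year - spec$baseline_year) /
          (spec$horizon_year - spec$baseline_year), 2)
}

#' Apply a uniform warming increment to a stack
#'
#' Shifts the temperature layer by `+dT` at every valid cell; every other
#' layer, the masks and the geometry are untouched. Attempts to perturb any
#' other layer are rejected.
#'
#' @param stack a `LayerStack` containing a temperature layer.
#' @param dT uniform increment in degC.
#' @param layer name of the temperature layer (only `"temperature"` may be
#'   perturbed).
#' @return a new `LayerStack`; attribute `scenario_dT` records provenance.
#' @export
apply_scenario <- function(stack, dT, layer = "temperature") {
  if (layer != "temperature")
    stop("only the temperature layer may be perturbed; depth, salinity, ",
         "currents and landscape are held fixed under this scenario")
  if (!layer %in% names(stack$layers))
    stop("stack has no '", layer, "' layer")
  out <- stack
  tl <- out$layers[[layer]]
  tl$values[!tl$nodata_mask] <- tl$values[!tl$nodata_mask] + dT
  out$layers[[layer]] <- tl
  attr(out, "scenario_dT") <- (if (is.null(attr(stack, "scenario_dT"))) 0
                               else attr(stack, "scenario_dT")) + dT
  out
}
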