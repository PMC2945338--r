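#' Constant land-use rate series
#'
#' @param from,to inclusive calendar year range.
#' @param harvest_ha,clearing_ha,afforestation_ha constant rates, ha/yr.
#' @return A [rate_series()].
#' @examples
#' constant_series(1991, 2100, clearing_ha = 2237)
#' @export
constant_series <- function(from, to, harvest_ha = 0, clearing_ha = 0,
                            afforestation_ha = 0) {
  if (to < from) stop("inverted year range")
  rate_series(seq(from, to), harvest_ha, clearing_ha, afforestation_ha)
}

#' Linearly ramped rate series
#'
#' One event stream is interpolated affinely from \code{start} (at
#' \code{from}) to \code{end} (at \code{to}), endpoints included; the other
#' streams are zero. Used e.g. for scenarios in which an observed logging
#' rate decreases to zero, or doubles, by a horizon year.
#'
#' @param from,to inclusive calendar year range.
#' @param start,end non-negative endpoint rates, ha/yr.
#' @param component which stream to ramp.
#' @return A [rate_series()].
#' @examples
#' linear_ramp(2000, 2100, start = 2237, end = 0, component = "clearing")
#' @export
linear_ramp <- function(from, to, start, end,
                        component = c("harvest", "clearing", "afforestation")) {
  component <- match.arg(component)
  if (to < from) stop("inverted year range")
  if (start < 0 || end < 0) stop("negative endpoint rate")
  yrs <- seq(from, to)
  vals <- if (length(yrs) == 1) start else
    start + (end - start) * (yrs - from) / (to - from)
  args <- list(year = yrs)
  args[[paste0(component, "_ha")]] <- vals
  do.call(rate_series, args)
}

#' Proportional perturbation of a rate series
#'
#' Multiplies every rate by \code{1 + factor}; e.g. \code{factor = 0.15}
#' raises all rates by 15% for sensitivity analysis. Because the
#' book-keeping model is linear in area, perturbing all streams scales every
#' flux component by the same factor.
#'
#' @param series a [rate_series()].
#' @param factor perturbation, must exceed -1.
#' @param components streams to perturb (default all three).
#' @return The perturbed [rate_series()].
#' @export
perturb <- function(series, factor,
                    components = c("harvest", "clearing", "afforestation")) {
  series <- validate_rate_series(series)
  if (!is.numeric(factor) || length(factor) != 1 || factor <= -1)
    stop("'factor' must be a single number > -1")
  components <- match.arg(components, several.ok = TRUE)
  for (col in paste0(components, "_ha"))
    series[[col]] <- series[[col]] * (1 + factor)
  validate_rate_series(series)
}

#' Georgia land-use history template
#'
#' Parameterised reconstruction of the Georgian land-use-change rate series,
#' composed from the documented rules: (i) forest clearing from
#' \code{clearing_start} reflecting the decline of forest cover from ~55% in
#' the 19th century to ~41% by 1921; (ii) managed forest harvest from 1850,
#' at half the 1949 rate before 1946, at the peak rate through 1965, then
#' declining linearly to a modern rate by 1980; (iii) afforestation
#' campaigns over 1890-1980; and (iv) illegal logging treated as clearing,
#' zero before independence in 1991 and constant afterwards at the
#' annualised remotely sensed change rate (adjusted change area divided by
#' the epoch length).
#'
#' Every magnitude is a parameter: the underlying historical series were
#' archival and are not reproducible, so the defaults are plausibility
#' anchors (see the package vignette), not measurements.
#'
#' @param start,horizon first and last template year.
#' @param country_area_ha national land area.
#' @param cover_start,cover_end forest-cover fractions at
#'   \code{clearing_start} and \code{clearing_end}; their difference times
#'   the country area, spread uniformly, sets the historic clearing rate.
#' @param clearing_start,clearing_end historic clearing period.
#' @param harvest_start first harvest year; pre-1946 harvest runs at
#'   \code{0.5 * harvest_peak}.
#' @param harvest_peak harvest rate (ha/yr) for 1946-1965.
#' @param harvest_modern harvest rate reached in 1980 and held thereafter
#'   (linear decline 1966-1980).
#' @param afforestation_rate rate (ha/yr) over
#'   \code{afforestation_start:afforestation_end}.
#' @param afforestation_start,afforestation_end afforestation period.
#' @param illegal_start first year of illegal logging (independence).
#' @param change_area_ha remotely sensed adjusted forest-loss area for the
#'   observation epoch.
#' @param epoch_years epoch length used to annualise \code{change_area_ha}.
#' @return A [rate_series()] spanning \code{start:horizon}.
#' @examples
#' rs <- georgia_template()
#' rs[rs$year %in% c(1944, 1949, 1990, 1991), ]
#' @export
georgia_template <- function(start = 1800, horizon = 2100,
                             country_area_ha = 6.97e6,
                             cover_start = 0.55, cover_end = 0.41,
                             clearing_start = 1800, clearing_end = 1921,
                             harvest_start = 1850,
                             harvest_peak = 50000,
                             harvest_modern = 6000,
                             afforestation_rate = 2000,
                             afforestation_start = 1890,
                             afforestation_end = 1980,
                             illegal_start = 1991,
                             change_area_ha = 22370,
                             epoch_years = 10) {
  if (horizon < start) stop("inverted template year bounds")
  if (clearing_end < clearing_start || afforestation_end < afforestation_start)
    stop("inconsistent year bounds")
  if (any(c(country_area_ha, cover_start, cover_end, harvest_peak,
            harvest_modern, afforestation_rate, change_area_ha,
            epoch_years) < 0))
    stop("template magnitudes must be non-negative")
  yrs <- seq(start, horizon)
  harvest <- clearing <- afforestation <- numeric(length(yrs))

  clr_rate <- country_area_ha * (cover_start - cover_end) /
    (clearing_end - clearing_start + 1)
  clearing[yrs >= clearing_start & yrs <= clearing_end] <- clr_rate

  harvest[yrs >= harvest_start & yrs <= 1945] <- 0.5 * harvest_peak
  harvest[yrs >= 1946 & yrs <= 1965] <- harvest_peak
  decline <- yrs >= 1966 & yrs <= 1980
  harvest[decline] <- harvest_peak +
    (harvest_modern - harvest_peak) * (yrs[decline] - 1965) / 15
  harvest[yrs > 1980] <- harvest_modern

  afforestation[yrs >= afforestation_start & yrs <= afforestation_end] <-
    afforestation_rate

  clearing[yrs >= illegal_start] <- clearing[yrs >= illegal_start] +
    change_area_ha / epoch_years

  rate_series(yrs, harvest, clearing, afforestation)
}
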