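#' Annual land-use-change rate series
#'
#' A year-contiguous table of national land-use-change rates in hectares per
#' year, the driving input of the book-keeping model. Three event streams are
#' tracked: forest harvest (with reforestation), clearing of forest for
#' cropland or pasture, and afforestation or abandonment of agricultural
#' land.
#'
#' @param year integer vector of contiguous calendar years.
#' @param harvest_ha,clearing_ha,afforestation_ha non-negative rates in
#'   ha/yr; scalars are recycled over the years.
#' @return A data frame of class \code{"rate_series"} with columns
#'   \code{year}, \code{harvest_ha}, \code{clearing_ha},
#'   \code{afforestation_ha}.
#' @seealso [constant_series()], [linear_ramp()], [georgia_template()]
#' @export
rate_series <- function(year, harvest_ha = 0, clearing_ha = 0,
                        afforestation_ha = 0) {
  year <- as.integer(year)
  if (!length(year)) stop("empty year range")
  if (any(diff(year) != 1L))
    stop("years must be contiguous and increasing")
  out <- data.frame(year = year,
                    harvest_ha = rep_len(as.numeric(harvest_ha), length(year)),
                    clearing_ha = rep_len(as.numeric(clearing_ha), length(year)),
                    afforestation_ha = rep_len(as.numeric(afforestation_ha),
                                               length(year)))
  validate_rate_series(out)
}

validate_rate_series <- function(x) {
  cols <- c("year", "harvest_ha", "clearing_ha", "afforestation_ha")
  if (!all(cols %in% names(x)))
    stop("rate series needs columns: ", paste(cols, collapse = ", "))
  x <- x[cols]
  if (any(diff(x$year) != 1L)) {
    miss <- setdiff(seq(min(x$year), max(x$year)), x$year)
    stop("rate series has year gaps; missing: ", paste(miss, collapse = ", "))
  }
  rates <- as.matrix(x[-1])
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("rates must be finite and non-negative")
  class(x) <- c("rate_series", "data.frame")
  x
}

#' Add two rate series component-wise
#'
#' The union of the two year ranges is taken; years covered by only one
#' series contribute that series' rates (gaps between disjoint ranges are
#' filled with zero so the result stays contiguous).
#'
#' @param e1,e2 \code{rate_series} objects.
#' @return A \code{rate_series} spanning both inputs.
#' @export
"+.rate_series" <- function(e1, e2) {
  yrs <- seq(min(e1$year, e2$year), max(e1$year, e2$year))
  acc <- matrix(0, length(yrs), 3,
                dimnames = list(NULL, c("harvest_ha", "clearing_ha",
                                        "afforestation_ha")))
  for (s in list(e1, e2)) {
    i <- match(s$year, yrs)
    acc[i, ] <- acc[i, ] + as.matrix(s[c("harvest_ha", "clearing_ha",
                                         "afforestation_ha")])
  }
  validate_rate_series(data.frame(year = yrs, acc))
}
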