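#' Carbon book-keeping model coefficients
#'
#' Builds the full coefficient set used by the annual book-keeping model.
#' Defaults are the Georgian parameterisation: harvested or cleared biomass
#' is split between on-site slash and three wood-product pools (fuelwood
#' released within a year; short-lived products decaying at 10%/yr;
#' long-lived products at 1%/yr), vegetation regrows along a recovery curve
#' anchored at 5 tC/ha just after disturbance, 127 tC/ha at 80 years and the
#' mature 144 tC/ha at 100 years, and soil carbon moves between 134 tC/ha
#' (undisturbed) and a floor of 107 tC/ha.
#'
#' @param ... named overrides of any default listed below.
#'
#' @section Coefficients:
#' \describe{
#'   \item{slash_ratio_clearing, slash_ratio_harvest}{fraction of removed
#'     biomass left as slash (0.33 clearing, 0.09 harvest).}
#'   \item{slash_decay_rate}{slash decay, fraction of remaining stock per
#'     year (0.04).}
#'   \item{frac_1y_*, frac_10y_*, frac_100y_*}{fractions of removed biomass
#'     assigned to the 1/10/100-year product pools, per event type; with the
#'     slash ratio they sum to 1 for each type.}
#'   \item{decay_rate_10y, decay_rate_100y}{product-pool decay on remaining
#'     stock (0.10, 0.01 per year); the 1-year pool is released entirely in
#'     its first annual step.}
#'   \item{veg_c_mature, veg_c_min, veg_c_initial_recovery}{vegetation carbon
#'     density anchors, tC/ha (144, 5, 127).}
#'   \item{initial_recovery_time, full_recovery_time}{years to the
#'     initial-recovery and mature anchors (80, 100).}
#'   \item{soil_c_undisturbed, soil_c_disturbed, soil_c_min}{soil carbon
#'     densities, tC/ha (134, 114, 107); \code{soil_c_disturbed} is retained
#'     for completeness but unused by the default response curves.}
#'   \item{soil_recovery_time}{years for soil carbon to recover after
#'     abandonment (40); also sets the clearing-release e-folding time at a
#'     third of this value, so ~95% of the committed soil loss falls inside
#'     the recovery window.}
#'   \item{biomass_discount}{scalar on removed biomass per event (default 1),
#'     e.g. to discount partially cleared polygons.}
#'   \item{regrowth_curve}{\code{NULL} for the default piecewise-linear
#'     recovery curve, or a function \code{f(age, coeffs)} returning
#'     vegetation carbon density (tC/ha) for a vector of cohort ages.}
#' }
#'
#' @return A validated list of class \code{"carbon_coefficients"}.
#' @examples
#' carbon_coefficients()
#' carbon_coefficients(biomass_discount = 0.8)
#' @export
carbon_coefficients <- function(...) {
  co <- list(
    slash_ratio_clearing   = 0.33,
    slash_ratio_harvest    = 0.09,
    slash_decay_rate       = 0.04,
    frac_1y_clearing       = 0.500,
    frac_10y_clearing      = 0.100,
    frac_100y_clearing     = 0.070,
    frac_1y_harvest        = 0.307,
    frac_10y_harvest       = 0.072,
    frac_100y_harvest      = 0.531,
    decay_rate_10y         = 0.10,
    decay_rate_100y        = 0.01,
    veg_c_mature           = 144,
    veg_c_min              = 5,
    veg_c_initial_recovery = 127,
    initial_recovery_time  = 80,
    full_recovery_time     = 100,
    soil_c_undisturbed     = 134,
    soil_c_disturbed       = 114,
    soil_c_min             = 107,
    soil_recovery_time     = 40,
    biomass_discount       = 1.0,
    regrowth_curve         = NULL
  )
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == ""))
      stop("coefficient overrides must be named")
    unknown <- setdiff(names(dots), names(co))
    if (length(unknown))
      stop("unknown coefficient: ", paste(unknown, collapse = ", "))
    co[names(dots)] <- dots
  }
  validate_coefficients(co)
  structure(co, class = "carbon_coefficients")
}

validate_coefficients <- function(co) {
  rates <- c("slash_ratio_clearing", "slash_ratio_harvest", "slash_decay_rate",
             "frac_1y_clearing", "frac_10y_clearing", "frac_100y_clearing",
             "frac_1y_harvest", "frac_10y_harvest", "frac_100y_harvest",
             "decay_rate_10y", "decay_rate_100y")
  for (r in rates)
    if (!is.numeric(co[[r]]) || co[[r]] < 0 || co[[r]] > 1)
      stop("'", r, "' must be in [0, 1]")
  stocks <- c("veg_c_mature", "veg_c_min", "veg_c_initial_recovery",
              "soil_c_undisturbed", "soil_c_disturbed", "soil_c_min")
  for (s in stocks)
    if (!is.numeric(co[[s]]) || co[[s]] < 0)
      stop("'", s, "' must be a non-negative stock")
  for (tm in c("initial_recovery_time", "full_recovery_time",
               "soil_recovery_time"))
    if (!is.numeric(co[[tm]]) || co[[tm]] <= 0)
      stop("'", tm, "' must be a positive number of years")
  sum_h <- co$frac_1y_harvest + co$frac_10y_harvest + co$frac_100y_harvest +
    co$slash_ratio_harvest
  sum_c <- co$frac_1y_clearing + co$frac_10y_clearing + co$frac_100y_clearing +
    co$slash_ratio_clearing
  if (abs(sum_h - 1) > 1e-9 || abs(sum_c - 1) > 1e-9)
    stop("pool fractions plus slash ratio must sum to 1 for each event type")
  if (!(co$veg_c_min <= co$veg_c_initial_recovery &&
        co$veg_c_initial_recovery <= co$veg_c_mature))
    stop("need veg_c_min <= veg_c_initial_recovery <= veg_c_mature")
  if (!(co$soil_c_min <= co$soil_c_disturbed &&
        co$soil_c_disturbed <= co$soil_c_undisturbed))
    stop("need soil_c_min <= soil_c_disturbed <= soil_c_undisturbed")
  if (co$initial_recovery_time > co$full_recovery_time)
    stop("initial recovery time cannot exceed full recovery time")
  if (!is.numeric(co$biomass_discount) || co$biomass_discount < 0 ||
      co$biomass_discount > 1)
    stop("'biomass_discount' must be in [0, 1]")
  if (!is.null(co$regrowth_curve) && !is.function(co$regrowth_curve))
    stop("'regrowth_curve' must be NULL or a function(age, coeffs)")
  invisible(co)
}

#' @export
print.carbon_coefficients <- function(x, ...) {
  cat("Carbon book-keeping coefficients\n")
  num <- x[vapply(x, is.numeric, logical(1))]
  print(unlist(num), ...)
  cat("regrowth curve:",
      if (is.null(x$regrowth_curve)) "piecewise-linear default" else "custom",
      "\n")
  invisible(x)
}
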