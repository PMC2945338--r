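#' Annual carbon book-keeping model
#'
#' The model tracks carbon stocks year by year as land-use events occur,
#' rather than simulating photosynthesis and respiration. Each year's
#' harvest, clearing and afforestation rates (ha/yr) create event cohorts;
#' every live cohort then contributes annual release from decaying slash and
#' wood-product pools, release or uptake of soil carbon, and uptake by
#' regrowing vegetation. Summing over cohorts gives the national net flux
#' (release positive) at an annual time step.
#'
#' @name bookkeeping
#' @keywords internal
NULL

event_types <- c("harvest", "clearing", "abandonment")

# carbon density (tC/ha) removed from the site by one event type.
# A cleared site is levelled completely (full mature density leaves the
# site and never regrows); a harvested site is cut down to the
# post-disturbance minimum, from which regrowth restarts, so exactly the
# carbon later re-accumulated is what was removed (mass balance).
removed_density <- function(event_type, coeffs) {
  d <- switch(event_type,
              harvest = coeffs$veg_c_mature - coeffs$veg_c_min,
              clearing = coeffs$veg_c_mature,
              abandonment = 0,
              stop("unknown event type: ", event_type))
  d * coeffs$biomass_discount
}

#' Allocate an event's removed carbon to slash and product pools
#'
#' Vegetation carbon removed by a harvest or clearing event is split between
#' on-site slash and the 1/10/100-year wood-product pools using the event
#' type's fractions; the four allocations sum exactly to the removed carbon.
#' Abandonment removes no carbon.
#'
#' @param event_type one of \code{"harvest"}, \code{"clearing"},
#'   \code{"abandonment"}.
#' @param area affected area in hectares, \eqn{\ge 0}.
#' @param coeffs a [carbon_coefficients()] set.
#' @return Named list: \code{removed_tC}, \code{slash}, \code{pool_1y},
#'   \code{pool_10y}, \code{pool_100y} (all tC).
#' @export
allocate_event_carbon <- function(event_type, area,
                                  coeffs = carbon_coefficients()) {
  event_type <- match.arg(event_type, event_types)
  if (!is.numeric(area) || length(area) != 1 || !is.finite(area) || area < 0)
    stop("'area' must be a single non-negative number of hectares")
  removed <- area * removed_density(event_type, coeffs)
  fr <- switch(event_type,
               harvest = c(coeffs$slash_ratio_harvest, coeffs$frac_1y_harvest,
                           coeffs$frac_10y_harvest, coeffs$frac_100y_harvest),
               clearing = c(coeffs$slash_ratio_clearing, coeffs$frac_1y_clearing,
                            coeffs$frac_10y_clearing, coeffs$frac_100y_clearing),
               abandonment = c(0, 0, 0, 0))
  # assign the 100y pool by remainder so the split is exact in floating point
  alloc <- removed * fr
  if (removed > 0) alloc[4] <- removed - sum(alloc[1:3])
  list(removed_tC = removed, slash = alloc[1], pool_1y = alloc[2],
       pool_10y = alloc[3], pool_100y = alloc[4])
}

#' Create an event cohort
#'
#' A cohort is the set of hectares affected by one event type in one year,
#' tracked jointly: its slash and product pools, its age, and (implicitly,
#' through the age) its vegetation and soil state.
#'
#' @inheritParams allocate_event_carbon
#' @param event_year calendar year of the event.
#' @return An object of class \code{"event_cohort"}.
#' @export
event_cohort <- function(event_type, event_year, area,
                         coeffs = carbon_coefficients()) {
  al <- allocate_event_carbon(event_type, area, coeffs)
  structure(list(event_type = match.arg(event_type, event_types),
                 event_year = as.integer(event_year),
                 area = area,
                 slash = al$slash, pool_1y = al$pool_1y,
                 pool_10y = al$pool_10y, pool_100y = al$pool_100y,
                 age = 0L),
            class = "event_cohort")
}

#' Advance a cohort's slash and product pools by one year
#'
#' The 1-year pool (fuelwood) is released entirely in its first annual step;
#' the 10- and 100-year pools release 10% and 1% of their remaining stock,
#' and slash releases at the slash decay rate. All releases are of remaining
#' stock, so pools decay exponentially and never go negative.
#'
#' @param cohort an [event_cohort()].
#' @param coeffs a [carbon_coefficients()] set.
#' @return List with the aged \code{cohort}, \code{slash_release},
#'   \code{product_release} and their sum \code{released} (tC this year).
#' @export
decay_pools <- function(cohort, coeffs = carbon_coefficients()) {
  stopifnot(inherits(cohort, "event_cohort"))
  slash_rel <- coeffs$slash_decay_rate * cohort$slash
  prod_rel <- cohort$pool_1y + coeffs$decay_rate_10y * cohort$pool_10y +
    coeffs$decay_rate_100y * cohort$pool_100y
  cohort$slash <- cohort$slash - slash_rel
  cohort$pool_1y <- 0
  cohort$pool_10y <- cohort$pool_10y * (1 - coeffs$decay_rate_10y)
  cohort$pool_100y <- cohort$pool_100y * (1 - coeffs$decay_rate_100y)
  cohort$age <- cohort$age + 1L
  list(cohort = cohort, slash_release = slash_rel,
       product_release = prod_rel, released = slash_rel + prod_rel)
}

#' Vegetation recovery curve and annual regrowth uptake
#'
#' Vegetation carbon density as a function of cohort age: piecewise linear
#' from the post-disturbance minimum (5 tC/ha at age 0) through the
#' initial-recovery anchor (127 tC/ha at 80 y) to the mature density
#' (144 tC/ha at 100 y), constant thereafter. A custom curve supplied in
#' \code{coeffs$regrowth_curve} replaces the default. The annual uptake is
#' the year-over-year density increment, zero once mature.
#'
#' @param age cohort age(s) in years since the event, \eqn{\ge 0}.
#' @param coeffs a [carbon_coefficients()] set.
#' @return List with \code{veg_c_density} (tC/ha at \code{age}) and
#'   \code{uptake} (tC/ha gained between \code{age - 1} and \code{age}).
#' @export
regrowth_uptake <- function(age, coeffs = carbon_coefficients()) {
  if (any(age < 0)) stop("'age' must be non-negative")
  dens <- veg_density(age, coeffs)
  list(veg_c_density = dens,
       uptake = dens - veg_density(pmax(age - 1, 0), coeffs))
}

veg_density <- function(age, coeffs) {
  if (!is.null(coeffs$regrowth_curve)) return(coeffs$regrowth_curve(age, coeffs))
  stats::approx(x = c(0, coeffs$initial_recovery_time, coeffs$full_recovery_time),
                y = c(coeffs$veg_c_min, coeffs$veg_c_initial_recovery,
                      coeffs$veg_c_mature),
                xout = pmin(age, coeffs$full_recovery_time), rule = 2)$y
}

# per-ha soil carbon density for a clearing cohort at a given age:
# exponential approach from the undisturbed level to the floor, with
# e-folding time soil_recovery_time / 3 (~95% of the committed loss within
# the recovery window, matching the sharp initial release after clearing)
soil_density_clearing <- function(age, coeffs) {
  tau <- coeffs$soil_recovery_time / 3
  gap <- coeffs$soil_c_undisturbed - coeffs$soil_c_min
  coeffs$soil_c_min + gap * exp(-age / tau)
}

# per-ha soil carbon for an abandonment cohort: linear recovery from the
# post-clearing floor back to the undisturbed level over the recovery time
soil_density_abandonment <- function(age, coeffs) {
  gap <- coeffs$soil_c_undisturbed - coeffs$soil_c_min
  pmin(coeffs$soil_c_min + gap * age / coeffs$soil_recovery_time,
       coeffs$soil_c_undisturbed)
}

#' Annual soil carbon flux of a cohort
#'
#' Clearing cohorts release soil carbon along a decreasing exponential from
#' the undisturbed level (134 tC/ha) towards the floor (107 tC/ha); release
#' is sharpest immediately after clearing. Abandonment cohorts accumulate
#' soil carbon linearly back to the undisturbed level over the soil recovery
#' time. Harvest cohorts have no soil flux.
#'
#' @param cohort an [event_cohort()] (its current age is used; call after
#'   [decay_pools()] so ages start at 1 in the event year).
#' @param coeffs a [carbon_coefficients()] set.
#' @return List with \code{soil_release} and \code{soil_uptake} (tC this
#'   year, both \eqn{\ge 0}; at most one is non-zero).
#' @export
soil_flux <- function(cohort, coeffs = carbon_coefficients()) {
  stopifnot(inherits(cohort, "event_cohort"))
  age <- cohort$age
  rel <- upt <- 0
  if (cohort$event_type == "clearing" && age >= 1) {
    rel <- (soil_density_clearing(age - 1, coeffs) -
            soil_density_clearing(age, coeffs)) * cohort$area
  } else if (cohort$event_type == "abandonment" && age >= 1) {
    upt <- (soil_density_abandonment(age, coeffs) -
            soil_density_abandonment(age - 1, coeffs)) * cohort$area
  }
  list(soil_release = rel, soil_uptake = upt)
}

#' Committed carbon of a land-use event
#'
#' Closed-form long-horizon total release (positive) or uptake (negative)
#' once every pool has equilibrated: clearing commits the full vegetation
#' stock plus the soil loss; harvest with reforestation commits zero (every
#' tonne routed through slash and products is eventually re-fixed by
#' regrowth); abandonment commits the negative of the vegetation and soil
#' gains. Used as an analytic oracle for long simulations.
#'
#' @inheritParams allocate_event_carbon
#' @return Committed net release in tC (negative for a net sink).
#' @export
committed_carbon <- function(event_type, area,
                             coeffs = carbon_coefficients()) {
  event_type <- match.arg(event_type, event_types)
  soil_gap <- coeffs$soil_c_undisturbed - coeffs$soil_c_min
  veg_gain <- coeffs$veg_c_mature - coeffs$veg_c_min
  switch(event_type,
         clearing = area * (coeffs$veg_c_mature * coeffs$biomass_discount +
                              soil_gap),
         harvest = 0,
         abandonment = -area * (veg_gain + soil_gap))
}

#' Run the book-keeping model over a rate series
#'
#' Steps the model annually from the first rate year to \code{horizon_year}.
#' Each year, that year's rates create new cohorts (events at year start);
#' all live cohorts are then aged one year and their slash, product, soil
#' and regrowth fluxes accumulated. Harvest cohorts regrow on site; clearing
#' cohorts release soil carbon and never regrow; afforestation/abandonment
#' cohorts accumulate vegetation and soil carbon. The model is deterministic
#' and linear in area.
#'
#' @param rates a [rate_series()] (ha/yr).
#' @param coeffs a [carbon_coefficients()] set.
#' @param horizon_year last simulated year; must not precede the last rate
#'   year. Years after the rate series end have no new events.
#' @return A data frame of class \code{"flux_series"} with columns
#'   \code{year}, \code{slash_release}, \code{product_release},
#'   \code{soil_release}, \code{soil_uptake}, \code{regrowth_uptake},
#'   \code{net}, all in Tg C/yr with release positive; \code{net} composes
#'   the per-event flux sums
#'   (\eqn{net = slash + products + soil_{rel} - soil_{upt} - regrowth}).
#' @examples
#' rs <- constant_series(2000, 2005, clearing_ha = 1000)
#' run_simulation(rs, horizon_year = 2020)
#' @export
run_simulation <- function(rates, coeffs = carbon_coefficients(),
                           horizon_year = max(rates$year)) {
  rates <- validate_rate_series(rates)
  validate_coefficients(coeffs)
  if (horizon_year < max(rates$year))
    stop("'horizon_year' precedes the last rate year")
  years <- seq(min(rates$year), horizon_year)
  ny <- length(years)

  # parallel cohort state vectors (one slot per event stream per year)
  type <- integer(0)        # 1 harvest, 2 clearing, 3 abandonment
  area <- slash <- p1 <- p10 <- p100 <- age <- numeric(0)

  dens_removed <- vapply(event_types, removed_density, numeric(1),
                         coeffs = coeffs)
  frac <- rbind(harvest = c(coeffs$slash_ratio_harvest, coeffs$frac_1y_harvest,
                            coeffs$frac_10y_harvest, coeffs$frac_100y_harvest),
                clearing = c(coeffs$slash_ratio_clearing, coeffs$frac_1y_clearing,
                             coeffs$frac_10y_clearing, coeffs$frac_100y_clearing),
                abandonment = c(0, 0, 0, 0))
  out <- matrix(0, ny, 6,
                dimnames = list(NULL, c("slash_release", "product_release",
                                        "soil_release", "soil_uptake",
                                        "regrowth_uptake", "net")))
  rate_mat <- as.matrix(rates[c("harvest_ha", "clearing_ha",
                                "afforestation_ha")])
  for (i in seq_len(ny)) {
    ri <- match(years[i], rates$year)
    if (!is.na(ri)) {
      for (k in 1:3) {
        a <- rate_mat[ri, k]
        if (a > 0) {
          removed <- a * dens_removed[k]
          type <- c(type, k); area <- c(area, a); age <- c(age, 0)
          slash <- c(slash, removed * frac[k, 1])
          p1 <- c(p1, removed * frac[k, 2])
          p10 <- c(p10, removed * frac[k, 3])
          p100 <- c(p100, removed * frac[k, 4])
        }
      }
    }
    if (!length(type)) next
    age <- age + 1

    sl_rel <- coeffs$slash_decay_rate * slash
    pr_rel <- p1 + coeffs$decay_rate_10y * p10 + coeffs$decay_rate_100y * p100
    slash <- slash - sl_rel
    p1[] <- 0
    p10 <- p10 * (1 - coeffs$decay_rate_10y)
    p100 <- p100 * (1 - coeffs$decay_rate_100y)

    grow <- type != 2L
    re_upt <- numeric(length(type))
    re_upt[grow] <- (veg_density(age[grow], coeffs) -
                     veg_density(age[grow] - 1, coeffs)) * area[grow]

    cl <- type == 2L
    so_rel <- sum((soil_density_clearing(age[cl] - 1, coeffs) -
                   soil_density_clearing(age[cl], coeffs)) * area[cl])
    ab <- type == 3L
    so_upt <- sum((soil_density_abandonment(age[ab], coeffs) -
                   soil_density_abandonment(age[ab] - 1, coeffs)) * area[ab])

    out[i, 1:5] <- c(sum(sl_rel), sum(pr_rel), so_rel, so_upt, sum(re_upt))
  }
  out <- out / 1e6  # tC -> Tg C
  out[, "net"] <- out[, "slash_release"] + out[, "product_release"] +
    out[, "soil_release"] - out[, "soil_uptake"] - out[, "regrowth_uptake"]
  res <- data.frame(year = years, out)
  class(res) <- c("flux_series", "data.frame")
  res
}

#' @export
print.flux_series <- function(x, ...) {
  cat(sprintf("Annual carbon flux series, %d-%d (Tg C/yr, release positive)\n",
              min(x$year), max(x$year)))
  NextMethod()
}
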