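co <- carbon_coefficients()

test_that("pool fractions plus slash close the mass balance for both event types", {
  expect_equal(co$frac_1y_harvest + co$frac_10y_harvest + co$frac_100y_harvest +
                 co$slash_ratio_harvest, 1, tolerance = 1e-12)
  expect_equal(co$frac_1y_clearing + co$frac_10y_clearing + co$frac_100y_clearing +
                 co$slash_ratio_clearing, 1, tolerance = 1e-12)
  expect_error(carbon_coefficients(frac_1y_harvest = 0.4), "sum to 1")
})

test_that("event allocation splits removed carbon exactly by the type fractions", {
  ch <- allocate_event_carbon("harvest", 1, co)
  expect_equal(ch$slash + ch$pool_1y + ch$pool_10y + ch$pool_100y,
               ch$removed_tC)
  expect_equal(ch$pool_1y / ch$removed_tC, co$frac_1y_harvest)
  expect_equal(ch$slash / ch$removed_tC, co$slash_ratio_harvest)

  cc <- allocate_event_carbon("clearing", 1, co)
  # a cleared site is levelled: the full mature stock leaves the site
  expect_equal(cc$removed_tC, co$veg_c_mature)
  expect_equal(cc$pool_1y, 0.500 * 144)
  expect_equal(cc$pool_10y, 0.100 * 144)
  expect_equal(cc$slash, 0.33 * 144)

  z <- allocate_event_carbon("clearing", 0, co)
  expect_equal(z$removed_tC + z$slash + z$pool_1y + z$pool_10y + z$pool_100y, 0)
  expect_error(allocate_event_carbon("fire", 1, co))
  expect_error(allocate_event_carbon("harvest", -1, co), "non-negative")
})

test_that("pool decay releases 100%/10%/1% and slash at its own rate", {
  ck <- event_cohort("harvest", 2000, 0, co)
  ck$pool_10y <- 100
  st <- decay_pools(ck, co)
  expect_equal(st$product_release, 10)
  expect_equal(st$cohort$pool_10y, 90)

  empty <- decay_pools(event_cohort("harvest", 2000, 0, co), co)
  expect_equal(empty$released, 0)

  # 1y pool empties in its first step; slash decays at 4%
  c1 <- event_cohort("clearing", 2000, 1, co)
  st1 <- decay_pools(c1, co)
  expect_equal(st1$cohort$pool_1y, 0)
  expect_equal(st1$slash_release, co$slash_decay_rate * 0.33 * 144)
})

test_that("iterated decay matches the geometric-series closed form", {
  ck <- event_cohort("harvest", 2000, 0, co)
  ck$pool_10y <- 100
  cum <- 0
  for (i in 1:50) {
    st <- decay_pools(ck, co)
    ck <- st$cohort
    cum <- cum + st$released
  }
  expect_equal(cum, 100 * (1 - 0.9^50), tolerance = 1e-9)
  expect_true(all(c(ck$slash, ck$pool_1y, ck$pool_10y, ck$pool_100y) >= 0))
})

test_that("the regrowth curve passes through all density anchors", {
  expect_equal(regrowth_uptake(0, co)$veg_c_density, 5)
  expect_equal(regrowth_uptake(80, co)$veg_c_density, 127)
  expect_equal(regrowth_uptake(100, co)$veg_c_density, 144)
  expect_equal(regrowth_uptake(150, co)$veg_c_density, 144)
  expect_equal(regrowth_uptake(150, co)$uptake, 0)
  # constant increment over the initial recovery phase
  ages <- 1:80
  up <- regrowth_uptake(ages, co)$uptake
  expect_equal(up, rep((127 - 5) / 80, 80))
  # monotone non-decreasing density
  dens <- regrowth_uptake(0:120, co)$veg_c_density
  expect_true(all(diff(dens) >= 0))
})

test_that("soil response releases 27 tC/ha after clearing and recovers after abandonment", {
  cl <- event_cohort("clearing", 2000, 1, co)
  cum <- 0
  for (i in 1:500) {
    cl$age <- i
    cum <- cum + soil_flux(cl, co)$soil_release
  }
  expect_equal(cum, co$soil_c_undisturbed - co$soil_c_min, tolerance = 1e-6)

  ab <- event_cohort("abandonment", 2000, 1, co)
  ab$age <- 41
  expect_equal(soil_flux(ab, co)$soil_uptake, 0)
  ab$age <- 10
  expect_equal(soil_flux(ab, co)$soil_uptake, 27 / 40)
  # harvest cohorts have no soil flux
  hv <- event_cohort("harvest", 2000, 1, co)
  hv$age <- 3
  expect_equal(unlist(soil_flux(hv, co)), c(soil_release = 0, soil_uptake = 0))
})

test_that("zero rates give identically zero flux", {
  fx <- run_simulation(constant_series(1950, 2000), horizon_year = 2100)
  expect_true(all(as.matrix(fx[-1]) == 0))
})

test_that("a single cleared hectare converges to its committed 171 tC", {
  rs <- constant_series(2000, 2000, clearing_ha = 1)
  fx <- run_simulation(rs, co, horizon_year = 2500)
  cum_tC <- sum(fx$net) * 1e6
  committed <- committed_carbon("clearing", 1, co)
  expect_equal(committed, 171)
  expect_lt(abs(cum_tC - committed) / committed, 0.005)
  # components are individually non-negative
  expect_true(all(as.matrix(fx[2:6]) >= 0))
})

test_that("harvest with reforestation nets to ~0 of its gross release", {
  rs <- constant_series(2000, 2000, harvest_ha = 10)
  fx <- run_simulation(rs, co, horizon_year = 2500)
  gross <- sum(fx$slash_release + fx$product_release) * 1e6
  expect_equal(committed_carbon("harvest", 10, co), 0)
  expect_lt(abs(sum(fx$net)) * 1e6, 0.01 * gross)
})

test_that("abandonment commits the negative vegetation and soil gains", {
  expect_equal(committed_carbon("abandonment", 2, co), -2 * (139 + 27))
  rs <- constant_series(2000, 2000, afforestation_ha = 1)
  fx <- run_simulation(rs, co, horizon_year = 2300)
  expect_equal(sum(fx$net) * 1e6, committed_carbon("abandonment", 1, co),
               tolerance = 1e-9)
  expect_equal(committed_carbon("clearing", 0, co), 0)
})

test_that("the model is linear in area and equivariant under time shifts", {
  rr <- random_rate_series(1990, 2020, 800, 400, 150, seed = 11)
  f1 <- run_simulation(rr, co, horizon_year = 2080)
  r3 <- rr
  for (cl in c("harvest_ha", "clearing_ha", "afforestation_ha"))
    r3[[cl]] <- 3 * r3[[cl]]
  f3 <- run_simulation(r3, co, horizon_year = 2080)
  for (cl in names(f1)[-1])
    expect_equal(f3[[cl]], 3 * f1[[cl]], tolerance = 1e-9)

  rshift <- rr
  rshift$year <- rr$year + 25
  fs <- run_simulation(rshift, co, horizon_year = 2105)
  expect_equal(fs$year, f1$year + 25)
  expect_equal(fs$net, f1$net, tolerance = 1e-9)
})

test_that("pools are non-increasing after creation and never negative", {
  rs <- constant_series(2000, 2000, clearing_ha = 5)
  ck <- event_cohort("clearing", 2000, 5, co)
  prev <- c(ck$slash, ck$pool_10y, ck$pool_100y)
  for (i in 1:100) {
    ck <- decay_pools(ck, co)$cohort
    cur <- c(ck$slash, ck$pool_10y, ck$pool_100y)
    expect_true(all(cur <= prev + 1e-12) && all(cur >= 0))
    prev <- cur
  }
})

test_that("a small afforestation stream barely moves the template's net flux", {
  base <- georgia_template()
  fx0 <- run_simulation(base, co, horizon_year = 2100)
  extra <- base + constant_series(1991, 2100, afforestation_ha = 200)
  fx1 <- run_simulation(extra, co, horizon_year = 2100)
  d2010 <- abs(fx1$net[fx1$year == 2010] - fx0$net[fx0$year == 2010])
  expect_lt(d2010, 0.05)
})

test_that("simulation guards its preconditions", {
  rs <- constant_series(2000, 2010, harvest_ha = 10)
  expect_error(run_simulation(rs, co, horizon_year = 2005), "precedes")
  bad <- rs
  bad$harvest_ha[3] <- -1
  expect_error(run_simulation(bad, co), "non-negative")
})
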