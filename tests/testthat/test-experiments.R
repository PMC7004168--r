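test_that("scenario presets carry their defining parameter values", {
  tab <- list_scenarios()
  expect_setequal(tab$name, c("REF", "LOWSCAV", "HIGHSCAV", "FESCAV",
                              "INORGANIC_CU", "INORGANIC_CU2"))
  ref <- scenario_params("REF")
  expect_equal(ref$KD_p, 100e-3); expect_equal(ref$KD_g, 5e-3)
  expect_true(ref$reversible)
  expect_equal(c(ref$ksCu_N, ref$ksCu_D), c(4, 12))
  expect_equal(ref$bioavailable_pool, "ALL_DCU")
  expect_equal(scenario_params("LOWSCAV")$KD_p, 50e-3)
  expect_equal(scenario_params("LOWSCAV")$KD_g, 1e-3)
  expect_equal(scenario_params("HIGHSCAV")$KD_p, 200e-3)
  expect_equal(scenario_params("HIGHSCAV")$KD_g, 10e-3)
  expect_false(scenario_params("FESCAV")$reversible)
  ic2 <- scenario_params("INORGANIC-CU2")
  expect_equal(ic2$bioavailable_pool, "CU_PRIME")
  expect_equal(c(ic2$ksCu_N, ic2$ksCu_D), c(0.01, 0.03))
  # FESCAV differs from REF only through the reversibility switch
  fe <- scenario_params("FESCAV")
  expect_equal(unclass(fe)[names(fe) != "reversible"],
               unclass(ref)[names(ref) != "reversible"])
  expect_error(scenario_params("NOPE"), "unknown scenario")
})

test_that("identical scenario configurations give identical runs", {
  g <- test_grid(8, 400)
  f <- cu_forcing(g, P_N = 0.03, PartC_p = 1, graz_Z_on_N = 0.05,
                  mort_N = 0.05, Kz = 10, river_flux = 50)
  a <- run_scenario("REF", grid = g, forcing = f, dt = 0.5, max_years = 3)
  b <- run_scenario("REF", grid = g, forcing = f, dt = 0.5, max_years = 3)
  expect_identical(unclass(a$run$state), unclass(b$run$state))
  expect_identical(a$budget, b$budget)
  # an override reproducing a preset gives that preset's run
  c <- run_scenario("REF", grid = g, forcing = f, dt = 0.5, max_years = 3,
                    overrides = list(KD_p = 200e-3, KD_g = 10e-3))
  d <- run_scenario("HIGHSCAV", grid = g, forcing = f, dt = 0.5,
                    max_years = 3)
  expect_equal(unclass(c$run$state), unclass(d$run$state))
})

test_that("profile linearity matches a closed-form correlation oracle", {
  z <- seq(0, 4000, by = 100)
  lin <- profile_linearity(1 + 5e-4 * z, z)
  expect_equal(lin$R, 1, tolerance = 1e-12)
  expect_equal(lin$slope, 5e-4, tolerance = 1e-12)
  expect_false(lin$degenerate)

  flat <- profile_linearity(rep(1.3, length(z)), z)
  expect_true(flat$degenerate)
  expect_equal(flat$R, 0)
  expect_equal(flat$slope, 0)

  set.seed(21)
  noisy <- 1 + 5e-4 * z + rnorm(length(z), 0, 0.1)
  ln <- profile_linearity(noisy, z)
  expect_equal(ln$R, cor_textbook(z, noisy), tolerance = 1e-12)
  expect_lt(ln$p_value, 0.01)
  # a depth window restricts the fit
  lw <- profile_linearity(noisy, z, window = c(1000, 3000))
  expect_equal(lw$n, sum(z >= 1000 & z <= 3000))
})

test_that("flux unit conversion is exact and reversible", {
  # 31 Gmol/yr over the top 100 m of 3.6e14 m2
  v <- convert_flux(31)
  expect_equal(v, 31e21 / 365.25 / (3.6e14 * 100 * 1e3), tolerance = 1e-12)
  expect_equal(round(v, 1), 2.4)
  expect_equal(convert_flux(0), 0)
  set.seed(5)
  x <- runif(10, 0, 100)
  expect_equal(convert_flux(convert_flux(x), invert = TRUE), x,
               tolerance = 1e-12)
})

test_that("quota maps report mmol per mol and flag missing biomass", {
  g <- test_grid(5, 100)
  p <- cu_params()
  pn <- c(0.05, 0.05, 0.05, 0, 0.05)
  f <- cu_forcing(g, P_N = pn, P_D = 0.02)
  # cells at the maximal quota theta_max = 2e-3 molCu/molP -> 2 mmol/mol
  st <- cu_state(g, CuN = p$theta_max * pn * 1e3, CuD = 0.01)
  r <- structure(list(state = st, forcing = f, grid = g), class = "cu_run")
  qm <- quota_map(r)
  expect_equal(qm$quota_N[c(1:3, 5)], rep(2, 4), tolerance = 1e-12)
  expect_true(is.na(qm$quota_N[4]) && qm$flagged_N[4])
  expect_equal(qm$quota_D, rep(0.5, 5), tolerance = 1e-12)
})

test_that("the budget ledger reproduces hand-computed arithmetic", {
  # single cell, 100 m deep, with simple forcing and a known state
  g <- column_grid(n_levels = 1, total_depth = 100)
  f <- cu_forcing(g, P_N = 0.05, PartC_p = 1, graz_Z_on_N = 0.1,
                  mort_N = 0.05, river_flux = 50, aero_flux = 10)
  p <- cu_params()
  st <- cu_state(g, DCu = 0.8, pCuPart = 0.1, CuN = 0.02)
  r <- structure(list(state = st, forcing = f, params = p, grid = g),
                 class = "cu_run")
  b <- cu_budget(r, horizon_depth = 100)
  area <- 3.6e14
  toG <- function(x) x * area * 365.25 * 1e-18
  # inventories: conc * depth * 1000 -> nmol/m2
  expect_equal(b$inventory_DCu, 0.8 * 100 * 1000 * area * 1e-18)
  expect_equal(b$inventory_CuPart, 0.1 * 100 * 1000 * area * 1e-18)
  # inputs straight from the forcing
  expect_equal(b$flux_river, toG(50))
  expect_equal(b$flux_aerosol, toG(10 * 0.40))
  # remineralization: lambda * CuPart over the cell
  expect_equal(b$flux_remin, toG(p$lambda_remin * 0.1 * 100 * 1000))
  # particulate export: w_small * pCuPart through 100 m
  expect_equal(b$flux_particle_export, toG(1000 * p$w_small * 0.1))
  # residence time = inventories / exports
  expect_equal(b$residence_time_yr,
               (b$inventory_DCu + b$inventory_CuPart) /
                 (b$flux_scav_export + b$flux_particle_export))
  # a closed, empty column: no exports, residence time not finite
  r0 <- structure(list(state = cu_state(g), forcing = cu_forcing(g),
                       params = p, grid = g), class = "cu_run")
  b0 <- cu_budget(r0)
  expect_equal(b0$flux_uptake, 0)
  expect_false(is.finite(b0$residence_time_yr))
})
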