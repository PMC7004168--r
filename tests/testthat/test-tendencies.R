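p_ref <- cu_params()

test_that("uptake follows the quota-regulated Michaelis-Menten form", {
  # full quota shuts uptake off exactly; no substrate means none either
  expect_identical(uptake_rate(5, p_ref$theta_max, "N", p_ref), 0)
  expect_identical(uptake_rate(0, 1e-3, "D", p_ref), 0)
  # half-saturated, empty quota: mu_max cancels against the regulation
  # denominator, leaving theta_max / 2 = 1e-3 molCu/molP/day
  expect_equal(uptake_rate(4, 0, "N", p_ref), 1e-3, tolerance = 1e-12)
  # monotone increasing in substrate, decreasing in quota
  b <- seq(0, 20, length.out = 40)
  expect_true(all(diff(uptake_rate(b, 1e-3, "N", p_ref)) > 0))
  th <- seq(0, p_ref$theta_max, length.out = 40)
  expect_true(all(diff(uptake_rate(1, th, "N", p_ref)) < 0))
  # exceeding the quota is a domain error
  expect_error(uptake_rate(1, p_ref$theta_max * 1.01, "N", p_ref),
               "quota violation")
})

test_that("scavenging relaxes towards the particle-load equilibrium", {
  # no particles: pure desorption drive of the whole scavenged pool
  expect_equal(scavenging_flux(0.5, 0.2, 0, 100e-3, p_ref), -0.2)
  # the equilibrium point is a fixed point
  ztrc <- 10 * 100e-3
  expect_equal(scavenging_flux(0.001, 0.001 * ztrc / (ztrc + 1), 10,
                               100e-3, p_ref), 0)
  # direct arithmetic at ztrc = 1
  expect_equal(scavenging_flux(0.001, 0, 10, 100e-3, p_ref), 5e-4)
  # irreversible variant clamps desorption but keeps adsorption
  p_ir <- cu_params(reversible = FALSE)
  expect_identical(scavenging_flux(0.5, 0.2, 0, 100e-3, p_ir), 0)
  expect_equal(scavenging_flux(0.001, 0, 10, 100e-3, p_ir), 5e-4)
  # equilibrium fraction is monotone in particle load and in KD
  fr <- function(PartC, KD) PartC * KD / (PartC * KD + 1)
  expect_true(all(diff(fr(seq(0, 50, 1), 0.1)) > 0))
  expect_true(all(diff(fr(10, seq(0.001, 0.5, 0.01))) > 0))
})

test_that("remineralization is linear and first order", {
  expect_identical(remineralization(0, p_ref), 0)
  expect_equal(remineralization(1, cu_params(lambda_remin = 0.03)), 0.03)
  expect_equal(remineralization(2, p_ref), 2 * remineralization(1, p_ref))
})

test_that("grazed copper is partitioned conservatively with a quota cap", {
  p <- cu_params(sigma_recycle = 0.5)
  g0 <- grazing_partition(1, 0, 10, p)
  expect_identical(g0$recycled_to_DCu, 0)
  expect_identical(g0$excreted_to_CuPart, 0)
  # grazed Cu below the zooplankton quota cap: all retained
  gb <- grazing_partition(1, 0.1, 1000, p)   # cap = 10 >> grazed = 0.1
  expect_identical(gb$recycled_to_DCu, 0)
  expect_identical(gb$excreted_to_CuPart, 0)
  expect_equal(gb$retained, 0.1)
  # grazed 1.0, cap 0.4, sigma 0.5 -> 0.3 / 0.3
  gc <- grazing_partition(10, 0.1, 40, p)
  expect_equal(gc$retained, 0.4)
  expect_equal(gc$recycled_to_DCu, 0.3)
  expect_equal(gc$excreted_to_CuPart, 0.3)
  # conservation for random draws
  set.seed(7)
  for (k in 1:20) {
    cu <- runif(1, 0, 5); gr <- runif(1, 0, 0.3); cg <- runif(1, 0, 100)
    gp <- grazing_partition(cu, gr, cg, p)
    expect_equal(gp$recycled_to_DCu + gp$excreted_to_CuPart + gp$retained,
                 gr * cu, tolerance = 1e-14)
  }
})

test_that("mortality and aggregation transfers are conservative arithmetic", {
  expect_identical(mortality_transfer(0.5, 0, p_ref), 0)
  expect_equal(mortality_transfer(0.5, 0.1, p_ref), 0.05)
  ag <- aggregation_transfer(0.2, 0.3, 0.05)
  expect_equal(ag$CuPart_to_large, 0.01)
  expect_equal(ag$SCu_to_large, 0.015)
  expect_identical(aggregation_transfer(0.2, 0.3, 0)$CuPart_to_large, 0)
})

test_that("surface sources dissolve into the top cell only", {
  g <- test_grid(3, 30)
  f <- cu_forcing(g, aero_flux = 100)
  expect_equal(external_sources(NULL, f, p_ref, 10), 4e-3)
  f2 <- cu_forcing(g, aero_flux = 100, river_flux = 50)
  expect_equal(external_sources(NULL, f2, cu_params(Sol_Cu = 1), 10),
               (100 + 50) / 10 * 1e-3)
  expect_equal(external_sources(NULL, cu_forcing(g), p_ref, 10), 0)
  td <- cu_tendencies(cu_state(g, DCu = 0.5), f2, p_ref, g)
  expect_true(all(td$external[-1] == 0))
})

test_that("assembled tendencies conserve copper cell by cell", {
  g <- test_grid(5, 100)
  # all-zero state gives all-zero tendencies
  td0 <- cu_tendencies(cu_state(g), cu_forcing(g), p_ref, g)
  expect_true(all(td0$tendencies == 0))

  # closed cells with every process active: tendencies sum to zero
  f <- cu_forcing(g, P_N = 0.05, P_D = 0.02, PartC_p = 2, PartC_g = 0.5,
                  graz_Z_on_N = 0.05, graz_M_on_N = 0.03,
                  graz_Z_on_D = 0.05, graz_M_on_D = 0.03,
                  mort_N = 0.05, mort_D = 0.05, agg_rate = 0.02, Kz = 10)
  st <- cu_state(g, DCu = 0.8, SCup = 0.05, SCug = 0.01, pCuPart = 0.04,
                 gCuPart = 0.02, CuN = 0.06, CuD = 0.02)
  td <- cu_tendencies(st, f, p_ref, g)
  expect_equal(rowSums(td$tendencies), rep(0, 5), tolerance = 1e-12)

  # with external sources the imbalance equals the input exactly
  f_in <- cu_forcing(g, P_N = 0.05, graz_Z_on_N = 0.1, mort_N = 0.05,
                     PartC_p = 1, aero_flux = 100, river_flux = 50)
  td_in <- cu_tendencies(st, f_in, p_ref, g)
  expect_equal(rowSums(td_in$tendencies), td_in$external, tolerance = 1e-12)
})

test_that("single-process activation reproduces the standalone operator", {
  g <- test_grid(4, 40)
  f <- cu_forcing(g, PartC_p = 10)   # scavenging on small particles only
  st <- cu_state(g, DCu = 0.83, SCup = 0.001)
  td <- cu_tendencies(st, f, p_ref, g)
  sp <- solve_speciation(rep(0.83, 4), ligand_system(p_ref$L_total,
                                                     p_ref$K_L))
  expected <- scavenging_flux(sp$Cu_prime, rep(0.001, 4), rep(10, 4),
                              p_ref$KD_p, p_ref)
  expect_equal(unname(td$tendencies[, "SCup"]), expected)
  expect_equal(unname(td$tendencies[, "DCu"]), -expected)
})

test_that("restricting uptake to inorganic Cu can only reduce it", {
  g <- test_grid(4, 40)
  f <- cu_forcing(g, P_N = 0.05, P_D = 0.02)
  st <- cu_state(g, DCu = c(0.1, 0.5, 1, 3), CuN = 0.01, CuD = 0.005)
  td_all <- cu_tendencies(st, f, cu_params(bioavailable_pool = "ALL_DCU"),
                          g)
  td_cup <- cu_tendencies(st, f, cu_params(bioavailable_pool = "CU_PRIME"),
                          g)
  up <- function(td) td$fluxes$up_N + td$fluxes$up_D
  expect_true(all(up(td_cup) <= up(td_all)))
  expect_true(any(up(td_cup) < up(td_all)))
})
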