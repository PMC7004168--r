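test_that("the vertical grid is well formed and can degenerate to a box", {
  g <- column_grid()
  expect_equal(g$n_levels, 50)
  expect_equal(g$z_edges[1], 0)
  expect_true(all(diff(g$z_edges) > 0))
  expect_equal(max(g$z_edges), 5000)
  expect_equal(sum(g$thickness), 5000)
  expect_true(all(g$z_centers > g$z_edges[-51] & g$z_centers < g$z_edges[-1]))
  expect_equal(g$thickness[1:20], rep(10, 20))

  box <- column_grid(n_levels = 1, total_depth = 200)
  expect_equal(box$thickness, 200)
  expect_error(column_grid(z_edges = c(0, 10, 5)), "strictly increasing")
})

test_that("a zero step and mixing of a uniform profile are no-ops", {
  g <- test_grid(10, 100)
  f <- cu_forcing(g, Kz = 50)
  st <- cu_state(g, DCu = 0.7)
  expect_identical(step(st, f, cu_params(), g, dt = 0)$state, st)
  # DCu does not sink; with no forcing processes a uniform dissolved profile
  # is an exact steady state of the transport operators
  out <- step(st, f, cu_params(), g, dt = 1)
  expect_equal(unclass(out$state)[, "DCu"], rep(0.7, 10), tolerance = 1e-12)
  expect_equal(out$burial, 0)
})

test_that("explicit upwind sinking advects a spike at the right speed", {
  g <- test_grid(30, 300)
  f <- cu_forcing(g)
  p <- cu_params(w_small = 2, w_large_surface = 2, w_large_deep = 2,
                 lambda_remin = 1e-12)
  spike <- numeric(30); spike[5] <- 1
  st <- cu_state(g, pCuPart = spike)
  com <- function(s) sum(g$z_centers * s[, "pCuPart"]) / sum(s[, "pCuPart"])
  mass <- function(s) sum(unclass(s) * g$thickness)  # all tracers
  com0 <- com(st); m0 <- mass(st)
  nstep <- 10; dt <- 1
  for (k in seq_len(nstep))
    st <- step(st, f, p, g, dt = dt, sinking_scheme = "explicit")$state
  # centre of mass moves w * t; first-order upwind only smears around it
  expect_equal(com(st) - com0, p$w_small * nstep * dt, tolerance = 1e-6)
  expect_equal(mass(st), m0, tolerance = 1e-12)
  expect_true(all(unclass(st) >= 0))
})

test_that("an explicit step beyond the advective limit names the timestep", {
  g <- test_grid(10, 100)
  f <- cu_forcing(g)
  st <- cu_state(g, gCuPart = 0.1)
  expect_error(step(st, f, cu_params(), g, dt = 1,
                    sinking_scheme = "explicit"),
               "CFL violation.*dt = 1")
  expect_error(run_to_steady_state(st, f, cu_params(), g, dt = 1,
                                   max_years = 1,
                                   sinking_scheme = "explicit"),
               "CFL")
})

test_that("sinking fluxes are consistent with concentrations and burial", {
  g <- test_grid(10, 100)
  p <- cu_params()
  st <- cu_state(g, SCup = 0.02, pCuPart = 0.01)
  expect_equal(sinking_flux_at(50, cu_state(g), p, g), 0)
  # constant w, constant concentration: flux = w * c (per m2)
  expect_equal(sinking_flux_at(50, st, p, g), 1000 * p$w_small * 0.03)
  # flux at the bottom edge times dt matches the step's burial entry
  f <- cu_forcing(g)
  out <- step(st, f, p, g, dt = 0.5)
  expect_equal(out$burial,
               0.5 * sinking_flux_at(100, out$state, p, g),
               tolerance = 1e-12)
})

test_that("a closed column conserves copper and reports a closed ledger", {
  g <- test_grid(15, 600)
  f <- cu_forcing(g, P_N = 0.03, P_D = 0.01, PartC_p = 1.5, PartC_g = 0.4,
                  graz_Z_on_N = 0.05, graz_M_on_N = 0.03,
                  graz_Z_on_D = 0.04, graz_M_on_D = 0.03,
                  mort_N = 0.05, mort_D = 0.05, agg_rate = 0.02, Kz = 20)
  st <- cu_state(g, DCu = 1, SCup = 0.01, CuN = 0.01, CuD = 0.005)
  r <- run_to_steady_state(st, f, cu_params(), g, dt = 0.5, max_years = 5)
  led <- r$ledger
  expect_equal(led$external_in, 0)
  expect_equal(led$inventory_final - led$inventory_initial,
               -led$burial, tolerance = 1e-9)
  expect_lt(abs(led$drift) / led$inventory_initial, 1e-9)
})

test_that("an unforced, process-free state converges immediately", {
  g <- test_grid(8, 80)
  f <- cu_forcing(g, Kz = 10)
  st <- cu_state(g, DCu = 0.5)   # uniform dissolved Cu, nothing else
  r <- run_to_steady_state(st, f, cu_params(), g, dt = 0.5, max_years = 10)
  expect_true(r$converged)
  expect_equal(r$years_run, 2)   # needs two annual means to compare
  expect_equal(unclass(r$state)[, "DCu"], rep(0.5, 8), tolerance = 1e-10)
})

test_that("implicit and explicit sinking agree at small Courant number", {
  g <- test_grid(20, 200)
  f <- cu_forcing(g, PartC_p = 1)
  p <- cu_params(w_large_surface = 2, w_large_deep = 2)
  st <- cu_state(g, pCuPart = 0.05)
  dt <- 0.2
  si <- se <- st
  for (k in 1:50) {
    si <- step(si, f, p, g, dt, sinking_scheme = "implicit")$state
    se <- step(se, f, p, g, dt, sinking_scheme = "explicit")$state
  }
  expect_equal(unclass(si)[, "pCuPart"], unclass(se)[, "pCuPart"],
               tolerance = 0.05)
})
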