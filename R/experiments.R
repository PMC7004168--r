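#' Run a named scenario to steady state
#'
#' Convenience harness around [run_to_steady_state()]: builds the preset
#' parameters for one of the named experiments, integrates the column, and
#' attaches a surface budget ledger.
#'
#' @param name Scenario name (see [list_scenarios()]).
#' @param grid A [column_grid()]; default the standard 50-level, 5000-m grid.
#' @param forcing A [cu_forcing()]; default [idealized_column_forcing()] on
#'   `grid`.
#' @param overrides Named list of [cu_params()] overrides applied on top of
#'   the preset.
#' @param initial Initial [cu_state()]; default a uniform dissolved profile
#'   at the ligand concentration (the natural buffer scale of the system)
#'   with every other tracer empty.
#' @param dt,max_years,tol Passed to [run_to_steady_state()].
#' @param budget_horizon Depth of the budget ledger horizon, m. Default 100.
#' @return A list of class `cu_scenario`: `run` (a `cu_run`), `budget` (a
#'   [cu_budget()]) and `name`.
#' @examples
#' \donttest{
#' sc <- run_scenario("REF", max_years = 5)
#' sc$budget
#' }
#' @export
run_scenario <- function(name = "REF", grid = column_grid(),
                         forcing = idealized_column_forcing(grid),
                         overrides = list(), initial = NULL,
                         dt = 0.5, max_years = 200, tol = 1e-5,
                         budget_horizon = 100) {
  params <- do.call(scenario_params, c(list(name), overrides))
  if (is.null(initial))
    initial <- cu_state(grid, DCu = mean(params$L_total))
  run <- run_to_steady_state(initial, forcing, params, grid,
                             dt = dt, max_years = max_years, tol = tol)
  structure(list(name = attr(params, "scenario"), run = run,
                 budget = cu_budget(run, horizon_depth = budget_horizon)),
            class = "cu_scenario")
}

#' @export
print.cu_scenario <- function(x, ...) {
  cat("Scenario", x$name, "\n")
  print(x$run)
  print(x$budget)
  invisible(x)
}

#' Linearity of a depth profile
#'
#' Ordinary least-squares regression of concentration on depth over a depth
#' window; the correlation coefficient `R` measures how closely the profile
#' approaches the linear shape that reversible scavenging maintains. The
#' p-value is the usual t-test on the regression slope.
#'
#' @param profile Concentrations, nmol/L (one per depth).
#' @param depth Depths, m, same length.
#' @param window Length-2 depth window `c(zmin, zmax)`, m; points outside are
#'   ignored. Default the full range.
#' @return A list: `R` (correlation coefficient; 0 with `degenerate = TRUE`
#'   when the profile or window has no variance), `slope` (nmol/L per m),
#'   `p_value`, `n` (points used), `degenerate`.
#' @examples
#' z <- seq(0, 4000, by = 100)
#' profile_linearity(1 + 5e-4 * z, z)$R   # exactly linear: R = 1
#' @export
profile_linearity <- function(profile, depth, window = range(depth)) {
  if (length(profile) != length(depth))
    stop("'profile' and 'depth' must have the same length", call. = FALSE)
  keep <- is.finite(profile) & depth >= window[1] & depth <= window[2]
  y <- profile[keep]; z <- depth[keep]
  n <- length(y)
  if (n < 3L || stats::sd(z) == 0 || stats::sd(y) == 0)
    return(list(R = 0, slope = 0, p_value = NA_real_, n = n,
                degenerate = TRUE))
  fit <- stats::lm(y ~ z)
  # an exactly linear profile triggers a perfect-fit warning in summary.lm;
  # its p-value is still the right degenerate limit (0)
  sm <- suppressWarnings(stats::summary.lm(fit))
  list(R = unname(stats::cor(y, z)),
       slope = unname(stats::coef(fit)[2]),
       p_value = unname(sm$coefficients[2, 4]),
       n = n, degenerate = FALSE)
}

#' Convert a global-equivalent flux to a volumetric rate
#'
#' Expresses a flux in Gmol/yr, distributed over a depth horizon of a
#' reference ocean area, as pmol per litre per day (and back with
#' `invert = TRUE`). 31 Gmol/yr over the top 100 m of 3.6e14 m2 is
#' 2.36 pmol L-1 day-1.
#'
#' @param flux Flux in Gmol/yr (or pmol L-1 day-1 when `invert = TRUE`).
#' @param horizon_depth Depth of the layer, m. Default 100.
#' @param ocean_area Reference ocean area, m2. Default 3.6e14.
#' @param invert Direction of the conversion.
#' @return The converted flux.
#' @examples
#' convert_flux(31)                 # 2.36 pmol/L/day
#' convert_flux(convert_flux(31), invert = TRUE)
#' @export
convert_flux <- function(flux, horizon_depth = 100, ocean_area = 3.6e14,
                         invert = FALSE) {
  litres <- ocean_area * horizon_depth * 1e3
  fac <- 1e21 / 365.25 / litres   # Gmol/yr -> pmol/day/L
  if (invert) flux / fac else flux * fac
}

#' Cellular Cu:P quota map
#'
#' Per-cell Cu:P ratio of each phytoplankton group, in mmolCu/molP. Cells
#' where the group's biomass is below `floor` carry `NA` and are flagged.
#'
#' @param result A `cu_run` (or a [cu_state()] together with `forcing`).
#' @param forcing The [cu_forcing()] supplying the biomass; taken from the
#'   run when omitted.
#' @param floor Biomass floor, umolP/L. Default 1e-4.
#' @return Data frame: `depth_m`, `quota_N`, `quota_D` (mmolCu/molP),
#'   `flagged_N`, `flagged_D`.
#' @export
quota_map <- function(result, forcing = NULL, floor = 1e-4) {
  if (inherits(result, "cu_run")) {
    state <- result$state
    if (is.null(forcing)) forcing <- result$forcing
    depth <- result$grid$z_centers
  } else stop("'result' must be a cu_run", call. = FALSE)
  s <- unclass(state)
  q <- function(cu, p) ifelse(p >= floor, cu / p, NA_real_)
  data.frame(depth_m = depth,
             quota_N = q(s[, "CuN"], forcing$P_N),
             quota_D = q(s[, "CuD"], forcing$P_D),
             flagged_N = forcing$P_N < floor,
             flagged_D = forcing$P_D < floor)
}

#' Surface copper budget ledger
#'
#' Integrates every process over a depth horizon of the final state of a run
#' and reports the ledger in global-equivalent units: per-area column fluxes
#' multiplied by a reference ocean area (a reporting convention that makes
#' the column's magnitudes comparable with basin-scale ledgers; clearly
#' labelled in the output). Also reports Cu:C ratios of each process (using
#' the forcing's carbon fluxes, and the Redfield ratio 106 molC:molP for the
#' dissolved phase) and the residence time of copper above the horizon.
#'
#' @param result A `cu_run` from [run_to_steady_state()] or
#'   [run_scenario()].
#' @param horizon_depth Budget horizon, m. Default 100.
#' @param ocean_area Reference ocean area for global-equivalent reporting,
#'   m2. Default 3.6e14.
#' @param dissolved_P Dissolved phosphorus used for the dissolved-phase Cu:C
#'   ratio via Redfield carbon, umolP/L. Default 0.5.
#' @return An object of class `cu_budget`: a list with `inventory_DCu`,
#'   `inventory_CuPart` (Gmol); fluxes in Gmol/yr (`flux_river`,
#'   `flux_aerosol`, `flux_uptake`, `flux_recycling`, `flux_remin`,
#'   `flux_scav`, `flux_scav_export`, `flux_particle_export`); Cu:C ratios in
#'   umolCu/molC (`CuC_uptake`, `CuC_recycling`, `CuC_remin`, `CuC_export`,
#'   `CuC_dissolved`); `residence_time_yr`; and the reporting conventions.
#' @export
cu_budget <- function(result, horizon_depth = 100, ocean_area = 3.6e14,
                      dissolved_P = 0.5) {
  if (!inherits(result, "cu_run"))
    stop("'result' must be a cu_run", call. = FALSE)
  grid <- result$grid; forcing <- result$forcing; params <- result$params
  state <- result$state
  s <- unclass(state)

  # overlap of each cell with the horizon, m
  ov <- pmax(0, pmin(grid$z_edges[-1], horizon_depth) -
                pmin(grid$z_edges[-length(grid$z_edges)], horizon_depth))
  # nmol/L * m * 1000 -> nmol/m2; * area * 1e-18 -> Gmol
  to_Gmol <- function(conc) sum(conc * ov) * 1000 * ocean_area * 1e-18
  # nmol/L/day rate profile -> Gmol/yr over horizon
  to_Gmol_yr <- function(rate) to_Gmol(rate) * 365.25

  fl <- cu_process_fluxes(state, forcing, params, grid)

  inv_DCu <- to_Gmol(s[, "DCu"])
  inv_CuPart <- to_Gmol(s[, "SCup"] + s[, "SCug"] +
                        s[, "pCuPart"] + s[, "gCuPart"])

  flux_river <- forcing$river_flux * ocean_area * 365.25 * 1e-18
  flux_aerosol <- forcing$aero_flux * params$Sol_Cu * ocean_area * 365.25 *
    1e-18
  flux_uptake <- to_Gmol_yr(fl$up_N + fl$up_D)
  flux_recycling <- to_Gmol_yr(fl$recycled_N + fl$recycled_D +
                               fl$retained_N + fl$retained_D)
  flux_remin <- to_Gmol_yr(fl$remin_p + fl$remin_g +
                           fl$remin_sp + fl$remin_sg)
  flux_scav <- to_Gmol_yr(fl$scav_p_pos + fl$scav_g_pos -
                          fl$scav_p_neg - fl$scav_g_neg)

  # export: sinking fluxes through the horizon, split by origin
  i <- min(max(findInterval(horizon_depth, grid$z_edges,
                            left.open = TRUE), 1L), grid$n_levels)
  wl <- w_large_at(horizon_depth, params)
  scav_export <- unname(1000 * (params$w_small * s[i, "SCup"] +
                                wl * s[i, "SCug"]) *
    ocean_area * 365.25 * 1e-18)
  particle_export <- unname(1000 * (params$w_small * s[i, "pCuPart"] +
                                    wl * s[i, "gCuPart"]) *
    ocean_area * 365.25 * 1e-18)

  # carbon fluxes from the forcing (Redfield biomass carbon), molC/yr
  # rate [mmolC/m3/day] -> molC/yr over horizon/area
  C_Gmol_yr <- function(rate) sum(rate * ov) * 1e-3 * ocean_area * 365.25 *
    1e-9   # Gmol C / yr
  gN <- forcing$graz_Z_on_N + forcing$graz_M_on_N
  gD <- forcing$graz_Z_on_D + forcing$graz_M_on_D
  C_uptake <- C_Gmol_yr(params$mu_max * 106 *
                        (forcing$P_N + forcing$P_D))
  C_grazed <- C_Gmol_yr(106 * (gN * forcing$P_N + gD * forcing$P_D))
  C_remin <- C_Gmol_yr(params$lambda_remin *
                       (forcing$PartC_p + forcing$PartC_g))
  C_export <- unname((params$w_small * forcing$PartC_p[i] +
                      wl * forcing$PartC_g[i]) * ocean_area * 365.25 *
                     1e-12)   # GmolC/yr

  # both fluxes in Gmol/yr; umolCu/molC = 1e6 * (molCu/molC)
  CuC <- function(cu, c) if (c > 0) 1e6 * cu / c else NA_real_

  total_export <- scav_export + particle_export
  res_time <- if (total_export > 0) (inv_DCu + inv_CuPart) / total_export
              else Inf

  structure(list(
    horizon_depth = horizon_depth, ocean_area = ocean_area,
    inventory_DCu = inv_DCu, inventory_CuPart = inv_CuPart,
    flux_river = flux_river, flux_aerosol = flux_aerosol,
    flux_uptake = flux_uptake, flux_recycling = flux_recycling,
    flux_remin = flux_remin, flux_scav = flux_scav,
    flux_scav_export = scav_export, flux_particle_export = particle_export,
    CuC_uptake = CuC(flux_uptake, C_uptake),
    CuC_recycling = CuC(flux_recycling, C_grazed),
    CuC_remin = CuC(flux_remin, C_remin),
    CuC_export = CuC(particle_export, C_export),
    CuC_dissolved = {
      mean_DCu <- sum(s[, "DCu"] * ov) / sum(ov)          # nmol/L
      1e6 * (mean_DCu * 1e-9) / (dissolved_P * 1e-6 * 106)
    },
    residence_time_yr = res_time),
    class = "cu_budget")
}

#' @export
print.cu_budget <- function(x, ...) {
  gm <- function(v) formatC(v, digits = 3, format = "g")
  cat(sprintf("Cu budget, 0-%g m (global equivalent over %.3g m2)\n",
              x$horizon_depth, x$ocean_area))
  cat("  inventories (Gmol):   DCu ", gm(x$inventory_DCu),
      ",  particulate ", gm(x$inventory_CuPart), "\n", sep = "")
  cat("  inputs (Gmol/yr):     river ", gm(x$flux_river),
      ",  aerosol (dissolved) ", gm(x$flux_aerosol), "\n", sep = "")
  cat("  cycling (Gmol/yr):    uptake ", gm(x$flux_uptake),
      ",  recycling ", gm(x$flux_recycling),
      ",  remineralization ", gm(x$flux_remin), "\n", sep = "")
  cat("  export (Gmol/yr):     scavenged ", gm(x$flux_scav_export),
      ",  biogenic particles ", gm(x$flux_particle_export), "\n", sep = "")
  cat("  Cu:C (umolCu/molC):   uptake ", gm(x$CuC_uptake),
      ", recycling ", gm(x$CuC_recycling),
      ", remin ", gm(x$CuC_remin),
      ", export ", gm(x$CuC_export),
      ", dissolved ", gm(x$CuC_dissolved), "\n", sep = "")
  cat("  residence time:       ", gm(x$residence_time_yr), " yr\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.cu_budget <- function(x, ...) {
  num <- x[vapply(x, is.numeric, TRUE)]
  data.frame(quantity = names(num), value = unlist(num, use.names = FALSE))
}
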