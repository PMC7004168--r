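forcing_profile_fields <- c("P_N", "P_D", "PartC_p", "PartC_g",
                            "graz_Z_on_N", "graz_Z_on_D",
                            "graz_M_on_N", "graz_M_on_D",
                            "mort_N", "mort_D", "agg_rate", "Kz")

#' Prescribed ecosystem forcing for the copper column
#'
#' Bundles the ecosystem drivers that the copper tracers respond to but do not
#' feed back on: phytoplankton phosphorus biomass (`P_N`, `P_D`, umolP/L),
#' small/large particulate organic carbon (`PartC_p`, `PartC_g`, mmolC/m3),
#' micro/mesozooplankton grazing rates on each group (`graz_*`, 1/day),
#' phytoplankton mortality (`mort_N`, `mort_D`, 1/day), small-to-large
#' particle aggregation (`agg_rate`, 1/day), vertical mixing (`Kz`, m2/day),
#' and the surface copper inputs `aero_flux` (total aerosol deposition,
#' nmol m-2 day-1, of which a solubility fraction dissolves) and `river_flux`
#' (dissolved riverine input, nmol m-2 day-1), applied to the top cell only.
#'
#' @param grid A [column_grid()].
#' @param ... Named fields; profile fields (scalars recycled over the column)
#'   and the two scalar surface fluxes. Missing fields default to zero.
#' @return An object of class `cu_forcing`: list of per-cell profile vectors
#'   plus scalar `aero_flux` and `river_flux`.
#' @seealso [idealized_column_forcing()], [budget_scale_forcing()]
#' @export
cu_forcing <- function(grid, ...) {
  args <- list(...)
  bad <- setdiff(names(args), c(forcing_profile_fields,
                                "aero_flux", "river_flux"))
  if (length(bad))
    stop("unknown forcing field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  n <- grid$n_levels
  f <- list()
  for (nm in forcing_profile_fields) {
    v <- if (is.null(args[[nm]])) 0 else args[[nm]]
    f[[nm]] <- rep_len(as.numeric(v), n)
  }
  for (nm in c("aero_flux", "river_flux")) {
    v <- if (is.null(args[[nm]])) 0 else args[[nm]]
    if (length(v) != 1L)
      stop("'", nm, "' is a scalar surface flux", call. = FALSE)
    f[[nm]] <- as.numeric(v)
  }
  if (any(vapply(f, function(v) any(!is.finite(v)) || any(v < 0), TRUE)))
    stop("all forcing fields must be finite and >= 0", call. = FALSE)
  structure(f, class = "cu_forcing", n_levels = n)
}

#' @export
print.cu_forcing <- function(x, ...) {
  cat("Cu column forcing (", attr(x, "n_levels"), " levels)\n", sep = "")
  cat(sprintf("  surface P_N + P_D: %.3g umolP/L; PartC_p + PartC_g: %.3g mmolC/m3\n",
              x$P_N[1] + x$P_D[1], x$PartC_p[1] + x$PartC_g[1]))
  cat(sprintf("  aerosol deposition %.3g, river input %.3g nmol m-2 day-1\n",
              x$aero_flux, x$river_flux))
  invisible(x)
}

# Default surface flux densities (nmol m-2 day-1) chosen so that, integrated
# over a 3.6e14 m2 reference ocean area, the river input totals 6.7 Gmol/yr
# and dissolved aerosol input 0.27 Gmol/yr at 40% solubility.
.default_ocean_area <- 3.6e14
.default_river_flux <- 6.7e18 / .default_ocean_area / 365.25
.default_aero_flux <- (0.27 / 0.40) * 1e18 / .default_ocean_area / 365.25

#' Idealized synthetic column forcing
#'
#' Generates deterministic forcing profiles with the qualitative vertical
#' structure of open-ocean ecosystem fields: biomass confined to the euphotic
#' zone with an exponential tail, particulate organic carbon following a
#' Martin power-law attenuation below a reference depth, grazing / mortality /
#' aggregation rates uniform, strong mixing in a surface mixed layer and weak
#' mixing below, and surface-only aerosol and river copper inputs. Optional
#' multiplicative lognormal noise (seeded, bit-reproducible) perturbs the
#' biomass and particle profiles.
#'
#' @param grid A [column_grid()].
#' @param P_N0,P_D0 Euphotic-zone phosphorus biomass, umolP/L. The defaults
#'   (0.035 and 0.015) describe a moderately productive open-ocean column
#'   (living carbon ~5 mmolC/m3 at Redfield stoichiometry), consistent with
#'   the default particle load; they give a euphotic-zone Cu uptake of a few
#'   pmol per litre per day, the magnitude observed in open-ocean surface
#'   waters, and keep inorganic Cu' genuinely scarce -- the regime the
#'   bioavailability experiments probe.
#' @param z_eu Euphotic depth, m (biomass constant above, decaying below).
#'   Default 100.
#' @param efold Biomass e-folding scale below `z_eu`, m. Default 30.
#' @param PartC_p0,PartC_g0 Upper-ocean particulate organic carbon, mmolC/m3.
#'   Defaults 2 and 0.5.
#' @param z0 Reference depth of the Martin curve, m. Default 100.
#' @param martin_b Martin attenuation exponent. Default 0.858.
#' @param graz_Z,graz_M Micro/mesozooplankton grazing rates, 1/day, applied to
#'   both phytoplankton groups. Defaults 0.05 and 0.03.
#' @param mort Phytoplankton mortality rate, 1/day. Default 0.05.
#' @param agg Small-to-large aggregation rate, 1/day. Default 0.02.
#' @param mld Mixed-layer depth, m. Default 50.
#' @param Kz_ml,Kz_deep Mixing coefficients within/below the mixed layer,
#'   m2/day. Defaults 100 and 1.
#' @param aero_flux,river_flux Surface inputs, nmol m-2 day-1. Defaults as in
#'   [budget_scale_forcing()].
#' @param noise_amp Standard deviation of the lognormal noise (0 = exact
#'   analytic profiles). Default 0.
#' @param seed Integer seed for the noise; same seed, same output,
#'   bit-identically. Default 1.
#' @return A [cu_forcing()] object.
#' @examples
#' f <- idealized_column_forcing(column_grid())
#' f$PartC_p[1]
#' @export
idealized_column_forcing <- function(grid,
                                     P_N0 = 0.035, P_D0 = 0.015,
                                     z_eu = 100, efold = 30,
                                     PartC_p0 = 2, PartC_g0 = 0.5,
                                     z0 = 100, martin_b = 0.858,
                                     graz_Z = 0.05, graz_M = 0.03,
                                     mort = 0.05, agg = 0.02,
                                     mld = 50, Kz_ml = 100, Kz_deep = 1,
                                     aero_flux = .default_aero_flux,
                                     river_flux = .default_river_flux,
                                     noise_amp = 0, seed = 1) {
  z <- grid$z_centers
  bio_shape <- ifelse(z <= z_eu, 1, exp(-(z - z_eu) / efold))
  martin <- ifelse(z <= z0, 1, (z / z0)^(-martin_b))
  noise <- function(k) rep(1, length(z))
  if (noise_amp > 0) {
    rng <- local_rng(seed)
    on.exit(rng(), add = TRUE)
    noise <- function(k) exp(stats::rnorm(length(z), 0, noise_amp))
  }
  cu_forcing(grid,
             P_N = P_N0 * bio_shape * noise(1),
             P_D = P_D0 * bio_shape * noise(2),
             PartC_p = PartC_p0 * martin * noise(3),
             PartC_g = PartC_g0 * martin * noise(4),
             graz_Z_on_N = graz_Z, graz_Z_on_D = graz_Z,
             graz_M_on_N = graz_M, graz_M_on_D = graz_M,
             mort_N = mort, mort_D = mort, agg_rate = agg,
             Kz = ifelse(z <= mld, Kz_ml, Kz_deep),
             aero_flux = aero_flux, river_flux = river_flux)
}

# Run fn with a private RNG stream; returns a restore function.
local_rng <- function(seed) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
}

#' Forcing scaled to the global surface copper budget
#'
#' [idealized_column_forcing()] with surface fluxes set so that, multiplied by
#' a 3.6e14 m2 reference ocean area, the riverine input integrates to
#' `river_Gmol_yr` Gmol/yr and the dissolved aerosol input to
#' `aero_dissolved_Gmol_yr` Gmol/yr at the stated solubility -- making the
#' column's budget ledger comparable, as a global equivalent, with
#' basin-scale ledgers.
#'
#' @param grid A [column_grid()].
#' @param river_Gmol_yr Global-equivalent river input, Gmol/yr. Default 6.7.
#' @param aero_dissolved_Gmol_yr Global-equivalent dissolved aerosol input,
#'   Gmol/yr. Default 0.27.
#' @param Sol_Cu Aerosol solubility used to back out total deposition from the
#'   dissolved flux. Default 0.40.
#' @param ocean_area Reference ocean area, m2. Default 3.6e14.
#' @param ... Passed to [idealized_column_forcing()].
#' @return A [cu_forcing()] object.
#' @export
budget_scale_forcing <- function(grid, river_Gmol_yr = 6.7,
                                 aero_dissolved_Gmol_yr = 0.27,
                                 Sol_Cu = 0.40, ocean_area = 3.6e14, ...) {
  river <- river_Gmol_yr * 1e18 / ocean_area / 365.25
  aero <- (aero_dissolved_Gmol_yr / Sol_Cu) * 1e18 / ocean_area / 365.25
  idealized_column_forcing(grid, aero_flux = aero, river_flux = river, ...)
}

#' Write / read forcing profiles as CSV
#'
#' The CSV holds one row per grid cell (column `depth_m` plus every profile
#' field); the scalar surface fluxes are stored in `#`-comment header lines.
#' Units: biomass umolP/L, particulate carbon mmolC/m3, rates 1/day, mixing
#' m2/day, fluxes nmol m-2 day-1; depth positive downward in metres.
#'
#' @param forcing A [cu_forcing()] object.
#' @param grid The [column_grid()] the forcing lives on.
#' @param path File path.
#' @return `write_forcing_csv` returns `path` invisibly; `read_forcing_csv`
#'   returns a [cu_forcing()].
#' @export
write_forcing_csv <- function(forcing, grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# aero_flux: %.17g", forcing$aero_flux),
               sprintf("# river_flux: %.17g", forcing$river_flux)), con)
  df <- data.frame(depth_m = grid$z_centers)
  for (nm in forcing_profile_fields) df[[nm]] <- forcing[[nm]]
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_forcing_csv
#' @export
read_forcing_csv <- function(path, grid) {
  hdr <- readLines(path, n = 10L)
  hdr <- hdr[startsWith(hdr, "#")]
  get_scalar <- function(key) {
    ln <- grep(paste0("^# *", key, ":"), hdr, value = TRUE)
    if (!length(ln)) return(0)
    as.numeric(sub(".*:", "", ln[1]))
  }
  df <- utils::read.csv(path, comment.char = "#")
  if (nrow(df) != grid$n_levels)
    stop("forcing file has ", nrow(df), " rows but the grid has ",
         grid$n_levels, " levels", call. = FALSE)
  args <- c(df[forcing_profile_fields],
            list(aero_flux = get_scalar("aero_flux"),
                 river_flux = get_scalar("river_flux")))
  do.call(cu_forcing, c(list(grid), args))
}
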