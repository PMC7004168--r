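#' Quota-regulated copper uptake rate
#'
#' Specific Cu uptake by a phytoplankton group, per mol of cellular
#' phosphorus:
#' \deqn{Up = \mu_{max}\,\theta_{max}\,\frac{bCu}{bCu + ks}\,
#'       \frac{1 - \theta/\theta_{max}}{c - \theta/\theta_{max}}}
#' with `c` the quota-regulation constant (> 1). Uptake follows
#' Michaelis-Menten kinetics in the bioavailable Cu concentration `bCu` and is
#' down-regulated as the cellular Cu:P quota `theta` approaches its maximum,
#' vanishing exactly at `theta = theta_max`. Multiplying by the cell's
#' phosphorus biomass gives the volumetric dissolved-Cu sink.
#'
#' @param bCu Bioavailable Cu, nmol/L (total dissolved Cu or inorganic Cu'
#'   depending on the scenario's bioavailability switch).
#' @param theta Current cellular Cu:P quota, molCu/molP, in
#'   `[0, theta_max]`.
#' @param group `"N"` (nanophytoplankton) or `"D"` (diatoms); selects the
#'   half-saturation constant.
#' @param params A [cu_params()].
#' @return Specific uptake, molCu molP-1 day-1 (vectorized over `bCu` /
#'   `theta`).
#' @examples
#' p <- cu_params()
#' uptake_rate(4, 0, "N", p)   # half-saturated, empty quota: 1e-3
#' @export
uptake_rate <- function(bCu, theta, group = c("N", "D"), params = cu_params()) {
  group <- match.arg(group)
  if (any(bCu < 0)) stop("'bCu' must be >= 0", call. = FALSE)
  if (any(theta < 0)) stop("'theta' must be >= 0", call. = FALSE)
  if (any(theta > params$theta_max * (1 + 1e-12)))
    stop("quota violation: 'theta' exceeds theta_max", call. = FALSE)
  ks <- if (group == "N") params$ksCu_N else params$ksCu_D
  rel <- .cap1(theta / params$theta_max)
  mm <- bCu / (bCu + ks)
  params$mu_max * params$theta_max * mm *
    (1 - rel) / (params$quota_reg_const - rel)
}

#' Reversible scavenging tendency
#'
#' Adsorption/desorption exchange of inorganic copper with one sinking
#' particle class. The equilibrium scavenged concentration is
#' `Cu' * ztrc / (ztrc + 1)` with `ztrc = PartC * KD`; the tendency relaxes
#' the scavenged pool towards it over the timescale `tau_scav`:
#' positive values transfer dissolved Cu' to the scavenged pool (net
#' scavenging, where particles are abundant), negative values release
#' scavenged Cu back to solution (net desorption, where the particle load is
#' low). Ligand-bound CuL is protected from scavenging. With
#' `params$reversible = FALSE` (iron-like scavenging) the desorption branch is
#' clamped to zero and scavenged Cu can return to solution only through
#' bacterial remineralization.
#'
#' @param Cu_prime Inorganic dissolved Cu, nmol/L.
#' @param SCu Cu currently scavenged on this particle class, nmol/L.
#' @param PartC Particulate organic carbon of the class, mmolC/m3.
#' @param KD Partition coefficient of the class, m3/mmolC.
#' @param params A [cu_params()] (supplies `tau_scav` and `reversible`).
#' @return Net adsorption tendency, nmol L-1 day-1 (signed; vectorized).
#' @examples
#' scavenging_flux(0.001, 0, 10, 100e-3)   # ztrc = 1: 5e-4 nmol/L/day
#' @export
scavenging_flux <- function(Cu_prime, SCu, PartC, KD, params = cu_params()) {
  if (any(Cu_prime < 0) || any(SCu < 0) || any(PartC < 0) || any(KD < 0))
    stop("scavenging inputs must be >= 0", call. = FALSE)
  ztrc <- PartC * KD
  disp <- ztrc / (ztrc + 1) * Cu_prime - SCu
  if (!params$reversible) disp <- pmax(disp, 0)
  disp / params$tau_scav
}

#' First-order remineralization of particulate copper
#'
#' Bacterial conversion of biogenic particulate Cu back to the dissolved
#' pool, at rate `lambda_remin` per day.
#'
#' @param CuPart Particulate Cu, nmol/L.
#' @param params A [cu_params()].
#' @return Dissolved-Cu source, nmol L-1 day-1.
#' @export
remineralization <- function(CuPart, params = cu_params()) {
  if (any(CuPart < 0)) stop("'CuPart' must be >= 0", call. = FALSE)
  params$lambda_remin * CuPart
}

#' Partition grazed copper between retention, recycling and excretion
#'
#' Zooplankton graze phytoplankton Cu at `graz * Cu_phi`. They hold a fixed
#' Cu:C quota (`curat`) and no explicit Cu tracer, so of the grazed copper
#' they retain up to `curat` times the grazed carbon; of the remainder a
#' fraction `sigma_recycle` is recycled to dissolved Cu and the rest is
#' excreted to large biogenic particles as fecal pellets. The three routes
#' sum to the grazed copper exactly.
#'
#' @param Cu_phi Phytoplankton Cu, nmol/L.
#' @param graz Grazing rate, 1/day.
#' @param C_grazed Grazed carbon, mmolC m-3 day-1.
#' @param params A [cu_params()].
#' @return List of `recycled_to_DCu`, `excreted_to_CuPart` and `retained`
#'   (nmol L-1 day-1 each; vectorized).
#' @examples
#' # grazed Cu 1.0, retention cap 0.4, sigma 0.5 -> 0.3 recycled, 0.3 excreted
#' grazing_partition(10, 0.1, 40, cu_params(sigma_recycle = 0.5))
#' @export
grazing_partition <- function(Cu_phi, graz, C_grazed, params = cu_params()) {
  if (any(Cu_phi < 0) || any(graz < 0) || any(C_grazed < 0))
    stop("grazing inputs must be >= 0", call. = FALSE)
  grazed <- graz * Cu_phi
  # curat [umolCu/molC] * C_grazed [mmolC/m3/day] -> 1e-3 nmol L-1 day-1
  cap <- 1e-3 * params$curat * C_grazed
  retained <- grazed + (cap - grazed) * (cap < grazed)   # pmin(grazed, cap)
  leftover <- grazed - retained
  list(recycled_to_DCu = params$sigma_recycle * leftover,
       excreted_to_CuPart = (1 - params$sigma_recycle) * leftover,
       retained = retained)
}

#' Mortality transfer of phytoplankton copper to small particles
#'
#' @param Cu_phi Phytoplankton Cu, nmol/L.
#' @param mort Mortality rate, 1/day.
#' @param params A [cu_params()] (unused; kept for a uniform operator
#'   signature).
#' @return Source to small biogenic particulate Cu (equal to the sink from the
#'   phytoplankton pool), nmol L-1 day-1.
#' @export
mortality_transfer <- function(Cu_phi, mort, params = cu_params()) {
  if (any(Cu_phi < 0) || any(mort < 0))
    stop("mortality inputs must be >= 0", call. = FALSE)
  mort * Cu_phi
}

#' Aggregation of small into large particles
#'
#' Small biogenic particulate Cu and small-particle scavenged Cu aggregate
#' into their large-particle counterparts at `agg_rate`; total particulate Cu
#' is unchanged.
#'
#' @param pCuPart Small biogenic particulate Cu, nmol/L.
#' @param SCup Small-particle scavenged Cu, nmol/L.
#' @param agg_rate Aggregation rate, 1/day.
#' @return List of `CuPart_to_large` and `SCu_to_large`, nmol L-1 day-1.
#' @export
aggregation_transfer <- function(pCuPart, SCup, agg_rate) {
  if (any(pCuPart < 0) || any(SCup < 0) || any(agg_rate < 0))
    stop("aggregation inputs must be >= 0", call. = FALSE)
  list(CuPart_to_large = agg_rate * pCuPart,
       SCu_to_large = agg_rate * SCup)
}

#' Surface copper sources from aerosol deposition and rivers
#'
#' Aerosol Cu dissolves instantaneously upon deposition with solubility
#' `Sol_Cu`; riverine Cu arrives fully dissolved. Both enter the dissolved
#' pool of the top grid cell only.
#'
#' @param state A [cu_state()] (unused; kept for a uniform operator
#'   signature).
#' @param forcing A [cu_forcing()] supplying `aero_flux` (total deposition)
#'   and `river_flux`, nmol m-2 day-1.
#' @param params A [cu_params()] supplying `Sol_Cu`.
#' @param thickness_top Thickness of the top cell, m.
#' @return Dissolved-Cu source in the top cell, nmol L-1 day-1.
#' @examples
#' f <- cu_forcing(column_grid(n_levels = 1), aero_flux = 100)
#' external_sources(NULL, f, cu_params(), 10)   # 4e-3 nmol/L/day
#' @export
external_sources <- function(state, forcing, params, thickness_top) {
  if (thickness_top <= 0) stop("'thickness_top' must be > 0", call. = FALSE)
  # nmol m-2 day-1 / m = nmol m-3 day-1 = 1e-3 nmol L-1 day-1
  (forcing$aero_flux * params$Sol_Cu + forcing$river_flux) /
    thickness_top * 1e-3
}

# Branch-free clamps (hot path; avoid pmin/pmax attribute handling).
.clamp_pos <- function(x) x * (x > 0)                  # pmax(x, 0)
.cap1 <- function(x) 1 + (x - 1) * (x < 1)             # pmin(x, 1)

# All per-cell process fluxes (nmol L-1 day-1), unlimited. Each flux is a
# transfer with a single source pool; `dt` (days), when given, scales every
# flux out of a pool so the pool cannot be driven negative within the step
# (flux limiting preserves pairwise conservation exactly).
cu_process_fluxes <- function(state, forcing, params, grid, dt = NULL) {
  s <- unclass(state)
  sp <- solve_speciation(s[, "DCu"],
                         ligand_system(params$L_total, params$K_L))
  bCu <- if (params$bioavailable_pool == "CU_PRIME") sp$Cu_prime
         else s[, "DCu"]

  p_floor <- 1e-6  # umolP/L below which a group is treated as absent
  theta_of <- function(cu, p) 1e-3 * cu / (p + p_floor) * (p > p_floor)
  theta_N <- params$theta_max * .cap1(theta_of(s[, "CuN"], forcing$P_N) / params$theta_max)
  theta_D <- params$theta_max * .cap1(theta_of(s[, "CuD"], forcing$P_D) / params$theta_max)
  # specific rate [molCu/molP/day] * P [umolP/L] * 1e3 -> nmol/L/day
  up_N <- uptake_rate(bCu, theta_N, "N", params) * forcing$P_N * 1e3
  up_D <- uptake_rate(bCu, theta_D, "D", params) * forcing$P_D * 1e3

  scav_p <- scavenging_flux(sp$Cu_prime, s[, "SCup"], forcing$PartC_p,
                            params$KD_p, params)
  scav_g <- scavenging_flux(sp$Cu_prime, s[, "SCug"], forcing$PartC_g,
                            params$KD_g, params)

  remin_p <- remineralization(s[, "pCuPart"], params)
  remin_g <- remineralization(s[, "gCuPart"], params)
  # Irreversibly scavenged Cu is remobilized by bacterial activity only.
  if (!params$reversible) {
    remin_sp <- remineralization(s[, "SCup"], params)
    remin_sg <- remineralization(s[, "SCug"], params)
  } else {
    remin_sp <- remin_sg <- numeric(nrow(s))
  }

  graz_N_rate <- forcing$graz_Z_on_N + forcing$graz_M_on_N
  graz_D_rate <- forcing$graz_Z_on_D + forcing$graz_M_on_D
  # Redfield carbon biomass: 106 * P [umolP/L = mmolP/m3] -> mmolC/m3
  gp_N <- grazing_partition(s[, "CuN"], graz_N_rate,
                            graz_N_rate * 106 * forcing$P_N, params)
  gp_D <- grazing_partition(s[, "CuD"], graz_D_rate,
                            graz_D_rate * 106 * forcing$P_D, params)

  mort_N <- mortality_transfer(s[, "CuN"], forcing$mort_N, params)
  mort_D <- mortality_transfer(s[, "CuD"], forcing$mort_D, params)
  agg <- aggregation_transfer(s[, "pCuPart"], s[, "SCup"], forcing$agg_rate)

  ext <- numeric(nrow(s))
  ext[1] <- external_sources(state, forcing, params, grid$thickness[1])

  fl <- list(up_N = up_N, up_D = up_D,
             scav_p_pos = .clamp_pos(scav_p), scav_p_neg = .clamp_pos(-scav_p),
             scav_g_pos = .clamp_pos(scav_g), scav_g_neg = .clamp_pos(-scav_g),
             remin_p = remin_p, remin_g = remin_g,
             remin_sp = remin_sp, remin_sg = remin_sg,
             graz_N = graz_N_rate * s[, "CuN"],
             graz_D = graz_D_rate * s[, "CuD"],
             recycled_N = gp_N$recycled_to_DCu,
             recycled_D = gp_D$recycled_to_DCu,
             excreted_N = gp_N$excreted_to_CuPart,
             excreted_D = gp_D$excreted_to_CuPart,
             retained_N = gp_N$retained, retained_D = gp_D$retained,
             mort_N = mort_N, mort_D = mort_D,
             agg_p = agg$CuPart_to_large, agg_s = agg$SCu_to_large,
             ext = ext)

  if (!is.null(dt)) {
    lim <- function(pool, outflow) {
      .cap1(pool / (dt * outflow + .Machine$double.xmin))
    }
    f_DCu <- lim(s[, "DCu"],
                 fl$up_N + fl$up_D + fl$scav_p_pos + fl$scav_g_pos)
    f_SCup <- lim(s[, "SCup"], fl$scav_p_neg + fl$agg_s + fl$remin_sp)
    f_SCug <- lim(s[, "SCug"], fl$scav_g_neg + fl$remin_sg)
    f_pCuPart <- lim(s[, "pCuPart"], fl$remin_p + fl$agg_p)
    f_gCuPart <- lim(s[, "gCuPart"], fl$remin_g)
    f_CuN <- lim(s[, "CuN"], fl$graz_N + fl$mort_N)
    f_CuD <- lim(s[, "CuD"], fl$graz_D + fl$mort_D)
    for (nm in c("up_N", "up_D", "scav_p_pos", "scav_g_pos"))
      fl[[nm]] <- fl[[nm]] * f_DCu
    for (nm in c("scav_p_neg", "agg_s", "remin_sp"))
      fl[[nm]] <- fl[[nm]] * f_SCup
    for (nm in c("scav_g_neg", "remin_sg")) fl[[nm]] <- fl[[nm]] * f_SCug
    for (nm in c("remin_p", "agg_p")) fl[[nm]] <- fl[[nm]] * f_pCuPart
    fl$remin_g <- fl$remin_g * f_gCuPart
    for (nm in c("graz_N", "recycled_N", "excreted_N", "retained_N"))
      fl[[nm]] <- fl[[nm]] * f_CuN
    fl$mort_N <- fl$mort_N * f_CuN
    for (nm in c("graz_D", "recycled_D", "excreted_D", "retained_D"))
      fl[[nm]] <- fl[[nm]] * f_CuD
    fl$mort_D <- fl$mort_D * f_CuD
  }
  fl
}

# Assemble the seven tracer tendencies (nmol L-1 day-1) from process fluxes.
assemble_tendencies <- function(fl) {
  cbind(DCu = fl$ext + fl$recycled_N + fl$recycled_D +
              fl$retained_N + fl$retained_D +
              fl$remin_p + fl$remin_g + fl$remin_sp + fl$remin_sg +
              fl$scav_p_neg + fl$scav_g_neg -
              fl$up_N - fl$up_D - fl$scav_p_pos - fl$scav_g_pos,
        SCup = fl$scav_p_pos - fl$scav_p_neg - fl$agg_s - fl$remin_sp,
        SCug = fl$scav_g_pos - fl$scav_g_neg + fl$agg_s - fl$remin_sg,
        pCuPart = fl$mort_N + fl$mort_D - fl$remin_p - fl$agg_p,
        gCuPart = fl$excreted_N + fl$excreted_D + fl$agg_p - fl$remin_g,
        CuN = fl$up_N - fl$mort_N - fl$graz_N,
        CuD = fl$up_D - fl$mort_D - fl$graz_D)
}

#' Local tracer tendencies
#'
#' Sums every biogeochemical source and sink -- uptake, scavenging exchange,
#' remineralization, grazing recycling/excretion, mortality, aggregation and
#' the surface external inputs -- into per-cell time derivatives of the seven
#' copper tracers. Every internal sink of one pool is a source of another
#' (copper retained by the implicit zooplankton pool, which is held at fixed
#' quota and hence at steady state, re-enters as large biogenic particles),
#' so the tendencies sum to the external input exactly.
#'
#' @param state A [cu_state()].
#' @param forcing A [cu_forcing()] on the same grid.
#' @param params A [cu_params()].
#' @param grid A [column_grid()] (needed for the top-cell thickness).
#' @return A list: `tendencies` (matrix, cells x tracers, nmol L-1 day-1),
#'   `retention` (per-cell flux passing through the implicit zooplankton pool
#'   on its way to large particles; diagnostic), `external` (per-cell surface
#'   source) and `fluxes` (the per-process flux vectors).
#' @examples
#' g <- column_grid(n_levels = 3, total_depth = 30)
#' td <- cu_tendencies(cu_state(g, DCu = 0.5), cu_forcing(g), cu_params(), g)
#' rowSums(td$tendencies)   # closed, unforced cells: all zero
#' @export
cu_tendencies <- function(state, forcing, params, grid) {
  fl <- cu_process_fluxes(state, forcing, params, grid)
  list(tendencies = assemble_tendencies(fl),
       retention = fl$retained_N + fl$retained_D,
       external = fl$ext,
       fluxes = fl)
}
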