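#' Copper model parameters
#'
#' Collects every constant of the copper cycling model: aerosol solubility,
#' zooplankton Cu:C, uptake half-saturation constants, the maximum cellular
#' Cu:P quota, scavenging partition coefficients, the ligand stability
#' constant, plus the auxiliary rates (remineralization, sinking, recycling
#' partition, scavenging relaxation) the column model needs but which the
#' global model this emulates inherits from its host ecosystem model.
#'
#' @param Sol_Cu Solubility of aerosol copper upon deposition, dimensionless
#'   fraction in `[0, 1]`. Default 0.40.
#' @param curat Fixed Cu:C ratio of zooplankton, umolCu/molC. Grazed copper up
#'   to `curat` times the grazed carbon is retained by the (implicit)
#'   zooplankton pool. Default 10.
#' @param ksCu_N,ksCu_D Half-saturation constants for Cu uptake by
#'   nanophytoplankton and diatoms, nmolCu/L. Defaults 4 and 12 (for uptake of
#'   total dissolved Cu).
#' @param theta_max Maximum cellular Cu:P quota, molCu/molP. Default 2e-3.
#' @param KD_p,KD_g Scavenging partition coefficients for small and large
#'   particles, m3/mmolC, so that `ztrc = PartC * KD` is dimensionless.
#'   Defaults 100e-3 and 5e-3.
#' @param K_L Conditional stability constant of the Cu-binding ligand, L/mol.
#'   Default `10^13.5`.
#' @param L_total Total ligand concentration, nmol/L, uniform. Default 1.
#' @param mu_max Maximum phytoplankton growth rate, 1/day, shared by both
#'   groups. Default 1.05.
#' @param quota_reg_const Dimensionless constant in the quota-regulation
#'   denominator `(1 - theta/theta_max) / (quota_reg_const - theta/theta_max)`;
#'   must exceed 1. Default 1.05.
#' @param lambda_remin First-order remineralization rate of biogenic
#'   particulate Cu, 1/day. Default 0.03.
#' @param tau_scav Relaxation timescale towards the scavenging equilibrium,
#'   days. The adsorption/desorption exchange is fast compared with sinking,
#'   so results are insensitive to this value provided it stays well below the
#'   particle transit time. Default 1.
#' @param w_small Sinking speed of small particles, m/day, depth-constant.
#'   Default 2.
#' @param w_large_surface,w_large_deep Large-particle sinking speed at the
#'   surface and its deep asymptote, m/day. Speed increases linearly from
#'   `w_large_surface` below `z_sink_ref`, reaching `w_large_deep` 2000 m
#'   deeper. Defaults 50 and 200.
#' @param z_sink_ref Depth below which large-particle sinking accelerates, m.
#'   Default 100.
#' @param sigma_recycle Fraction of non-retained grazed Cu recycled to the
#'   dissolved pool (the remainder is excreted to large biogenic particles),
#'   dimensionless in `[0, 1]`. Default 0.5.
#' @param reversible Logical; if `TRUE` (default) scavenging is a reversible
#'   exchange (desorption where particles are scarce), if `FALSE` adsorption
#'   is one-way and scavenged Cu is returned only by bacterial
#'   remineralization (iron-like scavenging).
#' @param bioavailable_pool Which dissolved pool phytoplankton can take up:
#'   `"ALL_DCU"` (total dissolved Cu, default) or `"CU_PRIME"` (inorganic Cu'
#'   only).
#' @return An object of class `cu_params` (a named list).
#' @seealso [scenario_params()] for the named experiment presets.
#' @export
cu_params <- function(Sol_Cu = 0.40,
                      curat = 10,
                      ksCu_N = 4,
                      ksCu_D = 12,
                      theta_max = 2e-3,
                      KD_p = 100e-3,
                      KD_g = 5e-3,
                      K_L = 10^13.5,
                      L_total = 1,
                      mu_max = 1.05,
                      quota_reg_const = 1.05,
                      lambda_remin = 0.03,
                      tau_scav = 1,
                      w_small = 2,
                      w_large_surface = 50,
                      w_large_deep = 200,
                      z_sink_ref = 100,
                      sigma_recycle = 0.5,
                      reversible = TRUE,
                      bioavailable_pool = c("ALL_DCU", "CU_PRIME")) {
  bioavailable_pool <- match.arg(toupper(bioavailable_pool),
                                 c("ALL_DCU", "CU_PRIME"))
  p <- list(Sol_Cu = Sol_Cu, curat = curat, ksCu_N = ksCu_N, ksCu_D = ksCu_D,
            theta_max = theta_max, KD_p = KD_p, KD_g = KD_g, K_L = K_L,
            L_total = L_total, mu_max = mu_max,
            quota_reg_const = quota_reg_const, lambda_remin = lambda_remin,
            tau_scav = tau_scav, w_small = w_small,
            w_large_surface = w_large_surface, w_large_deep = w_large_deep,
            z_sink_ref = z_sink_ref, sigma_recycle = sigma_recycle,
            reversible = isTRUE(reversible),
            bioavailable_pool = bioavailable_pool)
  validate_cu_params(p)
  structure(p, class = "cu_params")
}

validate_cu_params <- function(p) {
  num <- c("Sol_Cu", "curat", "ksCu_N", "ksCu_D", "theta_max", "KD_p", "KD_g",
           "K_L", "mu_max", "quota_reg_const", "lambda_remin", "tau_scav",
           "w_small", "w_large_surface", "w_large_deep", "z_sink_ref",
           "sigma_recycle")
  for (nm in num) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("parameter '%s' must be a single finite number", nm),
           call. = FALSE)
  }
  strictly_pos <- c("curat", "ksCu_N", "ksCu_D", "theta_max", "KD_p", "KD_g",
                    "K_L", "mu_max", "lambda_remin", "tau_scav", "w_small",
                    "w_large_surface", "w_large_deep", "z_sink_ref")
  for (nm in strictly_pos)
    if (p[[nm]] <= 0)
      stop(sprintf("parameter '%s' must be > 0", nm), call. = FALSE)
  if (p$Sol_Cu < 0 || p$Sol_Cu > 1)
    stop("'Sol_Cu' must lie in [0, 1]", call. = FALSE)
  if (p$sigma_recycle < 0 || p$sigma_recycle > 1)
    stop("'sigma_recycle' must lie in [0, 1]", call. = FALSE)
  if (p$quota_reg_const <= 1)
    stop("'quota_reg_const' must be > 1", call. = FALSE)
  if (!is.numeric(p$L_total) || any(p$L_total < 0))
    stop("'L_total' must be >= 0", call. = FALSE)
  invisible(p)
}

#' @export
print.cu_params <- function(x, ...) {
  cat("Cu model parameters\n")
  cat(sprintf("  scavenging: KD_p = %g, KD_g = %g m3/mmolC, %s\n",
              x$KD_p, x$KD_g,
              if (x$reversible) "reversible" else "irreversible (Fe-like)"))
  cat(sprintf("  uptake: ks = %g/%g nmol/L (N/D) on %s, theta_max = %g molCu/molP\n",
              x$ksCu_N, x$ksCu_D, x$bioavailable_pool, x$theta_max))
  cat(sprintf("  ligand: L = %g nmol/L, K_L = 10^%.2f L/mol\n",
              x$L_total[1], log10(x$K_L)))
  cat(sprintf("  sources: aerosol solubility %g; zooplankton Cu:C %g umol/molC\n",
              x$Sol_Cu, x$curat))
  invisible(x)
}

# Named experiment presets: partition coefficients, scavenging mode,
# half-saturation constants and the bioavailable-pool switch.
scenario_table <- function() {
  list(
    REF           = list(KD_p = 100e-3, KD_g = 5e-3, reversible = TRUE,
                         ksCu_N = 4, ksCu_D = 12,
                         bioavailable_pool = "ALL_DCU"),
    LOWSCAV       = list(KD_p = 50e-3, KD_g = 1e-3, reversible = TRUE,
                         ksCu_N = 4, ksCu_D = 12,
                         bioavailable_pool = "ALL_DCU"),
    HIGHSCAV      = list(KD_p = 200e-3, KD_g = 10e-3, reversible = TRUE,
                         ksCu_N = 4, ksCu_D = 12,
                         bioavailable_pool = "ALL_DCU"),
    FESCAV        = list(KD_p = 100e-3, KD_g = 5e-3, reversible = FALSE,
                         ksCu_N = 4, ksCu_D = 12,
                         bioavailable_pool = "ALL_DCU"),
    INORGANIC_CU  = list(KD_p = 100e-3, KD_g = 5e-3, reversible = TRUE,
                         ksCu_N = 4, ksCu_D = 12,
                         bioavailable_pool = "CU_PRIME"),
    INORGANIC_CU2 = list(KD_p = 100e-3, KD_g = 5e-3, reversible = TRUE,
                         ksCu_N = 0.01, ksCu_D = 0.03,
                         bioavailable_pool = "CU_PRIME")
  )
}

#' List the named simulation scenarios
#'
#' @return A data frame with one row per preset scenario and its defining
#'   parameters: partition coefficients, scavenging reversibility, uptake
#'   half-saturation constants and the bioavailable Cu pool.
#' @examples
#' list_scenarios()
#' @export
list_scenarios <- function() {
  tab <- scenario_table()
  data.frame(name = names(tab),
             KD_p = vapply(tab, `[[`, 0, "KD_p"),
             KD_g = vapply(tab, `[[`, 0, "KD_g"),
             reversible = vapply(tab, `[[`, TRUE, "reversible"),
             ksCu_N = vapply(tab, `[[`, 0, "ksCu_N"),
             ksCu_D = vapply(tab, `[[`, 0, "ksCu_D"),
             bioavailable_pool = vapply(tab, `[[`, "", "bioavailable_pool"),
             row.names = NULL)
}

#' Parameters for a named scenario
#'
#' Builds a full [cu_params()] set from one of the preset experiments,
#' optionally with further overrides.
#'
#' @param name Scenario name: `"REF"`, `"LOWSCAV"`, `"HIGHSCAV"`, `"FESCAV"`,
#'   `"INORGANIC_CU"` or `"INORGANIC_CU2"` (hyphens accepted in place of
#'   underscores).
#' @param ... Named [cu_params()] arguments overriding the preset.
#' @return A `cu_params` object with attribute `"scenario"` set to `name`.
#' @examples
#' scenario_params("HIGHSCAV")$KD_p   # 0.2
#' @export
scenario_params <- function(name = "REF", ...) {
  key <- toupper(gsub("-", "_", name))
  tab <- scenario_table()
  if (!key %in% names(tab))
    stop("unknown scenario '", name, "'; valid: ",
         paste(names(tab), collapse = ", "), call. = FALSE)
  args <- utils::modifyList(tab[[key]], list(...))
  p <- do.call(cu_params, args)
  attr(p, "scenario") <- key
  p
}
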