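#' One-ligand copper speciation system
#'
#' Defines the organic ligand pool that complexes dissolved copper. A single
#' bulk ligand class `L` binds inorganic copper through
#' `Cu' + L <-> CuL` with conditional stability constant `K_L`
#' (`K_L = [CuL] / ([Cu'] [L_free])`, concentrations in mol/L). The default
#' values -- 1 nmol/L of ligand and `K_L = 10^13.5` L/mol -- are a bulk
#' average over the strong and weak ligand classes observed in seawater, and
#' keep more than 99% of surface dissolved Cu organically complexed.
#'
#' @param L_total Total ligand concentration, nmol/L. May be a scalar or a
#'   vector (one value per grid cell) for sensitivity runs with a ligand
#'   profile. Must be non-negative.
#' @param K_L Conditional stability constant for `Cu' + L = CuL`, L/mol
#'   (free-ligand convention). Must be strictly positive.
#' @return An object of class `ligand_system`: a list with elements
#'   `L_total` and `K_L`.
#' @examples
#' lig <- ligand_system()            # 1 nM, 10^13.5 L/mol
#' solve_speciation(0.83, lig)
#' @seealso [solve_speciation()]
#' @export
ligand_system <- function(L_total = 1, K_L = 10^13.5) {
  if (!is.numeric(L_total) || any(!is.finite(L_total)) || any(L_total < 0))
    stop("'L_total' must be finite and >= 0 (nmol/L)", call. = FALSE)
  if (!is.numeric(K_L) || length(K_L) != 1L || !is.finite(K_L) || K_L <= 0)
    stop("'K_L' must be a single finite value > 0 (L/mol)", call. = FALSE)
  structure(list(L_total = as.numeric(L_total), K_L = as.numeric(K_L)),
            class = "ligand_system")
}

#' Equilibrium partitioning of dissolved copper between Cu' and CuL
#'
#' Solves the mass-action system
#' \deqn{K_L [Cu'] [L_{free}] = [CuL], \quad
#'       [Cu'] + [CuL] = DCu, \quad
#'       [L_{free}] + [CuL] = L_{total}}
#' in closed form. Eliminating either unknown gives a quadratic; each output
#' is computed from the numerically stable root expression
#' (the `2c / (b + sqrt(b^2 - 4ac))` branch), which avoids catastrophic
#' cancellation when `K_L * L_total >> 1` and nearly all Cu is complexed --
#' the regime that holds throughout the ocean at the default ligand load.
#'
#' Speciation is treated as instantaneous: ligand production and degradation
#' kinetics are not modelled, and the equilibrium is recomputed from the
#' current `DCu` whenever it is needed.
#'
#' @param DCu Total dissolved copper, nmol/L (scalar or vector). The sum of
#'   inorganic `Cu'` and ligand-bound `CuL`.
#' @param ligands A [ligand_system()]. `L_total` is recycled against `DCu`.
#' @return An object of class `cu_speciation`: a list of numeric vectors
#'   `Cu_prime`, `CuL`, `L_free` (all nmol/L) and `fraction_bound`
#'   (`CuL / DCu`, in `[0, 1]`; defined as 0 where `DCu = 0`).
#' @examples
#' sp <- solve_speciation(0.83, ligand_system(1, 10^13.5))
#' sp$fraction_bound        # > 0.99
#' @export
solve_speciation <- function(DCu, ligands = ligand_system()) {
  if (!inherits(ligands, "ligand_system"))
    ligands <- do.call(ligand_system, as.list(ligands))
  if (!is.numeric(DCu) || any(!is.finite(DCu)))
    stop("'DCu' must be finite (nmol/L)", call. = FALSE)
  if (any(DCu < 0))
    stop("'DCu' must be >= 0 (nmol/L)", call. = FALSE)
  n <- max(length(DCu), length(ligands$L_total))
  DCu <- rep_len(as.numeric(DCu), n)
  L <- rep_len(ligands$L_total, n)
  K <- ligands$K_L * 1e-9   # L/mol -> per (nmol/L)

  # Cu' is the positive root of K y^2 + b y - DCu = 0 with
  # b = K (L - DCu) + 1; pick the branch that adds same-sign quantities so
  # neither regime (excess ligand or excess copper) cancels.
  stable_root <- function(b, c0) {
    disc <- sqrt(b * b + 4 * K * c0)
    ifelse(b >= 0, 2 * c0 / (b + disc), (disc - b) / (2 * K))
  }
  cu_prime <- stable_root(K * (L - DCu) + 1, DCu)
  # L_free solves the symmetric quadratic (roles of DCu and L swapped).
  l_free <- stable_root(K * (DCu - L) + 1, L)
  # CuL from mass action on the two well-conditioned roots (the direct CuL
  # quadratic has a discriminant that cancels when DCu ~ L at large K).
  cul <- K * cu_prime * l_free

  frac <- cul / (DCu + .Machine$double.xmin)
  cap01 <- function(x) {x <- x * (x > 0); 1 + (x - 1) * (x < 1)}
  structure(list(Cu_prime = cu_prime * (cu_prime > 0),
                 CuL = cul * (cul > 0),
                 L_free = l_free * (l_free > 0),
                 fraction_bound = cap01(frac)),
            class = "cu_speciation")
}

#' @export
print.cu_speciation <- function(x, ...) {
  n <- length(x$CuL)
  cat("Cu speciation (", n, if (n == 1L) " sample" else " samples", ")\n",
      sep = "")
  df <- data.frame(Cu_prime = x$Cu_prime, CuL = x$CuL,
                   L_free = x$L_free, fraction_bound = x$fraction_bound)
  print(utils::head(df, 10), ...)
  if (n > 10L) cat("... (", n - 10L, " more)\n", sep = "")
  invisible(x)
}
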