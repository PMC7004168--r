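cu_tracers <- c("DCu", "SCup", "SCug", "pCuPart", "gCuPart", "CuN", "CuD")

#' Copper tracer state on a vertical grid
#'
#' The seven copper tracers, each a concentration profile in nmol/L:
#' dissolved Cu (`DCu`), Cu scavenged onto small and large particles
#' (`SCup`, `SCug`), Cu in small and large biogenic particles (`pCuPart`,
#' `gCuPart`), and Cu held in nanophytoplankton and diatom biomass
#' (`CuN`, `CuD`).
#'
#' @param grid A [column_grid()].
#' @param DCu,SCup,SCug,pCuPart,gCuPart,CuN,CuD Initial profiles, nmol/L;
#'   scalars are recycled over the column. All must be non-negative.
#' @return An object of class `cu_state`: a numeric matrix with one row per
#'   grid cell and one column per tracer.
#' @examples
#' st <- cu_state(column_grid(n_levels = 5), DCu = 0.5)
#' colnames(st)
#' @export
cu_state <- function(grid, DCu = 0, SCup = 0, SCug = 0, pCuPart = 0,
                     gCuPart = 0, CuN = 0, CuD = 0) {
  n <- grid$n_levels
  vals <- list(DCu, SCup, SCug, pCuPart, gCuPart, CuN, CuD)
  m <- vapply(vals, function(v) rep_len(as.numeric(v), n), numeric(n))
  if (n == 1L) m <- matrix(m, nrow = 1L)
  colnames(m) <- cu_tracers
  if (any(!is.finite(m)) || any(m < 0))
    stop("all tracer concentrations must be finite and >= 0", call. = FALSE)
  structure(m, class = c("cu_state", "matrix", "array"))
}

as_cu_state <- function(m) {
  structure(m, class = c("cu_state", "matrix", "array"))
}

#' @export
print.cu_state <- function(x, ...) {
  cat("Cu tracer state (nmol/L), ", nrow(x), " levels\n", sep = "")
  print(utils::head(unclass(x), 8), ...)
  if (nrow(x) > 8L) cat("... (", nrow(x) - 8L, " more levels)\n", sep = "")
  invisible(x)
}

# Volume-weighted column inventory per tracer, nmol/m^2.
# 1 nmol/L = 1000 nmol/m^3, integrated over cell thickness in m.
state_inventory <- function(state, grid) {
  colSums(unclass(state) * (1000 * grid$thickness))
}
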