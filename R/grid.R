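#' Vertical grid for the water column
#'
#' Builds a 1-D vertical grid, positive downward from the sea surface. The
#' default resolves the upper ocean at `upper_res` metres down to
#' `upper_depth`, then stretches geometrically to `total_depth`, which
#' resolves both the euphotic zone and the deep dissolved-copper gradient at
#' negligible cost. With `n_levels = 1` the column degenerates to a 0-D box.
#'
#' @param n_levels Number of cells. Default 50.
#' @param total_depth Depth of the bottom interface, m. Default 5000.
#' @param upper_depth Depth of the uniformly resolved upper layer, m.
#'   Default 200.
#' @param upper_res Cell thickness within the upper layer, m. Default 10.
#' @param z_edges Optional explicit interface depths (overrides the other
#'   arguments); strictly increasing from 0.
#' @return An object of class `column_grid`: list with `n_levels`, `z_edges`
#'   (length `n_levels + 1`, starting at 0), `z_centers` and `thickness`
#'   (each length `n_levels`), all in metres.
#' @examples
#' g <- column_grid()
#' range(g$thickness)
#' @export
column_grid <- function(n_levels = 50, total_depth = 5000,
                        upper_depth = 200, upper_res = 10, z_edges = NULL) {
  if (is.null(z_edges)) {
    if (n_levels < 1) stop("'n_levels' must be >= 1", call. = FALSE)
    if (n_levels == 1L) {
      z_edges <- c(0, total_depth)
    } else {
      n_upper <- min(n_levels - 1L, as.integer(round(upper_depth / upper_res)))
      upper <- seq(0, by = upper_res, length.out = n_upper + 1L)
      n_lower <- n_levels - n_upper
      remaining <- total_depth - upper[length(upper)]
      if (remaining <= 0)
        stop("'total_depth' must exceed the uniformly resolved layer",
             call. = FALSE)
      # geometric stretching: upper_res * sum_{k=1..n_lower} r^k = remaining
      f <- function(r) upper_res * sum(r^seq_len(n_lower)) - remaining
      if (f(1) >= 0 || n_lower == 1L) {
        lower <- rep(remaining / n_lower, n_lower)
      } else {
        hi <- 2
        while (f(hi) < 0) hi <- hi * 2
        r <- stats::uniroot(f, c(1 + 1e-9, hi), tol = 1e-12)$root
        lower <- upper_res * r^seq_len(n_lower)
        lower <- lower * remaining / sum(lower)  # exact closure
      }
      z_edges <- c(upper, upper[length(upper)] + cumsum(lower))
    }
  }
  z_edges <- as.numeric(z_edges)
  if (length(z_edges) < 2L || z_edges[1] != 0 || any(diff(z_edges) <= 0))
    stop("'z_edges' must be strictly increasing from 0", call. = FALSE)
  thickness <- diff(z_edges)
  structure(list(n_levels = length(thickness),
                 z_edges = z_edges,
                 z_centers = z_edges[-length(z_edges)] + thickness / 2,
                 thickness = thickness),
            class = "column_grid")
}

#' @export
print.column_grid <- function(x, ...) {
  cat(sprintf("Water-column grid: %d levels, 0-%g m (cells %g-%g m thick)\n",
              x$n_levels, max(x$z_edges),
              signif(min(x$thickness), 3), signif(max(x$thickness), 3)))
  invisible(x)
}

# Large-particle sinking speed profile at given depths (m/day): constant
# w_large_surface above z_sink_ref, then increasing linearly to w_large_deep
# over the following 2000 m.
w_large_at <- function(z, params) {
  frac <- pmin(1, pmax(0, (z - params$z_sink_ref) / 2000))
  params$w_large_surface + (params$w_large_deep - params$w_large_surface) * frac
}
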