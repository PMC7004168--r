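# Independent oracles and small fixture builders used across the suite.

# Bisection on the scalar mass-balance residual
# f(CuL) = K (DCu - CuL) (L - CuL) - CuL, bracketing [0, min(DCu, L)].
# Deliberately independent of the closed-form quadratic in the package.
bisect_speciation <- function(DCu, L_total, K_L, iter = 200L) {
  Kn <- K_L * 1e-9
  if (DCu == 0 || L_total == 0)
    return(list(CuL = 0, Cu_prime = DCu, L_free = L_total))
  f <- function(x) Kn * (DCu - x) * (L_total - x) - x
  lo <- 0
  hi <- min(DCu, L_total)
  for (k in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  cul <- (lo + hi) / 2
  list(CuL = cul, Cu_prime = DCu - cul, L_free = L_total - cul)
}

# Textbook correlation coefficient, written out (oracle for
# profile_linearity's R).
cor_textbook <- function(x, y) {
  xm <- sum(x) / length(x)
  ym <- sum(y) / length(y)
  sum((x - xm) * (y - ym)) /
    sqrt(sum((x - xm)^2) * sum((y - ym)^2))
}

# Small uniform test grid.
test_grid <- function(n = 10, depth = 100) {
  column_grid(n_levels = n, total_depth = depth, upper_depth = depth,
              upper_res = depth / n)
}

# Forcing with everything off except what is supplied.
quiet_forcing <- function(grid, ...) cu_forcing(grid, ...)
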