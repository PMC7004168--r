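# Tracers hosted by each sinking particle class.
.small_sinkers <- c("SCup", "pCuPart")
.large_sinkers <- c("SCug", "gCuPart")

# Precompute the implicit transport solvers for a fixed (grid, Kz, dt):
# - mixing: backward-Euler conservative diffusion, tridiagonal, inverted once;
# - sinking: backward-Euler flux-form first-order upwind per particle class,
#   lower bidiagonal, inverted once.
# Both operators are M-matrices, so their inverses are non-negative
# (monotone, positivity-preserving) and mass is conserved exactly in flux
# form: what leaves the bottom edge is the burial flux.
make_transport_operators <- function(grid, forcing, params, dt) {
  n <- grid$n_levels
  h <- grid$thickness
  ops <- list(dt = dt, n = n)

  # mixing
  if (n > 1L) {
    dzc <- diff(grid$z_centers)
    Kz_edge <- (forcing$Kz[-n] + forcing$Kz[-1]) / 2
    A <- diag(n)
    for (i in seq_len(n)) {
      if (i > 1L) {
        a <- dt * Kz_edge[i - 1] / (h[i] * dzc[i - 1])
        A[i, i - 1] <- A[i, i - 1] - a
        A[i, i] <- A[i, i] + a
      }
      if (i < n) {
        b <- dt * Kz_edge[i] / (h[i] * dzc[i])
        A[i, i + 1] <- A[i, i + 1] - b
        A[i, i] <- A[i, i] + b
      }
    }
    ops$mix <- solve(A)
  } else {
    ops$mix <- matrix(1, 1, 1)
  }

  # sinking (speeds evaluated at cell bottom edges)
  sink_op <- function(w_edge) {
    A <- diag(1 + dt * w_edge / h)
    if (n > 1L)
      A[cbind(2:n, 1:(n - 1))] <- -dt * w_edge[-n] / h[-1]
    list(M = solve(A), w_bottom = w_edge[n])
  }
  z_bot <- grid$z_edges[-1]
  ops$sink_small <- sink_op(rep(params$w_small, n))
  ops$sink_large <- sink_op(w_large_at(z_bot, params))
  ops$w_small_edge <- rep(params$w_small, n)
  ops$w_large_edge <- w_large_at(z_bot, params)
  ops
}

#' Advance the tracer state by one timestep
#'
#' Operator-split step: explicit flux-limited local biogeochemical
#' tendencies, then particle sinking, then vertical mixing. Sinking and
#' mixing use implicit (backward-Euler) conservative solvers by default, so
#' the step is unconditionally stable, positivity-preserving, and
#' deterministic; with `sinking_scheme = "explicit"` a first-order explicit
#' upwind step is taken instead and the advective CFL condition
#' `max(w) * dt <= min(thickness)` is enforced.
#'
#' @param state A [cu_state()].
#' @param forcing A [cu_forcing()] on the same grid.
#' @param params A [cu_params()].
#' @param grid A [column_grid()].
#' @param dt Timestep, days. `dt = 0` returns the state unchanged.
#' @param ops Precomputed transport operators (internal; built automatically
#'   when `NULL`). Reuse across steps for speed.
#' @param sinking_scheme `"implicit"` (default) or `"explicit"`.
#' @return A list: `state` (updated [cu_state()]), and the step's
#'   area-specific mass-ledger entries in nmol/m2: `external_in` and
#'   `burial`.
#' @examples
#' g <- column_grid(n_levels = 5, total_depth = 100)
#' st <- cu_state(g, DCu = 0.5)
#' step(st, cu_forcing(g), cu_params(), g, dt = 0)$state   # unchanged
#' @export
step <- function(state, forcing, params, grid, dt, ops = NULL,
                 sinking_scheme = c("implicit", "explicit")) {
  sinking_scheme <- match.arg(sinking_scheme)
  if (dt < 0) stop("'dt' must be >= 0", call. = FALSE)
  if (dt == 0)
    return(list(state = state, external_in = 0, burial = 0))
  if (is.null(ops)) ops <- make_transport_operators(grid, forcing, params, dt)
  h <- grid$thickness
  if (sinking_scheme == "explicit") {
    wmax <- max(ops$w_small_edge, ops$w_large_edge)
    if (wmax * dt > min(h) * (1 + 1e-12))
      stop(sprintf(paste0("CFL violation: dt = %g day exceeds the explicit ",
                          "sinking limit min(thickness)/max(w) = %g day"),
                   dt, min(h) / wmax), call. = FALSE)
  }

  # local biogeochemistry (flux-limited explicit Euler)
  fl <- cu_process_fluxes(state, forcing, params, grid, dt = dt)
  s <- unclass(state) + dt * assemble_tendencies(fl)
  external_in <- sum(fl$ext * h) * 1000 * dt

  # sinking
  burial <- 0
  n <- grid$n_levels
  if (sinking_scheme == "implicit") {
    s[, .small_sinkers] <- ops$sink_small$M %*% s[, .small_sinkers]
    s[, .large_sinkers] <- ops$sink_large$M %*% s[, .large_sinkers]
    burial <- dt * 1000 *
      (ops$sink_small$w_bottom * sum(s[n, .small_sinkers]) +
       ops$sink_large$w_bottom * sum(s[n, .large_sinkers]))
  } else {
    adv <- function(cols, w_edge) {
      flux <- w_edge * s[, cols, drop = FALSE]   # downward, at bottom edges
      inflow <- rbind(0, flux[-n, , drop = FALSE])
      s[, cols] <<- s[, cols] + dt / h * (inflow - flux)
      burial <<- burial + dt * 1000 * sum(flux[n, ])
    }
    adv(.small_sinkers, ops$w_small_edge)
    adv(.large_sinkers, ops$w_large_edge)
  }

  # mixing (all tracers)
  if (n > 1L) s <- ops$mix %*% s
  s[s < 0] <- 0  # round-off guard; implicit operators are monotone
  colnames(s) <- cu_tracers
  list(state = as_cu_state(s), external_in = external_in, burial = burial)
}

#' Downward copper sinking flux at a depth
#'
#' Particulate copper flux carried past depth `z` by both particle classes,
#' using the upwind (overlying) cell's concentrations. At the bottom edge
#' this is the burial flux.
#'
#' @param z Depth, m (positive downward).
#' @param state A [cu_state()].
#' @param params A [cu_params()].
#' @param grid A [column_grid()].
#' @return Downward flux, nmol m-2 day-1.
#' @export
sinking_flux_at <- function(z, state, params, grid) {
  if (z < 0 || z > max(grid$z_edges))
    stop("'z' must lie within the column", call. = FALSE)
  i <- min(max(findInterval(z, grid$z_edges, left.open = TRUE), 1L),
           grid$n_levels)
  s <- unclass(state)
  unname(1000 * (params$w_small * (s[i, "SCup"] + s[i, "pCuPart"]) +
                 w_large_at(z, params) * (s[i, "SCug"] + s[i, "gCuPart"])))
}

#' Integrate the column to steady state
#'
#' Steps the tracer system with steady forcing until the annual-mean
#' tendencies become negligible or `max_years` elapse. Convergence is
#' declared when, for every tracer, the change of the annual-mean column-mean
#' concentration between consecutive years, expressed as a daily rate
#' relative to the concentration itself, drops below `tol`.
#'
#' @param state Initial [cu_state()].
#' @param forcing A [cu_forcing()] (held constant in time).
#' @param params A [cu_params()].
#' @param grid A [column_grid()].
#' @param dt Timestep, days. Default 0.25.
#' @param max_years Integration cap, years (365 days each). Default 200.
#' @param tol Convergence tolerance on the relative annual-mean tendency,
#'   1/day. Default 1e-5.
#' @param sinking_scheme Passed to [step()].
#' @return An object of class `cu_run`: list with `state` (final
#'   [cu_state()]), `time_series` (data frame of annual-mean column-mean
#'   concentrations per tracer, nmol/L), `converged`, `years_run`, `ledger`
#'   (nmol/m2: `inventory_initial`, `inventory_final`, `external_in`,
#'   `burial`, `drift` = closure residual), plus the `grid`, `forcing`,
#'   `params` and `dt` used.
#' @examples
#' g <- column_grid(n_levels = 4, total_depth = 200)
#' r <- run_to_steady_state(cu_state(g, DCu = 0.5), cu_forcing(g),
#'                          cu_params(), g, dt = 0.5, max_years = 2)
#' r$ledger$drift   # ~ 0: closed column conserves mass
#' @export
run_to_steady_state <- function(state, forcing, params, grid, dt = 0.25,
                                max_years = 200, tol = 1e-5,
                                sinking_scheme = c("implicit", "explicit")) {
  sinking_scheme <- match.arg(sinking_scheme)
  if (dt <= 0) stop("'dt' must be > 0", call. = FALSE)
  ops <- make_transport_operators(grid, forcing, params, dt)
  if (sinking_scheme == "explicit") {
    wmax <- max(ops$w_small_edge, ops$w_large_edge)
    if (wmax * dt > min(grid$thickness) * (1 + 1e-12))
      stop(sprintf(paste0("CFL violation: dt = %g day exceeds the explicit ",
                          "sinking limit min(thickness)/max(w) = %g day"),
                   dt, min(grid$thickness) / wmax), call. = FALSE)
  }
  steps_per_year <- max(1L, as.integer(round(365 / dt)))
  h1000 <- 1000 * grid$thickness
  H <- sum(grid$thickness)
  inv0 <- sum(state_inventory(state, grid))

  external_in <- burial <- 0
  converged <- FALSE
  prev_mean <- NULL
  ts <- vector("list", max_years)
  yr <- 0L
  while (yr < max_years) {
    yr <- yr + 1L
    acc <- numeric(length(cu_tracers))
    for (k in seq_len(steps_per_year)) {
      st <- step(state, forcing, params, grid, dt, ops, sinking_scheme)
      state <- st$state
      external_in <- external_in + st$external_in
      burial <- burial + st$burial
      acc <- acc + colSums(unclass(state) * h1000)
    }
    ann_mean <- acc / (steps_per_year * H * 1000)   # nmol/L column mean
    ts[[yr]] <- ann_mean
    if (!is.null(prev_mean)) {
      rel_rate <- abs(ann_mean - prev_mean) / 365 / (ann_mean + 1e-12)
      if (max(rel_rate) < tol) converged <- TRUE
    }
    prev_mean <- ann_mean
    if (converged) break
  }

  invF <- sum(state_inventory(state, grid))
  ts <- do.call(rbind, ts[seq_len(yr)])
  colnames(ts) <- cu_tracers
  structure(list(
    state = state,
    time_series = data.frame(year = seq_len(yr), ts, check.names = FALSE),
    converged = converged,
    years_run = yr,
    ledger = list(inventory_initial = inv0, inventory_final = invF,
                  external_in = external_in, burial = burial,
                  drift = (invF - inv0) - (external_in - burial)),
    grid = grid, forcing = forcing, params = params, dt = dt),
    class = "cu_run")
}
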