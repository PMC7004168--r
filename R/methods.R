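#' @export
print.cu_run <- function(x, ...) {
  cat(sprintf("Cu column run: %d levels, %d years (dt = %g day), %s\n",
              x$grid$n_levels, x$years_run, x$dt,
              if (x$converged) "converged" else "max_years reached"))
  cat(sprintf("  column-mean DCu %.3g nmol/L; ledger closure %.2e (relative)\n",
              utils::tail(x$time_series$DCu, 1),
              abs(x$ledger$drift) / max(x$ledger$inventory_final, 1e-300)))
  invisible(x)
}

#' @export
summary.cu_run <- function(object, ...) {
  s <- unclass(object$state)
  g <- object$grid
  lin <- profile_linearity(s[, "DCu"], g$z_centers,
                           window = c(200, max(g$z_centers)))
  out <- list(
    n_levels = g$n_levels,
    years_run = object$years_run,
    converged = object$converged,
    surface_DCu = mean(s[g$z_centers <= 50, "DCu"]),
    deep_DCu = mean(s[g$z_centers >= 1000 & g$z_centers <= 4000, "DCu"]),
    linearity = lin,
    ledger = object$ledger)
  class(out) <- "summary.cu_run"
  out
}

#' @export
print.summary.cu_run <- function(x, ...) {
  cat(sprintf("Cu column run summary (%d levels, %d years, %s)\n",
              x$n_levels, x$years_run,
              if (x$converged) "converged" else "not converged"))
  cat(sprintf("  DCu: %.3g nmol/L (0-50 m mean), %.3g nmol/L (1000-4000 m mean)\n",
              x$surface_DCu, x$deep_DCu))
  cat(sprintf("  sub-euphotic linearity: R = %.3f, slope = %.3g nmol/L per m\n",
              x$linearity$R, x$linearity$slope))
  cat(sprintf("  mass ledger: in %.4g, buried %.4g, drift %.3g nmol/m2\n",
              x$ledger$external_in, x$ledger$burial, x$ledger$drift))
  invisible(x)
}

#' Plot tracer profiles of a run
#'
#' Depth profiles of the final state (depth increasing downward) for a
#' chosen set of tracers.
#'
#' @param x A `cu_run`.
#' @param tracers Tracer names to draw; default `"DCu"`.
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, `x`.
#' @export
plot.cu_run <- function(x, tracers = "DCu", ...) {
  s <- unclass(x$state)[, tracers, drop = FALSE]
  graphics::matplot(s, x$grid$z_centers, type = "l", lty = 1,
                    ylim = rev(range(x$grid$z_centers)),
                    xlab = "concentration (nmol/L)", ylab = "depth (m)", ...)
  if (length(tracers) > 1L)
    graphics::legend("bottomright", legend = tracers, lty = 1,
                     col = seq_along(tracers))
  invisible(x)
}
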