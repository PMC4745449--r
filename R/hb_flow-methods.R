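#' @export
print.hb_flow <- function(x, ...) {
  cat("Herschel-Bulkley vessel flow solution (", x$method, " pressure gradient)\n",
      sep = "")
  print(x$fluid)
  cat(sprintf("Prescribed flow rate Q = %g; %d axial stations on [0, %g]\n",
              x$Q, length(x$z), x$geometry$total_length))
  cat(sprintf("Total flow resistance lambda(L) = %.4f\n",
              x$lambda[length(x$lambda)]))
  invisible(x)
}

#' @export
summary.hb_flow <- function(object, ...) {
  imax <- which.max(object$tau_w)
  imin <- which.min(object$tau_w)
  out <- list(
    method = object$method, fluid = object$fluid, Q = object$Q,
    n_stations = length(object$z),
    L = object$geometry$total_length,
    q_range = range(object$q),
    tau_w_max = object$tau_w[imax], z_tau_max = object$z[imax],
    tau_w_min = object$tau_w[imin], z_tau_min = object$z[imin],
    plug_radius_range = range(object$plug_radius),
    lambda_total = object$lambda[length(object$lambda)])
  class(out) <- "summary.hb_flow"
  out
}

#' @export
print.summary.hb_flow <- function(x, ...) {
  cat("Steady Herschel-Bulkley flow through a tapered vessel\n")
  print(x$fluid)
  cat(sprintf("Q = %g, method = %s, %d stations on [0, %g]\n",
              x$Q, x$method, x$n_stations, x$L))
  cat(sprintf("Pressure gradient q:  %.4f .. %.4f\n",
              x$q_range[1], x$q_range[2]))
  cat(sprintf("Wall shear stress:    max %.4f at z = %.3f; min %.4f at z = %.3f\n",
              x$tau_w_max, x$z_tau_max, x$tau_w_min, x$z_tau_min))
  cat(sprintf("Plug-core radius:     %.5f .. %.5f\n",
              x$plug_radius_range[1], x$plug_radius_range[2]))
  cat(sprintf("Flow resistance lambda(0 -> L) = %.4f\n", x$lambda_total))
  invisible(x)
}

#' @export
coef.hb_flow <- function(object, ...) {
  c(n = object$fluid$n, k = object$fluid$k, tau_y = object$fluid$tau_y,
    Q = object$Q, zeta = object$geometry$zeta)
}

#' Evaluate a fitted flow solution at new axial positions
#'
#' Recomputes the local quantities exactly at the requested positions
#' (radius, pressure gradient, wall shear stress, plug radius) with the
#' same method as the fit; the cumulative resistance is interpolated
#' linearly from the fitted profile (its grid is dense by default, so the
#' interpolation error is far below the quadrature error).
#'
#' @param object An \code{\link{hb_flow}} fit.
#' @param z Axial positions within \eqn{[0, L]}; default the fit grid.
#' @param ... Unused.
#' @return A data frame with columns \code{z}, \code{R}, \code{q},
#'   \code{tau_w}, \code{plug_radius}, \code{lambda}.
#' @export
predict.hb_flow <- function(object, z = NULL, ...) {
  if (is.null(z))
    return(data.frame(z = object$z, R = object$R, q = object$q,
                      tau_w = object$tau_w,
                      plug_radius = object$plug_radius,
                      lambda = object$lambda))
  R <- vessel_radius(object$geometry, z)
  q <- if (object$method == "numerical")
    solve_pressure_gradient(R, object$Q, object$fluid)
  else q_analytical(R, object$Q, object$fluid, object$quad_coef)
  lam <- stats::approx(object$z, object$lambda, xout = z)$y
  data.frame(z = as.numeric(z), R = R, q = q, tau_w = R * q / 2,
             plug_radius = 2 * object$fluid$tau_y / q, lambda = lam)
}

#' Implicit-relation residuals of a fitted flow solution
#'
#' Residual of the exact flow-rate relation at each axial station,
#' normalised by its left-hand side. For a \code{"numerical"} fit these
#' are at solver tolerance (~1e-12); for an \code{"analytical"} fit they
#' measure the truncation error of the small-yield-stress expansion.
#'
#' @param object An \code{\link{hb_flow}} fit.
#' @param ... Unused.
#' @return Numeric vector of relative residuals, one per axial station.
#' @export
residuals.hb_flow <- function(object, ...) {
  f <- object$fluid
  flow_rate_residual(object$q, object$R, object$Q, f) /
    .eq_lhs(object$q, object$R, object$Q, f)
}

#' Plot axial profiles of a fitted flow solution
#'
#' Four stacked panels against axial distance: wall radius, pressure
#' gradient, wall shear stress and cumulative flow resistance.
#'
#' @param x An \code{\link{hb_flow}} fit.
#' @param ... Graphical parameters passed to \code{plot}.
#' @return \code{x}, invisibly.
#' @export
plot.hb_flow <- function(x, ...) {
  op <- graphics::par(mfrow = c(4, 1), mar = c(2.5, 4, 1, 1), mgp = c(2, 0.7, 0))
  on.exit(graphics::par(op))
  graphics::plot(x$z, x$R, type = "l", xlab = "z", ylab = "R(z)", ...)
  graphics::plot(x$z, x$q, type = "l", xlab = "z", ylab = "q(z)", ...)
  graphics::plot(x$z, x$tau_w, type = "l", xlab = "z",
                 ylab = expression(tau[w]), ...)
  graphics::plot(x$z, x$lambda, type = "l", xlab = "z",
                 ylab = expression(lambda), ...)
  invisible(x)
}
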