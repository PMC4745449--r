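#' Stream function of the local velocity profile
#'
#' Closed-form Stokes stream function \eqn{\psi(r) = \int_0^r r' w(r')\,dr'}
#' of the plug-core velocity profile, satisfying \eqn{w = (1/r)
#' \partial\psi/\partial r}, \eqn{\psi(0) = 0} and \eqn{\psi(R) = Q/2}
#' (mass conservation, since \eqn{Q = 2\int_0^R r w\,dr}). With
#' \eqn{m = (n+1)/n}, \eqn{s = R_p/R}, \eqn{u = r/R - s} and \eqn{A} as in
#' \code{\link{hb_velocity}}:
#' \deqn{\psi = w_p r^2/2, \quad r \le R_p,}
#' \deqn{\psi = w_p R_p^2/2 + A\Big[(1-s)^m \frac{r^2 - R_p^2}{2}
#'   - R^2\Big(\frac{n\,u^{(3n+1)/n}}{3n+1} +
#'             \frac{s\,n\,u^{(2n+1)/n}}{2n+1}\Big)\Big], \quad r > R_p.}
#'
#' @param r Radial position(s), \eqn{0 \le r \le R}. Vectorised.
#' @param R Local tube radius.
#' @param q Pressure gradient \eqn{-dp/dz > 0}.
#' @param fluid An \code{\link{hb_fluid}}.
#' @return Stream function value(s), same length as \code{r}.
#' @examples
#' # Newtonian: psi = r^2 - r^4/2, so psi(1) = 1/2 = Q/2
#' stream_function(c(0.5, 1), R = 1, q = 8, fluid = newtonian_fluid())
#' @export
stream_function <- function(r, R, q, fluid) {
  fluid <- as_hb_fluid(fluid)
  stopifnot(is.numeric(r), is.numeric(R), length(R) == 1L,
            is.numeric(q), length(q) == 1L, R > 0, q > 0)
  if (any(r < -1e-15) || any(r > R * (1 + 1e-12)))
    stop("r must lie within [0, R]")
  n <- fluid$n
  p <- .hb_profile(R, q, fluid)
  .check_flow(p$s)
  Rp <- p$s * R
  wp <- p$A * (1 - p$s)^p$m
  psi <- wp * pmin(r, Rp)^2 / 2
  sheared <- r > Rp
  if (any(sheared)) {
    u <- r[sheared] / R - p$s
    psi[sheared] <- wp * Rp^2 / 2 +
      p$A * ((1 - p$s)^p$m * (r[sheared]^2 - Rp^2) / 2 -
               R^2 * (n * u^((3 * n + 1) / n) / (3 * n + 1) +
                        p$s * n * u^((2 * n + 1) / n) / (2 * n + 1)))
  }
  psi
}

#' Radial velocity and stream-function profile at one station
#'
#' Solves for the local pressure gradient at axial position \code{z} and
#' evaluates the velocity and stream function on a radial grid from the
#' axis to the wall.
#'
#' @param geometry A \code{\link{vessel_geometry}}.
#' @param fluid An \code{\link{hb_fluid}}.
#' @param z Axial position.
#' @param Q Prescribed flow rate; default 1.
#' @param r_count Number of radial intervals; the grid has
#'   \code{r_count + 1} points. Default 100.
#' @param method Pressure-gradient method, as in \code{\link{hb_flow}}.
#' @return An object of class \code{"radial_field"}: list with \code{z},
#'   \code{R}, \code{q}, \code{plug_radius}, \code{r}, \code{w},
#'   \code{psi}.
#' @export
radial_field <- function(geometry, fluid, z, Q = 1, r_count = 100L,
                         method = c("numerical", "analytical")) {
  method <- match.arg(method)
  stopifnot(r_count >= 3L)
  fluid <- as_hb_fluid(fluid)
  R <- vessel_radius(geometry, z)
  q <- if (method == "numerical") solve_pressure_gradient(R, Q, fluid)
  else q_analytical(R, Q, fluid)
  r <- seq(0, R, length.out = r_count + 1L)
  structure(list(z = z, R = R, q = q,
                 plug_radius = 2 * fluid$tau_y / q,
                 r = r,
                 w = hb_velocity(r, R, q, fluid),
                 psi = stream_function(r, R, q, fluid)),
            class = "radial_field")
}

#' @export
print.radial_field <- function(x, ...) {
  cat(sprintf("Radial field at z = %g: R = %g, q = %.4f, R_p = %.5f, %d points\n",
              x$z, x$R, x$q, x$plug_radius, length(x$r)))
  cat(sprintf("  centreline w = %.4f, psi(wall) = %.6f\n",
              x$w[1L], x$psi[length(x$psi)]))
  invisible(x)
}

#' Gridded (z, r/R) velocity and stream-function field
#'
#' Builds the field behind streamline/contour plots: at each axial station
#' the local pressure gradient is solved, then velocity and stream function
#' are evaluated on a signed fractional-radius grid spanning \eqn{[-1, 1]}
#' (the negative half mirrors the positive one; no asymmetry is modelled).
#' The wall streamline carries \eqn{\psi = Q/2} at every station, so
#' closed contour levels can be drawn directly from \code{psi}.
#'
#' @param geometry A \code{\link{vessel_geometry}}.
#' @param fluid An \code{\link{hb_fluid}}.
#' @param z_grid Axial stations within \eqn{[0, L]}.
#' @param Q Prescribed flow rate; default 1.
#' @param r_count Radial half-grid resolution: the signed grid has
#'   \code{2*r_count + 1} points. Default 50.
#' @param method Pressure-gradient method, as in \code{\link{hb_flow}}.
#' @return An object of class \code{"hb_field_grid"}: list with
#'   \code{z}, \code{r_fraction} (signed \eqn{r/R}), \code{R}, \code{q},
#'   and matrices \code{w}, \code{psi} of dimension
#'   \code{length(z)} x \code{length(r_fraction)}.
#' @export
field_grid <- function(geometry, fluid, z_grid, Q = 1, r_count = 50L,
                       method = c("numerical", "analytical")) {
  method <- match.arg(method)
  stopifnot(r_count >= 3L, length(z_grid) >= 1L)
  fluid <- as_hb_fluid(fluid)
  rfrac <- seq(-1, 1, length.out = 2L * r_count + 1L)
  R <- vessel_radius(geometry, z_grid)
  q <- if (method == "numerical") solve_pressure_gradient(R, Q, fluid)
  else q_analytical(R, Q, fluid)
  w <- matrix(NA_real_, length(z_grid), length(rfrac))
  psi <- matrix(NA_real_, length(z_grid), length(rfrac))
  for (i in seq_along(z_grid)) {
    r_half <- abs(rfrac) * R[i]
    w[i, ] <- hb_velocity(r_half, R[i], q[i], fluid)
    psi[i, ] <- stream_function(r_half, R[i], q[i], fluid)
  }
  structure(list(z = as.numeric(z_grid), r_fraction = rfrac, R = R, q = q,
                 w = w, psi = psi, Q = Q, fluid = fluid, method = method),
            class = "hb_field_grid")
}

#' @export
print.hb_field_grid <- function(x, ...) {
  cat(sprintf("Velocity/stream-function field: %d x %d (z x r/R) grid\n",
              length(x$z), length(x$r_fraction)))
  cat(sprintf("  z in [%g, %g]; psi(wall) = Q/2 = %g\n",
              min(x$z), max(x$z), x$Q / 2))
  invisible(x)
}

#' Streamline contour plot of a field grid
#'
#' Draws filled stream-function contours over (z, signed r/R), the view
#' used to compare stenotic and dilated stretches.
#'
#' @param x An \code{\link{field_grid}} result.
#' @param nlevels Number of contour levels; default 15.
#' @param ... Passed to \code{\link[graphics]{contour}}.
#' @return \code{x}, invisibly.
#' @export
plot.hb_field_grid <- function(x, nlevels = 15, ...) {
  graphics::contour(x$z, x$r_fraction, x$psi, nlevels = nlevels,
                    xlab = "z", ylab = "r/R", ...)
  invisible(x)
}
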