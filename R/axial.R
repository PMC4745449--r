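# --- composite-Simpson machinery -------------------------------------------
#
# The resistance integrand q(z)/Q is continuous but has a kinked derivative
# at segment boundaries, so every integral is split there and each smooth
# piece gets its own uniform Simpson grid (even interval count).

# uniform grid over [z0, z1] with an even number of intervals of size ~ dz
.piece_grid <- function(z0, z1, dz) {
  nint <- max(2L, 2L * ceiling((z1 - z0) / (2 * dz)))
  seq(z0, z1, length.out = nint + 1L)
}

# breakpoints of smooth stretches intersected with [z0, z1]
.smooth_breaks <- function(geometry, z0, z1) {
  b <- as.vector(t(geometry$bounds))
  br <- sort(unique(c(z0, b[b > z0 + 1e-12 & b < z1 - 1e-12], z1)))
  br
}

# cumulative integral at every node of a uniform grid, exact for cubics on
# each interval pair (endpoint rule of the fitted parabola); the value at
# pair boundaries coincides with composite Simpson
.cumsimpson <- function(z, f) {
  m <- length(z) - 1L
  stopifnot(m >= 2L, m %% 2L == 0L)
  h <- (z[length(z)] - z[1L]) / m
  out <- numeric(length(z))
  idx <- seq(1L, m - 1L, by = 2L)           # start of each interval pair
  f0 <- f[idx]; f1 <- f[idx + 1L]; f2 <- f[idx + 2L]
  first <- h / 12 * (5 * f0 + 8 * f1 - f2)  # integral over first interval
  second <- h / 12 * (-f0 + 8 * f1 + 5 * f2)
  inc <- numeric(m)
  inc[idx] <- first
  inc[idx + 1L] <- second
  out[-1L] <- cumsum(inc)
  out
}

# --- model fit ---------------------------------------------------------------

#' Fit the axial flow solution over a vessel
#'
#' Solves the steady Herschel-Bulkley flow problem along the whole vessel
#' for a prescribed flow rate: at every axial station the local pressure
#' gradient \eqn{q(z)} is obtained either by Newton-Raphson solution of the
#' implicit flow-rate relation (\code{method = "numerical"}, exact) or from
#' the small-yield-stress expansion (\code{method = "analytical"}). Wall
#' shear stress follows as \eqn{\tau_w = Rq/2} and the cumulative flow
#' resistance as \eqn{\lambda(z) = \int_0^z q(z')/Q\,dz'} by composite
#' Simpson quadrature with the grid split at segment boundaries (where the
#' integrand's derivative is kinked).
#'
#' @param geometry A \code{\link{vessel_geometry}}.
#' @param fluid An \code{\link{hb_fluid}}.
#' @param Q Prescribed flow rate (per \eqn{\pi}); default 1.
#' @param method \code{"numerical"} (implicit-relation root) or
#'   \code{"analytical"} (small-\eqn{\tau_y} expansion).
#' @param dz Target axial grid spacing; default 0.001 (7001 stations on
#'   the default length-7 vessel).
#' @param quad_coef Quadratic-coefficient function passed to
#'   \code{\link{q_analytical}} when \code{method = "analytical"}.
#' @return An object of class \code{"hb_flow"}: a list with the aligned
#'   axial profiles \code{z}, \code{R}, \code{q}, \code{tau_w},
#'   \code{lambda}, plus \code{plug_radius}, the inputs and the call.
#'   Supports \code{print}, \code{summary}, \code{coef}, \code{predict},
#'   \code{residuals} and \code{plot}.
#' @examples
#' fit <- hb_flow(default_geometry(), hb_fluid(0.8, 1.2, 0.1), dz = 0.01)
#' summary(fit)
#' @export
hb_flow <- function(geometry, fluid, Q = 1,
                    method = c("numerical", "analytical"),
                    dz = 0.001, quad_coef = hb_quadratic_coef) {
  method <- match.arg(method)
  stopifnot(inherits(geometry, "vessel_geometry"))
  fluid <- as_hb_fluid(fluid)
  if (!(is.numeric(Q) && length(Q) == 1L && Q > 0))
    stop("'Q' must be a positive scalar")
  if (!(is.numeric(dz) && dz > 0)) stop("'dz' must be positive")

  br <- .smooth_breaks(geometry, 0, geometry$total_length)
  zs <- lapply(seq_len(length(br) - 1L),
               function(i) .piece_grid(br[i], br[i + 1L], dz))

  solve_piece <- function(z) {
    R <- vessel_radius(geometry, z)
    q <- tryCatch(
      if (method == "numerical") solve_pressure_gradient(R, Q, fluid)
      else q_analytical(R, Q, fluid, quad_coef),
      error = function(e) stop("at z in [", min(z), ", ", max(z), "]: ",
                               conditionMessage(e), call. = FALSE))
    rp <- 2 * fluid$tau_y / q
    if (any(rp >= R))
      stop("no-flow (full plug) at z = ", z[which(rp >= R)[1L]])
    list(z = z, R = R, q = q, lam = .cumsimpson(z, q / Q))
  }
  pieces <- lapply(zs, solve_piece)

  # concatenate, dropping duplicated breakpoints, accumulating lambda
  z <- pieces[[1L]]$z; R <- pieces[[1L]]$R; q <- pieces[[1L]]$q
  lam <- pieces[[1L]]$lam
  for (p in pieces[-1L]) {
    off <- lam[length(lam)]
    z <- c(z, p$z[-1L]); R <- c(R, p$R[-1L]); q <- c(q, p$q[-1L])
    lam <- c(lam, off + p$lam[-1L])
  }

  structure(list(z = z, R = R, q = q, tau_w = R * q / 2, lambda = lam,
                 plug_radius = 2 * fluid$tau_y / q,
                 method = method, fluid = fluid, geometry = geometry,
                 Q = Q, dz = dz, quad_coef = quad_coef,
                 call = match.call()),
            class = "hb_flow")
}

#' Cumulative flow resistance
#'
#' Resistance to flow accumulated from the inlet,
#' \eqn{\lambda(z_{end}) = \int_0^{z_{end}} q(z)/Q\,dz}, by composite
#' Simpson quadrature split at segment boundaries. With
#' \code{method = "numerical"} the integrand uses the exact implicit-root
#' pressure gradient; with \code{"analytical"} the expansion is integrated
#' term by term as
#' \eqn{a\int R^{-(3n+1)} + b\int R^{-1} + c\int R^{3n-1}} with
#' \eqn{a = 2k((3n+1)/n)^n Q^{n-1}},
#' \eqn{b = 2(3n+1)\tau_y/((2n+1)Q)} and
#' \eqn{c = C(n)\,n^n \tau_y^2/(2k(3n+1)^n Q^{n+1})}.
#'
#' @param geometry A \code{\link{vessel_geometry}}.
#' @param fluid An \code{\link{hb_fluid}}.
#' @param Q Prescribed flow rate; default 1.
#' @param z_end Upper integration limit; default the full length \eqn{L}.
#' @param z_start Lower integration limit; default 0.
#' @param method \code{"numerical"} or \code{"analytical"}.
#' @param dz Target quadrature spacing; default 0.001.
#' @param quad_coef Quadratic-coefficient function (analytical mode).
#' @return Nonnegative scalar resistance.
#' @examples
#' # straight Newtonian tube of unit length: lambda = 8kL
#' flow_resistance(vessel_geometry(0, list(), 1), newtonian_fluid())
#' @export
flow_resistance <- function(geometry, fluid, Q = 1, z_end = NULL,
                            z_start = 0,
                            method = c("numerical", "analytical"),
                            dz = 0.001, quad_coef = hb_quadratic_coef) {
  method <- match.arg(method)
  stopifnot(inherits(geometry, "vessel_geometry"))
  fluid <- as_hb_fluid(fluid)
  if (is.null(z_end)) z_end <- geometry$total_length
  if (!(z_start >= 0 && z_end <= geometry$total_length + 1e-12 &&
        z_start <= z_end))
    stop("need 0 <= z_start <= z_end <= L")
  if (z_end == z_start) return(0)

  n <- fluid$n; ty <- fluid$tau_y
  integrand <- if (method == "numerical") {
    function(z) solve_pressure_gradient(vessel_radius(geometry, z),
                                        Q, fluid) / Q
  } else {
    a <- 2 * fluid$k * ((3 * n + 1) / n)^n * Q^(n - 1)
    b <- 2 * (3 * n + 1) * ty / ((2 * n + 1) * Q)
    cc <- quad_coef(n) * n^n * ty^2 /
      (2 * fluid$k * (3 * n + 1)^n * Q^(n + 1))
    function(z) {
      R <- vessel_radius(geometry, z)
      a * R^(-(3 * n + 1)) + b / R + cc * R^(3 * n - 1)
    }
  }

  br <- .smooth_breaks(geometry, z_start, z_end)
  total <- 0
  for (i in seq_len(length(br) - 1L)) {
    z <- .piece_grid(br[i], br[i + 1L], dz)
    f <- integrand(z)
    cs <- .cumsimpson(z, f)
    total <- total + cs[length(cs)]
  }
  total
}
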