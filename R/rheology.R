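#' Plug-core radius
#'
#' Radius \eqn{R_p = 2\tau_y/q} of the central rigid plug, inside which the
#' shear stress falls below the yield stress. Flow exists only while
#' \eqn{R_p < R}; callers comparing against the local radius should treat
#' \eqn{R_p \ge R} as a no-flow state.
#'
#' @param q Local pressure gradient \eqn{q = -dp/dz > 0}. Vectorised.
#' @param fluid An \code{\link{hb_fluid}}.
#' @return Nonnegative plug radius, same length as \code{q}.
#' @export
plug_radius <- function(q, fluid) {
  fluid <- as_hb_fluid(fluid)
  stopifnot(is.numeric(q))
  if (any(q <= 0)) stop("pressure gradient 'q' must be positive")
  2 * fluid$tau_y / q
}

# shared velocity-profile pieces: m = (n+1)/n, A = n/(n+1) (q/2k)^{1/n} R^m,
# s = R_p/R = tau_y/tau_w
.hb_profile <- function(R, q, fluid) {
  n <- fluid$n
  m <- (n + 1) / n
  s <- 2 * fluid$tau_y / (q * R)
  list(m = m, s = s,
       A = n / (n + 1) * (q / (2 * fluid$k))^(1 / n) * R^m)
}

.check_flow <- function(s) {
  if (any(s >= 1))
    stop("no-flow: yield stress not exceeded at the wall (plug radius >= R)")
}

#' Axial velocity profile
#'
#' Exact velocity of steady Herschel-Bulkley tube flow at local radius
#' \eqn{R} under pressure gradient \eqn{q}: with \eqn{m = (n+1)/n},
#' \eqn{s = R_p/R} and \eqn{A = \frac{n}{n+1} (q/2k)^{1/n} R^m},
#' \deqn{w(r) = A[(1-s)^m - (r/R - s)^m], \quad r \ge R_p,}
#' and the constant plug value \eqn{w_p = A(1-s)^m} for \eqn{r < R_p}.
#' Satisfies no slip, \eqn{w(R) = 0}.
#'
#' @param r Radial position(s), \eqn{0 \le r \le R}. Vectorised.
#' @param R Local tube radius.
#' @param q Pressure gradient \eqn{-dp/dz > 0}.
#' @param fluid An \code{\link{hb_fluid}}.
#' @return Axial velocity, same length as \code{r}.
#' @examples
#' # Newtonian Poiseuille flow: w = 2(1 - r^2) for q = 8, R = 1, k = 1
#' hb_velocity(c(0, 0.5, 1), R = 1, q = 8, fluid = newtonian_fluid())
#' @export
hb_velocity <- function(r, R, q, fluid) {
  fluid <- as_hb_fluid(fluid)
  stopifnot(is.numeric(r), is.numeric(R), length(R) == 1L,
            is.numeric(q), length(q) == 1L, R > 0, q > 0)
  if (any(r < -1e-15) || any(r > R * (1 + 1e-12)))
    stop("r must lie within [0, R]")
  p <- .hb_profile(R, q, fluid)
  .check_flow(p$s)
  u <- pmax(r / R - p$s, 0)          # plug region collapses to u = 0
  p$A * ((1 - p$s)^p$m - u^p$m)
}

#' Flow rate for a given pressure gradient
#'
#' Exact Herschel-Bulkley flow-rate relation,
#' \deqn{Q = \frac{n R^3}{3n+1} \Big(\frac{qR}{2k}\Big)^{1/n} (1-s)^{(n+1)/n}
#'   \Big[1 + \frac{2n}{2n+1}s + \frac{2n^2}{(2n+1)(n+1)}s^2\Big],}
#' with \eqn{s = R_p/R = \tau_y/\tau_w}. \eqn{Q} is the volumetric rate per
#' \eqn{\pi} (i.e. \eqn{Q = 2\int_0^R r\,w\,dr}). The \eqn{n = 1} case is
#' the Buckingham-Reiner relation; \eqn{\tau_y = 0} gives the power-law
#' closed form \eqn{Q = \frac{nR^3}{3n+1}(qR/2k)^{1/n}}.
#'
#' @param q Pressure gradient \eqn{-dp/dz > 0}. Vectorised with \code{R}.
#' @param R Local tube radius.
#' @param fluid An \code{\link{hb_fluid}}.
#' @return Flow rate (per \eqn{\pi}).
#' @examples
#' hb_flow_rate(8, 1, newtonian_fluid())  # q R^4 / 8k = 1
#' @export
hb_flow_rate <- function(q, R, fluid) {
  fluid <- as_hb_fluid(fluid)
  stopifnot(is.numeric(q), is.numeric(R), all(q > 0), all(R > 0))
  n <- fluid$n
  s <- 2 * fluid$tau_y / (q * R)
  .check_flow(s)
  (n * R^3 / (3 * n + 1)) * (q * R / (2 * fluid$k))^(1 / n) *
    (1 - s)^((n + 1) / n) *
    (1 + 2 * n / (2 * n + 1) * s +
       2 * n^2 / ((2 * n + 1) * (n + 1)) * s^2)
}

#' Wall shear stress
#'
#' Stress exerted on the wall by the flow, \eqn{\tau_w = Rq/2} — the exact
#' stress balance of locally fully developed tube flow, independent of the
#' constitutive law.
#'
#' @param q Pressure gradient \eqn{-dp/dz > 0}. Vectorised.
#' @param R Local tube radius. Vectorised.
#' @return Wall shear stress \eqn{Rq/2}.
#' @export
wall_shear_stress <- function(q, R) {
  stopifnot(is.numeric(q), is.numeric(R))
  if (any(q <= 0) || any(R <= 0)) stop("'q' and 'R' must be positive")
  R * q / 2
}
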